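# Low-level voxel geometry shared by the phantom and bullseye modules.

# Voxel-centre coordinates (mm) for a 3D grid, origin at the grid centre.
grid_coords_mm <- function(dim, voxel_size) {
  stopifnot(length(dim) == 3L, length(voxel_size) == 3L)
  centre <- (dim + 1) / 2
  lapply(1:3, function(a) (seq_len(dim[a]) - centre[a]) * voxel_size[a])
}

# index (i,j,k) matrix for TRUE voxels of a logical 3D array
mask_ijk <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# mm coordinates of mask voxels (n x 3), origin at grid centre
mask_coords_mm <- function(mask, voxel_size) {
  ijk <- mask_ijk(mask)
  centre <- (dim(mask) + 1) / 2
  sweep(sweep(ijk, 2, centre, "-"), 2, voxel_size, "*")
}

# Exact distance (mm) from each row of `pts` to the nearest row of `surf`,
# computed in chunks through BLAS so that no n_pts x n_surf matrix is ever
# fully materialized. Both are n x 3 matrices in mm.
nearest_surface_distance <- function(pts, surf, chunk = 1024L) {
  if (nrow(surf) == 0L) {
    rlang::abort("surface point set is empty")
  }
  s2 <- rowSums(surf^2)
  out <- numeric(nrow(pts))
  idx <- seq_len(nrow(pts))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, nrow(pts))]
    p <- pts[sel, , drop = FALSE]
    d2 <- outer(rowSums(p^2), s2, "+") - 2 * tcrossprod(p, surf)
    out[sel] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Voxels of `mask` that touch (6-connectivity) a voxel of `other`.
touching_voxels <- function(mask, other) {
  d <- dim(mask)
  shifted <- array(FALSE, d)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      idx_from <- lapply(d, seq_len)
      idx_to <- idx_from
      if (s == 1L) {
        idx_from[[a]] <- 2:d[a]; idx_to[[a]] <- 1:(d[a] - 1L)
      } else {
        idx_from[[a]] <- 1:(d[a] - 1L); idx_to[[a]] <- 2:d[a]
      }
      sub <- do.call(`[`, c(list(other), idx_from))
      tmp <- array(FALSE, d)
      tmp <- do.call(`[<-`, c(list(tmp), idx_to, list(sub)))
      shifted <- shifted | tmp
    }
  }
  mask & shifted
}

# Separable Gaussian blur of a 3D array; sigma_mm scalar, voxel_size length-3.
# Kernel truncated at 3 sigma; edges renormalized by blurring a ones-array.
gaussian_blur3d <- function(x, sigma_mm, voxel_size) {
  if (sigma_mm <= 0) return(x)
  blur_axis <- function(arr, axis) {
    sigma_vox <- sigma_mm / voxel_size[axis]
    r <- max(1L, ceiling(3 * sigma_vox))
    k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
    k <- k / sum(k)
    n <- dim(arr)[axis]
    # band matrix applying the truncated kernel along one axis
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[off + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    res <- array(m, dp)
    aperm(res, order(perm))
  }
  for (a in 1:3) x <- blur_axis(x, a)
  x
}

# 26-connected components of a sparse voxel set on a 3D grid.
# `ijk`: n x 3 integer matrix of voxel indices. Returns integer component
# labels (1..k) in the order of the input rows.
connected_components_26 <- function(ijk, dim) {
  n <- nrow(ijk)
  if (n == 0L) return(integer(0))
  key <- (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dim[1] &
      nb[, 2] >= 1L & nb[, 2] <= dim[2] &
      nb[, 3] >= 1L & nb[, 3] <= dim[3]
    nb_key <- (nb[, 3] - 1L) * dim[1] * dim[2] + (nb[, 2] - 1L) * dim[1] + nb[, 1]
    hit <- match(nb_key, key)
    sel <- ok & !is.na(hit)
    if (any(sel)) {
      edges[[length(edges) + 1L]] <- cbind(which(sel), hit[sel])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    e <- e[e[, 1] < e[, 2], , drop = FALSE]
    g <- igraph::add_edges(g, t(e))
  }
  igraph::components(g)$membership
}
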