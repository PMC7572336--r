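# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops, separate from the package's vectorized implementations.

# small, fast phantom used where full default size is unnecessary
small_phantom_spec <- function(lesion_count = 3L, ...) {
  phantom_spec(
    grid_shape = c(40L, 40L, 40L),
    brain_axes = c(17, 14.5, 14.5),
    ventricle_axes = c(7, 4.5, 4.5),
    cortex_thickness = 2.5,
    bg_offset = 10, bg_axes = c(3.8, 3.3, 3.3),
    lesion_count = lesion_count,
    ...
  )
}

# nested-box toy geometry on a cubic grid: ventricle slab, WM slab, cortex
# slab along the first axis; returns the three masks
toy_box_masks <- function(n = 32L, vent_to = 6L, wm_to = 24L, cortex_to = 28L) {
  vent <- array(FALSE, c(n, n, n))
  wm <- array(FALSE, c(n, n, n))
  cortex <- array(FALSE, c(n, n, n))
  mid <- 5:(n - 4)
  vent[1:vent_to, mid, mid] <- TRUE
  wm[(vent_to + 1):wm_to, mid, mid] <- TRUE
  cortex[(wm_to + 1):cortex_to, mid, mid] <- TRUE
  list(vent = vent, wm = wm, cortex = cortex)
}

# brute-force normalized depth: per-voxel loop over every surface voxel
oracle_depth <- function(vent, cortex, wm, voxel_size = c(1, 1, 1)) {
  vi <- which(vent, arr.ind = TRUE)
  ci <- which(cortex, arr.ind = TRUE)
  wi <- which(wm, arr.ind = TRUE)
  vox <- min(voxel_size)
  depth <- array(NA_real_, dim(wm))
  for (r in seq_len(nrow(wi))) {
    p <- wi[r, ] * voxel_size
    dv <- max(sqrt(min(colSums((t(vi) * voxel_size - p)^2))) - vox, 0)
    dc <- max(sqrt(min(colSums((t(ci) * voxel_size - p)^2))) - vox, 0)
    depth[wi[r, , drop = FALSE]] <- dv / (dv + dc)
  }
  depth
}

# brute-force 26-connected flood fill labelling of a logical array
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  key <- function(v) paste(v, collapse = ",")
  remaining <- new.env()
  for (r in seq_len(nrow(idx))) assign(key(idx[r, ]), idx[r, ], envir = remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(ls(remaining)) > 0) {
    nxt <- nxt + 1L
    seed_key <- ls(remaining)[1]
    queue <- list(get(seed_key, envir = remaining))
    rm(list = seed_key, envir = remaining)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      lab[matrix(v, 1)] <- nxt
      for (o in seq_len(nrow(offs))) {
        nb <- v + offs[o, ]
        if (all(nb >= 1) && all(nb <= d)) {
          k <- key(nb)
          if (exists(k, envir = remaining, inherits = FALSE)) {
            rm(list = k, envir = remaining)
            queue[[length(queue) + 1L]] <- nb
          }
        }
      }
    }
  }
  lab
}

# mid-rank Spearman from first principles: explicit average ranks and the
# covariance formula, no call to cor()
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# synthetic voxel matrix for matrix-level mixture tests: three well-separated
# tissue classes over three channels, with hard or softened priors
make_mixture_fixture <- function(n_per = 4000L, sep = 30, noise = 5,
                                 soft = 0, seed = 1) {
  withr::with_seed(seed, {
    mu <- rbind(csf = c(30, 25, 140),
                gm = c(90, 112, 100),
                wm = c(120, 100, 90))
    x <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n_per * 3, rep(mu[k, ], each = n_per), noise), n_per, 3)
    }))
    colnames(x) <- c("t1", "flair", "fse")
    labels <- rep(rownames(mu), each = n_per)
    priors <- sapply(rownames(mu), function(k) {
      p <- as.numeric(labels == k)
      if (soft > 0) p <- (1 - soft) * p + soft / 3
      p
    })
    list(x = x, priors = priors, labels = labels, mu = mu)
  })
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
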