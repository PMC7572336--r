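#' Normalized white-matter depth between ventricle and cortex
#'
#' Computes, for every voxel of the white-matter domain, the normalized depth
#' `d = d_v / (d_v + d_c)` where `d_v` and `d_c` are Euclidean distances (mm)
#' to the ventricular surface and the cortical sheet. `d` is 0 on voxels
#' touching the ventricle and 1 on voxels touching the cortex; equidistant
#' layer binning is performed on this field. Distances are taken to the
#' nearest labelled voxel centre minus one voxel, so face-adjacent voxels sit
#' exactly on the surface.
#'
#' @param ventricle_mask,cortex_mask,wm_mask Logical 3D arrays on the same
#'   grid; `wm_mask` is the domain over which depth is defined (typically
#'   white matter plus basal ganglia). The three masks must be disjoint.
#' @param voxel_size Numeric length-3, mm per axis.
#' @return A numeric 3D array with depth in \[0, 1\] on `wm_mask` voxels and
#'   `NA` elsewhere.
#' @export
normalized_depth <- function(ventricle_mask, cortex_mask, wm_mask, voxel_size = c(1, 1, 1)) {
  stopifnot(identical(dim(ventricle_mask), dim(cortex_mask)),
            identical(dim(ventricle_mask), dim(wm_mask)))
  if (any(wm_mask & (ventricle_mask | cortex_mask)) || any(ventricle_mask & cortex_mask)) {
    rlang::abort("masks must be disjoint", class = "bullseye_geometry_error")
  }
  pts <- mask_coords_mm(wm_mask, voxel_size)
  # only the surface voxels facing the domain matter for nearest distances
  vb <- touching_voxels(ventricle_mask, wm_mask)
  cb <- touching_voxels(cortex_mask, wm_mask)
  if (!any(vb)) vb <- ventricle_mask
  if (!any(cb)) cb <- cortex_mask
  surf_v <- mask_coords_mm(vb, voxel_size)
  surf_c <- mask_coords_mm(cb, voxel_size)
  vox <- min(voxel_size)
  d_v <- pmax(nearest_surface_distance(pts, surf_v) - vox, 0)
  d_c <- pmax(nearest_surface_distance(pts, surf_c) - vox, 0)
  denom <- d_v + d_c
  if (any(denom == 0)) {
    bad <- mask_ijk(wm_mask)[which(denom == 0)[1], ]
    rlang::abort(
      sprintf("voxel (%d, %d, %d) touches both the ventricular and cortical surfaces (d_v + d_c = 0)",
              bad[1], bad[2], bad[3]),
      class = "bullseye_geometry_error"
    )
  }
  depth <- array(NA_real_, dim(wm_mask))
  depth[wm_mask] <- d_v / denom
  depth
}

#' Bin normalized depth into equidistant layers
#'
#' Divides the \[0, 1\] depth field into `n_layers` equidistant half-open bins
#' `[0, 1/n), [1/n, 2/n), ...` with the final bin closed at 1, so
#' `layer = 1 + floor(d * n_layers)` and `d = 1` maps to `n_layers`.
#' Layer 1 is the most periventricular band; layer `n_layers` the deep /
#' juxtacortical band.
#'
#' @param depth A depth array from [normalized_depth()] (NA outside domain).
#' @param n_layers Number of layers (default 4).
#' @return Integer array of layer labels (NA outside the depth domain).
#' @examples
#' assign_layers(array(c(0.1, 0.5, 1), c(3, 1, 1)))
#' @export
assign_layers <- function(depth, n_layers = 4L) {
  if (n_layers < 1L) {
    rlang::abort("n_layers must be >= 1", class = "bullseye_parameter_error")
  }
  layer <- 1L + as.integer(floor(depth * n_layers))
  layer[!is.na(depth) & depth >= 1] <- as.integer(n_layers)
  array(layer, dim(depth))
}

#' Build the 36-region bullseye parcellation
#'
#' Crosses depth layers with lobar labels: region id
#' `(lobe - 1) * n_layers + layer`, enumerated lobe-major in the fixed order
#' FR, FL, TR, TL, PR, PL, OR, OL, BG. Layered voxels without a lobe label
#' are labelled 0 ("unassigned") and tallied in the QC attribute rather than
#' dropped.
#'
#' @param layers Integer layer array from [assign_layers()].
#' @param lobar_labels Integer array of lobar labels 1..9 (0 = none) on the
#'   same grid.
#' @param n_layers Number of layers used to build `layers`.
#' @return Object of class `bullseye_parcellation`: list with the integer
#'   `labels` array, the `lookup` tibble (`region_id`, `lobe`, `layer`,
#'   `region`, `n_voxels`) and `n_unassigned`.
#' @export
build_parcellation <- function(layers, lobar_labels, n_layers = 4L) {
  stopifnot(identical(dim(layers), dim(lobar_labels)))
  labels <- array(NA_integer_, dim(layers))
  dom <- !is.na(layers)
  lob <- lobar_labels[dom]
  lay <- layers[dom]
  id <- ifelse(lob >= 1L, (lob - 1L) * n_layers + lay, 0L)
  labels[dom] <- id
  lookup <- bullseye_region_lookup(n_layers) |>
    dplyr::mutate(n_voxels = vapply(.data$region_id, function(r) sum(id == r), 0L))
  structure(
    list(labels = labels, lookup = lookup, n_layers = as.integer(n_layers),
         n_unassigned = sum(id == 0L)),
    class = "bullseye_parcellation"
  )
}

#' @export
print.bullseye_parcellation <- function(x, ...) {
  cat("<bullseye_parcellation>", sum(x$lookup$n_voxels > 0), "of",
      nrow(x$lookup), "regions populated;", x$n_unassigned, "unassigned voxels\n")
  invisible(x)
}

#' Basal-ganglia lobar mask
#'
#' Extracts the basal-ganglia segment (internal capsule and thalamus
#' analogue) from a tissue label array; it is treated as the ninth lobar
#' segment, crossed with the four depth layers like the cortical lobes.
#'
#' @param tissue_labels Integer tissue array (code 4 = basal ganglia).
#' @return Logical mask.
#' @export
basal_ganglia_region <- function(tissue_labels) {
  mask <- tissue_labels == .tissue_codes[["bg"]]
  if (!any(mask)) {
    rlang::abort("tissue labels contain no basal-ganglia class",
                 class = "bullseye_configuration_error")
  }
  mask
}

#' Parcellate a phantom into bullseye regions
#'
#' Convenience wrapper: computes normalized depth over white matter plus
#' basal ganglia, bins it into `n_layers` equidistant layers, and crosses
#' with the phantom's lobar labels.
#'
#' @param phantom A `brain_phantom`.
#' @param n_layers Number of depth layers (default 4).
#' @return A `bullseye_parcellation`.
#' @examples
#' ph <- make_phantom(phantom_spec(lesion_count = 0))
#' parc <- bullseye_parcellate(ph)
#' parc$lookup
#' @export
bullseye_parcellate <- function(phantom, n_layers = 4L) {
  stopifnot(inherits(phantom, "brain_phantom"))
  wm_bg <- phantom$tissue == .tissue_codes[["wm"]] |
    phantom$tissue == .tissue_codes[["bg"]]
  depth <- normalized_depth(
    ventricle_mask = phantom$tissue == .tissue_codes[["csf"]],
    cortex_mask = phantom$tissue == .tissue_codes[["gm"]],
    wm_mask = wm_bg, voxel_size = phantom$voxel_size
  )
  layers <- assign_layers(depth, n_layers)
  build_parcellation(layers, phantom$lobes, n_layers)
}
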