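#' Regional WMH load from a probability map and a parcellation
#'
#' The load of a region is the probability mass of the lesion map over that
#' region times the voxel volume (mm^3); the total is the sum over the 36
#' bullseye regions. Probability mass on layered voxels without a lobe label
#' is reported separately as `unassigned` and excluded from the total, with
#' a warning when non-zero.
#'
#' @param map Numeric 3D lesion probability array.
#' @param parc A `bullseye_parcellation` on the same grid.
#' @param voxel_size Numeric length-3, mm per axis.
#' @return A tibble with one row per region: `region_id`, `lobe`, `layer`,
#'   `region`, `load_mm3`, `region_volume_mm3`, `relative_load`. Attributes
#'   `load_total` (mm^3, sum over the 36 regions) and `load_unassigned`.
#' @examples
#' ph <- make_phantom(phantom_spec(lesion_count = 0))
#' parc <- bullseye_parcellate(ph)
#' loads <- regional_load(ph$lesion * 1, parc, ph$voxel_size)
#' attr(loads, "load_total")
#' @export
regional_load <- function(map, parc, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(parc, "bullseye_parcellation"))
  if (!identical(dim(map), dim(parc$labels))) {
    rlang::abort("probability map and parcellation are on different grids",
                 class = "bullseye_alignment_error")
  }
  vv <- prod(voxel_size)
  labs <- parc$labels
  dom <- !is.na(labs)
  sums <- vapply(split(map[dom], labs[dom]), sum, 0)
  ids <- as.integer(names(sums))
  lookup <- parc$lookup
  load_vec <- setNames(numeric(nrow(lookup)), lookup$region_id)
  load_vec[as.character(ids[ids > 0])] <- sums[ids > 0] * vv
  unassigned <- if (any(ids == 0)) sums[["0"]] * vv else 0
  if (unassigned > 0) {
    rlang::warn(sprintf(
      "%.2f mm3 of lesion probability mass lies on unassigned voxels and is excluded from the total",
      unassigned))
  }
  out <- lookup |>
    dplyr::mutate(
      load_mm3 = as.numeric(load_vec),
      region_volume_mm3 = .data$n_voxels * vv,
      relative_load = dplyr::if_else(.data$region_volume_mm3 > 0,
                                     .data$load_mm3 / .data$region_volume_mm3,
                                     NA_real_)
    ) |>
    dplyr::select(-"n_voxels")
  attr(out, "load_total") <- sum(out$load_mm3)
  attr(out, "load_unassigned") <- unassigned
  out
}

#' Widen a regional load table into one cohort row
#'
#' @param loads Output of [regional_load()].
#' @return One-row tibble with `load_region_1` .. `load_region_36`,
#'   `load_total` and `load_unassigned`.
#' @export
loads_to_row <- function(loads) {
  wide <- setNames(as.list(loads$load_mm3), paste0("load_region_", loads$region_id))
  tibble::as_tibble_row(c(wide,
                          load_total = attr(loads, "load_total"),
                          load_unassigned = attr(loads, "load_unassigned")))
}

#' Spearman correlation of each regional load with the total
#'
#' @param cohort A cohort tibble with `load_region_1` .. `load_region_36`
#'   and `load_total` (at least 10 subjects).
#' @return A tibble `region_id`, `region`, `rho`, `undefined` — `rho` is NA
#'   and `undefined` TRUE for zero-variance regions.
#' @export
regional_total_correlation <- function(cohort) {
  if (nrow(cohort) < 10L) {
    rlang::abort("need at least 10 subjects", class = "bullseye_input_error")
  }
  lookup <- bullseye_region_lookup()
  purrr::map_dfr(lookup$region_id, function(r) {
    x <- cohort[[paste0("load_region_", r)]]
    undef <- sd(x) == 0 || sd(cohort$load_total) == 0
    tibble::tibble(
      region_id = r, region = lookup$region[r],
      rho = if (undef) NA_real_ else cor(x, cohort$load_total, method = "spearman"),
      undefined = undef
    )
  })
}
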