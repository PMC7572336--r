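#' Apply quality-control exclusions to a subject manifest
#'
#' Removes subjects carrying any exclusion flag. A subject with several
#' flags is counted once, attributed to the first flag in the fixed
#' precedence order of `flags` (meningioma before artifact by default, so
#' the per-reason tallies are disjoint).
#'
#' @param manifest Tibble with a unique `subject_id` column and logical
#'   flag columns.
#' @param flags Named character vector: names are the reported reasons in
#'   precedence order, values the flag columns.
#' @return List of class `wmh_qc`: `included` (flag-free rows) and `report`
#'   (tibble with one row per reason plus `included` / `total`).
#' @examples
#' m <- tibble::tibble(subject_id = as.character(1:5),
#'                     qc_meningioma = c(TRUE, FALSE, FALSE, FALSE, FALSE),
#'                     qc_artifact = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' apply_qc(m)$report
#' @export
apply_qc <- function(manifest,
                     flags = c(meningioma = "qc_meningioma",
                               artifact_or_segmentation_failure = "qc_artifact")) {
  if (nrow(manifest) == 0L) {
    rlang::abort("empty manifest", class = "bullseye_input_error")
  }
  if (anyDuplicated(manifest$subject_id)) {
    rlang::abort("duplicate subject ids in manifest",
                 class = "bullseye_manifest_error")
  }
  missing_cols <- setdiff(unname(flags), names(manifest))
  if (length(missing_cols)) {
    rlang::abort(paste("missing flag columns:", paste(missing_cols, collapse = ", ")),
                 class = "bullseye_manifest_error")
  }
  fm <- sapply(unname(flags), function(cl) as.logical(manifest[[cl]]))
  fm <- matrix(fm, nrow = nrow(manifest))
  any_flag <- rowSums(fm) > 0
  # first TRUE flag in precedence order
  reason_idx <- apply(fm, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  report <- tibble::tibble(
    reason = names(flags),
    n_excluded = vapply(seq_along(flags), function(i) sum(reason_idx == i, na.rm = TRUE), 0L)
  ) |>
    dplyr::bind_rows(tibble::tibble(
      reason = c("included", "total"),
      n_excluded = c(sum(!any_flag), nrow(manifest))
    ))
  structure(list(included = manifest[!any_flag, ], report = report),
            class = "wmh_qc")
}

#' @export
print.wmh_qc <- function(x, ...) {
  tot <- x$report$n_excluded[x$report$reason == "total"]
  inc <- x$report$n_excluded[x$report$reason == "included"]
  cat("<wmh_qc>", inc, "of", tot, "subjects included\n")
  print(x$report)
  invisible(x)
}
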