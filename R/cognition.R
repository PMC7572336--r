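#' Semantic proactive interference score
#'
#' Second-list learning expressed as a percentage of first-list learning:
#' `100 * list2 / list1`. Subjects who learned no first-list words have an
#' undefined score; those rows are returned as NA (flagged, never imputed).
#'
#' @param list1_learned,list2_learned Non-negative word counts (<= 16 each).
#' @return Numeric vector of percentages with NA where `list1_learned` is 0;
#'   attribute `n_undefined` counts the flagged rows.
#' @examples
#' semantic_proactive_interference(c(16, 16, 0), c(16, 8, 4))
#' @export
semantic_proactive_interference <- function(list1_learned, list2_learned) {
  stopifnot(length(list1_learned) == length(list2_learned))
  if (any(list1_learned < 0 | list2_learned < 0, na.rm = TRUE) ||
      any(list1_learned > 16 | list2_learned > 16, na.rm = TRUE)) {
    rlang::abort("word counts must lie in [0, 16]",
                 class = "bullseye_parameter_error")
  }
  out <- ifelse(list1_learned == 0, NA_real_,
                100 * list2_learned / list1_learned)
  n_undef <- sum(list1_learned == 0, na.rm = TRUE)
  if (n_undef > 0) {
    rlang::warn(sprintf("%d subject(s) learned no first-list words; score flagged missing", n_undef))
  }
  attr(out, "n_undefined") <- n_undef
  out
}

#' Default cognitive domain map
#'
#' Memory covers the seven memory-binding outcomes (including semantic
#' proactive interference, configurable); executive function covers the
#' seven WAIS-IV subtests.
#'
#' @param include_spi Include semantic proactive interference in the memory
#'   composite (default TRUE).
#' @return Named list of character vectors (domain -> measure columns).
#' @export
cognitive_domains <- function(include_spi = TRUE) {
  meas <- cognitive_measure_table()
  mem <- meas$measure[meas$domain == "memory"]
  if (!include_spi) mem <- setdiff(mem, "semantic_proactive_interference")
  list(memory = mem, executive = meas$measure[meas$domain == "executive"])
}

#' Domain z-score composites
#'
#' Each subtest is z-scored against the analysis sample's own mean and SD,
#' then composites are the unweighted mean of the z-scores within each
#' domain (rows missing a subtest average over the available ones).
#'
#' @param data Cohort tibble containing the subtest columns.
#' @param domains Named list mapping domain to subtest columns; composites
#'   are appended as `<domain>_z`.
#' @return `data` with one `_z` column appended per domain.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 30))
#' coh <- cognitive_composites(coh)
#' summary(coh$memory_z)
#' @export
cognitive_composites <- function(data, domains = cognitive_domains()) {
  for (dom in names(domains)) {
    cols <- domains[[dom]]
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols)) {
      rlang::abort(paste("missing subtest columns:",
                         paste(missing_cols, collapse = ", ")),
                   class = "bullseye_input_error")
    }
    z <- sapply(cols, function(cl) {
      v <- data[[cl]]
      s <- sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        rlang::abort(sprintf("subtest '%s' has zero variance", cl),
                     class = "bullseye_input_error")
      }
      (v - mean(v, na.rm = TRUE)) / s
    })
    data[[paste0(dom, "_z")]] <- rowMeans(as.matrix(z), na.rm = TRUE)
  }
  data
}

#' Pearson cross-correlation of cognitive measures
#'
#' Pairwise Pearson correlations with two-sided p-values from the standard
#' t transform, over the 14 subtests plus any domain composites present.
#'
#' @param data Cohort tibble (needs at least 4 complete pairs per cell).
#' @param columns Character vector of columns to correlate; defaults to the
#'   14 measures plus `memory_z` / `executive_z` when present.
#' @return Object of class `wmh_xcor`: list with symmetric matrices `r`,
#'   `p`, pairwise `n`, and `flagged` (constant columns, whose entries are
#'   NA).
#' @export
cross_correlation <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(cognitive_measure_table()$measure,
                           "memory_z", "executive_z"), names(data))
  }
  m <- as.matrix(data[, columns])
  if (nrow(m) < 4L) {
    rlang::abort("need at least 4 subjects", class = "bullseye_input_error")
  }
  flagged <- columns[apply(m, 2, function(v) sd(v, na.rm = TRUE) == 0)]
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(m))
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), pmax(n - 2, 1))
  diag(r) <- 1
  diag(p) <- NA_real_
  r[, flagged] <- r[flagged, ] <- NA_real_
  p[, flagged] <- p[flagged, ] <- NA_real_
  structure(list(r = r, p = p, n = n, columns = columns, flagged = flagged),
            class = "wmh_xcor")
}

#' @export
print.wmh_xcor <- function(x, ...) {
  cat("<wmh_xcor>", length(x$columns), "measures;",
      sum(x$p < 0.05, na.rm = TRUE) / 2, "significant pairs (p < 0.05)\n")
  invisible(x)
}

#' Tidy a cross-correlation object: one row per measure pair
#' @param x A `wmh_xcor`.
#' @param ... Unused.
#' @method tidy wmh_xcor
#' @export
tidy.wmh_xcor <- function(x, ...) {
  cn <- x$columns
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    measure1 = cn[pairs[, 1]], measure2 = cn[pairs[, 2]],
    r = x$r[pairs], p = x$p[pairs], n = x$n[pairs]
  )
}
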