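#' Covariate adjustment specification
#'
#' Cognitive measures are adjusted for age, sex, education and APOE-e4
#' allele count; WMH loads additionally for total intracranial volume.
#' Sensitivity analyses append extra confounder columns to both sides.
#'
#' @param covariates_cognition Covariate columns for the cognitive side.
#' @param tiv_column Head-size column appended on the WMH side.
#' @param extras Extra confounder columns appended to both sides.
#' @return List of class `adjustment_spec` with `covariates_cognition` and
#'   `covariates_wmh`.
#' @export
adjustment_spec <- function(covariates_cognition = c("age", "sex", "education",
                                                     "apoe_e4_count"),
                            tiv_column = "tiv",
                            extras = character()) {
  cog <- c(covariates_cognition, extras)
  wmh <- c(covariates_cognition, tiv_column, extras)
  if (anyDuplicated(cog) || anyDuplicated(wmh)) {
    rlang::abort("duplicated covariate names", class = "bullseye_parameter_error")
  }
  structure(list(covariates_cognition = cog, covariates_wmh = wmh,
                 extras = extras),
            class = "adjustment_spec")
}

#' Residualize a variable on covariates
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' covariate columns; the residuals are asserted orthogonal to every
#' covariate. `method = "rank"` residualizes mid-ranks on mid-ranked
#' covariates, a robustness option.
#'
#' @param values Numeric vector.
#' @param covariates Data frame or matrix of numeric covariates (same rows).
#' @param method `"ols"` (default) or `"rank"`.
#' @return Numeric residual vector.
#' @export
residualize <- function(values, covariates, method = c("ols", "rank")) {
  method <- match.arg(method)
  X0 <- as.matrix(as.data.frame(covariates))
  storage.mode(X0) <- "double"
  stopifnot(length(values) == nrow(X0))
  n <- length(values)
  if (n <= ncol(X0) + 1L) {
    rlang::abort("need more observations than covariates + 1",
                 class = "bullseye_input_error")
  }
  y <- if (method == "rank") rank(values) else values
  Xc <- if (method == "rank") apply(X0, 2, rank) else X0
  X <- cbind(`(intercept)` = 1, Xc)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    rlang::abort(paste("rank-deficient design; collinear columns:",
                       paste(dropped, collapse = ", ")),
                 class = "bullseye_rank_error")
  }
  r <- qr.resid(qrx, y)
  dots <- abs(crossprod(X, r))
  tol <- 1e-8 * n * max(1, sd(y)) * pmax(1, apply(abs(X), 2, max))
  if (any(dots > tol)) {
    rlang::abort("residuals not orthogonal to covariates (numerical failure)")
  }
  r
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Scalar rho; NA with a warning if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    rlang::abort("need n >= 3", class = "bullseye_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("constant input: Spearman rho undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

# scaled mid-ranks: mean 0, crossprod(sx, sy)/(n-1) = Pearson of ranks
scaled_ranks <- function(v) {
  r <- rank(v)
  as.numeric(scale(r))
}

#' Permutation p-value for a Spearman correlation
#'
#' Reassigns the outcome vector `y` to the predictors `n_perm` times without
#' resampling (each reassignment is a permutation) and recomputes rho. The
#' default, literal left-tail definition counts the permutations whose rho
#' is lower than the observed one and divides by `n_perm`; it is
#' directional (sensible when the hypothesized associations are negative)
#' and can return exactly 0. A two-sided option and an add-one smoothing
#' option `(1 + count) / (1 + n_perm)` are provided.
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param seed Integer seed for the permutation stream (NULL = current RNG).
#' @param sidedness `"lower"` (left tail, default) or `"two_sided"`.
#' @param smoothing Use `(1 + count) / (1 + n_perm)` (default FALSE).
#' @return Scalar p-value with attribute `rho` (the observed statistic).
#' @examples
#' x <- rnorm(30); y <- rnorm(30)
#' permutation_pvalue(x, y, n_perm = 500, seed = 1, sidedness = "two_sided")
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000L, seed = NULL,
                               sidedness = c("lower", "two_sided"),
                               smoothing = FALSE) {
  sidedness <- match.arg(sidedness)
  if (n_perm < 100L) rlang::warn("fewer than 100 permutations: p-value is coarse")
  sx <- scaled_ranks(x)
  ry <- rank(y)
  sy <- as.numeric(scale(ry))
  n <- length(x)
  rho_obs <- sum(sx * sy) / (n - 1)
  rho_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(sx * sy[sample.int(n)]) / (n - 1)
    }, 0)
  })
  # tolerance guards against float noise misclassifying exactly-tied
  # statistics (common at small n where the rank statistic is discrete)
  eps <- 1e-10
  count <- switch(sidedness,
                  lower = sum(rho_perm < rho_obs - eps),
                  two_sided = sum(abs(rho_perm) >= abs(rho_obs) - eps))
  p <- if (smoothing) (1 + count) / (1 + n_perm) else count / n_perm
  attr(p, "rho") <- rho_obs
  p
}

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(rho) +/- z_(1-alpha/2) / sqrt(n - 3))`. Degenerate
#' (`|rho| = 1`) inputs return the point interval with a warning.
#'
#' @param rho Correlation estimate(s).
#' @param n Sample size(s) (> 3).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `ci_low`, `ci_high`.
#' @export
rho_confidence_interval <- function(rho, n, level = 0.95) {
  stopifnot(all(n > 3))
  n <- rep_len(n, length(rho))
  z <- qnorm(1 - (1 - level) / 2)
  degenerate <- !is.na(rho) & abs(rho) >= 1
  if (any(degenerate)) {
    rlang::warn("|rho| = 1: degenerate confidence interval")
  }
  lo <- hi <- rho
  ok <- !is.na(rho) & !degenerate
  lo[ok] <- tanh(atanh(rho[ok]) - z / sqrt(n[ok] - 3))
  hi[ok] <- tanh(atanh(rho[ok]) + z / sqrt(n[ok] - 3))
  tibble::tibble(ci_low = lo, ci_high = hi)
}

#' Global and regional WMH-cognition association map
#'
#' For every predictor (total and 36 regional WMH loads) crossed with every
#' outcome (domain composites and individual measures): residualize the
#' load on age, sex, education, APOE-e4 count and TIV, residualize the
#' outcome on the same covariates minus TIV, compute Spearman's rho between
#' the residuals, a Fisher-z 95% CI, and a permutation p-value by outcome
#' reassignment. Rows with missing values are dropped listwise per outcome
#' (regional loads are always complete, so all predictors of one outcome
#' share rows and, by default, share one permutation stream). Significance
#' is flagged at p < 0.05 with no multiplicity correction, mirroring the
#' headline analysis; a Benjamini-Hochberg column `p_bh` is reported
#' alongside as a clearly-labelled extra.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]); composites are
#'   computed on the fly if absent.
#' @param predictors Predictor columns (default `load_total` +
#'   `load_region_1..36`).
#' @param outcomes Outcome columns (default `memory_z`, `executive_z` and
#'   the 14 measures).
#' @param adjustment An [adjustment_spec()].
#' @param n_perm Permutations per outcome (default 10000).
#' @param seed Integer seed; fixed seed gives identical results.
#' @param sidedness Passed to the permutation test (`"lower"` default).
#' @param shared_permutations If TRUE (default) the predictors of one
#'   outcome share the permutation stream; FALSE draws an independent
#'   stream per cell.
#' @param residual_method `"ols"` or `"rank"` residualization.
#' @return Tibble of class `wmh_association`: one row per predictor x
#'   outcome with `rho`, `ci_low`, `ci_high`, `p_perm`, `significant`,
#'   `p_bh`, `n`, `n_perm`.
#' @export
association_map <- function(cohort,
                            predictors = NULL, outcomes = NULL,
                            adjustment = adjustment_spec(),
                            n_perm = 10000L, seed = 1L,
                            sidedness = c("lower", "two_sided"),
                            shared_permutations = TRUE,
                            residual_method = c("ols", "rank")) {
  sidedness <- match.arg(sidedness)
  residual_method <- match.arg(residual_method)
  if (is.null(predictors)) {
    predictors <- c("load_total", paste0("load_region_", 1:36))
  }
  if (is.null(outcomes)) {
    if (!all(c("memory_z", "executive_z") %in% names(cohort))) {
      cohort <- cognitive_composites(cohort)
    }
    outcomes <- intersect(c("memory_z", "executive_z",
                            cognitive_measure_table()$measure),
                          names(cohort))
  }
  if (length(predictors) == 0L || length(outcomes) == 0L) {
    rlang::abort("empty predictor or outcome list",
                 class = "bullseye_parameter_error")
  }
  missing_cols <- setdiff(c(predictors, outcomes,
                            adjustment$covariates_wmh), names(cohort))
  if (length(missing_cols)) {
    rlang::abort(paste("columns absent from cohort:",
                       paste(missing_cols, collapse = ", ")),
                 class = "bullseye_input_error")
  }

  rows_out <- vector("list", length(outcomes))
  for (oi in seq_along(outcomes)) {
    oc <- outcomes[[oi]]
    used <- c(adjustment$covariates_wmh, predictors, oc)
    keep <- complete.cases(cohort[, used])
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      rlang::inform(sprintf("outcome %s: %d row(s) dropped listwise", oc, n_dropped))
    }
    dat <- cohort[keep, ]
    n <- nrow(dat)
    y_res <- residualize(dat[[oc]], dat[, adjustment$covariates_cognition],
                         method = residual_method)
    sy <- scaled_ranks(y_res)
    SP <- vapply(predictors, function(pc) {
      scaled_ranks(residualize(dat[[pc]], dat[, adjustment$covariates_wmh],
                               method = residual_method))
    }, numeric(n))
    rho_obs <- drop(crossprod(SP, sy)) / (n - 1)

    perm_seed <- seed + oi
    p_perm <- with_seed(perm_seed, {
      counts <- numeric(length(predictors))
      chunk <- 2000L
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        if (shared_permutations) {
          idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
          RP <- crossprod(SP, matrix(sy[idx], n, b)) / (n - 1)
        } else {
          RP <- matrix(0, length(predictors), b)
          for (j in seq_along(predictors)) {
            idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
            RP[j, ] <- crossprod(SP[, j], matrix(sy[idx], n, b)) / (n - 1)
          }
        }
        counts <- counts + switch(sidedness,
          lower = rowSums(RP < rho_obs - 1e-10),
          two_sided = rowSums(abs(RP) >= abs(rho_obs) - 1e-10))
        done <- done + b
      }
      counts / n_perm
    })
    ci <- rho_confidence_interval(rho_obs, rep(n, length(rho_obs)))
    rows_out[[oi]] <- tibble::tibble(
      predictor = predictors, outcome = oc, n = n,
      rho = rho_obs, ci_low = ci$ci_low, ci_high = ci$ci_high,
      p_perm = p_perm, n_perm = as.integer(n_perm)
    )
  }
  out <- dplyr::bind_rows(rows_out) |>
    dplyr::mutate(significant = .data$p_perm < 0.05,
                  p_bh = stats::p.adjust(.data$p_perm, method = "BH"))
  class(out) <- c("wmh_association", class(out))
  attr(out, "seed") <- seed
  attr(out, "sidedness") <- sidedness
  attr(out, "adjustment") <- adjustment
  out
}

#' @export
print.wmh_association <- function(x, ...) {
  cat("<wmh_association>", nrow(x), "predictor x outcome cells;",
      sum(x$significant), "significant at p < 0.05 (",
      attr(x, "sidedness"), "permutation test )\n")
  NextMethod()
}

#' Tidy an association map (returns the underlying tibble)
#' @param x A `wmh_association`.
#' @param ... Unused.
#' @method tidy wmh_association
#' @export
tidy.wmh_association <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.wmh_association
#' @method glance wmh_association
#' @export
glance.wmh_association <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_perm = x$n_perm[1],
    sidedness = attr(x, "sidedness"),
    seed = attr(x, "seed")
  )
}

#' Sensitivity re-run with extra confounders
#'
#' Re-runs [association_map()] with extra confounder columns appended to
#' both covariate sets and reports, per cell, whether the significance flag
#' flips or the rho sign changes.
#'
#' @param cohort Cohort tibble.
#' @param extras Character vector of extra confounder columns (e.g.
#'   `caide_like`, `depression_like`, `mta_like`).
#' @param adjustment Base [adjustment_spec()].
#' @param ... Passed to [association_map()].
#' @return List of class `wmh_sensitivity`: `base`, `extended`,
#'   `comparison` (per-cell flags) and `summary` (flip counts).
#' @export
sensitivity_rerun <- function(cohort, extras,
                              adjustment = adjustment_spec(), ...) {
  stopifnot(length(extras) > 0)
  base <- association_map(cohort, adjustment = adjustment, ...)
  ext_spec <- adjustment_spec(
    covariates_cognition = setdiff(adjustment$covariates_cognition,
                                   adjustment$extras),
    extras = extras
  )
  extended <- association_map(cohort, adjustment = ext_spec, ...)
  comparison <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(base), "predictor", "outcome",
                  rho_base = "rho", sig_base = "significant"),
    dplyr::select(tibble::as_tibble(extended), "predictor", "outcome",
                  rho_ext = "rho", sig_ext = "significant"),
    by = c("predictor", "outcome")
  ) |>
    dplyr::mutate(significance_flip = .data$sig_base != .data$sig_ext,
                  sign_flip = sign(.data$rho_base) != sign(.data$rho_ext))
  structure(
    list(base = base, extended = extended, comparison = comparison,
         summary = tibble::tibble(
           n_cells = nrow(comparison),
           n_significance_flips = sum(comparison$significance_flip),
           n_sign_flips = sum(comparison$sign_flip),
           extras = paste(extras, collapse = "+"))),
    class = "wmh_sensitivity"
  )
}

#' @export
print.wmh_sensitivity <- function(x, ...) {
  cat("<wmh_sensitivity> extras:", x$summary$extras, "|",
      x$summary$n_significance_flips, "of", x$summary$n_cells,
      "cells flip significance\n")
  invisible(x)
}
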