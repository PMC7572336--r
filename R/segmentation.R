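#' Segmentation configuration
#'
#' Tunables for the prior-constrained Gaussian-mixture lesion segmentation.
#'
#' @param max_components_per_class Maximum Gaussian components allowed per
#'   healthy tissue class during model selection (>= 1).
#' @param em_tolerance Relative log-likelihood change declaring convergence.
#' @param em_max_iters Maximum EM iterations per fit.
#' @param selection_criterion Only `"BIC"` is implemented.
#' @param flair_hyperintensity_k Candidate lesion voxels must exceed the
#'   fitted grey-matter FLAIR mean by `k` grey-matter SDs (k > 0). The gate
#'   is needed because the unexpected-observations class also absorbs
#'   hypointense artifacts.
#' @param min_lesion_size Connected components (26-connectivity on
#'   probability > 0.5) smaller than this voxel count are removed (>= 1).
#' @param outlier_prior Voxel-wise mixing mass reserved for the
#'   unexpected-observations class (0 < value < 1).
#' @param outlier_cov_inflation Initial outlier covariance = inflation x
#'   pooled healthy covariance.
#' @param outlier_update If FALSE (default) the outlier component's mean and
#'   covariance stay fixed at their broad initialization, so it cannot
#'   collapse onto dense healthy tissue; TRUE lets EM update it.
#' @param prior_smoothing_mm Smoothing applied to label-derived priors by
#'   [segment_wmh()].
#' @param flair_channel Name of the FLAIR-like channel.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(max_components_per_class = 2L,
                       em_tolerance = 1e-5,
                       em_max_iters = 100L,
                       selection_criterion = "BIC",
                       flair_hyperintensity_k = 1.5,
                       min_lesion_size = 3L,
                       outlier_prior = 0.05,
                       outlier_cov_inflation = 4,
                       outlier_update = FALSE,
                       prior_smoothing_mm = 1,
                       flair_channel = "flair") {
  if (max_components_per_class < 1L || flair_hyperintensity_k <= 0 ||
      min_lesion_size < 1L || outlier_prior <= 0 || outlier_prior >= 1) {
    rlang::abort("invalid segmentation configuration",
                 class = "bullseye_parameter_error")
  }
  selection_criterion <- match.arg(selection_criterion, "BIC")
  structure(
    list(max_components_per_class = as.integer(max_components_per_class),
         em_tolerance = em_tolerance, em_max_iters = as.integer(em_max_iters),
         selection_criterion = selection_criterion,
         flair_hyperintensity_k = flair_hyperintensity_k,
         min_lesion_size = as.integer(min_lesion_size),
         outlier_prior = outlier_prior,
         outlier_cov_inflation = outlier_cov_inflation,
         outlier_update = isTRUE(outlier_update),
         prior_smoothing_mm = prior_smoothing_mm,
         flair_channel = flair_channel),
    class = "seg_config"
  )
}

# log N(x; mu, Sigma) for all rows of x; ridge-regularizes a singular Sigma
log_dmvnorm <- function(x, mu, sigma, ridge_eps) {
  d <- ncol(x)
  U <- tryCatch(chol(sigma), error = function(e) NULL)
  tries <- 0L
  while (is.null(U) && tries < 8L) {
    sigma <- sigma + diag(ridge_eps * 10^tries, d)
    U <- tryCatch(chol(sigma), error = function(e) NULL)
    tries <- tries + 1L
  }
  if (is.null(U)) rlang::abort("covariance irreparably singular")
  xc <- sweep(x, 2, mu)
  w <- xc %*% backsolve(U, diag(d))
  q <- rowSums(w^2)
  list(logdens = -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + q),
       sigma = sigma, ridged = tries > 0L)
}

row_max <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1) for (j in 2:ncol(m)) out <- pmax(out, m[, j])
  out
}

# initialize components for one healthy class by quantile-splitting along the
# principal axis of the prior-weighted data
init_class_components <- function(x, w, k) {
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  sigma <- crossprod(xc * sqrt(w)) + diag(1e-8, ncol(x))
  if (k == 1L) return(list(list(mean = mu, cov = sigma, tau = 1)))
  v <- eigen(sigma, symmetric = TRUE)$vectors[, 1]
  proj <- drop(xc %*% v)
  qs <- quantile(proj[w > 0], probs = seq(0, 1, length.out = k + 1L))
  grp <- cut(proj, breaks = unique(c(-Inf, qs[-c(1, k + 1L)], Inf)), labels = FALSE)
  lapply(seq_len(k), function(g) {
    sel <- which(grp == g & w > 0)
    if (length(sel) < ncol(x) + 1L) sel <- which(w > 0)
    wg <- w[sel] / sum(w[sel])
    mug <- colSums(x[sel, , drop = FALSE] * wg)
    xcg <- sweep(x[sel, , drop = FALSE], 2, mug)
    list(mean = mug, cov = crossprod(xcg * sqrt(wg)) + diag(1e-8, ncol(x)),
         tau = 1 / k)
  })
}

#' Fit the prior-constrained Gaussian mixture with an outlier class
#'
#' Expectation-maximization for a multivariate Gaussian mixture over the
#' channel intensities of brain voxels. The healthy classes (CSF, cortical
#' GM, WM) receive voxel-wise mixing weights from the spatial tissue priors,
#' scaled by `1 - outlier_prior`; a single broad "unexpected observations"
#' component with weight `outlier_prior` everywhere absorbs lesions and
#' artifacts. Each healthy class may carry several Gaussian components with
#' shared (global) within-class weights.
#'
#' @param x Numeric matrix, one row per brain voxel, one column per channel.
#' @param priors Numeric matrix with columns `csf`, `gm`, `wm` summing to 1
#'   per row (voxel-wise class priors).
#' @param n_components Named integer vector: components per healthy class,
#'   e.g. `c(csf = 1, gm = 1, wm = 2)`.
#' @param config A [seg_config()].
#' @return Object of class `wmh_mixture`: component table, responsibility
#'   matrix, outlier posterior, log-likelihood trace, BIC.
#' @export
em_fit <- function(x, priors, n_components = c(csf = 1L, gm = 1L, wm = 1L),
                   config = seg_config()) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    rlang::abort("non-finite intensities in input", class = "bullseye_input_error")
  }
  priors <- as.matrix(priors)[, c("csf", "gm", "wm")]
  stopifnot(nrow(priors) == nrow(x))
  n <- nrow(x); d <- ncol(x)
  n_components <- n_components[c("csf", "gm", "wm")]
  # fixed outlier parameters are not free; within-class weights add K_c - 1
  n_free <- (sum(n_components) + as.integer(config$outlier_update)) *
    (d + d * (d + 1) / 2) + sum(n_components - 1L)
  if (n <= 10 * n_free) {
    rlang::abort("too few voxels for the requested model complexity",
                 class = "bullseye_input_error")
  }
  ridge_eps <- 1e-6 * mean(apply(x, 2, var))

  # initialization
  comp_class <- rep(names(n_components), times = n_components)
  comps <- list()
  pooled <- matrix(0, d, d)
  for (cls in names(n_components)) {
    ini <- init_class_components(x, priors[, cls] + 1e-12, n_components[[cls]])
    pooled <- pooled + Reduce(`+`, lapply(ini, `[[`, "cov")) / length(ini) *
      mean(priors[, cls])
    comps <- c(comps, ini)
  }
  comps <- c(comps, list(list(mean = colMeans(x),
                              cov = config$outlier_cov_inflation * pooled +
                                diag(ridge_eps, d),
                              tau = 1)))
  comp_class <- c(comp_class, "outlier")
  K <- length(comps)

  log_w_class <- cbind(log(pmax(priors, 0) * (1 - config$outlier_prior)),
                       log(config$outlier_prior))
  colnames(log_w_class) <- c("csf", "gm", "wm", "outlier")

  ll_trace <- numeric(0)
  resp <- NULL
  for (iter in seq_len(config$em_max_iters)) {
    # E-step
    L <- matrix(-Inf, n, K)
    for (k in seq_len(K)) {
      dd <- log_dmvnorm(x, comps[[k]]$mean, comps[[k]]$cov, ridge_eps)
      comps[[k]]$cov <- dd$sigma
      L[, k] <- dd$logdens + log(comps[[k]]$tau) + log_w_class[, comp_class[k]]
    }
    m <- row_max(L)
    pe <- exp(L - m)
    rs <- rowSums(pe)
    ll <- sum(m + log(rs))
    resp <- pe / rs
    if (length(ll_trace) > 0) {
      prev <- ll_trace[length(ll_trace)]
      if (ll < prev - 1e-8 * max(1, abs(prev))) {
        rlang::abort(sprintf(
          "EM log-likelihood decreased (%.10g -> %.10g)", prev, ll))
      }
      if (abs(ll - prev) < config$em_tolerance * abs(prev)) {
        ll_trace <- c(ll_trace, ll)
        break
      }
    }
    ll_trace <- c(ll_trace, ll)
    # M-step
    for (k in seq_len(K)) {
      if (comp_class[k] == "outlier" && !config$outlier_update) next
      rk <- resp[, k]
      sk <- sum(rk)
      if (sk < d + 1) next  # starved component: keep previous parameters
      mu <- colSums(x * rk) / sk
      xc <- sweep(x, 2, mu)
      comps[[k]]$mean <- mu
      comps[[k]]$cov <- crossprod(xc * sqrt(rk / sk))
    }
    for (cls in unique(comp_class)) {
      ks <- which(comp_class == cls)
      if (length(ks) > 1) {
        mass <- colSums(resp[, ks, drop = FALSE])
        for (i in seq_along(ks)) comps[[ks[i]]]$tau <- mass[i] / sum(mass)
      }
    }
  }

  loglik <- ll_trace[length(ll_trace)]
  bic <- -2 * loglik + n_free * log(n)
  components <- tibble::tibble(
    class = comp_class,
    component = unlist(lapply(table(factor(comp_class, levels = unique(comp_class))),
                              seq_len), use.names = FALSE),
    weight = vapply(comps, `[[`, 0, "tau"),
    mean = lapply(comps, `[[`, "mean"),
    cov = lapply(comps, `[[`, "cov")
  )
  structure(
    list(components = components, resp = resp, comp_class = comp_class,
         outlier_posterior = resp[, K],
         ll_trace = ll_trace, loglik = loglik, bic = bic,
         n_components = n_components, n_free = n_free, n = n,
         channels = colnames(x), config = config),
    class = "wmh_mixture"
  )
}

#' @export
print.wmh_mixture <- function(x, ...) {
  cat("<wmh_mixture>", paste(names(x$n_components), x$n_components,
                             sep = "=", collapse = " "),
      sprintf("+ outlier | logLik %.1f | BIC %.1f | %d iters\n",
              x$loglik, x$bic, length(x$ll_trace)))
  invisible(x)
}

#' Tidy a fitted mixture: one row per Gaussian component
#' @param x A fitted `wmh_mixture`.
#' @param ... Unused.
#' @return A tibble with class, component index, weight and channel means.
#' @method tidy wmh_mixture
#' @export
tidy.wmh_mixture <- function(x, ...) {
  dplyr::mutate(
    x$components,
    mean = purrr::map(.data$mean, ~ tibble::as_tibble_row(setNames(as.list(.x), x$channels)))
  ) |>
    tidyr::unnest(mean) |>
    dplyr::select(-"cov")
}

#' @rdname tidy.wmh_mixture
#' @method glance wmh_mixture
#' @export
glance.wmh_mixture <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, BIC = x$bic, n_iter = length(x$ll_trace),
    n_voxels = x$n, n_free = x$n_free,
    csf_components = x$n_components[["csf"]],
    gm_components = x$n_components[["gm"]],
    wm_components = x$n_components[["wm"]]
  )
}

#' Select the mixture's component counts by BIC
#'
#' Greedy incremental search over the number of Gaussian components per
#' healthy class: starting from one component each, repeatedly add a
#' component to the class whose addition most improves the Bayesian
#' information criterion, stopping when no addition improves it or the
#' per-class maximum is reached. Candidates in which a *healthy* component
#' becomes FLAIR-hyperintense (FLAIR mean above the grey-matter reference
#' plus `flair_hyperintensity_k` SDs) are rejected: hyperintense tissue is
#' by definition an unexpected observation and must be modelled by the
#' outlier class, not absorbed into a healthy one.
#'
#' @inheritParams em_fit
#' @return The best `wmh_mixture`; attribute `"candidates"` holds the
#'   per-candidate diagnostics tibble (counts, logLik, BIC, accepted).
#' @export
select_model <- function(x, priors, config = seg_config()) {
  counts <- c(csf = 1L, gm = 1L, wm = 1L)
  best <- em_fit(x, priors, counts, config)
  diag_rows <- list(tibble::tibble(
    csf = 1L, gm = 1L, wm = 1L, logLik = best$loglik, BIC = best$bic,
    hyperintense_healthy = FALSE, accepted = TRUE))
  repeat {
    trial_models <- list()
    for (cls in names(counts)) {
      if (counts[[cls]] >= config$max_components_per_class) next
      trial <- counts
      trial[[cls]] <- trial[[cls]] + 1L
      fit <- tryCatch(em_fit(x, priors, trial, config), error = function(e) e)
      if (inherits(fit, "error")) next
      trial_models[[cls]] <- fit
    }
    if (length(trial_models) == 0L) break
    hyper <- vapply(trial_models, healthy_hyperintense, TRUE, config = config)
    bics <- vapply(trial_models, `[[`, 0, "bic")
    bics[hyper] <- Inf  # healthy classes must not model hyperintense tissue
    winner <- names(which.min(bics))
    improved <- is.finite(bics[[winner]]) && bics[[winner]] < best$bic
    for (cls in names(trial_models)) {
      m <- trial_models[[cls]]
      diag_rows[[length(diag_rows) + 1L]] <- tibble::tibble(
        csf = m$n_components[["csf"]], gm = m$n_components[["gm"]],
        wm = m$n_components[["wm"]], logLik = m$loglik, BIC = m$bic,
        hyperintense_healthy = hyper[[cls]],
        accepted = improved && cls == winner)
    }
    if (!improved) break
    best <- trial_models[[winner]]
    counts <- best$n_components
  }
  attr(best, "candidates") <- dplyr::bind_rows(diag_rows)
  best
}

# TRUE if any healthy component's FLAIR mean exceeds the grey-matter
# hyperintensity gate -- such a component is modelling unexpected tissue
healthy_hyperintense <- function(model, config) {
  flair_idx <- match(config$flair_channel, model$channels)
  if (is.na(flair_idx)) return(FALSE)
  ref <- gm_flair_reference(model, flair_idx)
  thr <- ref$mean + config$flair_hyperintensity_k * ref$sd
  healthy <- model$components[model$components$class != "outlier", ]
  any(vapply(healthy$mean, `[[`, 0, flair_idx) > thr)
}

# FLAIR reference statistics of the fitted grey-matter class (weight-averaged
# moments over its components)
gm_flair_reference <- function(model, flair_idx) {
  comp <- model$components[model$components$class == "gm", ]
  w <- comp$weight / sum(comp$weight)
  mus <- vapply(comp$mean, `[[`, 0, flair_idx)
  vars <- vapply(comp$cov, function(s) s[flair_idx, flair_idx], 0)
  mu <- sum(w * mus)
  list(mean = mu, sd = sqrt(sum(w * (vars + mus^2)) - mu^2))
}

#' Extract the lesion probability map
#'
#' Candidate lesion probability is the posterior responsibility of the
#' unexpected-observations class, masked to voxels whose FLAIR-like
#' intensity exceeds the fitted grey-matter FLAIR mean by
#' `flair_hyperintensity_k` grey-matter SDs (white-matter hyperintensities
#' are, by definition, hyperintense).
#'
#' @param model A fitted `wmh_mixture`.
#' @param channels Named list of 3D intensity arrays (must include the
#'   configured FLAIR channel).
#' @param mask Logical 3D brain mask matching the voxel order used to fit
#'   `model`.
#' @param config A [seg_config()].
#' @return Numeric 3D array in \[0, 1\], zero outside the brain mask.
#' @export
lesion_probability <- function(model, channels, mask, config = seg_config()) {
  stopifnot(inherits(model, "wmh_mixture"))
  flair <- channels[[config$flair_channel]]
  stopifnot(identical(dim(flair), dim(mask)))
  flair_idx <- match(config$flair_channel, model$channels)
  ref <- gm_flair_reference(model, flair_idx)
  gate <- flair[mask] > ref$mean + config$flair_hyperintensity_k * ref$sd
  p <- model$outlier_posterior * gate
  out <- array(0, dim(mask))
  out[mask] <- pmin(pmax(p, 0), 1)
  out
}

#' Remove spurious false-positive detections
#'
#' Zeroes lesion probability outside white matter and basal ganglia, then
#' removes connected components (26-connectivity on probability > 0.5)
#' smaller than `min_lesion_size` voxels. Total probability mass never
#' increases.
#'
#' @param map Numeric 3D lesion probability array.
#' @param tissue_labels Integer tissue array on the same grid (2 = WM,
#'   4 = basal ganglia).
#' @param config A [seg_config()].
#' @return Corrected probability array.
#' @export
false_positive_correction <- function(map, tissue_labels, config = seg_config()) {
  stopifnot(identical(dim(map), dim(tissue_labels)))
  allowed <- tissue_labels == .tissue_codes[["wm"]] |
    tissue_labels == .tissue_codes[["bg"]]
  out <- map
  out[!allowed] <- 0
  hi <- out > 0.5
  if (any(hi)) {
    ijk <- mask_ijk(hi)
    memb <- connected_components_26(ijk, dim(map))
    sizes <- tabulate(memb)
    drop <- sizes[memb] < config$min_lesion_size
    if (any(drop)) {
      out[ijk[drop, , drop = FALSE]] <- 0
    }
  }
  out
}

#' Segment white-matter hyperintensities on a phantom
#'
#' End-to-end subject-level segmentation: label-derived smoothed tissue
#' priors, BIC-selected prior-constrained Gaussian mixture with an outlier
#' class, FLAIR-gated lesion probability extraction, and false-positive
#' correction.
#'
#' @param phantom A `brain_phantom`.
#' @param config A [seg_config()].
#' @return List of class `wmh_segmentation`: `prob` (corrected probability
#'   array), `prob_raw` (before false-positive correction), `model`,
#'   `config`.
#' @examples
#' \donttest{
#' ph <- make_phantom(phantom_spec(lesion_count = 3, seed = 2))
#' seg <- segment_wmh(ph)
#' sum(seg$prob) # probability mass ~ lesion volume in voxels
#' }
#' @export
segment_wmh <- function(phantom, config = seg_config()) {
  stopifnot(inherits(phantom, "brain_phantom"))
  priors <- tissue_priors(phantom, smoothing_mm = config$prior_smoothing_mm)
  mask <- priors$mask
  x <- do.call(cbind, lapply(phantom$channels, function(ch) ch[mask]))
  colnames(x) <- names(phantom$channels)
  pr <- cbind(csf = priors$csf[mask], gm = priors$gm[mask], wm = priors$wm[mask])
  model <- select_model(x, pr, config)
  raw <- lesion_probability(model, phantom$channels, mask, config)
  corrected <- false_positive_correction(raw, phantom$tissue, config)
  structure(list(prob = corrected, prob_raw = raw, model = model,
                 config = config),
            class = "wmh_segmentation")
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat("<wmh_segmentation> probability mass", sprintf("%.1f", sum(x$prob)),
      "voxels;", sum(x$prob > 0.5), "voxels above 0.5\n")
  invisible(x)
}
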