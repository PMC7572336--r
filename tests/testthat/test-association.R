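test_that("residualization matches the normal-equations oracle on a 6-row toy", {
  X <- cbind(age = c(50, 55, 60, 62, 48, 71), sex = c(0, 1, 1, 0, 1, 0))
  y <- c(3.2, 1.5, -0.7, 2.2, 0.4, -1.9)
  r <- residualize(y, X)
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
  expect_equal(r, as.numeric(y - Xd %*% beta), tolerance = 1e-10)
  # residuals orthogonal to each covariate
  expect_lt(max(abs(crossprod(Xd, r))), 1e-8 * length(y) * max(abs(Xd)))
})

test_that("residualization handles degenerate relations between y and covariates", {
  withr::with_seed(2, {
    x <- rnorm(40)
    noise <- rnorm(40)
  })
  # y exactly linear in the covariate -> residuals vanish
  y_lin <- 2 + 3 * x
  expect_lt(max(abs(residualize(y_lin, cbind(x = x)))), 1e-8 * sd(y_lin))
  # y already orthogonal to the design -> residualization is the identity
  v0 <- residualize(noise, cbind(x = x))
  expect_equal(residualize(v0, cbind(x = x)), v0, tolerance = 1e-10)
  # collinear design names the offending column
  expect_error(residualize(noise, cbind(a = x, b = 2 * x)),
               regexp = "\\bb\\b", class = "bullseye_rank_error")
})

test_that("Spearman rho handles monotone and tied data", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman_rho(x, exp(x / 10)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # ties: compare against a from-scratch mid-rank oracle
  withr::with_seed(6, {
    for (i in 1:5) {
      a <- sample(1:5, 12, replace = TRUE)
      b <- sample(1:4, 12, replace = TRUE)
      expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
    }
  })
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
})

test_that("the literal left-tail permutation p is near 1 for a perfect positive match", {
  x <- seq_len(50)
  p <- permutation_pvalue(x, x, n_perm = 500, seed = 1)
  expect_gte(p, 0.99)
  expect_equal(attr(p, "rho"), 1)
})

test_that("the sampled permutation p agrees with exhaustive enumeration at n = 6", {
  x <- c(0.3, -1.2, 0.8, 2.1, -0.4, 1.0)
  y <- c(0.1, -0.9, 1.4, 0.3, -1.1, 0.6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6L), ]
  rho_obs <- spearman_rho(x, y)
  rho_all <- apply(perms, 1, function(idx) spearman_rho(x, y[idx]))
  p_exact_lower <- mean(rho_all < rho_obs)
  p_exact_two <- mean(abs(rho_all) >= abs(rho_obs))

  n_perm <- 4000L
  p_lower <- permutation_pvalue(x, y, n_perm = n_perm, seed = 3)
  p_two <- permutation_pvalue(x, y, n_perm = n_perm, seed = 3,
                              sidedness = "two_sided")
  se_lower <- sqrt(p_exact_lower * (1 - p_exact_lower) / n_perm)
  se_two <- sqrt(p_exact_two * (1 - p_exact_two) / n_perm)
  expect_lt(abs(p_lower - p_exact_lower), 3 * se_lower)
  expect_lt(abs(p_two - p_exact_two), 3 * se_two)
})

test_that("permutation options behave as documented", {
  x <- seq_len(30)
  withr::with_seed(4, y <- rnorm(30))
  expect_warning(permutation_pvalue(x, y, n_perm = 50, seed = 1), "100")
  p_raw <- permutation_pvalue(x, y, n_perm = 200, seed = 2)
  p_smooth <- permutation_pvalue(x, y, n_perm = 200, seed = 2, smoothing = TRUE)
  expect_equal(as.numeric(p_smooth), (1 + as.numeric(p_raw) * 200) / 201)
  # identical seeds reproduce the p-value to the last digit
  expect_identical(permutation_pvalue(x, y, n_perm = 300, seed = 9),
                   permutation_pvalue(x, y, n_perm = 300, seed = 9))
})

test_that("Fisher-z confidence intervals match the closed form", {
  ci <- rho_confidence_interval(0, 403)
  halfwidth <- tanh(qnorm(0.975) / sqrt(400))
  expect_equal(ci$ci_high, halfwidth, tolerance = 1e-12)
  expect_equal(ci$ci_low, -halfwidth, tolerance = 1e-12)
  # independently coded transform oracle over a grid
  for (rho in c(-0.8, -0.07, 0, 0.3)) {
    for (n in c(20, 561)) {
      ci <- rho_confidence_interval(rho, n)
      z <- 0.5 * log((1 + rho) / (1 - rho))
      lo <- (exp(2 * (z - 1.959963984540054 / sqrt(n - 3))) - 1) /
        (exp(2 * (z - 1.959963984540054 / sqrt(n - 3))) + 1)
      expect_equal(ci$ci_low, lo, tolerance = 1e-12)
      expect_true(ci$ci_low <= rho && rho <= ci$ci_high)
    }
  }
  expect_warning(ci1 <- rho_confidence_interval(1, 20), "degenerate")
  expect_equal(ci1$ci_low, 1)
})

test_that("the association map is reproducible and respects its contracts", {
  coh <- cognitive_composites(simulate_cohort(cohort_spec(n_subjects = 150,
                                                          seed = 19)))
  am1 <- association_map(coh, outcomes = c("memory_z", "coding"),
                         n_perm = 300, seed = 5)
  am2 <- association_map(coh, outcomes = c("memory_z", "coding"),
                         n_perm = 300, seed = 5)
  expect_identical(as.data.frame(am1), as.data.frame(am2))
  expect_equal(nrow(am1), 37L * 2L)
  expect_true(all(am1$rho >= -1 & am1$rho <= 1))
  expect_true(all(am1$ci_low <= am1$rho & am1$rho <= am1$ci_high))
  expect_true(all(am1$p_perm >= 0 & am1$p_perm <= 1))
  expect_identical(am1$significant, am1$p_perm < 0.05)
  expect_error(association_map(coh, predictors = character()),
               class = "bullseye_parameter_error")
})

test_that("rows with missing outcomes are dropped listwise per analysis cell", {
  coh <- cognitive_composites(simulate_cohort(cohort_spec(n_subjects = 120,
                                                          seed = 21)))
  coh$semantic_proactive_interference[1:7] <- NA
  am <- suppressMessages(association_map(
    coh, predictors = "load_total",
    outcomes = c("semantic_proactive_interference", "coding"),
    n_perm = 200, seed = 2))
  expect_equal(am$n[am$outcome == "semantic_proactive_interference"], 113L)
  expect_equal(am$n[am$outcome == "coding"], 120L)
})

test_that("sensitivity re-runs flag rank deficiency and attenuate confounded effects", {
  b <- matrix(0, 36, 14,
              dimnames = list(NULL, cognitive_measure_table()$measure))
  b[3, "coding"] <- -0.35
  coh <- cognitive_composites(simulate_cohort(cohort_spec(n_subjects = 300,
                                                          beta = b, seed = 25)))
  # duplicating an existing covariate must fail loudly
  coh$age_copy <- coh$age
  expect_error(
    suppressMessages(sensitivity_rerun(coh, extras = "age_copy",
                                       predictors = "load_total",
                                       outcomes = "coding",
                                       n_perm = 200, seed = 3)),
    class = "bullseye_rank_error")

  # a confounder built from the planted predictor absorbs the effect
  coh$confound <- log(coh$load_region_3)
  sens <- sensitivity_rerun(coh, extras = "confound",
                            predictors = "load_region_3",
                            outcomes = "coding", n_perm = 300, seed = 4)
  rho_base <- sens$comparison$rho_base
  rho_ext <- sens$comparison$rho_ext
  expect_lt(abs(rho_ext), abs(rho_base))
  expect_lt(abs(rho_ext), 0.12)

  # an irrelevant extra leaves the map essentially unchanged
  withr::with_seed(5, coh$irrelevant <- rnorm(nrow(coh)))
  sens2 <- sensitivity_rerun(coh, extras = "irrelevant",
                             outcomes = c("coding", "memory_z"),
                             n_perm = 300, seed = 6)
  expect_lt(sens2$summary$n_significance_flips / sens2$summary$n_cells, 0.1)
})
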