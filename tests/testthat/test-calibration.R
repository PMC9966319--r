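# Calibration-regime statistics: chi-square variance bounds, the sensitivity
# fit, content recovery, and the closed-form relative-error bounds.

test_that("replicate_stats computes the replicate summaries and chi-square bound", {
  s0 <- replicate_stats(c(5, 5, 5, 5))
  expect_equal(s0$mean, 5)
  expect_equal(s0$var, 0)
  expect_equal(s0$v_max, 0)
  expect_equal(s0$gamma2_mean, 0)
  s1 <- replicate_stats(c(1, 2, 3))
  expect_equal(s1$mean, 2)
  expect_equal(s1$var, 1)
  expect_equal(s1$var_of_mean, 0.5)          # divisor n - 1
  s1n <- replicate_stats(c(1, 2, 3), divisor_mode = "n")
  expect_equal(s1n$var_of_mean, 1 / 3)
  # V_max / sigma^2_mean at n = 10, P = 0.95: 9 / chisq_0.05(9) = 2.7067
  s2 <- replicate_stats(rnorm(10) + 100, confidence = 0.95)
  expect_equal(s2$v_max / s2$var_of_mean, 2.7067, tolerance = 1e-4)
  expect_error(replicate_stats(5), ">= 2")
  expect_error(replicate_stats(c(-1, 1, 0.5, -0.5)), "zero mean")
})

test_that("the chi-square inflation is > 1 and decreasing in n at P = 0.95", {
  infl <- vapply(3:100, chi2_inflation, numeric(1), P = 0.95)
  expect_true(all(infl > 1))
  expect_true(all(diff(infl) < 0))
})

test_that("fit_sensitivity recovers exact synthetic calibration", {
  calib <- lapply(c(5, 10, 15), function(C)
    list(known_concentration = C, known_rel_error = 0,
         replicate_areas = rep(2 * C - 0.5, 4)))
  fit <- fit_sensitivity(calib)
  expect_equal(fit$K, 2, tolerance = 1e-10)
  expect_equal(fit$delta_S, rep(0.5, 3), tolerance = 1e-9)
  expect_equal(fit$delta_K_rel, 0, tolerance = 1e-9)
  # censored replicates are excluded with a warning
  calib2 <- calib
  calib2[[1]]$replicate_areas[2] <- 0
  expect_warning(
    fit2 <- fit_sensitivity(calib2, censored_flags = list(
      c(FALSE, TRUE, FALSE, FALSE), rep(FALSE, 4), rep(FALSE, 4))),
    "censored")
  expect_equal(fit2$K, 2, tolerance = 1e-10)
  # degenerate designs
  expect_error(fit_sensitivity(list(list(known_concentration = 5,
                                         known_rel_error = 0,
                                         replicate_areas = c(0, 0, 0)))),
               "unidentifiable")
  expect_error(fit_sensitivity(lapply(c(5, 5), function(C)
    list(known_concentration = C, known_rel_error = 0,
         replicate_areas = c(9, 10, 11)))), "distinct")
})

test_that("fitted K is within its standard-error band at the nominal rate", {
  set.seed(31)
  hit <- logical(300)
  for (r in seq_len(300)) {
    calib <- lapply(c(5, 10, 15), function(C)
      list(known_concentration = C, known_rel_error = 0,
           replicate_areas = 2 * C - 0.5 + rnorm(10, 0, 0.4)))
    fit <- fit_sensitivity(calib)
    hit[r] <- abs(fit$K - 2) <= 3 * fit$se_K
  }
  expect_gte(mean(hit), 0.95)
})

test_that("solve_c_act: worked identities and both algebraic forms", {
  fit <- list(K = 2)
  known <- list(known_concentration = 10, known_rel_error = 0)
  # M = Mhat implies C_act = C exactly
  cs <- fake_stats(18, 0); ms <- fake_stats(18, 0)
  expect_equal(solve_c_act(cs, ms, known, fit)$c_act, 10)
  # direct substitution in both algebraic forms
  sol <- solve_c_act(fake_stats(18, 0), fake_stats(22, 0), known, fit)
  expect_equal(sol$delta_S, 2)
  expect_equal(sol$c_act, 12)
  expect_equal(sol$ratio_form, 12, tolerance = 1e-12)
  # zero measurement signal with no offset: C_act = 0
  sol0 <- solve_c_act(fake_stats(20, 0), fake_stats(0, 0), known, fit)
  expect_equal(sol0$delta_S, 0)
  expect_equal(sol0$c_act, 0)
})

test_that("additive/ratio form agreement holds across random inputs", {
  set.seed(5)
  for (i in 1:50) {
    K <- runif(1, 0.5, 5); C <- runif(1, 1, 20)
    Mhat <- runif(1, 5, 50); M <- runif(1, 5, 50)
    sol <- solve_c_act(fake_stats(Mhat, 0), fake_stats(M, 0),
                       list(known_concentration = C), list(K = K))
    expect_equal(sol$ratio_form, sol$c_act, tolerance = 1e-10)
  }
})

test_that("the additive bound combines its type-A and type-B terms", {
  # zero variances: only the type-B standard term survives
  b0 <- bound_additive(fake_stats(10, 0), fake_stats(10, 0), gamma_i = 0.01)
  expect_equal(as.numeric(b0), 0.01)
  expect_equal(attr(b0, "type_A"), 0)
  # gamma^2 terms of 1e-4 each with g = 2
  cs <- fake_stats(10, v_max = 1e-4 * 100)   # v_max / M^2 = 1e-4
  ms <- fake_stats(10, v_max = 1e-4 * 100)
  b1 <- bound_additive(cs, ms, gamma_i = 0, g = 2)
  expect_equal(as.numeric(b1), 2 * sqrt(2e-4), tolerance = 1e-12)
  # doubling g doubles type A only
  b2 <- bound_additive(cs, ms, gamma_i = 0.03, g = 4)
  expect_equal(attr(b2, "type_A"), 2 * attr(b1, "type_A"))
  expect_equal(attr(b2, "type_B"), 0.03)
  # invariance under common rescaling of all areas
  scale <- 7.3
  b3 <- bound_additive(fake_stats(10 * scale, 1e-2 * scale^2),
                  fake_stats(12 * scale, 2e-2 * scale^2), gamma_i = 0.01)
  b4 <- bound_additive(fake_stats(10, 1e-2), fake_stats(12, 2e-2), gamma_i = 0.01)
  expect_equal(as.numeric(b3), as.numeric(b4), tolerance = 1e-12)
  # the per-definition denominator normalizes the measurement term by M^2
  b5 <- bound_additive(fake_stats(10, 1e-2), fake_stats(20, 4e-2), gamma_i = 0,
                  g = 2, denominator = "own_mean")
  expect_equal(as.numeric(b5), 2 * sqrt(1e-2 / 100 + 4e-2 / 400),
               tolerance = 1e-12)
})

test_that("the multiplicative bound reproduces its term structure", {
  known <- list(known_concentration = 10, known_rel_error = 0.02)
  # all variances zero, delta = 0: only the rescaled standard term
  b0 <- bound_multiplicative(fake_stats(18, 0), fake_stats(22, 0), known,
                  delta_S = 2, delta = 0)
  expect_equal(as.numeric(b0), 0.02 * 24 / 20, tolerance = 1e-12)
  # M = Mhat: the K-uncertainty term vanishes regardless of delta
  b1 <- bound_multiplicative(fake_stats(18, 0), fake_stats(18, 0), known,
                  delta_S = 2, delta = 0.4)
  expect_equal(attr(b1, "term_K"), 0)
  # full numeric case: (1/10) * (|22-18| * (20/24) * 0.05) = 0.016667
  known0 <- list(known_concentration = 10, known_rel_error = 0)
  b2 <- bound_multiplicative(fake_stats(18, 0), fake_stats(22, 0), known0,
                  delta_S = 2, delta = 0.05)
  expect_equal(as.numeric(b2), 1 / 10 * 4 * (20 / 24) * 0.05,
               tolerance = 1e-12)
})

test_that("required replicates bracket the target and behave monotonically", {
  expect_equal(required_replicates(0.05, gamma_i = 0, observed_sigma_rel = 0), 2L)
  expect_error(required_replicates(0.01, gamma_i = 0.02,
                                   observed_sigma_rel = 0.01),
               "unattainable")
  n <- required_replicates(0.021, gamma_i = 0.02, observed_sigma_rel = 0.05)
  # verify by evaluating the additive bound at n and n - 1
  bound_at <- function(n) {
    2 * sqrt(2 * 0.05^2 / qchisq(0.05, n - 1)) + 0.02
  }
  expect_lte(bound_at(n), 0.021)
  expect_gt(bound_at(n - 1), 0.021)
  # tightening the target never lowers n
  n2 <- required_replicates(0.0205, gamma_i = 0.02, observed_sigma_rel = 0.05)
  expect_gte(n2, n)
})
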