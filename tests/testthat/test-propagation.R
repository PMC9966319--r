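# Forward-mode sensitivity propagation, the random and systematic bounds,
# and the Monte Carlo alternative.

# A prepared noisy-phantom stack shared by several blocks.
prop_fixture <- function(noise_sd = 0.15, n = 8L, seed = 23L) {
  spec <- gel_phantom_spec(
    lanes = list(list(band_spec("main", 5, 0.42, 0.015),
                      band_spec("side", 2, 0.52, 0.015))),
    image_height = 128, image_width = 24,
    impulse_response = gaussian_psf(0.02, 1 / 127),
    baseline_model = list(type = "polynomial", coefficients = c(8, 12)),
    noise_sd = noise_sd, replicate_jitter = 0L, gain = 10, seed = seed)
  lane <- range(gelquantr:::lane_columns(spec, 1))
  st <- build_stack(render_replicates(spec, n), max_shift = 0)
  pp <- gel_pipeline(lane, spec$impulse_response, baseline_window = 41,
                     baseline_smooth = 7, lambda = "auto", kind = "cosine",
                     max_iter = 60, target_support = c(0.32, 0.47), gain = 10)
  list(spec = spec, st = st, pp = pp, lane = lane)
}

test_that("unregistered pipeline stages are rejected by name", {
  psf <- gaussian_psf(0.02, 1 / 99)
  expect_error(gel_pipeline(c(1, 5), psf, stages = c("baseline", "fourier")),
               "fourier")
})

test_that("a linear read-out pipeline has the trapezoid weights as derivative", {
  mi <- matrix(1, 80, 10); vm <- matrix(0.04, 80, 10)
  st <- fake_stack(mi, vm)
  psf <- gaussian_psf(0.02, 1 / 79)
  pp <- gel_pipeline(c(2, 6), psf, lambda = 0, target_support = c(0.3, 0.7),
                     stages = "area")
  sens <- forward_sensitivity(pp, st)
  w <- sens$record$weights
  expect_equal(sens$d_dh, w)
  # d/dI is the row weight replicated across the lane, zero outside
  expect_equal(sens$d_dI[, 2], w)
  expect_true(all(sens$d_dI[, c(1, 7:10)] == 0))
  # closed-form random bound for a linear functional with uniform variance
  rb <- random_bound(sens, st$variance_of_mean, g = 2)
  expect_equal(rb, 2 * sqrt(0.04 * 5 * sum(w^2)), tolerance = 1e-12)
  expect_error(random_bound(sens, -st$variance_of_mean), "negative variance")
})

test_that("linear pipeline: the analytic bound matches Monte Carlo exactly", {
  mi <- matrix(2, 60, 8); vm <- matrix(0.09, 60, 8)
  psf <- gaussian_psf(0.02, 1 / 59)
  pp <- gel_pipeline(c(3, 6), psf, lambda = 0, target_support = c(0.2, 0.8),
                     stages = "area")
  st <- fake_stack(mi, vm)
  sens <- forward_sensitivity(pp, st)
  rb <- random_bound(sens, vm, g = 2)
  mc <- monte_carlo_uq(pp, mi, vm, n_draws = 3000, seed = 5, g = 2)
  # exact linearization: g * sd agrees with the bound within MC error
  mc_se <- 2 * mc$sd / sqrt(2 * (3000 - 1))
  expect_lt(abs(2 * mc$sd - rb), 4 * mc_se)
  # normal theory: central-interval half-width ~ 1.96 sd at the 95% level
  half <- (mc$hi - mc$lo) / 2
  expect_equal(half, qnorm(1 - (1 - mc$level) / 2) * mc$sd, tolerance = 0.1)
  # determinism
  mc2 <- monte_carlo_uq(pp, mi, vm, n_draws = 3000, seed = 5, g = 2)
  expect_identical(mc, mc2)
})

test_that("full-chain forward sensitivity matches central finite differences", {
  fx <- prop_fixture()
  sens <- forward_sensitivity(fx$pp, fx$st)
  rec <- sens$record
  scale <- max(abs(rec$h))
  idx <- seq(10, 120, by = 14)
  fd <- vapply(idx, function(i) {
    s <- 1e-5 * scale
    hp <- rec$h; hp[i] <- hp[i] + s
    hm <- rec$h; hm[i] <- hm[i] - s
    (gelquantr:::chain_value(rec, hp) - gelquantr:::chain_value(rec, hm)) / (2 * s)
  }, numeric(1))
  expect_lt(max(abs(sens$d_dh[idx] - fd)) / max(abs(fd)), 1e-3)
})

test_that("tangent propagation is independent of direction batching", {
  fx <- prop_fixture()
  p <- extract_profile(fx$st, fx$pp$lane_bounds)
  rec <- gelquantr:::chain_record(fx$pp, p$h, p$var_h, p$m)
  n <- length(p$h)
  full <- gelquantr:::chain_jvp(rec, diag(n))
  split <- c(gelquantr:::chain_jvp(rec, diag(n)[, 1:40]),
             gelquantr:::chain_jvp(rec, diag(n)[, 41:n]))
  expect_equal(unname(full), unname(split), tolerance = 1e-12)
})

test_that("random bound tracks the Monte Carlo spread of the full chain", {
  fx <- prop_fixture()
  sens <- forward_sensitivity(fx$pp, fx$st)
  rb <- random_bound(sens, fx$st$variance_of_mean, g = 2)
  lane_cols <- match(fx$pp$lane_bounds[1]:fx$pp$lane_bounds[2],
                     fx$st$crop_window$cols)
  ppc <- fx$pp; ppc$lane_bounds <- range(lane_cols)
  mc <- monte_carlo_uq(ppc, fx$st$mean_image, fx$st$variance_of_mean,
                       n_draws = 1000, seed = 7, g = 2)
  expect_equal(rb, 2 * mc$sd, tolerance = 0.25)
})

test_that("systematic bound: constant map collapses to mean times carrier length", {
  fx <- prop_fixture()
  sens <- forward_sensitivity(fx$pp, fx$st)
  n <- length(sens$d_dfh)
  const_map <- structure(list(delta_syst = rep(0.7, n), delta_syst_mean = 0.7,
                              forbidden_regions = list(c(0, 0.1)),
                              warnings = character(0)),
                         class = "syst_bound_map")
  D <- diff(sens$record$support)
  expect_equal(systematic_bound(sens, const_map), 0.7 * D * sens$area_to_c,
               tolerance = 1e-12)
  zero_map <- const_map; zero_map$delta_syst <- rep(0, n)
  zero_map$delta_syst_mean <- 0
  expect_equal(systematic_bound(sens, zero_map), 0)
})

test_that("zero noise and zero systematic give identical Monte Carlo draws", {
  mi <- matrix(3, 50, 6); vm <- matrix(0, 50, 6)
  psf <- gaussian_psf(0.02, 1 / 49)
  pp <- gel_pipeline(c(2, 5), psf, lambda = 0, target_support = c(0.2, 0.8),
                     stages = "area")
  mc <- monte_carlo_uq(pp, mi, vm, n_draws = 120, seed = 1)
  expect_equal(mc$sd, 0)
  expect_equal(mc$lo, mc$hi)
  expect_error(monte_carlo_uq(pp, mi, vm, n_draws = 50, seed = 1), ">= 100")
})

test_that("complex-step derivatives validate the smooth linear sub-chain", {
  # a complex-safe implementation of convolution followed by weighted
  # integration (the smooth part of the chain, no clipping or minima)
  n <- 64
  m <- seq(0, 1, length.out = n)
  psf <- gaussian_psf(0.03, m[2] - m[1])
  r <- psf$r * psf$dm
  half <- (length(r) - 1) / 2
  w <- runif(n)
  f_smooth <- function(x) {
    out <- vector(mode(x), n)
    for (i in seq_len(n)) {
      js <- max(1, i - half):min(n, i + half)
      out[i] <- sum(r[half + 1 + i - js] * x[js])
    }
    sum(w * out)
  }
  set.seed(9)
  x <- runif(n)
  cs <- complex_step_gradient(f_smooth, x, indices = c(5, 20, 40))
  fd <- vapply(c(5, 20, 40), function(k) {
    xp <- x; xp[k] <- xp[k] + 1e-6
    xm <- x; xm[k] <- xm[k] - 1e-6
    (f_smooth(xp) - f_smooth(xm)) / 2e-6
  }, numeric(1))
  expect_equal(cs, fd, tolerance = 1e-6)
})

test_that("processing the mean image is no noisier than averaging per-image results", {
  set.seed(77)
  reps <- 24
  c_mean <- c_per <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- gel_phantom_spec(
      lanes = list(list(band_spec("main", 5, 0.42, 0.02),
                        band_spec("side", 3, 0.50, 0.02))),
      image_height = 96, image_width = 18,
      impulse_response = gaussian_psf(0.02, 1 / 95),
      noise_sd = 0.6, replicate_jitter = 0L, gain = 10,
      seed = 1000L + r)
    lane <- range(gelquantr:::lane_columns(spec, 1))
    st <- build_stack(render_replicates(spec, 6), max_shift = 0)
    pp <- gel_pipeline(lane, spec$impulse_response, baseline_window = 31,
                       baseline_smooth = 5, lambda = 1e-4, kind = "cosine",
                       max_iter = 40, target_support = c(0.32, 0.46),
                       gain = 10)
    sens <- forward_sensitivity(pp, st)
    c_mean[r] <- sens$value
    rec <- sens$record
    per <- vapply(st$aligned, function(a) {
      h <- rowSums(a[, match(lane[1]:lane[2], st$crop_window$cols)])
      gelquantr:::chain_value(rec, h)
    }, numeric(1))
    c_per[r] <- mean(per)
  }
  expect_lte(var(c_mean), var(c_per) * 1.05)
})
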