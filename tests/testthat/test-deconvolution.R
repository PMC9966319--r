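# Tikhonov/minimal-modulus deconvolution and the non-negativity iteration.

test_that("impulse-response constructor enforces its invariants", {
  expect_error(impulse_response(c(1, 2), 0.01), "odd")
  expect_error(impulse_response(c(-1, 2, 1), 0.01), "non-negative")
  expect_error(impulse_response(c(0, 1, 5), 0.01, symmetrize = FALSE),
               "symmetric")
  psf <- gaussian_psf(0.02, 1 / 199)
  expect_equal(psf$area, 1, tolerance = 1e-12)
  expect_equal(psf$r, rev(psf$r))
})

test_that("a delta kernel is inverted exactly; limits behave", {
  dm <- 1 / 255
  delta <- impulse_response(1 / dm, dm)
  m <- seq(0, 1, length.out = 256)
  net <- 5 * dnorm(m, 0.5, 0.05)
  for (k in c("cosine", "hartley")) {
    out <- deconvolve(net, delta, 0, k)
    expect_lt(max(abs(out - net)), 1e-10 * max(net))
  }
  # lambda -> infinity kills the output
  big <- deconvolve(net, delta, 1e12, "cosine")
  expect_lt(max(abs(big)), 1e-6 * max(net))
  # a smooth kernel has near-zero spectral coefficients: lambda = 0 is refused
  psf <- gaussian_psf(0.03, 1 / 255)
  expect_error(deconvolve(net, psf, 0, "cosine"), "ill-posed")
})

test_that("overlapping Gaussian pair: areas recovered within 2%, peaks narrowed", {
  op <- overlap_profile()
  res <- deconvolve_profile(op$blurred, op$psf, lambda = "auto",
                            kind = "cosine", max_iter = 300)
  pk <- detect_peaks(res$h_act, op$m, 0.02)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$area[1], 3, tolerance = 0.02)
  expect_equal(pk$area[2], 1, tolerance = 0.02)
  # the valley between the peaks deepens after deconvolution
  valley <- op$m > 0.45 & op$m < 0.55
  expect_lt(min(res$h_act[valley]) / max(res$h_act),
            min(op$blurred[valley]) / max(op$blurred))
  # negativity energy small relative to signal energy
  expect_lt(sum(pmin(res$h_act, 0)^2), 1e-4 * sum(res$h_act^2))
  # trace non-increasing after the first iteration
  tr <- res$negativity_energy_trace
  if (length(tr) > 1)
    expect_true(all(diff(tr) <= 1e-10 * max(tr, 1e-300)))
})

test_that("area is conserved across 1-4 band phantoms and both transforms", {
  set.seed(6)
  for (nb in 1:4) {
    centers <- seq(0.3, 0.7, length.out = nb)
    amounts <- runif(nb, 1, 4)
    op <- overlap_profile(amounts = amounts, centers = centers,
                          width = 0.012, psf_width = 0.025)
    for (k in c("cosine", "hartley")) {
      res <- deconvolve_profile(op$blurred, op$psf, lambda = "auto",
                                kind = k, max_iter = 200)
      expect_equal(gelquantr:::trapz(op$m, res$h_act),
                   gelquantr:::trapz(op$m, op$blurred), tolerance = 0.01)
    }
  }
})

test_that("reconvolution of the solution reproduces the data near the noise floor", {
  op <- overlap_profile()
  set.seed(8)
  noise_sd <- 0.02 * max(op$blurred)
  noisy <- op$blurred + rnorm(length(op$blurred), 0, noise_sd)
  res <- deconvolve_profile(noisy, op$psf, lambda = "auto", kind = "cosine",
                            max_iter = 150, noise_rms = noise_sd)
  expect_lt(res$reconv_residual, 1.5 * noise_sd)
})

test_that("the two transform routes agree on the same deconvolution problem", {
  # the routes share the linear filter but differ in boundary topology
  # (even reflection vs circular wrap), so agreement is asserted away from
  # one kernel half-width of the ends
  op <- overlap_profile()
  half <- (length(op$psf$r) - 1) / 2
  interior <- (half + 1):(length(op$blurred) - half)
  for (lam in c(1e-6, 1e-3)) {
    a <- deconvolve(op$blurred, op$psf, lam, "cosine")
    b <- deconvolve(op$blurred, op$psf, lam, "hartley")
    expect_lt(max(abs(a - b)[interior]), 1e-4 * max(abs(a)))
  }
})

test_that("non-negativity iteration: fixed point, single-pass stop, no-convergence flag", {
  op <- overlap_profile()
  dom <- gelquantr:::deconv_domain(length(op$blurred), op$psf, "cosine")
  lam <- 1e-5
  g <- dom$R / (dom$R^2 + lam)
  spec0 <- g * dom$fwd(op$blurred)
  constraint <- list(spectrum = spec0, passband = dom$R^2 >= lam, domain = dom)
  x0 <- dom$inv(spec0)
  # a signal consistent with its own passband constraint and non-negative is
  # a fixed point: returned unchanged after one iteration
  xpos <- pmax(x0, 0)
  cpos <- list(spectrum = dom$fwd(xpos), passband = rep(TRUE, dom$L2),
               domain = dom)
  r1 <- howard_iterate(xpos, cpos, max_iter = 10, tol = 1e-12)
  expect_equal(r1$iterations, 1L)
  expect_equal(r1$h_act, xpos, tolerance = 1e-10)
  # tol = Inf stops after exactly one clipping pass
  r2 <- howard_iterate(x0, constraint, max_iter = 50, tol = Inf)
  expect_equal(r2$iterations, 1L)
  # max_iter reached returns converged = FALSE, not an error
  r3 <- howard_iterate(x0, constraint, max_iter = 2, tol = 0)
  expect_false(r3$converged)
  expect_equal(r3$iterations, 2L)
  expect_error(howard_iterate(x0, constraint, max_iter = 0), "max_iter")
})

test_that("the impulse response is recoverable from an isolated band", {
  n <- 400
  m <- seq(0, 1, length.out = n)
  dm <- m[2] - m[1]
  true_psf <- gaussian_psf(0.02, dm)
  # grid-exact point mass of total amount 2: the band shape IS the kernel
  spike <- numeric(n); spike[which.min(abs(m - 0.5))] <- 2 / dm
  h <- gelquantr:::convolve_density(spike, true_psf, dm)
  p <- lane_profile(m, h)
  est <- estimate_psf(p, c(0.3, 0.7))
  # compare on the common support, unit-height scale
  k <- min(length(est$r), length(true_psf$r))
  ctr_e <- (length(est$r) + 1) / 2; ctr_t <- (length(true_psf$r) + 1) / 2
  half <- (k - 1) / 2
  re <- est$r[(ctr_e - half):(ctr_e + half)]
  rt <- true_psf$r[(ctr_t - half):(ctr_t + half)]
  expect_lt(sqrt(mean((re / max(re) - rt / max(rt))^2)), 0.02)
  expect_equal(est$r, rev(est$r))   # symmetrized by construction
  # flat interval: no band
  expect_error(estimate_psf(lane_profile(m, rep(0, n)), c(0.3, 0.7)), "no band")
  # two bands in the interval: refused
  spike2 <- spike; spike2[which.min(abs(m - 0.62))] <- 2 / dm
  h2 <- gelquantr:::convolve_density(spike2, true_psf, dm)
  expect_error(estimate_psf(lane_profile(m, h2), c(0.3, 0.8)), "multiple bands")
  # an asymmetric band still yields an exactly self-mirrored kernel
  h3 <- 3 * dgamma((m - 0.35) * 20, shape = 2, rate = 4)
  est3 <- estimate_psf(lane_profile(m, pmax(h3, 0)), c(0.3, 0.9))
  expect_equal(est3$r, rev(est3$r))
})
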