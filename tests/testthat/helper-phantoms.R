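# Shared fixtures: all synthetic, generated in code at test time.

# Two well-separated bands, unit-area Gaussian point-spread.
two_band_spec <- function(noise_sd = 0, jitter = 0L, seed = 11L, H = 160L,
                          W = 36L, gain = 10, baseline = NULL,
                          psf_width = 0.02) {
  gel_phantom_spec(
    lanes = list(list(band_spec("a", 5, 0.40, 0.02),
                      band_spec("b", 2, 0.60, 0.02))),
    image_height = H, image_width = W,
    impulse_response = gaussian_psf(psf_width, 1 / (H - 1)),
    baseline_model = baseline, noise_sd = noise_sd,
    replicate_jitter = jitter, gain = gain, seed = seed)
}

# Net (baseline-free) profile of overlapping Gaussian peaks plus its blur.
overlap_profile <- function(n = 512L, amounts = c(3, 1),
                            centers = c(0.45, 0.55), width = 0.015,
                            psf_width = 0.03) {
  m <- seq(0, 1, length.out = n)
  dm <- m[2] - m[1]
  truth <- numeric(n)
  for (i in seq_along(amounts))
    truth <- truth + amounts[i] * dnorm(m, centers[i], width)
  psf <- gaussian_psf(psf_width, dm)
  list(m = m, dm = dm, truth = truth, psf = psf,
       blurred = gelquantr:::convolve_density(truth, psf, dm))
}

# Minimal hand-built aligned_stack for arithmetic checks.
fake_stack <- function(mean_image, variance_of_mean, n = 4L) {
  structure(list(
    n = n, offsets = matrix(0L, n, 2),
    aligned = replicate(n, mean_image, simplify = FALSE),
    mean_image = mean_image, variance = variance_of_mean * n,
    variance_of_mean = variance_of_mean,
    crop_window = list(rows = seq_len(nrow(mean_image)),
                       cols = seq_len(ncol(mean_image))),
    mean_variance_divisor = "n", ids = NULL),
    class = "aligned_stack")
}

# Hand-built replicate_stats with prescribed mean and bounded variance.
fake_stats <- function(mean, v_max, n = 10L, P = 0.95) {
  structure(list(n = n, mean = mean, var = NA_real_, var_of_mean = NA_real_,
                 v_max = v_max, gamma2_mean = v_max / mean^2, confidence = P,
                 chi2_quantile = qchisq(1 - P, n - 1), divisor_mode = "n-1"),
            class = "replicate_stats")
}
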