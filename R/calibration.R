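## Uncertainty with standard samples: replicate statistics with chi-square
## one-sided confidence bounds on the variance of the mean, least-squares
## calibration of the sensitivity coefficient K, recovery of the actual
## content, closed-form relative-error bounds, and the inverse sample-size
## problem.

#' Chi-square inflation factor for a variance bound
#'
#' The ratio `V_max / sigma^2_mean = (n - 1) / chisq_{1-P}(n - 1)` by which
#' the one-sided upper confidence bound at probability `P` inflates the
#' estimated variance of the mean.  Greater than 1 for `P = 0.95` and
#' decreasing in `n`.
#'
#' @param n Number of replicates, >= 2.
#' @param P Confidence probability in (0, 1).
#' @return The inflation factor.
#' @export
chi2_inflation <- function(n, P = 0.95) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  (n - 1) / stats::qchisq(1 - P, df = n - 1)
}

#' Relative statistical uncertainty of a replicate standard deviation
#'
#' How far the true standard deviation may exceed its point estimate from `n`
#' repeats, at one-sided confidence `P`:
#' `sqrt((n - 1) / chisq_{1-P}(n - 1)) - 1`.  With 30 or fewer repeats at 95%
#' confidence this is at least 25--30%, which is why reproducibility studies
#' on few repeats need the accompanying uncertainty statement.
#'
#' @inheritParams chi2_inflation
#' @return Relative excess (0.28 means +28%).
#' @export
sd_rel_uncertainty <- function(n, P = 0.95) {
  sqrt(chi2_inflation(n, P)) - 1
}

#' Replicate statistics with a chi-square variance bound
#'
#' For replicate peak areas: the mean `M`, sample variance `sigma^2`
#' (divisor `n - 1`), variance of the mean (divisor `n - 1` by default,
#' matching the replicate-area convention; `"n"` exposes the image-domain
#' convention), the one-sided upper confidence bound
#' `V_max = (n - 1)/chisq_{1-P}(n - 1) * sigma^2_mean`, and the bounded
#' relative variance `gamma^2_mean = V_max / M^2`.
#'
#' @param values Replicate areas, length >= 2.
#' @param confidence Confidence probability `P` (default 0.95).
#' @param divisor_mode `"n-1"` (default) or `"n"` for the variance of the
#'   mean.
#' @return Object of class `replicate_stats` with fields `n`, `mean`, `var`,
#'   `var_of_mean`, `v_max`, `gamma2_mean`, `confidence`, `chi2_quantile`.
#' @export
replicate_stats <- function(values, confidence = 0.95,
                            divisor_mode = c("n-1", "n")) {
  divisor_mode <- match.arg(divisor_mode)
  n <- length(values)
  if (n < 2L) stop("need >= 2 replicates", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  M <- mean(values)
  s2 <- sum((values - M)^2) / (n - 1)
  div <- if (divisor_mode == "n-1") n - 1 else n
  s2m <- s2 / div
  q <- stats::qchisq(1 - confidence, df = n - 1)
  vmax <- (n - 1) / q * s2m
  if (M == 0 && s2 > 0)
    stop("zero mean with nonzero variance: relative statistics undefined",
         call. = FALSE)
  g2 <- if (M == 0) 0 else vmax / M^2
  structure(list(n = n, mean = M, var = s2, var_of_mean = s2m, v_max = vmax,
                 gamma2_mean = g2, confidence = confidence, chi2_quantile = q,
                 divisor_mode = divisor_mode),
            class = "replicate_stats")
}

#' Fit the sensitivity coefficient K by least squares
#'
#' Calibration model: replicate area `S_ij = K * C_i - DS + noise`.  `K` and a
#' common intercept are fitted by least squares over every (non-censored)
#' replicate of every calibration component; per-component systematic offsets
#' `DS_i = K * C_i - M_i` are then recovered from the component means.  The
#' relative uncertainty of `K` is reported as `delta = g * SE(K) / K`.
#'
#' @param calibration List of components, each a list with
#'   `known_concentration` (`C_i > 0`), `known_rel_error` (`gamma_i >= 0`),
#'   and `replicate_areas` (length >= 2).
#' @param censored_flags Optional list of logical vectors matching
#'   `replicate_areas`; censored observations are excluded with a warning.
#' @param g Coverage factor scaling the standard error of `K` (default 2).
#' @return Object of class `calibration_fit` with `K`, `delta_K_rel`,
#'   `delta_S` (per component), `intercept`, and the fitted `lm` summary
#'   pieces.
#' @export
fit_sensitivity <- function(calibration, censored_flags = NULL, g = 2) {
  stopifnot(length(calibration) >= 1L)
  C <- S <- numeric(0)
  comp <- integer(0)
  for (i in seq_along(calibration)) {
    areas <- calibration[[i]]$replicate_areas
    if (length(areas) < 2L) stop("each component needs >= 2 replicates",
                                 call. = FALSE)
    keep <- rep(TRUE, length(areas))
    if (!is.null(censored_flags)) {
      keep <- !censored_flags[[i]]
      if (any(!keep))
        warning(sprintf("component %d: %d censored replicate(s) excluded from the fit",
                        i, sum(!keep)), call. = FALSE)
    }
    C <- c(C, rep(calibration[[i]]$known_concentration, sum(keep)))
    S <- c(S, areas[keep])
    comp <- c(comp, rep(i, sum(keep)))
  }
  if (length(S) == 0L || all(S == 0))
    stop("unidentifiable: no usable (non-zero) calibration areas", call. = FALSE)
  if (length(unique(C)) < 2L)
    stop("unidentifiable design: need >= 2 distinct known concentrations",
         call. = FALSE)
  fit <- stats::lm(S ~ C)
  K <- unname(stats::coef(fit)[2])
  if (!is.finite(K) || K <= 0)
    stop("calibration fit produced non-positive K", call. = FALSE)
  # exact synthetic data triggers lm's perfect-fit note; SE(K) = 0 is correct
  se_K <- suppressWarnings(summary(fit)$coefficients[2, 2])
  delta <- g * se_K / K
  delta_S <- vapply(seq_along(calibration), function(i) {
    K * calibration[[i]]$known_concentration -
      mean(calibration[[i]]$replicate_areas[
        if (is.null(censored_flags)) TRUE else !censored_flags[[i]]])
  }, numeric(1))
  structure(list(K = K, delta_K_rel = delta, delta_S = delta_S,
                 intercept = unname(stats::coef(fit)[1]), se_K = se_K, g = g),
            class = "calibration_fit")
}

#' Recover the actual content of a component
#'
#' Solves the two-equation system of the calibration and measurement means:
#' `M_cal = K * C - DS` and `M_meas = K * C_act - DS`, giving
#' `DS = K * C - M_cal` and `C_act = C + (M_meas - M_cal) / K`.  The
#' equivalent ratio form `C_act = C * (M_meas + DS) / (M_cal + DS)` is
#' computed as a cross-check and must agree to 1e-10 relative (unless the
#' ratio is degenerate, in which case the additive form is returned flagged).
#'
#' @param calib_stats [replicate_stats()] of the calibration areas (mean
#'   `M_cal`).
#' @param meas_stats [replicate_stats()] of the measurement areas (mean
#'   `M_meas`).
#' @param known List with `known_concentration` (`C`) and `known_rel_error`.
#' @param fit A [fit_sensitivity()] result (or any list with positive `K`).
#' @return List with `c_act`, `delta_S`, `ratio_form`, `degenerate_ratio`.
#' @export
solve_c_act <- function(calib_stats, meas_stats, known, fit) {
  K <- fit$K
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  C <- known$known_concentration
  Mhat <- calib_stats$mean
  M <- meas_stats$mean
  dS <- K * C - Mhat
  c_act <- C + (M - Mhat) / K
  degenerate <- abs(Mhat + dS) < 1e-300
  ratio <- if (degenerate) NA_real_ else C * (M + dS) / (Mhat + dS)
  if (!degenerate && abs(ratio - c_act) > 1e-10 * max(1, abs(c_act)))
    stop("internal inconsistency between additive and ratio forms",
         call. = FALSE)
  list(c_act = c_act, delta_S = dS, ratio_form = ratio,
       degenerate_ratio = degenerate)
}

#' Relative-error bound from the additive error decomposition
#'
#' The marginal relative error of the recovered content:
#' `g * sqrt(gamma2_cal + gamma2_meas) + gamma_i`, where the two relative
#' variance terms carry the chi-square bound from [replicate_stats()].  By
#' default both terms are normalized by the calibration mean squared, which
#' keeps the bound a pure function of the calibration scale; set
#' `denominator = "own_mean"` to normalize the measurement term by its own
#' mean instead.  The two conventions differ whenever the sample and the
#' standard respond differently, and both are exposed deliberately rather
#' than silently harmonized.
#'
#' @param calib_stats,meas_stats [replicate_stats()] of calibration and
#'   measurement areas.
#' @param gamma_i Relative error of the known standard concentration
#'   (type-B term).
#' @param g Coverage factor (default 2).
#' @param denominator `"calibration_mean"` (both over `M_cal^2`) or
#'   `"own_mean"` (each over its own mean squared).
#' @return The bound, with attributes `type_A` and `type_B` giving the budget
#'   split.
#' @export
bound_additive <- function(calib_stats, meas_stats, gamma_i = 0, g = 2,
                      denominator = c("calibration_mean", "own_mean")) {
  denominator <- match.arg(denominator)
  Mhat <- calib_stats$mean
  if (Mhat == 0) stop("zero calibration mean", call. = FALSE)
  g2_cal <- calib_stats$v_max / Mhat^2
  g2_meas <- switch(denominator,
                    calibration_mean = meas_stats$v_max / Mhat^2,
                    own_mean = meas_stats$v_max / meas_stats$mean^2)
  type_A <- g * sqrt(g2_cal + g2_meas)
  out <- type_A + gamma_i
  attr(out, "type_A") <- type_A
  attr(out, "type_B") <- gamma_i
  out
}

#' Relative-error bound including the calibration-coefficient uncertainty
#'
#' The bound from the multiplicative error decomposition:
#' `gamma_i * (M + DS)/(Mhat + DS) + (1/C) * (g * sqrt(Vhat_max +
#' (Mhat^2/M^2) * V_max) + |M - Mhat| * (Mhat + DS)/(M + DS) * delta)`,
#' with `Vhat_max`, `V_max` the chi-square-bounded variances of the means and
#' `delta` the maximum relative uncertainty of `K`.  The `delta` term is
#' correlated with the calibration-mean errors; the conservative plain sum is
#' used, so the bound errs high.
#'
#' @inheritParams bound_additive
#' @param known List with `known_concentration` and `known_rel_error`.
#' @param delta_S Systematic offset `DS` for this component.
#' @param delta Maximum relative uncertainty of `K` (e.g.
#'   `fit$delta_K_rel`).
#' @return The bound, with attributes splitting the three terms.
#' @export
bound_multiplicative <- function(calib_stats, meas_stats, known, delta_S, delta, g = 2) {
  Mhat <- calib_stats$mean
  M <- meas_stats$mean
  C <- known$known_concentration
  gamma_i <- known$known_rel_error %||% 0
  if (C <= 0) stop("known concentration must be > 0", call. = FALSE)
  if (abs(Mhat + delta_S) < 1e-300 || abs(M + delta_S) < 1e-300)
    stop("degenerate means: M + DS = 0", call. = FALSE)
  ratio <- (M + delta_S) / (Mhat + delta_S)
  term_std <- gamma_i * ratio
  term_rand <- g * sqrt(calib_stats$v_max + (Mhat^2 / M^2) * meas_stats$v_max) / C
  term_K <- abs(M - Mhat) / ratio * delta / C
  out <- term_std + term_rand + term_K
  attr(out, "term_std") <- term_std
  attr(out, "term_rand") <- term_rand
  attr(out, "term_K") <- term_K
  out
}

#' Number of replicates needed for a target accuracy
#'
#' The inverse problem: the smallest `n >= 2` such that the additive bound,
#' evaluated with equal pilot relative scatter for calibration and
#' measurement, does not exceed the target.  The chi-square quantile depends
#' on `n`, so `n` is found by upward scan; the result brackets the target
#' (the bound at `n - 1` exceeds it).
#'
#' @param target_bound Required relative error, must exceed `gamma_i`.
#' @param gamma_i Relative error of the standard.
#' @param observed_sigma_rel Pilot relative standard deviation of a single
#'   replicate area.
#' @param P Confidence probability for the variance bound.
#' @param g Coverage factor.
#' @param n_max Scan cap (error if exceeded).
#' @return Integer `n`.
#' @export
required_replicates <- function(target_bound, gamma_i = 0,
                                observed_sigma_rel = 0, P = 0.95, g = 2,
                                n_max = 100000L) {
  if (target_bound <= gamma_i)
    stop(sprintf("unattainable target: the type-B floor gamma_i = %g is not below %g",
                 gamma_i, target_bound), call. = FALSE)
  if (observed_sigma_rel <= 0) return(2L)
  bound_at <- function(n) {
    # gamma2_mean = V_max / M^2 with sigma^2_mean = sigma^2/(n-1):
    # (n-1)/chisq * sigma_rel^2/(n-1) = sigma_rel^2 / chisq_{1-P}(n-1)
    q <- stats::qchisq(1 - P, df = n - 1)
    g * sqrt(2 * observed_sigma_rel^2 / q) + gamma_i
  }
  for (n in 2:n_max) {
    if (bound_at(n) <= target_bound) return(as.integer(n))
  }
  stop("required replicate count exceeds n_max = ", n_max, call. = FALSE)
}

#' Empirical coverage of the g-sigma expanded interval
#'
#' Simulates Gaussian replicate sets, forms each mean and its estimated
#' standard error (divisor `n - 1` on the variance of the mean), and reports
#' the fraction of simulations in which the true mean lies inside
#' `mean +/- g * SE`.  For near-normal data, `g = 2` yields coverage of about
#' 0.90--0.95, the basis for the default coverage factor.
#'
#' @param g Coverage factor.
#' @param n Replicates per simulated set.
#' @param n_sim Number of simulated sets.
#' @param seed Integer seed.
#' @return Fraction covered.
#' @export
coverage_simulation <- function(g = 2, n = 10L, n_sim = 1e5, seed = 1L) {
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_sim * n), ncol = n)
    means <- rowMeans(x)
    se <- sqrt(apply(x, 1L, stats::var) / (n - 1))
    mean(abs(means) <= g * se)
  })
}
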