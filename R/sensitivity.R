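## Uncertainty propagation without standard samples: the measurement is
## C = f(I_mean), the composition of profile extraction, lower-envelope
## baseline removal, regularized deconvolution with the non-negativity
## iteration, and peak integration.  Random pixel errors are pushed through f
## by forward-mode dual-value propagation (a value paired with directional
## derivatives carried through every operation; at kinks -- clipping, running
## minima -- the one-sided derivative of the evaluated branch is used), giving
## the linearized random-error bound; baseline residuals from forbidden
## regions give the systematic bound; a Monte Carlo alternative avoids the
## linearization.

REGISTERED_STAGES <- c("baseline", "deconvolve", "howard", "area")

#' Define the post-averaging processing pipeline
#'
#' A declarative description of `f`: which stages run, with which parameters.
#' Only registered, sensitivity-capable stages are allowed.
#'
#' @param lane_bounds Column interval `c(lo, hi)` of the lane, in the frame of
#'   the image the pipeline is applied to.
#' @param psf An [impulse_response()].
#' @param baseline_window,baseline_smooth Envelope parameters, see
#'   [estimate_baseline()].
#' @param lambda Regularization: numeric, or `"auto"` for the discrepancy
#'   rule (resolved once on the reference data and then frozen).
#' @param kind Transform route, `"cosine"` or `"hartley"`.
#' @param max_iter,tol Non-negativity iteration controls.
#' @param target_support Mobility interval `c(lo, hi)` of the quantified
#'   peak; `NULL` selects the largest-area detected peak on the reference
#'   data and freezes its carrier.
#' @param min_prominence Peak-detection prominence for automatic target
#'   selection.
#' @param gain Sensitivity coefficient converting area to amount (C = area /
#'   gain); default 1 reports the area itself.
#' @param stages Ordered stage names; must be a subset of the registered set.
#' @return Object of class `gel_pipeline`.
#' @export
gel_pipeline <- function(lane_bounds, psf, baseline_window = 41L,
                         baseline_smooth = 11L, lambda = "auto",
                         kind = c("cosine", "hartley"), max_iter = 200L,
                         tol = NULL, target_support = NULL,
                         min_prominence = 0.05, gain = 1,
                         stages = REGISTERED_STAGES) {
  kind <- match.arg(kind)
  unknown <- setdiff(stages, REGISTERED_STAGES)
  if (length(unknown))
    stop("unsupported pipeline operation(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(lane_bounds = lane_bounds, psf = psf,
                 baseline_window = as.integer(baseline_window),
                 baseline_smooth = as.integer(baseline_smooth),
                 lambda = lambda, kind = kind, max_iter = as.integer(max_iter),
                 tol = tol, target_support = target_support,
                 min_prominence = min_prominence, gain = gain,
                 stages = stages),
            class = "gel_pipeline")
}

# Evaluate the profile-level chain once, recording everything the tangent
# propagation needs to replay the same control flow: the running-min argmin
# indices, the clip branches, the resolved lambda, the per-iteration
# negativity masks, the iteration count, and the frozen target support.
chain_record <- function(pp, h, var_h = NULL, m = NULL) {
  n <- length(h)
  if (is.null(m)) m <- seq(0, 1, length.out = n)
  rec <- list(pp = pp, h = h, m = m, n = n)

  if ("baseline" %in% pp$stages) {
    rmn <- running_min(h, pp$baseline_window)
    b1 <- running_mean(rmn$min, pp$baseline_smooth)
    low <- b1 < 0
    b2 <- pmax(b1, 0)
    high <- b2 > h
    h0 <- pmin(b2, h)
    rec$baseline <- list(idx = rmn$idx, low = low, high = high, h0 = h0)
    net <- h - h0
  } else {
    net <- h
  }
  rec$net <- net

  lambda <- pp$lambda
  if (identical(lambda, "auto")) {
    noise_rms <- if (is.null(var_h)) 0 else sqrt(mean(var_h))
    lambda <- select_lambda(net, pp$psf, noise_rms, pp$kind)
  }
  rec$lambda <- lambda

  if ("deconvolve" %in% pp$stages) {
    dom <- deconv_domain(n, pp$psf, pp$kind)
    g <- dom$R / (dom$R^2 + lambda)
    spec0 <- g * dom$fwd(net)
    x <- dom$inv(spec0)
    rec$dom <- dom; rec$filter <- g; rec$passband <- dom$R^2 >= lambda
    masks <- list()
    if ("howard" %in% pp$stages) {
      tol <- pp$tol
      if (is.null(tol)) tol <- 1e-10 * sum(x^2) + 1e-30
      it <- 0L
      repeat {
        it <- it + 1L
        masks[[it]] <- x < 0
        x <- pmax(x, 0)
        sp <- dom$fwd(x)
        sp[rec$passband] <- spec0[rec$passband]
        x <- dom$inv(sp)
        if (sum(pmin(x, 0)^2) <= tol || it >= pp$max_iter) break
      }
    }
    rec$masks <- masks
    rec$h_act <- x
  } else {
    rec$h_act <- net
  }

  if ("area" %in% pp$stages) {
    support <- pp$target_support
    if (is.null(support)) {
      pk <- detect_peaks(rec$h_act, m, pp$min_prominence)
      if (nrow(pk) == 0L) stop("no peak found for automatic target selection",
                               call. = FALSE)
      support <- unlist(pk[which.max(pk$area), c("m_lo", "m_hi")])
    }
    idx <- which(m >= support[1] & m <= support[2])
    if (length(idx) < 2L) stop("target support too narrow", call. = FALSE)
    w <- numeric(n)
    dm <- diff(m[idx])
    w[idx[1]] <- dm[1] / 2
    w[idx[length(idx)]] <- dm[length(dm)] / 2
    if (length(idx) > 2L)
      w[idx[-c(1, length(idx))]] <- (dm[-1] + dm[-length(dm)]) / 2
    rec$support <- support
    rec$weights <- w
    rec$area <- sum(w * rec$h_act)
    rec$C <- rec$area / pp$gain
  } else {
    rec$C <- NA_real_
  }
  rec
}

# Replay the recorded chain on a perturbed profile (same lambda, same target
# support, natural iteration count): the Monte Carlo evaluator.
chain_value <- function(rec, h) {
  pp <- rec$pp
  pp$lambda <- rec$lambda
  pp$target_support <- rec$support
  r2 <- chain_record(pp, h)
  r2$C
}

# Forward-mode tangent propagation through a recorded chain.  `dH` is an
# n x k matrix of directions with respect to the raw profile h (or the net
# signal when start = "net"); every stage's tangent map is applied columnwise.
chain_jvp <- function(rec, dH, start = c("h", "net")) {
  start <- match.arg(start)
  pp <- rec$pp
  if (!is.matrix(dH)) dH <- matrix(dH, ncol = 1L)
  if (start == "h" && "baseline" %in% pp$stages) {
    bl <- rec$baseline
    d_b1 <- running_mean(dH[bl$idx, , drop = FALSE], pp$baseline_smooth)
    d_h0 <- d_b1
    d_h0[bl$low, ] <- 0
    d_h0[bl$high, ] <- dH[bl$high, , drop = FALSE]
    d_net <- dH - d_h0
  } else {
    d_net <- dH
  }
  if ("deconvolve" %in% pp$stages) {
    dom <- rec$dom
    dspec0 <- rec$filter * dom$fwd(d_net)
    dx <- dom$inv(dspec0)
    for (mask in rec$masks) {
      dx[mask, ] <- 0
      dsp <- dom$fwd(dx)
      dsp[rec$passband, ] <- dspec0[rec$passband, , drop = FALSE]
      dx <- dom$inv(dsp)
    }
  } else {
    dx <- d_net
  }
  drop(crossprod(rec$weights, dx)) / pp$gain
}

#' Forward-mode sensitivity of the concentration to the mean image
#'
#' Computes the derivative of the pipeline output with respect to every pixel
#' of the mean image (and, along the way, with respect to each grid point of
#' the net signal) by pushing directional derivatives through every stage.
#' At kinks -- the clipping steps of the non-negativity iteration, the
#' running minima of the envelope -- the one-sided derivative of the branch
#' actually evaluated is used.  A finite-difference mode exists for
#' validation only.
#'
#' @param pipeline A [gel_pipeline()].
#' @param stack An [build_stack()] result; lane bounds are interpreted in the
#'   original image frame.
#' @param method `"forward-dual"` (default) or `"finite-difference-check"`
#'   (validation only; central differences on the profile).
#' @param fd_step Relative step for the finite-difference mode.
#' @return Object of class `sensitivity_map`: `d_dI` (matrix over the crop
#'   window, zero outside the lane), `d_dfh` (derivative w.r.t. the net
#'   signal), `d_dh` (w.r.t. the raw profile), `value` (the concentration),
#'   `record` (the frozen evaluation), `method`.
#' @export
forward_sensitivity <- function(pipeline, stack,
                                method = c("forward-dual",
                                           "finite-difference-check"),
                                fd_step = 1e-5) {
  method <- match.arg(method)
  stopifnot(inherits(pipeline, "gel_pipeline"), inherits(stack, "aligned_stack"))
  profile <- extract_profile(stack, pipeline$lane_bounds)
  n <- length(profile$h)
  rec <- chain_record(pipeline, profile$h, profile$var_h, profile$m)
  if (method == "forward-dual") {
    grad_h <- chain_jvp(rec, diag(n), start = "h")
    grad_net <- chain_jvp(rec, diag(n), start = "net")
  } else {
    scale <- max(abs(profile$h), 1)
    step <- fd_step * scale
    grad_h <- vapply(seq_len(n), function(i) {
      hp <- profile$h; hp[i] <- hp[i] + step
      hm <- profile$h; hm[i] <- hm[i] - step
      (chain_value(rec, hp) - chain_value(rec, hm)) / (2 * step)
    }, numeric(1))
    grad_net <- grad_h   # FD mode does not separate the baseline dependence
  }
  cw <- stack$crop_window
  d_dI <- matrix(0, length(cw$rows), length(cw$cols))
  lane_cols <- match(pipeline$lane_bounds[1]:pipeline$lane_bounds[2], cw$cols)
  d_dI[, lane_cols] <- grad_h
  structure(list(d_dI = d_dI, d_dfh = grad_net, d_dh = grad_h,
                 value = rec$C, record = rec, method = method,
                 area_to_c = 1 / pipeline$gain),
            class = "sensitivity_map")
}

#' Random-error bound on the concentration
#'
#' The linearized bound
#' `g * sqrt( sum_xy (df/dI_mean(x,y))^2 * sigma^2_mean(x,y) )`,
#' valid under independence of the repeated separations.
#'
#' @param sens A [forward_sensitivity()] result (or any list with `d_dI`).
#' @param variance_of_mean Variance-of-the-mean map on the same grid.
#' @param g Coverage factor (default 2).
#' @return Non-negative bound.
#' @export
random_bound <- function(sens, variance_of_mean, g = 2) {
  if (any(variance_of_mean < 0)) stop("negative variance input", call. = FALSE)
  if (!all(dim(sens$d_dI) == dim(variance_of_mean)))
    stop("shape mismatch between sensitivity and variance maps", call. = FALSE)
  g * sqrt(sum(sens$d_dI^2 * variance_of_mean))
}

#' Systematic-error bound on the concentration
#'
#' `mean(Delta_syst) * D + sum_m |dC/df_h(m)| * |Delta_syst(m) -
#' mean(Delta_syst)|`, with `D` the carrier length of the quantified peak.
#' For a constant map the second term vanishes and the bound is exactly
#' `mean * D` (scaled by the area-to-amount factor when a gain is set).
#'
#' @param sens A [forward_sensitivity()] result.
#' @param syst A [systematic_bounds()] map.
#' @param carrier Mobility interval `c(m_lo, m_hi)` of the quantified peak;
#'   defaults to the pipeline's frozen target support.
#' @return Non-negative bound.
#' @export
systematic_bound <- function(sens, syst, carrier = NULL) {
  stopifnot(inherits(syst, "syst_bound_map"))
  if (is.null(carrier)) carrier <- sens$record$support
  D <- carrier[2] - carrier[1]
  if (D <= 0) stop("carrier interval must have positive length", call. = FALSE)
  syst$delta_syst_mean * D * sens$area_to_c +
    sum(abs(sens$d_dfh) * abs(syst$delta_syst - syst$delta_syst_mean))
}

#' Monte Carlo uncertainty propagation
#'
#' Draws perturbations of the mean image -- an independent Gaussian field
#' with pointwise standard deviation `sqrt(sigma^2_mean)` plus, if a
#' systematic map is given, a fully correlated offset `u * Delta_syst(m)`
#' with one `u ~ U(-1, 1)` per draw -- runs the full pipeline per draw, and
#' summarizes the resulting concentrations.  Deterministic given `seed`.
#'
#' @param pipeline A [gel_pipeline()].
#' @param i_mean Mean image (matrix); lane bounds are taken as columns of
#'   this matrix.
#' @param sigma_mean_map Variance-of-the-mean map, same dimensions.
#' @param syst_model Optional [systematic_bounds()] map on the profile grid.
#' @param n_draws Number of draws, >= 100.
#' @param seed Integer seed.
#' @param g Coverage factor; the central interval reported matches its
#'   nominal normal level (`2*pnorm(g) - 1`).
#' @return List `mc_summary` with `mean`, `sd`, `lo`, `hi`, `level`,
#'   `n_draws`, `n_failed`, `seed`.  More than 1% failed draws is an error.
#' @export
monte_carlo_uq <- function(pipeline, i_mean, sigma_mean_map, syst_model = NULL,
                           n_draws = 1000L, seed = 1L, g = 2) {
  if (n_draws < 100L) stop("n_draws must be >= 100", call. = FALSE)
  stopifnot(all(dim(i_mean) == dim(sigma_mean_map)))
  lane <- pipeline$lane_bounds[1]:pipeline$lane_bounds[2]
  h_ref <- rowSums(i_mean[, lane, drop = FALSE])
  var_h <- rowSums(sigma_mean_map[, lane, drop = FALSE])
  rec <- chain_record(pipeline, h_ref, var_h)
  sd_lane <- sqrt(sigma_mean_map[, lane, drop = FALSE])
  H <- nrow(sd_lane); W <- ncol(sd_lane)
  with_seed(seed, {
    draws <- numeric(n_draws)
    failed <- 0L
    for (d in seq_len(n_draws)) {
      pert <- matrix(stats::rnorm(H * W), H, W) * sd_lane
      h <- h_ref + rowSums(pert)
      if (!is.null(syst_model))
        h <- h + stats::runif(1, -1, 1) * syst_model$delta_syst
      val <- tryCatch(chain_value(rec, h), error = function(e) NA_real_)
      if (is.na(val)) failed <- failed + 1L
      draws[d] <- val
    }
    if (failed > 0.01 * n_draws)
      stop(sprintf("Monte Carlo: %d of %d draws failed", failed, n_draws),
           call. = FALSE)
    ok <- draws[!is.na(draws)]
    level <- 2 * stats::pnorm(g) - 1
    qs <- stats::quantile(ok, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
    list(mean = mean(ok), sd = stats::sd(ok), lo = qs[1], hi = qs[2],
         level = level, n_draws = n_draws, n_failed = failed, seed = seed)
  })
}

#' Full uncertainty report for one lane
#'
#' Assembles the error budget of a single analysis: the concentration from
#' processing the mean image, the random-error bound propagated from the
#' pixel variance maps, the systematic bound from forbidden-region baseline
#' residuals, their sum as the total bound (instrumental errors transformed
#' through the processing chain, plus the processing-chain systematic term),
#' and optionally a Monte Carlo cross-check.
#'
#' @param stack An [build_stack()] result.
#' @param pipeline A [gel_pipeline()].
#' @param forbidden_regions List of mobility intervals free of analyte.
#' @param g Coverage factor.
#' @param mc_draws If > 0, also run [monte_carlo_uq()] with this many draws.
#' @param seed Seed for the Monte Carlo part.
#' @return Object of class `uncertainty_report` with `c`, `rand_bound`,
#'   `syst_bound`, `total_bound`, `mc_summary` (or NULL), `coverage_g`,
#'   `sens`, `syst_map`, `profile`, `baseline`.
#' @export
uncertainty_report <- function(stack, pipeline, forbidden_regions, g = 2,
                               mc_draws = 0L, seed = 1L) {
  profile <- extract_profile(stack, pipeline$lane_bounds)
  baseline <- estimate_baseline(profile, pipeline$baseline_window,
                                pipeline$baseline_smooth)
  syst <- systematic_bounds(profile, baseline, forbidden_regions)
  sens <- forward_sensitivity(pipeline, stack)
  rand <- random_bound(sens, stack$variance_of_mean, g)
  sb <- systematic_bound(sens, syst)
  mc <- NULL
  if (mc_draws > 0) {
    lane_cols <- match(pipeline$lane_bounds[1]:pipeline$lane_bounds[2],
                       stack$crop_window$cols)
    pp_crop <- pipeline
    pp_crop$lane_bounds <- range(lane_cols)
    mc <- monte_carlo_uq(pp_crop, stack$mean_image, stack$variance_of_mean,
                         syst_model = syst, n_draws = mc_draws, seed = seed,
                         g = g)
  }
  structure(list(c = sens$value, rand_bound = rand, syst_bound = sb,
                 total_bound = rand + sb, mc_summary = mc, coverage_g = g,
                 sens = sens, syst_map = syst, profile = profile,
                 baseline = baseline),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report>\n  C          = %.6g\n  rand bound = %.4g\n  syst bound = %.4g\n  total      = %.4g (g = %g)\n",
              x$c, x$rand_bound, x$syst_bound, x$total_bound, x$coverage_g))
  if (!is.null(x$mc_summary))
    cat(sprintf("  MC: mean %.6g, sd %.4g, %.1f%% interval [%.6g, %.6g] (%d draws)\n",
                x$mc_summary$mean, x$mc_summary$sd, 100 * x$mc_summary$level,
                x$mc_summary$lo, x$mc_summary$hi, x$mc_summary$n_draws))
  invisible(x)
}

#' Complex-step derivative of a smooth function
#'
#' Derivative estimation by an imaginary perturbation,
#' `Im(f(x + i*h*e_k)) / h`, exact to rounding for analytic functions
#' implemented without complex-plane-breaking operations (no `Re`, `abs`,
#' clipping, or branching on the value).  Provided as a validation mode for
#' smooth sub-chains; the production engine is the dual-value propagation,
#' which handles the kinks the full pipeline contains.
#'
#' @param f Function accepting a complex vector.
#' @param x Evaluation point (numeric vector).
#' @param indices Coordinates at which to differentiate (default all).
#' @param h Imaginary step (default 1e-20).
#' @return Numeric vector of partial derivatives.
#' @export
complex_step_gradient <- function(f, x, indices = seq_along(x), h = 1e-20) {
  vapply(indices, function(k) {
    xp <- as.complex(x)
    xp[k] <- xp[k] + complex(imaginary = h)
    Im(f(xp)) / h
  }, numeric(1))
}
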