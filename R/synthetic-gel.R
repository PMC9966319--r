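## Synthetic gel phantoms: multi-band lanes with known component amounts,
## Gaussian band spreading by a stated impulse response, additive baseline
## drift, pixel noise of stated variance, and small integer-pixel geometric
## offsets between replicates.  Every downstream stage is testable against the
## ground truth these functions carry.

#' Specify one electrophoretic band
#'
#' A band is one component's stained zone in a lane: a true amount, a center on
#' the normalized electrophoretic-mobility axis, and an intrinsic (pre-blur)
#' Gaussian spread.
#'
#' @param component_id Label for the component.
#' @param amount True substance quantity (arbitrary units); must be >= 0.
#' @param mobility_center Band center on the normalized mobility axis,
#'   strictly inside (0, 1).
#' @param width Standard deviation of the intrinsic band spread, in mobility
#'   units; must be > 0.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(component_id, amount, mobility_center, width) {
  stopifnot_scalar(amount); stopifnot_scalar(mobility_center); stopifnot_scalar(width)
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  if (mobility_center <= 0 || mobility_center >= 1)
    stop("mobility_center must lie strictly inside (0, 1)", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(component_id = as.character(component_id), amount = amount,
                 mobility_center = mobility_center, width = width),
            class = "band_spec")
}

#' Specify a gel-image phantom
#'
#' The forward model rendered for each replicate is
#' `baseline + sum_bands gain * amount * (r %*% gaussian(center, width))`
#' per lane column block, shifted by that replicate's integer jitter, plus
#' i.i.d. Gaussian pixel noise truncated at zero.  The mobility axis maps to
#' image rows, normalized to \[0, 1\]; larger row index means larger mobility.
#'
#' @param lanes List of lanes, each a list of [band_spec()] objects.
#' @param image_height,image_width Image size in pixels (rows = mobility axis).
#' @param impulse_response An [impulse_response()] kernel (the system
#'   point-spread along mobility), or `NULL` for an ideal (delta) system.
#' @param baseline_model Baseline drift along mobility: `NULL` for none, or a
#'   list with `type` ("polynomial" or "exponential") and `coefficients`
#'   (polynomial: intensity = sum c_k m^k; exponential: c1 * exp(c2 * m) + c3).
#' @param noise_sd Pixel-noise standard deviation (intensity units), >= 0.
#' @param replicate_jitter Maximum absolute integer (row, column) offset drawn
#'   per replicate, >= 0.
#' @param gain Intensity per unit amount (the true sensitivity coefficient K),
#'   > 0.
#' @param bias_offset True negative systematic area error per band (the
#'   censoring-threshold analogue), subtracted as a uniform density over each
#'   band's carrier before convolution. Default 0.
#' @param seed Integer master seed; every replicate's random stream is a pure
#'   function of `(seed, replicate_index)`.
#' @param lane_margin Fraction of each lane block left blank on either side.
#' @return An object of class `gel_phantom_spec`.
#' @export
gel_phantom_spec <- function(lanes, image_height = 256L, image_width = 64L,
                             impulse_response = NULL, baseline_model = NULL,
                             noise_sd = 0, replicate_jitter = 0L, gain = 1,
                             bias_offset = 0, seed = 1L, lane_margin = 0.15) {
  if (!is.list(lanes) || length(lanes) == 0L)
    stop("lanes must be a non-empty list", call. = FALSE)
  lanes <- lapply(lanes, function(ln) {
    if (inherits(ln, "band_spec")) ln <- list(ln)
    stopifnot(all(vapply(ln, inherits, logical(1), "band_spec")))
    ln
  })
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (replicate_jitter < 0) stop("replicate_jitter must be >= 0", call. = FALSE)
  if (!is.null(impulse_response) && !inherits(impulse_response, "impulse_response"))
    stop("impulse_response must be an impulse_response object or NULL", call. = FALSE)
  structure(list(lanes = lanes, image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 impulse_response = impulse_response,
                 baseline_model = baseline_model, noise_sd = noise_sd,
                 replicate_jitter = as.integer(replicate_jitter), gain = gain,
                 bias_offset = bias_offset, seed = as.integer(seed),
                 lane_margin = lane_margin),
            class = "gel_phantom_spec")
}

# Mobility grid of a phantom: rows 1..H mapped to [0, 1].
phantom_mobility_grid <- function(spec) {
  seq(0, 1, length.out = spec$image_height)
}

# Active (non-margin) column indices of one lane block.
lane_columns <- function(spec, lane) {
  n_lanes <- length(spec$lanes)
  if (lane < 1L || lane > n_lanes) stop("unknown lane: ", lane, call. = FALSE)
  block <- spec$image_width / n_lanes
  lo <- floor((lane - 1) * block) + 1L
  hi <- floor(lane * block)
  margin <- floor((hi - lo + 1L) * spec$lane_margin)
  (lo + margin):(hi - margin)
}

phantom_baseline <- function(spec, m) {
  bm <- spec$baseline_model
  if (is.null(bm)) return(numeric(length(m)))
  co <- bm$coefficients
  b <- switch(bm$type,
    polynomial = {
      acc <- numeric(length(m))
      for (k in seq_along(co)) acc <- acc + co[k] * m^(k - 1)
      acc
    },
    exponential = co[1] * exp(co[2] * m) + (if (length(co) >= 3) co[3] else 0),
    stop("unknown baseline_model type: ", bm$type, call. = FALSE))
  pmax(b, 0)
}

# Convolve a density sampled on the uniform mobility grid with an impulse
# response; linear (zero-padded) convolution, center-aligned.  The Riemann
# factor dm makes the discrete sum approximate the integral operator, so a
# unit-area kernel preserves integrals.
convolve_density <- function(dens, psf, dm) {
  if (is.null(psf)) return(dens)
  r <- psf$r
  k <- length(r)
  half <- (k - 1L) %/% 2L
  out <- stats::convolve(dens, rev(r), type = "open") * dm
  out[(half + 1L):(half + length(dens))]
}

# Noiseless, jitter-free single-lane profile density (intensity per unit m,
# lane-summed), excluding baseline.
phantom_lane_density <- function(spec, lane, deconvolved = FALSE) {
  m <- phantom_mobility_grid(spec)
  dm <- m[2] - m[1]
  psf <- spec$impulse_response
  psf_half <- if (is.null(psf)) 0 else (length(psf$r) - 1) / 2 * dm
  dens <- numeric(length(m))
  for (b in spec$lanes[[lane]]) {
    reach <- 4 * b$width + psf_half
    if (b$mobility_center - reach < 0 || b$mobility_center + reach > 1)
      stop(sprintf("band '%s' support after convolution exceeds the image",
                   b$component_id), call. = FALSE)
    d <- b$amount * stats::dnorm(m, b$mobility_center, b$width)
    if (spec$bias_offset > 0) {
      carrier <- abs(m - b$mobility_center) <= 3 * b$width
      d[carrier] <- d[carrier] - spec$bias_offset / (sum(carrier) * dm)
    }
    dens <- dens + d
  }
  dens <- spec$gain * dens
  if (!deconvolved) dens <- convolve_density(dens, psf, dm)
  dens
}

#' Render one replicate of a gel phantom
#'
#' @param spec A [gel_phantom_spec()].
#' @param replicate_index Replicate number, >= 0; the random stream is a pure
#'   function of `(spec$seed, replicate_index)`.
#' @return A [gel_image()] whose `true_offset` attribute records the drawn
#'   integer jitter `(dx, dy)`.
#' @export
render_gel_image <- function(spec, replicate_index = 0L) {
  stopifnot(inherits(spec, "gel_phantom_spec"), replicate_index >= 0)
  H <- spec$image_height; W <- spec$image_width
  m <- phantom_mobility_grid(spec)
  base <- matrix(rep(phantom_baseline(spec, m), W), nrow = H)
  for (lane in seq_along(spec$lanes)) {
    cols <- lane_columns(spec, lane)
    dens <- phantom_lane_density(spec, lane)
    base[, cols] <- base[, cols] + dens / length(cols)
  }
  with_seed(derive_seed(spec$seed, 1L, replicate_index), {
    j <- spec$replicate_jitter
    off <- if (j > 0) c(sample(-j:j, 1L), sample(-j:j, 1L)) else c(0L, 0L)
    # `off` is recorded in the alignment convention: shifting the rendered
    # image by (dx, dy) = off restores the unjittered frame, so recovered
    # alignment offsets equal the recorded jitter up to a common constant.
    img <- shift_matrix(base, -off[1], -off[2])
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), nrow = H)
    gel_image(pmax(img, 0), id = sprintf("phantom_rep%03d", replicate_index),
              true_offset = as.integer(off))
  })
}

# Integer shift with zero fill: out[x, y] = x0[x - dx, y - dy].
shift_matrix <- function(x, dx, dy) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  xs <- seq_len(H) - dx; ys <- seq_len(W) - dy
  okx <- xs >= 1L & xs <= H; oky <- ys >= 1L & ys <= W
  out[okx, oky] <- x[xs[okx], ys[oky]]
  out
}

#' Render a replicate set of a gel phantom
#'
#' @inheritParams render_gel_image
#' @param n Number of replicates, >= 1.
#' @return List of [gel_image()] objects with independent noise and jitter
#'   draws; deterministic given `spec$seed`.
#' @export
render_replicates <- function(spec, n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n) - 1L, function(i) render_gel_image(spec, i))
}

#' Ground-truth lane profile of a phantom
#'
#' Noiseless, jitter-free signal h(m) (or the deconvolved h_act(m)) on the same
#' mobility grid the extraction stage uses, excluding baseline drift.
#'
#' @inheritParams render_gel_image
#' @param lane Lane index.
#' @param deconvolved If `TRUE`, return the pre-blur h_act(m) instead of the
#'   convolved h(m).
#' @return A [lane_profile()] with zero variance.
#' @export
true_lane_profile <- function(spec, lane, deconvolved = FALSE) {
  if (lane < 1L || lane > length(spec$lanes))
    stop("unknown lane: ", lane, call. = FALSE)
  dens <- phantom_lane_density(spec, lane, deconvolved = deconvolved)
  lane_profile(m = phantom_mobility_grid(spec), h = dens,
               var_h = numeric(length(dens)),
               lane_bounds = range(lane_columns(spec, lane)))
}

#' Ground-truth manifest for a phantom replicate set
#'
#' @inheritParams render_replicates
#' @return List with per-lane component amounts, the drawn per-replicate
#'   offsets, and the true gain (K) and area bias.
#' @export
phantom_truth <- function(spec, n) {
  imgs <- render_replicates(spec, n)
  list(
    amounts = lapply(spec$lanes, function(ln)
      stats::setNames(vapply(ln, `[[`, numeric(1), "amount"),
                      vapply(ln, `[[`, character(1), "component_id"))),
    offsets = t(vapply(imgs, attr, integer(2), "true_offset")),
    gain = spec$gain, bias_offset = spec$bias_offset,
    noise_sd = spec$noise_sd, seed = spec$seed
  )
}

#' Read a phantom specification from a YAML file
#'
#' The YAML mirrors the [gel_phantom_spec()] arguments; lanes are lists of
#' band entries `(component_id, amount, mobility_center, width)`; an optional
#' `impulse_response` entry gives `(width, radius)` of a Gaussian kernel.
#'
#' @param path Path to the YAML file.
#' @return A [gel_phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("lanes", "image_height", "image_width", "impulse_response",
             "baseline_model", "noise_sd", "replicate_jitter", "gain",
             "bias_offset", "seed", "lane_margin")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown phantom config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lanes <- lapply(y$lanes, function(ln)
    lapply(ln, function(b) band_spec(b$component_id, b$amount,
                                     b$mobility_center, b$width)))
  H <- y$image_height %||% 256L
  psf <- NULL
  if (!is.null(y$impulse_response)) {
    dm <- 1 / (H - 1)
    psf <- gaussian_psf(y$impulse_response$width, dm,
                        radius = y$impulse_response$radius %||% 5)
  }
  gel_phantom_spec(lanes = lanes, image_height = H,
                   image_width = y$image_width %||% 64L,
                   impulse_response = psf, baseline_model = y$baseline_model,
                   noise_sd = y$noise_sd %||% 0,
                   replicate_jitter = y$replicate_jitter %||% 0L,
                   gain = y$gain %||% 1, bias_offset = y$bias_offset %||% 0,
                   seed = y$seed %||% 1L, lane_margin = y$lane_margin %||% 0.15)
}
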