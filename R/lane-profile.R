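## Lane-profile extraction, lower-envelope baseline estimation, and the
## systematic-error bound map built from forbidden-mobility regions.

#' Construct a lane profile
#'
#' The mobility signal h(m): row-wise lane-summed intensity with per-point
#' variance inherited from the variance of the mean image.
#'
#' @param m Strictly increasing normalized mobility grid.
#' @param h Intensity per grid point (finite).
#' @param var_h Per-point variance, >= 0.
#' @param lane_bounds Column interval `(lo, hi)` of the source image.
#' @return Object of class `lane_profile`.
#' @export
lane_profile <- function(m, h, var_h = numeric(length(h)), lane_bounds = NULL) {
  stopifnot(length(m) == length(h), length(h) == length(var_h))
  if (any(!is.finite(h))) stop("h must be finite", call. = FALSE)
  if (any(var_h < 0)) stop("var_h must be >= 0", call. = FALSE)
  if (any(diff(m) <= 0)) stop("m must be strictly increasing", call. = FALSE)
  structure(list(m = m, h = h, var_h = var_h, lane_bounds = lane_bounds),
            class = "lane_profile")
}

#' Extract the lane signal h(m) from an aligned stack
#'
#' For each row of the crop window, `h` is the sum of `I_mean` over the lane's
#' columns and `var_h` the sum of the variance-of-mean over the same pixels
#' (pixel independence assumption).  The sum (not mean or median) keeps peak
#' areas linear in the substance amount.  `m` is normalized to \[0, 1\] over
#' the lane rows.
#'
#' @param stack An [build_stack()] result.
#' @param lane_bounds Integer column interval `c(lo, hi)` in the coordinates
#'   of the original image frame.
#' @return A [lane_profile()].
#' @export
extract_profile <- function(stack, lane_bounds) {
  stopifnot(inherits(stack, "aligned_stack"))
  lane_bounds <- as.integer(round(lane_bounds))
  if (length(lane_bounds) != 2L || lane_bounds[1] > lane_bounds[2])
    stop("empty lane_bounds", call. = FALSE)
  cols <- match(lane_bounds[1]:lane_bounds[2], stack$crop_window$cols)
  if (any(is.na(cols)))
    stop("lane_bounds outside the crop window", call. = FALSE)
  h <- rowSums(stack$mean_image[, cols, drop = FALSE])
  v <- rowSums(stack$variance_of_mean[, cols, drop = FALSE])
  n <- length(h)
  lane_profile(m = seq(0, 1, length.out = n), h = h, var_h = v,
               lane_bounds = lane_bounds)
}

#' Lower-envelope baseline of a lane profile
#'
#' The baseline h0(m) is the running minimum of h over a centered window,
#' smoothed by a running mean, then clipped so that `0 <= h0 <= h` pointwise.
#' `h - h0` is the net signal passed to deconvolution.  Enlarging the window
#' never raises the envelope at any point.
#'
#' @param profile A [lane_profile()].
#' @param window Running-minimum window length (>= 1, in grid points).
#' @param smooth Running-mean window length (>= 1).
#' @return Object of class `gel_baseline` with elements `h0` and
#'   `method_params`.
#' @export
estimate_baseline <- function(profile, window = 41L, smooth = 11L) {
  stopifnot(inherits(profile, "lane_profile"))
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > length(profile$h))
    stop("window longer than profile", call. = FALSE)
  h0 <- baseline_value(profile$h, window, smooth)
  structure(list(h0 = h0,
                 method_params = list(window = as.integer(window),
                                      smooth = as.integer(smooth))),
            class = "gel_baseline")
}

# Plain-vector baseline computation shared with the sensitivity engine.
baseline_value <- function(h, window, smooth) {
  rm <- running_min(h, window)
  h0 <- running_mean(rm$min, smooth)
  pmin(pmax(h0, 0), h)
}

#' Net signal after baseline removal
#'
#' @param profile A [lane_profile()].
#' @param baseline An [estimate_baseline()] result.
#' @return Numeric vector `h - h0`, guaranteed >= 0.
#' @export
net_signal <- function(profile, baseline) {
  profile$h - baseline$h0
}

#' Systematic-error bound map from forbidden-mobility regions
#'
#' On mobility intervals declared free of analyte, any residual
#' `|h(m) - h0(m)|` is attributable to imperfect baseline removal and bounds
#' the possible systematic error there.  The map is extended to the full grid
#' by the maximum forbidden-region residual (conservative constant extension),
#' and its mean over the extended grid gives the scalar used by the
#' systematic-bound formula.
#'
#' @param profile A [lane_profile()].
#' @param baseline An [estimate_baseline()] result.
#' @param forbidden_regions List of `c(lo, hi)` mobility intervals inside the
#'   grid range, declared free of analyte.
#' @param peak_regions Optional list of known peak-carrier intervals; a
#'   forbidden region overlapping one triggers a recorded warning.
#' @return Object of class `syst_bound_map` with `delta_syst` (per grid
#'   point), `delta_syst_mean`, `forbidden_regions`, and `warnings`.
#' @export
systematic_bounds <- function(profile, baseline, forbidden_regions,
                              peak_regions = NULL) {
  stopifnot(inherits(profile, "lane_profile"))
  if (length(forbidden_regions) == 0L)
    stop("forbidden_regions must be non-empty", call. = FALSE)
  m <- profile$m
  warn <- character(0)
  in_forbidden <- rep(FALSE, length(m))
  for (fr in forbidden_regions) {
    if (fr[1] < min(m) || fr[2] > max(m))
      stop("forbidden region outside the mobility range", call. = FALSE)
    in_forbidden <- in_forbidden | (m >= fr[1] & m <= fr[2])
    if (!is.null(peak_regions)) {
      for (pr in peak_regions) {
        if (fr[1] < pr[2] && pr[1] < fr[2]) {
          w <- sprintf("forbidden region [%.3g, %.3g] overlaps peak carrier [%.3g, %.3g]",
                       fr[1], fr[2], pr[1], pr[2])
          warning(w, call. = FALSE)
          warn <- c(warn, w)
        }
      }
    }
  }
  resid <- abs(profile$h - baseline$h0)
  delta <- numeric(length(m))
  delta[in_forbidden] <- resid[in_forbidden]
  delta[!in_forbidden] <- max(resid[in_forbidden])
  structure(list(delta_syst = delta, delta_syst_mean = mean(delta),
                 forbidden_regions = forbidden_regions, warnings = warn),
            class = "syst_bound_map")
}

#' Parse forbidden-region strings
#'
#' Converts config entries like `"0.00:0.05"` into numeric intervals.
#'
#' @param x Character vector of `"lo:hi"` strings.
#' @return List of numeric `c(lo, hi)` intervals.
#' @export
parse_forbidden <- function(x) {
  lapply(x, function(s) {
    parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(is.na(parts)) || parts[1] >= parts[2])
      stop("bad forbidden-region string: ", s, call. = FALSE)
    parts
  })
}
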