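## Peak detection, carrier determination, area integration, and the
## sensitivity-threshold censoring rule.

#' Detect peaks in a deconvolved lane signal
#'
#' Peaks are local maxima with topographic prominence at least
#' `min_prominence` times the global maximum.  Each peak's support (carrier)
#' runs from the valley minimum (or zero crossing) on its left to the one on
#' its right; supports are disjoint half-open intervals that tile the region
#' where the signal is positive.
#'
#' @param h_act Non-negative sampled signal (post non-negativity iteration;
#'   small negative residuals are treated as zero).
#' @param m Mobility grid (defaults to a unit grid).
#' @param min_prominence Fraction of the global maximum, in `[0, 1)`.
#' @return A data.frame with one row per peak: `m_lo`, `m_hi`, `apex`,
#'   `carrier_length`, `area`; zero rows for an all-zero signal.
#' @export
detect_peaks <- function(h_act, m = NULL, min_prominence = 0.02) {
  n <- length(h_act)
  if (is.null(m)) m <- seq(0, 1, length.out = n)
  x <- pmax(h_act, 0)
  if (max(x) <= 0)
    return(data.frame(m_lo = numeric(0), m_hi = numeric(0),
                      apex = numeric(0), carrier_length = numeric(0),
                      area = numeric(0)))
  # local maxima (plateau-safe: strict rise before, non-rise after)
  cand <- which(diff(c(-Inf, x)) > 0 & diff(c(x, -Inf)) <= 0)
  # topographic prominence of each candidate
  prom <- vapply(cand, function(i) {
    lmin <- Inf
    j <- i
    left <- 0
    while (j > 1L) {
      j <- j - 1L
      lmin <- min(lmin, x[j])
      if (x[j] > x[i]) break
    }
    left <- if (is.finite(lmin)) lmin else 0
    rmin <- Inf
    j <- i
    while (j < n) {
      j <- j + 1L
      rmin <- min(rmin, x[j])
      if (x[j] > x[i]) break
    }
    right <- if (is.finite(rmin)) rmin else 0
    x[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence * max(x)]
  if (length(keep) == 0L) keep <- cand[which.max(prom)]
  keep <- sort(keep)
  # carrier boundaries: between consecutive peaks, the valley argmin; outer
  # boundaries at the edge of the positive support around the peak group
  eps <- 1e-12 * max(x)
  pos <- x > eps
  bounds <- integer(length(keep) + 1L)
  first_pos <- which(pos)[1]
  last_pos <- which(pos)[length(which(pos))]
  bounds[1] <- max(first_pos - 1L, 1L)
  bounds[length(bounds)] <- min(last_pos + 1L, n)
  if (length(keep) > 1L) {
    for (i in seq_len(length(keep) - 1L)) {
      seg <- keep[i]:keep[i + 1L]
      bounds[i + 1L] <- seg[which.min(x[seg])]
    }
  }
  out <- data.frame(
    m_lo = m[bounds[-length(bounds)]],
    m_hi = m[bounds[-1]],
    apex = m[keep],
    carrier_length = m[bounds[-1]] - m[bounds[-length(bounds)]],
    area = vapply(seq_along(keep), function(i)
      trapz(m[bounds[i]:bounds[i + 1L]], x[bounds[i]:bounds[i + 1L]]),
      numeric(1)))
  out
}

#' Integrate a peak area over a mobility support
#'
#' Trapezoidal integral of the signal over the given interval.
#'
#' @param h_act Sampled signal.
#' @param support Mobility interval `c(lo, hi)` within the grid.
#' @param m Mobility grid (defaults to a unit grid).
#' @return The area (intensity x mobility units).
#' @export
peak_area <- function(h_act, support, m = NULL) {
  n <- length(h_act)
  if (is.null(m)) m <- seq(0, 1, length.out = n)
  idx <- which(m >= support[1] & m <= support[2])
  if (length(idx) < 2L) stop("empty support", call. = FALSE)
  trapz(m[idx], h_act[idx])
}

#' Sensitivity-threshold policy
#'
#' @param c_min Minimum reportable amount, >= 0.
#' @return Object of class `threshold_policy`.
#' @export
threshold_policy <- function(c_min) {
  if (c_min < 0) stop("c_min must be >= 0", call. = FALSE)
  structure(list(c_min = c_min), class = "threshold_policy")
}

#' Apply the sensitivity threshold
#'
#' Amounts strictly below `c_min` are censored to zero; the boundary case
#' equal to `c_min` is reported.  The censoring event is flagged (attribute
#' `censored`) so the calibration stage can account for the induced negative
#' systematic error.
#'
#' @param concentration Measured amount(s).
#' @param policy A [threshold_policy()].
#' @return The input with censored entries set to 0 and a logical `censored`
#'   attribute of the same length.
#' @export
apply_threshold <- function(concentration, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  censored <- concentration < policy$c_min
  out <- ifelse(censored, 0, concentration)
  attr(out, "censored") <- censored
  out
}
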