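## Replicate alignment and averaging: integer-shift cross-correlation
## registration against the naive mean, pointwise mean image, and pointwise
## variance maps that model the random error of the raw data.

#' Construct a gel image
#'
#' @param intensities Numeric matrix indexed (row = x, column = y), all values
#'   finite and >= 0.
#' @param id Optional label.
#' @param pixel_pitch Optional physical scale (units per pixel).
#' @param true_offset Optional known (dx, dy) jitter, carried by phantoms.
#' @return Object of class `gel_image`.
#' @export
gel_image <- function(intensities, id = NULL, pixel_pitch = NULL,
                      true_offset = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(intensities, class = c("gel_image", "matrix"), id = id,
            pixel_pitch = pixel_pitch, true_offset = true_offset)
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image %s: %d x %d, range [%.3g, %.3g]>\n",
              attr(x, "id") %||% "", nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Integer offset maximizing the cross-correlation of two images
#'
#' Exhaustive search over all integer offsets `(dx, dy)` with
#' `|dx|, |dy| <= max_shift` for the one maximizing
#' `sum_xy reference(x, y) * image(x - dx, y - dy)` over the overlap region.
#' Ties are broken by smallest `|dx| + |dy|`, then lexicographically.
#'
#' @param reference,image Matrices (or [gel_image()]s) of identical dimensions.
#' @param max_shift Maximum absolute offset searched; must satisfy
#'   `0 <= max_shift < min(dim)/2`.
#' @return Integer vector `c(dx, dy)`.
#' @export
align_offset <- function(reference, image, max_shift) {
  reference <- unclass(reference); image <- unclass(image)
  if (!all(dim(reference) == dim(image)))
    stop("images must share dimensions", call. = FALSE)
  if (max_shift < 0 || max_shift >= min(dim(reference)) / 2)
    stop("max_shift must satisfy 0 <= max_shift < min(dim)/2", call. = FALSE)
  if (stats::sd(image) == 0 || stats::sd(reference) == 0)
    stop("degenerate alignment: constant (zero-variance) image", call. = FALSE)
  H <- nrow(reference); W <- ncol(reference)
  shifts <- -max_shift:max_shift
  best <- -Inf; best_off <- c(0L, 0L); best_key <- c(Inf, Inf, Inf)
  for (dx in shifts) for (dy in shifts) {
    xs <- max(1L, 1L + dx):min(H, H + dx)
    ys <- max(1L, 1L + dy):min(W, W + dy)
    cc <- sum(reference[xs, ys, drop = FALSE] *
                image[xs - dx, ys - dy, drop = FALSE])
    key <- c(abs(dx) + abs(dy), dx, dy)
    if (cc > best ||
        (cc == best && (key[1] < best_key[1] ||
          (key[1] == best_key[1] && (key[2] < best_key[2] ||
            (key[2] == best_key[2] && key[3] < best_key[3])))))) {
      best <- cc; best_off <- c(as.integer(dx), as.integer(dy)); best_key <- key
    }
  }
  best_off
}

#' Align a replicate set and form mean and variance maps
#'
#' Each image is aligned (integer shifts only) to the naive unshifted mean by
#' [align_offset()]; the pointwise mean `I_mean`, the pointwise sample variance
#' `sigma^2(x, y)` of the aligned images about `I_mean`, and the variance of
#' the mean `sigma^2_mean = sigma^2 / n` (or `/(n-1)`, see
#' `mean_variance_divisor`) are computed on the common valid crop window; no
#' wrapped or zero-filled pixels enter the statistics.
#'
#' @param images List of >= 2 [gel_image()]s with identical dimensions.
#' @param max_shift Maximum alignment shift passed to [align_offset()].
#' @param mean_variance_divisor `"n"` (default, the image-domain convention)
#'   or `"n-1"` (the replicate-area convention used in calibration); both are
#'   exposed deliberately, see the methods vignette.
#' @param iterate If `TRUE`, re-estimate the reference from the aligned mean
#'   and re-align until offsets stabilize (at most 5 passes); default is the
#'   single pass (the variance model assumes one alignment pass).
#' @return Object of class `aligned_stack` with elements `n`, `offsets`
#'   (n x 2 integer matrix), `aligned` (list of matrices on the crop window),
#'   `mean_image`, `variance`, `variance_of_mean`, `crop_window`
#'   (list of row/col index ranges in the original frame).
#' @export
build_stack <- function(images, max_shift = 5L,
                        mean_variance_divisor = c("n", "n-1"),
                        iterate = FALSE) {
  mean_variance_divisor <- match.arg(mean_variance_divisor)
  if (length(images) < 2L) stop("need >= 2 images", call. = FALSE)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("mixed image dimensions", call. = FALSE)
  mats <- lapply(images, unclass)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  ref <- Reduce(`+`, mats) / length(mats)
  offsets <- t(vapply(mats, function(im) align_offset(ref, im, max_shift),
                      integer(2)))
  if (iterate) {
    for (pass in 1:5) {
      st <- assemble_stack(mats, offsets, mean_variance_divisor)
      ref2 <- matrix(0, H, W)
      ref2[st$crop_window$rows, st$crop_window$cols] <- st$mean_image
      new_off <- t(vapply(mats, function(im) align_offset(ref2, im, max_shift),
                          integer(2)))
      if (all(new_off == offsets)) break
      offsets <- new_off
    }
  }
  assemble_stack(mats, offsets, mean_variance_divisor,
                 ids = lapply(images, attr, "id"))
}

assemble_stack <- function(mats, offsets, mean_variance_divisor, ids = NULL) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  n <- length(mats)
  # valid rows of aligned image i: x with 1 <= x - dx <= H
  r_lo <- max(1L + offsets[, 1]); r_hi <- min(H + offsets[, 1], H)
  c_lo <- max(1L + offsets[, 2]); c_hi <- min(W + offsets[, 2], W)
  if (r_lo > r_hi || c_lo > c_hi)
    stop("no common overlap after alignment", call. = FALSE)
  rows <- r_lo:r_hi; cols <- c_lo:c_hi
  aligned <- lapply(seq_len(n), function(i)
    mats[[i]][rows - offsets[i, 1], cols - offsets[i, 2], drop = FALSE])
  mean_image <- Reduce(`+`, aligned) / n
  variance <- Reduce(`+`, lapply(aligned, function(a) (a - mean_image)^2)) /
    (n - 1)
  div <- if (mean_variance_divisor == "n") n else n - 1
  structure(list(n = n, offsets = offsets, aligned = aligned,
                 mean_image = mean_image, variance = variance,
                 variance_of_mean = variance / div,
                 crop_window = list(rows = rows, cols = cols),
                 mean_variance_divisor = mean_variance_divisor,
                 ids = ids),
            class = "aligned_stack")
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("<aligned_stack: n = %d, crop %d x %d, offsets dx %s / dy %s>\n",
              x$n, length(x$crop_window$rows), length(x$crop_window$cols),
              paste(range(x$offsets[, 1]), collapse = ".."),
              paste(range(x$offsets[, 2]), collapse = "..")))
  invisible(x)
}
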