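## File interfaces: single-channel TIFF/PNG images, 2-column kernel CSVs,
## profile CSVs, replicate-area tables.

#' Write a gel image to TIFF
#'
#' @param image Matrix or [gel_image()].
#' @param path Output path.
#' @param bits 16 (integer, intensities scaled by `scale`) or 32 (float,
#'   stored as-is divided by `scale`).
#' @param scale Full-scale intensity mapped to 1.0; defaults to the image
#'   maximum (recorded in the return value).
#' @return Invisibly, the scale used.
#' @export
write_gel_image <- function(image, path, bits = 16L, scale = NULL) {
  m <- unclass(image)
  if (is.null(scale)) scale <- max(m, 1e-12)
  # the TIFF writer stores [0, 1] for all depths; the scale maps back
  tiff::writeTIFF(pmin(m / scale, 1), path, bits.per.sample = as.integer(bits))
  invisible(scale)
}

#' Read a gel image from TIFF or PNG
#'
#' @param path Input path (.tif/.tiff/.png).
#' @param scale Intensity multiplier applied after reading (inverse of the
#'   write-time scale).
#' @return A [gel_image()].
#' @export
read_gel_image <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  gel_image(m * scale, id = basename(path))
}

#' Write a lane profile (with baseline and systematic map) to CSV
#'
#' Columns: `m`, `h`, `var_h`, and when available `h0` and `delta_syst`.
#'
#' @param profile A [lane_profile()].
#' @param path Output path.
#' @param baseline Optional [estimate_baseline()] result.
#' @param syst Optional [systematic_bounds()] map.
#' @param header Optional character vector of provenance comment lines.
#' @export
write_profile_csv <- function(profile, path, baseline = NULL, syst = NULL,
                              header = NULL) {
  df <- data.frame(m = profile$m, h = profile$h, var_h = profile$var_h)
  if (!is.null(baseline)) df$h0 <- baseline$h0
  if (!is.null(syst)) df$delta_syst <- syst$delta_syst
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a lane profile CSV
#'
#' @param path Path written by [write_profile_csv()].
#' @return A list with `profile` ([lane_profile()]) and, when present,
#'   `h0` and `delta_syst` vectors.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  out <- list(profile = lane_profile(df$m, df$h,
                                     df$var_h %||% numeric(nrow(df))))
  out$h0 <- df$h0
  out$delta_syst <- df$delta_syst
  out
}

#' Write an impulse response to a 2-column CSV (m, r)
#'
#' @param psf An [impulse_response()].
#' @param path Output path.
#' @export
write_psf_csv <- function(psf, path) {
  half <- (length(psf$r) - 1L) / 2
  utils::write.csv(data.frame(m = (-half:half) * psf$dm, r = psf$r), path,
                   row.names = FALSE)
}

#' Read an impulse response from a 2-column CSV (m, r)
#'
#' @param path Input path.
#' @return An [impulse_response()].
#' @export
read_psf_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  dm <- stats::median(diff(df$m))
  impulse_response(df$r, dm)
}

#' Read replicate calibration areas from CSV
#'
#' Expected columns: `component`, `C_known`, `gamma_known`, `replicate`,
#' `area`.
#'
#' @param path Input path.
#' @return List of calibration components as consumed by
#'   [fit_sensitivity()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("component", "C_known", "gamma_known", "replicate", "area")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(split(df, df$component), function(d)
    list(known_concentration = d$C_known[1],
         known_rel_error = d$gamma_known[1],
         replicate_areas = d$area[order(d$replicate)]))
}

#' Read replicate measurement areas from CSV
#'
#' Expected columns: `component`, `replicate`, `area`.
#'
#' @param path Input path.
#' @return Named list of replicate-area vectors, one per component.
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("component", "replicate", "area")
  if (!all(need %in% names(df)))
    stop("measurement CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(split(df, df$component), function(d) d$area[order(d$replicate)])
}
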