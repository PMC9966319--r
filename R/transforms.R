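## Real-valued Fourier-family transforms used by the deconvolution stage.
## Two routes avoid complex arithmetic in the frequency domain: even
## symmetrization followed by a cosine transform, or the Hartley transform
## (cas basis).  Both are self-contained real-to-real maps with exact
## inverses, which keeps the whole processing chain real-valued and therefore
## amenable to forward-mode sensitivity propagation.

# Discrete Hartley transform: X_k = sum_j x_j * cas(2*pi*j*k/N),
# cas t = cos t + sin t.  Accepts a vector or a matrix (columns independent).
fht <- function(x) {
  if (is.matrix(x)) {
    f <- stats::mvfft(x)
  } else {
    f <- stats::fft(x)
  }
  Re(f) - Im(f)
}

# Inverse DHT: the DHT is an involution up to 1/N.
ifht <- function(x) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  fht(x) / n
}

# Whole-point even extension of a length-N signal to length 2N-2 (N > 2).
even_extend <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n <= 2L) return(x)
    rbind(x, x[(n - 1L):2L, , drop = FALSE])
  } else {
    n <- length(x)
    if (n <= 2L) return(x)
    c(x, x[(n - 1L):2L])
  }
}

# Real spectrum of an even-extended signal (DCT-I family, unnormalized):
# coefficients are the (real) DFT of the even extension; only the first N are
# unique.  Accepts matrices columnwise.
dct_even <- function(x) {
  y <- even_extend(x)
  f <- if (is.matrix(y)) stats::mvfft(y) else stats::fft(y)
  Re(f)
}

#' Real-valued spectral transform of a sampled signal
#'
#' `kind = "cosine"`: the signal is reflected about the origin (even,
#' whole-point symmetrization) and the real DFT coefficients of the extension
#' are returned -- a type-I cosine transform.  `kind = "hartley"`: discrete
#' Hartley coefficients on the cas basis.  Both are exactly invertible with
#' [inverse_real_transform()].
#'
#' @param signal Numeric vector, length >= 2.
#' @param kind `"cosine"` or `"hartley"`.
#' @return Object of class `real_spectrum` with elements `coefficients`,
#'   `transform_kind`, and `n` (original length).
#' @export
real_transform <- function(signal, kind = c("cosine", "hartley")) {
  kind <- match.arg(kind)
  if (length(signal) < 2L) stop("signal length must be >= 2", call. = FALSE)
  coef <- switch(kind, cosine = dct_even(signal), hartley = fht(signal))
  structure(list(coefficients = coef, transform_kind = kind,
                 n = length(signal)),
            class = "real_spectrum")
}

#' Invert a real-valued spectral transform
#'
#' @param spectrum A [real_transform()] result.
#' @return The original signal, to machine precision.
#' @export
inverse_real_transform <- function(spectrum) {
  stopifnot(inherits(spectrum, "real_spectrum"))
  co <- spectrum$coefficients
  switch(spectrum$transform_kind,
    cosine = {
      l <- length(co)
      Re(stats::fft(co, inverse = TRUE))[seq_len(spectrum$n)] / l
    },
    hartley = ifht(co))
}
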