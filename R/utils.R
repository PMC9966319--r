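#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit substream derivation: one master seed, one stream per
# (stage, index) pair.  Kept below 2^31 - 1.
derive_seed <- function(seed, stream, index = 0L) {
  seed <- as.double(seed)
  h <- (seed * 48271 + stream * 1000003 + index * 7919) %% 2147483629
  as.integer(h) + 1L
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over grid x (uniform or not).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Running minimum with centered window (odd width), edge-replicated padding.
# Returns both the minima and the index (into the original vector) achieving
# each one, which the forward-sensitivity engine needs for the evaluated-branch
# derivative.
running_min <- function(x, window) {
  n <- length(x)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window longer than profile", call. = FALSE)
  half <- (window - 1L) %/% 2L
  mins <- numeric(n)
  idx <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    j <- lo + which.min(x[lo:hi]) - 1L
    mins[i] <- x[j]
    idx[i] <- j
  }
  list(min = mins, idx = idx)
}

# Centered running mean with edge replication; linear in x.  `x` may be a
# matrix (columns treated independently).
running_mean <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  w <- 2L * half + 1L
  if (is.matrix(x)) {
    pad <- rbind(x[rep(1L, half), , drop = FALSE], x,
                 x[rep(nrow(x), half), , drop = FALSE])
    cs <- apply(pad, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1L):nrow(cs), , drop = FALSE] -
       cs[1L:(nrow(cs) - w), , drop = FALSE]) / w
  } else {
    pad <- c(rep(x[1L], half), x, rep(x[length(x)], half))
    cs <- c(0, cumsum(pad))
    (cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]) / w
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
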