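# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("parameter '%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", name),
         call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("parameter '%s' = %g is outside [%g, %g]",
                 name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

# 1D Gaussian smoothing with edge replication; sd in samples.
gauss_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  if (half <= 50) {
    as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
  } else {
    # FFT convolution for long kernels
    stats::convolve(xp, k, type = "filter")
  }
}

# Half-width at half maximum implied by the SD of a Gaussian.
HWHM_FACTOR <- sqrt(2 * log(2))
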