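#' Segment-averaged power spectral density of a thickness profile
#'
#' Splits the chronological thickness series into \code{n_segments}
#' contiguous equal segments, removes each segment's mean, and averages the
#' one-sided periodograms (Bartlett averaging; no taper by default). The
#' frequency unit is cycles per tablet, f = 1 / (number of tablets); the
#' power is a density (nm^2 per unit frequency) so that the integral of the
#' spectrum recovers the segment variance (Parseval).
#'
#' @param profile a \code{thickness_profile} or numeric thickness vector,
#'   evenly spaced at one tablet.
#' @param n_segments number of segments to average (default 10).
#' @param taper \code{"none"} (default) or \code{"hann"}.
#' @return object of class \code{spectral_estimate}: \code{f},
#'   \code{power}, \code{n_segments}, \code{segment_length}.
#' @export
psd_profile <- function(profile, n_segments = 10, taper = c("none", "hann")) {
  taper <- match.arg(taper)
  w <- if (inherits(profile, "thickness_profile")) profile$thickness
       else as.numeric(profile)
  n_segments <- as.integer(n_segments)
  L0 <- length(w)
  if (L0 < 4 * n_segments) {
    stop(sprintf("profile too short: need at least %d tablets for %d segments",
                 4 * n_segments, n_segments), call. = FALSE)
  }
  L <- L0 %/% n_segments
  half <- L %/% 2
  win <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  } else rep(1, L)
  u <- mean(win^2)
  acc <- numeric(half)
  for (s in seq_len(n_segments)) {
    seg <- w[((s - 1) * L + 1):(s * L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)
    pj <- 2 * Mod(X[2:(half + 1)])^2 / L / u   # one-sided density
    if (L %% 2 == 0) pj[half] <- pj[half] / 2  # Nyquist bin not doubled
    acc <- acc + pj
  }
  structure(list(f = seq_len(half) / L,
                 power = acc / n_segments,
                 n_segments = n_segments,
                 segment_length = L,
                 taper = taper),
            class = "spectral_estimate")
}

#' Fit a 1/f^alpha power law to a spectral estimate
#'
#' Degree-1 least squares of log10(power) against log10(f) over the fit
#' band; the spectral exponent is minus the slope. The default band
#' (0.0004 to 0.04 cycles/tablet, i.e. 25 to 2,500 tablets) requires
#' segments of at least 2,500 tablets; for shorter segments the lower bound
#' is raised to 4 / segment length with a message.
#'
#' @param spec a \code{\link{psd_profile}} result.
#' @param band c(f_lo, f_hi) in cycles per tablet.
#' @return list with \code{alpha}, \code{alpha_stderr}, \code{band},
#'   \code{n_bins}.
#' @export
fit_powerlaw <- function(spec, band = c(4e-4, 0.04)) {
  stopifnot(inherits(spec, "spectral_estimate"))
  f_lo <- band[1]; f_hi <- band[2]
  if (f_lo < 1 / spec$segment_length) {
    # requested bound unreachable for these segments: move up, skipping the
    # most leakage-biased lowest bins
    f_new <- 4 / spec$segment_length
    message(sprintf(
      "fit band lower bound raised from %g to %g (segment length %d)",
      f_lo, f_new, spec$segment_length))
    f_lo <- f_new
  }
  sel <- spec$f >= f_lo & spec$f <= f_hi
  zero <- sel & spec$power <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-power bins dropped from the fit band",
                    sum(zero)))
    sel <- sel & spec$power > 0
  }
  if (sum(sel) < 6) {
    stop("fewer than 6 frequency bins in the fit band", call. = FALSE)
  }
  fit <- stats::lm(log10(spec$power[sel]) ~ log10(spec$f[sel]))
  co <- summary(fit)$coefficients
  list(alpha = -unname(co[2, 1]), alpha_stderr = unname(co[2, 2]),
       band = c(f_lo, f_hi), n_bins = sum(sel))
}

#' High-frequency flattening of the thickness spectrum
#'
#' Corrective (anti-correlated) growth flattens the 1/f decay at high
#' frequencies and can turn the slope positive. Reports the log-log slope
#' above \code{f_threshold} with a sign classification.
#'
#' @param spec a \code{\link{psd_profile}} result.
#' @param f_threshold frequency cut (default 0.04 cycles/tablet, i.e. 25
#'   tablets).
#' @param flat_tol absolute slope below which the band counts as flat.
#' @return list with \code{slope}, \code{slope_stderr},
#'   \code{classification} (\code{"decaying"}, \code{"flat"},
#'   \code{"rising"}), \code{n_bins}.
#' @export
detect_flattening <- function(spec, f_threshold = 0.04, flat_tol = 0.15) {
  stopifnot(inherits(spec, "spectral_estimate"))
  sel <- spec$f > f_threshold & spec$power > 0
  if (sum(sel) < 4) stop("no usable bins above the threshold", call. = FALSE)
  fit <- stats::lm(log10(spec$power[sel]) ~ log10(spec$f[sel]))
  co <- summary(fit)$coefficients
  slope <- unname(co[2, 1])
  cls <- if (slope > flat_tol) "rising"
         else if (slope < -flat_tol) "decaying"
         else "flat"
  list(slope = slope, slope_stderr = unname(co[2, 2]),
       classification = cls, n_bins = sum(sel))
}
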