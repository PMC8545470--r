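#' Thickness deviations from the centered rolling mean of three
#'
#' The deviation of the Nth tablet is its thickness minus the centered
#' rolling mean of width three including itself:
#' \deqn{dev_N = w_N - (w_{N-1} + w_N + w_{N+1}) / 3
#'            = (2 w_N - w_{N-1} - w_{N+1}) / 3.}
#' Endpoints are dropped. Layers flagged \code{merged_excluded} create gaps:
#' no deviation is computed from a triple that spans a flagged layer (the
#' corresponding entries are NA).
#'
#' @param profile a \code{thickness_profile} or numeric thickness vector.
#' @return object of class \code{deviation_series}: data frame with
#'   \code{layer} (N = 2 .. L-1) and \code{dev} (nm, NA at gaps).
#' @export
rolling_deviation <- function(profile) {
  if (inherits(profile, "thickness_profile")) {
    w <- profile$thickness
    w[profile$flag != "ok"] <- NA_real_
  } else {
    w <- as.numeric(profile)
  }
  L <- length(w)
  if (L < 3) stop("profile must have at least 3 layers", call. = FALSE)
  i <- 2:(L - 1)
  dev <- (2 * w[i] - w[i - 1] - w[i + 1]) / 3
  structure(data.frame(layer = i, dev = dev),
            class = c("deviation_series", "data.frame"))
}

#' Correlation of adjacent-tablet thickness deviations
#'
#' Pearson correlation of (dev_N, dev_{N+1}) with least-squares slope, R^2
#' and a two-sided t-test p-value. Note that because the rolling-mean
#' detrend includes the tablet itself, even independent thicknesses yield an
#' expected correlation of -2/3; see \code{\link{lag1_autocorrelation}} for a
#' detrending-bias-aware companion estimator.
#'
#' @param devs a \code{\link{rolling_deviation}} result (or numeric vector).
#' @return object of class \code{adjacent_correlation}: \code{r}, \code{r2},
#'   \code{p}, \code{slope}, \code{n_pairs}.
#' @export
adjacent_correlation <- function(devs) {
  d <- if (inherits(devs, "deviation_series")) devs$dev else as.numeric(devs)
  x <- d[-length(d)]
  y <- d[-1]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 deviation pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate deviations (zero variance)", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(list(r = r, r2 = r^2, p = p, slope = slope, n_pairs = n),
            class = "adjacent_correlation")
}

#' @export
print.adjacent_correlation <- function(x, ...) {
  cat(sprintf("<adjacent_correlation> r = %.3f (R^2 = %.2f, p = %.3g, n = %d)\n",
              x$r, x$r2, x$p, x$n_pairs))
  invisible(x)
}

#' Detrending-bias-aware lag-1 thickness autocorrelation
#'
#' Companion estimator to \code{\link{adjacent_correlation}}: the thickness
#' series is high-pass filtered by subtracting a centered rolling mean of
#' width \code{window} (default 25 tablets, long against the tablet scale),
#' and the direct lag-1 Pearson autocorrelation of the residual is returned.
#' Under independent thicknesses its bias is of order -1/window rather than
#' the -2/3 induced by the width-three self-inclusive detrend.
#'
#' @param profile a \code{thickness_profile} or numeric vector.
#' @param window rolling-mean window (odd), default 25.
#' @return list with \code{r}, \code{n_pairs}, \code{window}.
#' @export
lag1_autocorrelation <- function(profile, window = 25) {
  w <- if (inherits(profile, "thickness_profile")) {
    ifelse(profile$flag == "ok", profile$thickness, NA_real_)
  } else as.numeric(profile)
  if (window %% 2 == 0) window <- window + 1
  half <- window %/% 2
  L <- length(w)
  if (L < window + 2) stop("profile too short for the high-pass window",
                           call. = FALSE)
  km <- rep(1 / window, window)
  trend <- as.numeric(stats::filter(w, km, sides = 2))
  resid <- w - trend
  x <- resid[-L]; y <- resid[-1]
  ok <- is.finite(x) & is.finite(y)
  list(r = stats::cor(x[ok], y[ok]), n_pairs = sum(ok), window = window)
}

#' Stage summary statistics of a thickness profile
#'
#' Per-window mean and SD of tablet thickness, plus the mean ratio and
#' variance ratio between the first and last windows (nacre matures by
#' thinning and by reducing thickness variance).
#'
#' @param profile a \code{thickness_profile}.
#' @param windows list of c(start, end) layer-index windows (1-based,
#'   inclusive); must not overlap.
#' @param labels optional window labels (e.g. "early", "mature").
#' @return object of class \code{stage_summary}: data frame \code{stages}
#'   (label, from, to, n, mean, sd) plus \code{mean_ratio} and
#'   \code{variance_ratio} (last / first).
#' @export
stage_statistics <- function(profile, windows,
                             labels = paste0("window", seq_along(windows))) {
  stopifnot(inherits(profile, "thickness_profile"))
  rows <- lapply(seq_along(windows), function(i) {
    wd <- windows[[i]]
    if (wd[1] > wd[2] || wd[1] < 1 || wd[2] > nrow(profile)) {
      stop(sprintf("window %d [%d, %d] outside the profile", i, wd[1], wd[2]),
           call. = FALSE)
    }
    sel <- profile$layer >= wd[1] & profile$layer <= wd[2] &
      profile$flag == "ok"
    if (!any(sel)) stop(sprintf("window %d is empty", i), call. = FALSE)
    th <- profile$thickness[sel]
    data.frame(label = labels[i], from = wd[1], to = wd[2],
               n = length(th), mean = mean(th), sd = stats::sd(th))
  })
  st <- do.call(rbind, rows)
  structure(list(stages = st,
                 mean_ratio = st$mean[nrow(st)] / st$mean[1],
                 variance_ratio = (st$sd[nrow(st)] / st$sd[1])^2),
            class = "stage_summary")
}

#' Nacre growth rate
#'
#' Total number of layers divided by the deposition time, optionally
#' converted to a linear rate using the mean tablet thickness.
#'
#' @param n_layers total number of nacre layers.
#' @param days deposition time in days (> 0).
#' @param mean_thickness_nm mean tablet thickness in nm (for the linear
#'   rate); NA to skip.
#' @return object of class \code{growth_rate}: \code{tablets_per_day},
#'   \code{microns_per_day}.
#' @export
growth_rate <- function(n_layers, days, mean_thickness_nm = NA_real_) {
  check_scalar(n_layers, "n_layers", lower = 0)
  check_scalar(days, "days", lower = 1e-12)
  tpd <- n_layers / days
  structure(list(tablets_per_day = tpd,
                 microns_per_day = tpd * mean_thickness_nm * 1e-3),
            class = "growth_rate")
}
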