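#' Angular spread of the layering from the 2D Fourier transform
#'
#' Computes the 2D power spectrum (Hann-windowed), integrates power over an
#' annulus at the first-order layering frequency (radius 1/d, width +/-30%),
#' bins it by azimuth (folded to 180 degrees, measured from the x axis), and
#' reports the half-width at half maximum of the azimuthal peak from a
#' Gaussian + constant fit. The azimuthal peak sits at the layer-normal
#' direction (90 degrees for horizontal layers).
#'
#' A list of images may be supplied; their annulus power is accumulated
#' before the fit (useful to average independent fields of view).
#'
#' @param image grayscale matrix (rows = growth direction) or list of such.
#' @param pixel_size nm per pixel.
#' @param d_mean mean layer spacing in nm; if NULL, estimated from the peak
#'   of the radial power profile.
#' @param annulus_frac annulus half-width as a fraction of the ring radius
#'   (default 0.3).
#' @param bin_deg azimuthal bin width in degrees.
#' @return object of class \code{angular_spectrum}: \code{azimuth_deg},
#'   \code{power}, \code{half_width_deg} (HWHM), \code{peak_azimuth_deg},
#'   \code{d_mean}, \code{criterion}.
#' @export
angular_spread <- function(image, pixel_size, d_mean = NULL,
                           annulus_frac = 0.3, bin_deg = 0.5) {
  imgs <- if (is.list(image)) image else list(image)
  check_scalar(pixel_size, "pixel_size", lower = 1e-9)
  breaks <- seq(0, 180, by = bin_deg)
  acc <- numeric(length(breaks) - 1L)
  d_est <- d_mean
  for (img in imgs) {
    H <- nrow(img); W <- ncol(img)
    wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(H) / (H + 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(W) / (W + 1))
    imw <- (img - mean(img)) * outer(wy, wx)
    P <- Mod(stats::fft(imw))^2
    fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / (H * pixel_size)
    fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / (W * pixel_size)
    FR <- sqrt(outer(fy^2, fx^2, "+"))
    if (is.null(d_est)) {
      # radial profile peak (exclude the lowest frequencies)
      fr <- as.numeric(FR); pw <- as.numeric(P)
      ok <- fr > 1 / (0.25 * H * pixel_size)
      rb <- seq(0, max(fr), length.out = 400)
      prof <- tapply(pw[ok], cut(fr[ok], rb), sum)
      pk <- which.max(prof)
      d_est <- 1 / ((rb[pk] + rb[pk + 1]) / 2)
    }
    r0 <- 1 / d_est
    ring <- FR >= r0 * (1 - annulus_frac) & FR <= r0 * (1 + annulus_frac)
    if (!any(ring)) stop("no layering signal in the annulus", call. = FALSE)
    az <- atan2(outer(fy, rep(1, W)), outer(rep(1, H), fx))[ring] * 180 / pi
    az <- az %% 180
    az[az >= 180 - bin_deg / 2] <- az[az >= 180 - bin_deg / 2] - 180
    az[az < 0] <- az[az < 0] + 180
    idx <- pmin(pmax(floor(az / bin_deg) + 1L, 1L), length(acc))
    acc <- acc + as.numeric(tapply(P[ring], factor(idx,
                                                   levels = seq_along(acc)),
                                   sum, default = 0))
  }
  mid <- breaks[-length(breaks)] + bin_deg / 2
  if (max(acc) <= 0) stop("no layering signal in the annulus", call. = FALSE)
  # center the axis on the peak (wrap-around on 180 degrees)
  pk_az <- mid[which.max(gauss_smooth(acc, 1))]
  rel <- ((mid - pk_az + 90) %% 180) - 90
  # background = median power well away from the peak, subtracted before
  # the moments; the half-width is 1.1774 x the power-weighted SD of the
  # azimuth (HWHM of the matching Gaussian), iteratively trimmed at
  # +/-3.5 SD for robustness against the diffuse background
  bg <- stats::median(acc[abs(rel) > 60])
  exc <- pmax(acc - bg, 0)
  win <- 50
  mu <- 0; sg <- NA_real_
  for (it in 1:4) {
    sel <- abs(rel - mu) <= win
    mu <- sum(rel[sel] * exc[sel]) / sum(exc[sel])
    sg <- sqrt(sum((rel[sel] - mu)^2 * exc[sel]) / sum(exc[sel]))
    win <- max(3.5 * sg, 3 * bin_deg)
  }
  structure(list(azimuth_deg = mid, power = acc,
                 half_width_deg = HWHM_FACTOR * sg,
                 peak_azimuth_deg = (pk_az + mu) %% 180,
                 d_mean = d_est,
                 criterion = "HWHM from background-subtracted power-weighted azimuthal moments (first-order annulus)"),
            class = "angular_spectrum")
}

#' @export
print.angular_spectrum <- function(x, ...) {
  cat(sprintf("<angular_spectrum> peak at %.1f deg, half-width %.2f deg (d = %.3g nm)\n",
              x$peak_azimuth_deg, x$half_width_deg, x$d_mean))
  invisible(x)
}

#' Construct a defect map
#'
#' @param x_m,y_m defect center coordinates in meters.
#' @param view per-defect view label (\code{"plan"} or
#'   \code{"cross-section"}).
#' @param width_m,height_m field dimensions in meters.
#' @return object of class \code{defect_map}.
#' @export
defect_map <- function(x_m, y_m, view = rep("cross-section", length(x_m)),
                       width_m, height_m) {
  check_scalar(width_m, "width_m", lower = 1e-30)
  check_scalar(height_m, "height_m", lower = 1e-30)
  stopifnot(length(x_m) == length(y_m), length(view) == length(x_m))
  if (length(x_m) && (any(x_m < 0 | x_m > width_m) ||
                      any(y_m < 0 | y_m > height_m))) {
    stop("defect centers outside the field", call. = FALSE)
  }
  structure(list(centers = data.frame(x_m = as.numeric(x_m),
                                      y_m = as.numeric(y_m),
                                      view = as.character(view)),
                 width_m = width_m, height_m = height_m,
                 area_m2 = width_m * height_m),
            class = "defect_map")
}

#' Place defect centers in a field at a target density
#'
#' \code{"exact"} mode places exactly \code{round(density x area)} centers
#' (deterministic count; uniform positions); \code{"poisson"} draws the
#' count from a Poisson distribution.
#'
#' @param width_m,height_m field dimensions in meters.
#' @param density areal density in m^-2.
#' @param mode \code{"exact"} or \code{"poisson"}.
#' @param view view label for all centers.
#' @param seed RNG seed.
#' @return a \code{\link{defect_map}}.
#' @export
defect_centers <- function(width_m, height_m, density,
                           mode = c("exact", "poisson"),
                           view = "cross-section", seed = 1L) {
  mode <- match.arg(mode)
  check_scalar(density, "density", lower = 0)
  area <- width_m * height_m
  with_seed(seed, {
    n <- if (mode == "exact") round(density * area)
         else stats::rpois(1, density * area)
    defect_map(stats::runif(n, 0, width_m), stats::runif(n, 0, height_m),
               rep(view, n), width_m, height_m)
  })
}

#' Topological-defect density
#'
#' Count divided by field area, with the Poisson standard error
#' sqrt(count)/area, reported per view and overall.
#'
#' @param map a \code{\link{defect_map}}.
#' @return object of class \code{defect_density}: data frame with rows per
#'   view plus \code{"all"}; columns \code{view}, \code{count},
#'   \code{area_m2}, \code{density_m2}, \code{poisson_se_m2}.
#' @export
defect_density <- function(map) {
  stopifnot(inherits(map, "defect_map"))
  if (map$area_m2 <= 0) stop("zero field area", call. = FALSE)
  views <- unique(map$centers$view)
  rows <- lapply(c(as.list(views), list(NULL)), function(v) {
    n <- if (is.null(v)) nrow(map$centers)
         else sum(map$centers$view == v)
    data.frame(view = if (is.null(v)) "all" else v,
               count = n, area_m2 = map$area_m2,
               density_m2 = n / map$area_m2,
               poisson_se_m2 = sqrt(n) / map$area_m2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("defect_density", "data.frame")
  out
}
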