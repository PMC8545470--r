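#' Estimate the dominant layering orientation of an image
#'
#' Uses the image structure tensor (averaged outer product of the intensity
#' gradient): the dominant gradient direction is normal to the layering.
#'
#' @param image grayscale matrix (rows = y, cols = x).
#' @param window Gaussian smoothing window (px) applied to the tensor
#'   components before averaging.
#' @return layering normal direction in degrees, measured from the x axis
#'   (90 means horizontal layers stacked along y).
#' @export
layering_orientation <- function(image, window = 64) {
  H <- nrow(image); W <- ncol(image)
  # central differences: gx and gy at a pixel share no source pixels, so
  # uncorrelated noise does not leak into the cross term
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  gy <- (image[ri + 1, ci] - image[ri - 1, ci]) / 2
  gx <- (image[ri, ci + 1] - image[ri, ci - 1]) / 2
  jxx <- mean(gx * gx); jyy <- mean(gy * gy); jxy <- mean(gx * gy)
  ang <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  (ang + 180) %% 180
}

#' Extract an intensity transect from an image
#'
#' Samples image intensity by bilinear interpolation along a straight line,
#' at steps of one pixel size. If no line is given, the sampling direction is
#' taken perpendicular to the layering (structure-tensor estimate) through
#' the image center, spanning as far as the image allows.
#'
#' @param image grayscale matrix (rows = y, cols = x), intensities in [0,1].
#' @param pixel_size nm per pixel.
#' @param line numeric c(x1, y1, x2, y2) in pixel coordinates (1-based), or
#'   NULL for the automatic perpendicular line.
#' @param window structure-tensor window for automatic orientation.
#' @return an object of class \code{transect}: \code{position_nm} (uniform,
#'   strictly increasing), \code{intensity}, \code{direction_deg},
#'   \code{source}.
#' @export
extract_transect <- function(image, pixel_size, line = NULL, window = 64) {
  check_scalar(pixel_size, "pixel_size", lower = 1e-9)
  H <- nrow(image); W <- ncol(image)
  if (is.null(line)) {
    normal <- layering_orientation(image, window)
    th <- normal * pi / 180
    dx <- cos(th); dy <- sin(th)
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    # longest segment through the center staying inside the image
    tmax <- function(d, c, lim) {
      if (abs(d) < 1e-12) return(Inf)
      max((1 - c) / d, (lim - c) / d)
    }
    t_hi <- min(abs(if (abs(dx) > 1e-12) c((1 - cx) / dx, (W - cx) / dx) else Inf),
                abs(if (abs(dy) > 1e-12) c((1 - cy) / dy, (H - cy) / dy) else Inf))
    line <- c(cx - dx * t_hi, cy - dy * t_hi, cx + dx * t_hi, cy + dy * t_hi)
  }
  x1 <- line[1]; y1 <- line[2]; x2 <- line[3]; y2 <- line[4]
  len_px <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len_px < 1) stop("degenerate (zero-length) transect line", call. = FALSE)
  n <- floor(len_px) + 1L
  tt <- seq(0, len_px, length.out = n)
  xs <- x1 + (x2 - x1) * tt / len_px
  ys <- y1 + (y2 - y1) * tt / len_px
  intens <- bilinear_sample(image, xs, ys)
  structure(list(position_nm = tt * pixel_size,
                 intensity = intens,
                 direction_deg = atan2(y2 - y1, x2 - x1) * 180 / pi,
                 source = sprintf("line (%.1f,%.1f)-(%.1f,%.1f)",
                                  x1, y1, x2, y2)),
            class = "transect")
}

# bilinear interpolation at (x, y) pixel coordinates (cols, rows), 1-based
bilinear_sample <- function(image, xs, ys) {
  H <- nrow(image); W <- ncol(image)
  xs <- pmin(pmax(xs, 1), W); ys <- pmin(pmax(ys, 1), H)
  x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  image[i00] * (1 - fx) * (1 - fy) + image[i01] * fx * (1 - fy) +
    image[i10] * (1 - fx) * fy + image[i11] * fx * fy
}

# Local minima (interior strict sign changes); plateaus take their center.
local_minima_idx <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # collapse zero runs: carry last nonzero sign forward for plateau handling
  idx <- which(nz)
  out <- integer(0)
  prev_sign <- s[idx[1]]
  prev_i <- idx[1]
  for (k in idx[-1]) {
    if (s[k] != prev_sign) {
      if (prev_sign < 0 && s[k] > 0) {
        # minimum between prev_i+1 and k (plateau center)
        out <- c(out, as.integer(round((prev_i + 1 + k) / 2)))
      }
      prev_sign <- s[k]
    }
    prev_i <- k
  }
  out
}

# Prominence of minima of `x` at indices `mins` (scipy-compatible
# convention: bases bounded by the nearest deeper minimum or signal edge).
minima_prominence <- function(x, mins) {
  if (!length(mins)) return(numeric(0))
  y <- -x
  peaks <- mins
  K <- length(peaks)
  hh <- y[peaks]
  # valleys between consecutive peaks, plus edge valleys
  v <- numeric(K + 1)
  bounds <- c(1L, peaks, length(y))
  for (k in seq_len(K + 1)) {
    v[k] <- min(y[bounds[k]:bounds[k + 1]])
  }
  # nearest strictly higher peak to the left / right (monotonic stacks)
  left_hi <- integer(K); right_hi <- integer(K)
  stk <- integer(0)
  for (k in seq_len(K)) {
    while (length(stk) && hh[stk[length(stk)]] <= hh[k]) {
      stk <- stk[-length(stk)]
    }
    left_hi[k] <- if (length(stk)) stk[length(stk)] else 0L
    stk <- c(stk, k)
  }
  stk <- integer(0)
  for (k in rev(seq_len(K))) {
    while (length(stk) && hh[stk[length(stk)]] <= hh[k]) {
      stk <- stk[-length(stk)]
    }
    right_hi[k] <- if (length(stk)) stk[length(stk)] else K + 1L
    stk <- c(stk, k)
  }
  # sparse table for range-min over v
  Kv <- K + 1
  LOG <- floor(log2(Kv))
  tab <- matrix(Inf, nrow = LOG + 1, ncol = Kv)
  tab[1, ] <- v
  if (LOG >= 1) for (l in seq_len(LOG)) {
    span <- 2^(l - 1)
    idx <- seq_len(Kv - 2 * span + 1)
    tab[l + 1, idx] <- pmin(tab[l, idx], tab[l, idx + span])
  }
  rmin <- function(a, b) { # min over v[a..b], a <= b
    l <- floor(log2(b - a + 1))
    min(tab[l + 1, a], tab[l + 1, b - 2^l + 1])
  }
  prom <- numeric(K)
  for (k in seq_len(K)) {
    lb <- rmin(left_hi[k] + 1L, k)       # valleys v[left_hi+1 .. k]
    rb <- rmin(k + 1L, right_hi[k])      # valleys v[k+1 .. right_hi]
    prom[k] <- hh[k] - max(lb, rb)
  }
  prom
}

#' Detect interlamellar sheaths along a transect
#'
#' Sheaths are identified as local minima of the (Gaussian-smoothed) BSE
#' intensity profile with prominence at least \code{min_prominence}; minima
#' positions are refined to sub-pixel precision with a 3-point parabola.
#'
#' @param transect a \code{transect} (or any list with \code{position_nm} and
#'   \code{intensity}).
#' @param smoothing_sd Gaussian smoothing SD in samples; default
#'   \code{max(1, sheath_width / 2 / step)}.
#' @param min_prominence minimum prominence (intensity units); default 25% of
#'   the robust tablet-sheath contrast (median intensity minus its 2%
#'   quantile).
#' @param sheath_width nominal sheath width in nm used for the default
#'   smoothing (default 15).
#' @return an object of class \code{interface_set}: data frame with
#'   \code{position} (nm, strictly increasing) and \code{prominence}.
#' @export
detect_sheaths <- function(transect, smoothing_sd = NULL,
                           min_prominence = NULL, sheath_width = 15) {
  s <- transect$intensity
  pos <- transect$position_nm
  if (length(s) < 3) stop("transect must have at least 3 samples")
  if (anyNA(s)) stop("transect intensities contain NA", call. = FALSE)
  step <- stats::median(diff(pos))
  if (is.null(smoothing_sd)) smoothing_sd <- max(1, sheath_width / 2 / step)
  sm <- gauss_smooth(s, smoothing_sd)
  mins <- local_minima_idx(sm)
  if (!length(mins)) {
    return(interface_set(numeric(0), numeric(0)))
  }
  prom <- minima_prominence(sm, mins)
  if (is.null(min_prominence)) {
    # robust tablet-sheath contrast: tablet level = median intensity; sheath
    # level = median of the deepest minima (first pass at half the maximum
    # prominence), read off a lightly smoothed profile. A noise floor (8x
    # the robust SD of the smoothed profile against its running median)
    # guards against noise extrema on very long transects.
    s1 <- gauss_smooth(s, 1)
    strong <- mins[prom >= 0.5 * max(prom)]
    contrast <- stats::median(s1) - stats::median(s1[strong])
    k_med <- min(31L, if (length(sm) %% 2 == 1) length(sm)
                      else length(sm) - 1L)
    sd_noise <- stats::mad(sm - stats::runmed(sm, k_med))
    min_prominence <- max(0.25 * contrast, 8 * sd_noise)
  }
  keep <- prom >= min_prominence & prom > 0
  mins <- mins[keep]; prom <- prom[keep]
  if (!length(mins)) return(interface_set(numeric(0), numeric(0)))
  # sub-pixel parabolic refinement on the smoothed profile
  off <- rep(0, length(mins))
  interior <- mins > 1 & mins < length(sm)
  i <- mins[interior]
  denom <- sm[i - 1] - 2 * sm[i] + sm[i + 1]
  ok <- denom > 0
  off[interior][ok] <- (0.5 * (sm[i - 1] - sm[i + 1]) / denom)[ok]
  off <- pmax(pmin(off, 0.5), -0.5)
  interface_set(pos[mins] + off * step, prom)
}

#' Construct an interface set
#'
#' @param position interface positions in nm (will be sorted).
#' @param prominence detection prominence per interface (>= 0).
#' @return data frame of class \code{interface_set}.
#' @export
interface_set <- function(position, prominence = rep(NA_real_,
                                                     length(position))) {
  stopifnot(length(position) == length(prominence))
  o <- order(position)
  out <- data.frame(position = as.numeric(position[o]),
                    prominence = as.numeric(prominence[o]))
  if (any(!is.na(out$prominence) & out$prominence < 0)) {
    stop("prominence must be non-negative")
  }
  class(out) <- c("interface_set", "data.frame")
  out
}

#' Tablet thicknesses from interface positions
#'
#' The Nth tablet thickness is the difference between the Nth and (N+1)th
#' interface positions.
#'
#' @param interfaces an \code{interface_set} or numeric vector of positions
#'   (nm).
#' @return a \code{thickness_profile} with \code{length(interfaces) - 1} rows.
#' @export
thickness_from_interfaces <- function(interfaces) {
  pos <- if (inherits(interfaces, "interface_set")) {
    interfaces$position
  } else as.numeric(interfaces)
  if (length(pos) < 2) stop("insufficient interfaces (need at least 2)",
                            call. = FALSE)
  w <- diff(sort(pos))
  if (any(w <= 0)) stop("duplicate interface positions", call. = FALSE)
  thickness_profile(w)
}

#' Flag apparent merged (double-thickness) layers
#'
#' A missed sheath merges two tablets into one apparent double-thickness
#' layer. Layers whose thickness exceeds \code{tau} times the rolling median
#' (window 11) are flagged \code{merged_excluded}; downstream statistics
#' exclude them.
#'
#' @param profile a \code{thickness_profile}.
#' @param tau multiplicative threshold (> 1), default 1.8.
#' @param window rolling-median window (odd), default 11.
#' @return the profile with updated flags.
#' @export
flag_merged_layers <- function(profile, tau = 1.8, window = 11) {
  stopifnot(inherits(profile, "thickness_profile"), nrow(profile) >= 1)
  check_scalar(tau, "tau", lower = 1 + 1e-9)
  w <- profile$thickness
  k <- min(window, if (length(w) %% 2 == 1) length(w) else length(w) - 1)
  if (k < 3) return(profile)
  med <- stats::runmed(w, k, endrule = "median")
  profile$flag[w > tau * med] <- "merged_excluded"
  profile
}

#' Build a thickness map from multiple transects across an image
#'
#' Runs sheath detection on \code{n_transects} vertical transects (evenly
#' spaced columns), then aligns layers between adjacent transects by
#' nearest-interface matching; cells that cannot be matched are masked (NA).
#'
#' @param image grayscale matrix.
#' @param pixel_size nm per pixel.
#' @param n_transects number of transects (>= 1).
#' @param ... passed to \code{\link{detect_sheaths}}.
#' @return an object of class \code{thickness_map}: \code{thickness} matrix
#'   (layers x transects, nm, NA = masked), \code{x_nm} transect lateral
#'   positions, \code{unmatched_fraction}.
#' @export
build_thickness_map <- function(image, pixel_size, n_transects = 16, ...) {
  check_scalar(n_transects, "n_transects", lower = 1)
  W <- ncol(image)
  cols <- unique(round(seq(1, W, length.out = n_transects)))
  sets <- lapply(cols, function(cc) {
    tr <- structure(list(position_nm = (seq_len(nrow(image)) - 1) * pixel_size,
                         intensity = image[, cc],
                         direction_deg = 90,
                         source = sprintf("column %d", cc)),
                    class = "transect")
    detect_sheaths(tr, ...)
  })
  d_med <- stats::median(unlist(lapply(sets, function(s) diff(s$position))))
  # label interfaces by chaining nearest matches across transects
  labels <- vector("list", length(sets))
  labels[[1]] <- seq_len(nrow(sets[[1]]))
  next_label <- length(labels[[1]]) + 1L
  unmatched <- 0L; total <- 0L
  for (j in seq_along(sets)[-1]) {
    prev <- sets[[j - 1]]$position; cur <- sets[[j]]$position
    lab <- rep(NA_integer_, length(cur))
    if (length(prev) && length(cur)) {
      for (m in seq_along(cur)) {
        i <- which.min(abs(prev - cur[m]))
        if (abs(prev[i] - cur[m]) <= d_med / 2) lab[m] <- labels[[j - 1]][i]
      }
      # resolve duplicate matches: keep the closest
      for (dup in unique(lab[duplicated(lab) & !is.na(lab)])) {
        idx <- which(lab == dup)
        best <- idx[which.min(abs(cur[idx] - prev[match(dup, labels[[j - 1]])]))]
        lab[setdiff(idx, best)] <- NA_integer_
      }
    }
    total <- total + length(lab); unmatched <- unmatched + sum(is.na(lab))
    for (m in which(is.na(lab))) {
      lab[m] <- next_label; next_label <- next_label + 1L
    }
    labels[[j]] <- lab
  }
  unmatched_fraction <- if (total) unmatched / total else 0
  if (unmatched_fraction > 0.2) {
    warning(sprintf(
      "layer correspondence failed for %.1f%% of interfaces; cells masked",
      100 * unmatched_fraction))
  }
  n_lab <- next_label - 1L
  thick <- matrix(NA_real_, nrow = n_lab - 1L, ncol = length(sets))
  for (j in seq_along(sets)) {
    lab <- labels[[j]]; pos <- sets[[j]]$position
    if (length(lab) < 2) next
    for (m in seq_len(length(lab) - 1L)) {
      if (lab[m + 1L] == lab[m] + 1L) {
        thick[lab[m], j] <- pos[m + 1L] - pos[m]
      }
    }
  }
  structure(list(thickness = thick,
                 x_nm = (cols - 1) * pixel_size,
                 unmatched_fraction = unmatched_fraction),
            class = "thickness_map")
}

#' Match detected interfaces against ground truth
#'
#' Greedy nearest matching within a tolerance; each truth interface can be
#' claimed once. Used to score detection recall and precision on synthetic
#' renders.
#'
#' @param detected an \code{interface_set} or numeric positions (nm).
#' @param truth numeric ground-truth positions (nm).
#' @param tol_nm matching tolerance (default half the median truth spacing).
#' @return list with \code{recall}, \code{precision}, \code{n_matched},
#'   \code{rmse_nm} (position error of matched pairs).
#' @export
match_interfaces <- function(detected, truth, tol_nm = NULL) {
  det <- if (inherits(detected, "interface_set")) detected$position
         else as.numeric(detected)
  if (is.null(tol_nm)) tol_nm <- stats::median(diff(sort(truth))) / 2
  used <- rep(FALSE, length(truth))
  err <- rep(NA_real_, length(det))
  for (m in seq_along(det)) {
    free <- which(!used)
    if (!length(free)) break
    i <- free[which.min(abs(truth[free] - det[m]))]
    if (abs(truth[i] - det[m]) <= tol_nm) {
      used[i] <- TRUE
      err[m] <- det[m] - truth[i]
    }
  }
  n_matched <- sum(!is.na(err))
  list(recall = n_matched / length(truth),
       precision = if (length(det)) n_matched / length(det) else NA_real_,
       n_matched = n_matched,
       rmse_nm = if (n_matched) sqrt(mean(err^2, na.rm = TRUE)) else NA_real_)
}
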