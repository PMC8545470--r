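#' Rendering specification for synthetic BSE-like micrographs
#'
#' Describes how a stack of interlamellar sheaths is turned into a grayscale
#' cross-sectional image with backscattered-electron-like contrast: bright
#' mineral tablets, dark organic sheaths, Gaussian blur and additive noise.
#'
#' @param pixel_size pixel size in nm/px (default 3, typical high-resolution
#'   BSE-SEM mosaics).
#' @param sheath_width organic sheath width in nm (rendered as a Gaussian dip
#'   of matching full width).
#' @param gray_tablet,gray_sheath tablet and sheath intensity levels in [0, 1];
#'   \code{gray_sheath < gray_tablet}.
#' @param blur_sd imaging blur SD in px.
#' @param noise_sd additive Gaussian noise SD in intensity units (default 10%
#'   of the tablet-sheath contrast).
#' @param orientation_halfwidth half-width at half maximum of the interface
#'   slope-angle distribution, degrees (0 = perfectly flat layers).
#' @param roughness_corr_length lateral correlation length of interface
#'   displacement, nm (facet length in the faceted model).
#' @param roughness_model \code{"smooth"} (Gaussian random field) or
#'   \code{"faceted"} (piecewise-linear facets of length
#'   \code{roughness_corr_length} with independent Gaussian slopes, like
#'   flat tablets meeting at kinks; the model of choice for Fourier
#'   orientation measurements, where each facet diffracts exactly at its
#'   tilt angle).
#' @param roughness_attenuation per-layer carry-over of interface displacement
#'   in [0, 1]; bumps and valleys in one layer persist, attenuated, into the
#'   next. Values near 1 give conformal (non-crossing) roughness.
#' @param image_width image width in px.
#' @return an object of class \code{render_spec}.
#' @export
render_spec <- function(pixel_size = 3,
                        sheath_width = 15,
                        gray_tablet = 0.8,
                        gray_sheath = 0.2,
                        blur_sd = 2,
                        noise_sd = 0.06,
                        orientation_halfwidth = 5,
                        roughness_corr_length = 10000,
                        roughness_model = c("smooth", "faceted"),
                        roughness_attenuation = 0.999,
                        image_width = 512) {
  roughness_model <- match.arg(roughness_model)
  check_scalar(pixel_size, "pixel_size", lower = 1e-6)
  check_scalar(sheath_width, "sheath_width", lower = 0)
  check_scalar(gray_tablet, "gray_tablet", lower = 0, upper = 1)
  check_scalar(gray_sheath, "gray_sheath", lower = 0, upper = 1)
  if (gray_sheath >= gray_tablet) {
    stop("parameter 'gray_sheath' must be below 'gray_tablet'", call. = FALSE)
  }
  check_scalar(blur_sd, "blur_sd", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(orientation_halfwidth, "orientation_halfwidth", lower = 0)
  if (orientation_halfwidth >= 90) {
    stop("parameter 'orientation_halfwidth' must be below 90 degrees",
         call. = FALSE)
  }
  check_scalar(roughness_corr_length, "roughness_corr_length", lower = 1e-6)
  check_scalar(roughness_attenuation, "roughness_attenuation",
               lower = 0, upper = 1)
  check_scalar(image_width, "image_width", lower = 1)
  structure(list(pixel_size = pixel_size, sheath_width = sheath_width,
                 gray_tablet = gray_tablet, gray_sheath = gray_sheath,
                 blur_sd = blur_sd, noise_sd = noise_sd,
                 orientation_halfwidth = orientation_halfwidth,
                 roughness_corr_length = roughness_corr_length,
                 roughness_model = roughness_model,
                 roughness_attenuation = roughness_attenuation,
                 image_width = as.integer(image_width)),
            class = "render_spec")
}

#' Build per-layer interface curves from a thickness profile
#'
#' Stacks interfaces cumulatively (\eqn{x_N = \sum_{i \le N} w_i}) and adds a
#' transverse displacement field \eqn{u_i(x)} per interface:
#' \eqn{u_{i+1} = a u_i + \sqrt{1 - a^2}\, v_i} with
#' \eqn{a} = \code{roughness_attenuation} and \eqn{v_i} fresh Gaussian noise
#' smoothed to the requested lateral correlation length. The common amplitude
#' is calibrated (per realization) so that the distribution of the interface
#' slope angle \eqn{\arctan(du/dx)} has exactly the requested half-width at
#' half maximum. Displacements are clipped so that the layer spacing never
#' falls below the profile's thickness floor.
#'
#' @param profile a \code{thickness_profile}.
#' @param render a \code{\link{render_spec}}.
#' @param seed RNG seed for the roughness fields.
#' @param margin_nm blank tablet margin above and below the stack (default
#'   three mean thicknesses).
#' @return an object of class \code{interface_field}: interface positions
#'   \code{y} (matrix, interfaces x columns, nm from the image top), lateral
#'   coordinates \code{x_nm}, partial-sheath extras, defect table.
#' @export
make_interface_field <- function(profile, render, seed = 1L,
                                 margin_nm = NULL) {
  stopifnot(inherits(profile, "thickness_profile"),
            inherits(render, "render_spec"))
  w <- profile$thickness
  if (!all(is.finite(w))) stop("profile contains non-finite thicknesses")
  if (is.null(margin_nm)) margin_nm <- 3 * mean(w)
  n_int <- length(w) + 1L
  W <- render$image_width
  base <- c(0, cumsum(w)) + margin_nm
  x_nm <- (seq_len(W) - 1) * render$pixel_size
  spec0 <- attr(profile, "spec")
  floor_nm <- if (!is.null(spec0)) spec0$floor else min(w) * 0.5

  if (render$orientation_halfwidth == 0 || W < 8) {
    y <- matrix(rep(base, W), nrow = n_int)
  } else {
    y <- with_seed(seed, {
      a <- render$roughness_attenuation
      sd_px <- render$roughness_corr_length / render$pixel_size / sqrt(2)
      lf_px <- max(2L, round(render$roughness_corr_length /
                               render$pixel_size))
      fresh <- if (identical(render$roughness_model, "faceted")) {
        function() {
          n_f <- ceiling(W / lf_px)
          sl <- stats::rnorm(n_f)
          # unit slope SD (not displacement SD): keeps the slope mixture
          # across interfaces homogeneous, hence Gaussian
          sl <- sl / stats::sd(sl)
          v <- cumsum(rep(sl, each = lf_px)[seq_len(W)])
          v - mean(v)
        }
      } else {
        function() {
          v <- gauss_smooth(stats::rnorm(W), sd_px)
          s <- stats::sd(v)
          if (s > 0) v / s else v
        }
      }
      u <- matrix(0, nrow = n_int, ncol = W)
      u[1, ] <- fresh()
      b <- sqrt(1 - a^2)
      for (i in seq_len(n_int - 1L)) u[i + 1L, ] <- a * u[i, ] + b * fresh()
      # calibrate amplitude: HWHM of arctan-slope distribution (degrees)
      slopes <- t(diff(t(u))) / render$pixel_size
      sl <- as.numeric(slopes)
      target <- render$orientation_halfwidth
      hw <- function(k) HWHM_FACTOR * stats::sd(atan(k * sl)) * 180 / pi
      upper <- 1
      while (hw(upper) < target && upper < 1e6) upper <- upper * 4
      if (hw(upper) < target) {
        stop(sprintf(
          "cannot reach orientation_halfwidth = %g deg with image width %d and roughness_corr_length %g nm",
          target, W, render$roughness_corr_length), call. = FALSE)
      }
      k <- stats::uniroot(function(k) hw(k) - target, c(0, upper),
                          tol = 1e-10)$root
      k * u + base
    })
    # enforce non-crossing / minimum spacing
    for (i in seq_len(n_int - 1L)) {
      y[i + 1L, ] <- pmax(y[i + 1L, ], y[i, ] + floor_nm)
    }
  }

  structure(list(y = y, x_nm = x_nm, profile = profile, render = render,
                 margin_nm = margin_nm, floor_nm = floor_nm,
                 extras = list(),
                 defects = data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                      layer = integer(0))),
            class = "interface_field")
}

#' Insert screw-dislocation-like defects into an interface field
#'
#' Each defect is a terminating partial sheath: an extra organic boundary that
#' starts at a point inside a host tablet and continues to the image edge. The
#' host tablet is locally thinned by \code{thinning_fraction} (a Gaussian
#' thinning envelope of scale \code{decay_length}), so the minimum local
#' thickness at the defect is \code{(1 - thinning_fraction)} times the
#' surrounding thickness; the displaced material is absorbed by the layer
#' above, preserving the long-range stacking.
#'
#' @param field an \code{\link{make_interface_field}} result.
#' @param density areal defect density in m^-2 (image area = lateral extent
#'   x stack height).
#' @param thinning_fraction local relative thickness reduction at the defect
#'   (default 0.28).
#' @param decay_length lateral scale of the thinning envelope, nm.
#' @param mode \code{"exact"} places round(density x area) defects
#'   (deterministic count); \code{"poisson"} draws the count.
#' @param seed RNG seed for defect placement.
#' @return the field with defects inserted and \code{defects} updated.
#' @export
insert_dislocations <- function(field, density, thinning_fraction = 0.28,
                                decay_length = 2000,
                                mode = c("exact", "poisson"), seed = 1L) {
  stopifnot(inherits(field, "interface_field"))
  mode <- match.arg(mode)
  check_scalar(density, "density", lower = 0)
  check_scalar(thinning_fraction, "thinning_fraction", lower = 0, upper = 0.95)
  if (density == 0) return(field)
  W <- length(field$x_nm)
  px <- field$render$pixel_size
  width_m <- W * px * 1e-9
  height_m <- (max(field$y[nrow(field$y), ]) - min(field$y[1, ])) * 1e-9
  area_m2 <- width_m * height_m
  n_def <- if (mode == "exact") round(density * area_m2) else NULL
  with_seed(seed, {
    if (mode == "poisson") n_def <- stats::rpois(1, density * area_m2)
    if (n_def < 1) return(field)
    n_lay <- nrow(field$y) - 1L
    hosts <- sample(seq.int(2L, max(2L, n_lay - 1L)), n_def, replace = TRUE)
    c0s <- sample(seq.int(max(1L, round(0.05 * W)),
                          min(W, round(0.95 * W))), n_def, replace = TRUE)
    for (d in seq_len(n_def)) {
      i <- hosts[d]; c0 <- c0s[d]
      w_loc <- field$y[i + 1L, ] - field$y[i, ]
      env <- thinning_fraction *
        exp(-(field$x_nm - field$x_nm[c0])^2 / (2 * decay_length^2))
      field$y[i + 1L, ] <- field$y[i, ] + w_loc * (1 - env)
      cols <- c0:W
      field$extras[[length(field$extras) + 1L]] <- list(
        cols = cols,
        y = (field$y[i, cols] + field$y[i + 1L, cols]) / 2)
      field$defects <- rbind(field$defects, data.frame(
        x_nm = field$x_nm[c0],
        y_nm = (field$y[i, c0] + field$y[i + 1L, c0]) / 2,
        layer = i))
    }
    field
  })
}

# stamp Gaussian sheath dips into a dip-accumulation sparse matrix
stamp_dips <- function(rows_center, cols, sigma_px, n_rows) {
  h <- ceiling(3 * sigma_px + 1)
  off <- seq.int(-h, h)
  r0 <- round(rows_center)
  ri <- rep(r0, each = length(off)) + off
  ci <- rep(cols, each = length(off))
  vv <- exp(-(ri - rep(rows_center, each = length(off)))^2 / (2 * sigma_px^2))
  keep <- ri >= 1L & ri <= n_rows
  list(i = ri[keep], j = ci[keep], x = vv[keep])
}

#' Render a synthetic cross-sectional micrograph
#'
#' Converts an interface field into a grayscale image: uniform tablet level,
#' Gaussian intensity dips of full width \code{sheath_width} centered on each
#' sheath centerline (so intensity minima fall exactly on the interfaces in a
#' noise-free render), optional Gaussian blur and additive noise.
#'
#' @param field an \code{\link{make_interface_field}} result (possibly with
#'   dislocations inserted).
#' @param seed RNG seed for the additive noise.
#' @param y_offset_nm top edge of the rendered window in nm (default 0).
#' @param height_px rendered height in px (default: full stack plus margins).
#' @return an object of class \code{synthetic_sample}: \code{image} (rows =
#'   growth direction, cols = lateral), \code{pixel_size}, per-column ground
#'   truth \code{truth_interfaces} (nm, relative to the rendered window top),
#'   \code{truth_profile} at the reference (center) column,
#'   \code{truth_defects}.
#' @export
render_micrograph <- function(field, seed = 1L, y_offset_nm = 0,
                              height_px = NULL) {
  stopifnot(inherits(field, "interface_field"))
  r <- field$render
  px <- r$pixel_size
  W <- length(field$x_nm)
  auto_height <- is.null(height_px)
  if (auto_height) {
    height_px <- ceiling((max(field$y) + field$margin_nm - y_offset_nm) / px)
  }
  H <- as.integer(height_px)
  y_rel <- field$y - y_offset_nm
  if (is.null(dim(y_rel))) y_rel <- matrix(y_rel, ncol = W)
  # a bounded canvas (explicit height, no window offset) rejects overflow;
  # windowed renders legitimately have interfaces outside the window
  if (!auto_height && y_offset_nm == 0 && min(y_rel) >= 0 &&
      max(y_rel) > H * px) {
    stop("interfaces exceed the rendered image height", call. = FALSE)
  }
  sigma_px <- max(r$sheath_width / px / 2.355, 0.5)
  # row j samples position (j - 1) * px, matching extract_transect
  rows_center <- as.numeric(t(y_rel)) / px + 1
  cols <- rep(seq_len(W), times = nrow(y_rel))
  st <- stamp_dips(rows_center, cols, sigma_px, H)
  for (ex in field$extras) {
    st2 <- stamp_dips((ex$y - y_offset_nm) / px + 1, ex$cols, sigma_px, H)
    st$i <- c(st$i, st2$i); st$j <- c(st$j, st2$j); st$x <- c(st$x, st2$x)
  }
  D <- Matrix::sparseMatrix(i = st$i, j = st$j, x = st$x, dims = c(H, W))
  img <- r$gray_tablet - (r$gray_tablet - r$gray_sheath) *
    pmin(as.matrix(D), 1)
  if (r$blur_sd > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = r$blur_sd))
  }
  if (r$noise_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(H * W, sd = r$noise_sd),
                                        nrow = H))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  ref <- max(1L, W %/% 2L)
  truth_int <- y_rel
  synthetic_sample(image = img, pixel_size = px,
                   truth_interfaces = truth_int,
                   truth_profile = thickness_profile(diff(truth_int[, ref])),
                   truth_defects = field$defects,
                   render = r, ref_column = ref)
}

#' Render a single synthetic transect (1D intensity profile)
#'
#' One-dimensional equivalent of \code{\link{render_micrograph}}: interface
#' positions along a line perpendicular to the layering are rendered as
#' Gaussian intensity dips on a bright background, blurred and noised. Useful
#' for full-pearl-scale profiles where a 2D image would be wastefully large.
#'
#' @param profile a \code{thickness_profile}.
#' @param render a \code{\link{render_spec}} (its lateral parameters are
#'   ignored).
#' @param seed RNG seed for the noise.
#' @param margin_nm blank margin before and after the stack.
#' @return a \code{synthetic_sample} whose \code{transect} field holds
#'   \code{position_nm} and \code{intensity}; \code{truth_interfaces} is the
#'   vector of interface positions in nm from the transect start.
#' @export
render_transect <- function(profile, render, seed = 1L, margin_nm = NULL) {
  stopifnot(inherits(profile, "thickness_profile"),
            inherits(render, "render_spec"))
  w <- profile$thickness
  if (is.null(margin_nm)) margin_nm <- 3 * mean(w)
  pos <- c(0, cumsum(w)) + margin_nm
  px <- render$pixel_size
  n <- ceiling((max(pos) + margin_nm) / px)
  sigma_px <- max(render$sheath_width / px / 2.355, 0.5)
  st <- stamp_dips(pos / px + 1, rep(1L, length(pos)), sigma_px, n)
  D <- as.numeric(Matrix::sparseMatrix(i = st$i, j = rep(1L, length(st$i)),
                                       x = st$x, dims = c(n, 1L)))
  intens <- render$gray_tablet -
    (render$gray_tablet - render$gray_sheath) * pmin(D, 1)
  if (render$blur_sd > 0) intens <- gauss_smooth(intens, render$blur_sd)
  if (render$noise_sd > 0) {
    intens <- with_seed(seed, intens + stats::rnorm(n, sd = render$noise_sd))
  }
  intens[intens < 0] <- 0
  intens[intens > 1] <- 1
  tr <- structure(list(position_nm = (seq_len(n) - 1) * px,
                       intensity = intens,
                       direction_deg = 90,
                       source = "synthetic transect"),
                  class = "transect")
  synthetic_sample(image = NULL, pixel_size = px,
                   truth_interfaces = pos,
                   truth_profile = profile,
                   truth_defects = data.frame(),
                   render = render, transect = tr)
}

#' Construct a synthetic sample container
#'
#' @param image grayscale matrix (rows = growth direction) or NULL.
#' @param pixel_size nm per pixel.
#' @param truth_interfaces per-column interface positions (matrix interfaces x
#'   columns) or a vector for a 1D transect, nm.
#' @param truth_profile ground-truth \code{thickness_profile} at the
#'   reference column.
#' @param truth_defects data frame of defect centers (x_nm, y_nm, layer).
#' @param render the \code{render_spec} used.
#' @param ref_column reference column index for \code{truth_profile}.
#' @param transect optional 1D transect (class \code{transect}).
#' @return an object of class \code{synthetic_sample}.
#' @export
synthetic_sample <- function(image, pixel_size, truth_interfaces,
                             truth_profile, truth_defects, render,
                             ref_column = 1L, transect = NULL) {
  if (is.matrix(truth_interfaces)) {
    inc <- apply(truth_interfaces, 2, function(col) all(diff(col) > 0))
    if (!all(inc)) stop("truth interfaces must be strictly increasing")
  } else if (is.unsorted(truth_interfaces, strictly = TRUE)) {
    stop("truth interfaces must be strictly increasing")
  }
  structure(list(image = image, pixel_size = pixel_size,
                 truth_interfaces = truth_interfaces,
                 truth_profile = truth_profile,
                 truth_defects = truth_defects,
                 render = render, ref_column = ref_column,
                 transect = transect),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  if (!is.null(x$image)) {
    cat(sprintf("<synthetic_sample> %d x %d px at %.3g nm/px, %d layers, %d defects\n",
                nrow(x$image), ncol(x$image), x$pixel_size,
                nrow(x$truth_profile), nrow(x$truth_defects)))
  } else {
    cat(sprintf("<synthetic_sample> 1D transect, %d samples at %.3g nm/px, %d layers\n",
                length(x$transect$intensity), x$pixel_size,
                nrow(x$truth_profile)))
  }
  invisible(x)
}

#' Synthetic fields of view for angular-order measurement
#'
#' Builds one laterally extended interface field with the requested
#' orientation statistics and renders it as a series of adjacent fields of
#' view (tiles), each cropped to rows fully inside the layer stack. The
#' Fourier measurement of orientation spread needs laterally coherent tilted
#' domains spanning many layer periods, so these fixtures use a long
#' roughness correlation length (10 um), near-conformal layer-to-layer
#' carry-over and a coarser pixel size than detection-scale renders: the
#' azimuthal broadening kernel scales with spacing/correlation-length and is
#' independent of pixel size. The realized slope-angle half-width of the
#' generated field is returned as ground truth.
#'
#' @param stage \code{"early"} or \code{"mature"} (sets thickness statistics
#'   and, unless overridden, the orientation half-width).
#' @param n_layers layers in the stack (default 150).
#' @param seed master seed.
#' @param n_tiles number of fields of view.
#' @param tile_width tile width in px.
#' @param pixel_size nm/px (default 24).
#' @param orientation_halfwidth override for the orientation half-width in
#'   degrees.
#' @param n_fields number of independent replicate fields (default 2); all
#'   tiles from all fields are returned for joint azimuthal averaging.
#' @return list: \code{images} (list of grayscale tiles),
#'   \code{pixel_size}, \code{truth_halfwidth_deg} (realized slope-angle
#'   HWHM of the generated field), \code{d_mean_nm}.
#' @export
simulate_angular_views <- function(stage = "early", n_layers = 150,
                                   seed = 1L, n_tiles = 24,
                                   tile_width = 1024, pixel_size = 24,
                                   orientation_halfwidth = NULL,
                                   n_fields = 2) {
  if (is.null(orientation_halfwidth)) {
    orientation_halfwidth <- preset_orientation(stage)
  }
  if (n_fields > 1) {
    # independent replicate fields average down the azimuthal speckle of
    # any single coherent field
    parts <- lapply(seq_len(n_fields) - 1L, function(k) {
      simulate_angular_views(stage, n_layers, seed + 1000L * k, n_tiles,
                             tile_width, pixel_size, orientation_halfwidth,
                             n_fields = 1)
    })
    return(list(images = do.call(c, lapply(parts, `[[`, "images")),
                pixel_size = pixel_size,
                truth_halfwidth_deg =
                  mean(vapply(parts, `[[`, 0, "truth_halfwidth_deg")),
                d_mean_nm = mean(vapply(parts, `[[`, 0, "d_mean_nm"))))
  }
  rs <- render_spec(pixel_size = pixel_size, blur_sd = 1, noise_sd = 0.06,
                    orientation_halfwidth = orientation_halfwidth,
                    roughness_corr_length = 10000,
                    roughness_model = "faceted",
                    roughness_attenuation = 0.999,
                    image_width = n_tiles * tile_width)
  prof <- make_thickness_profile(preset_growth(stage, n_layers = n_layers,
                                               seed = seed))
  field <- make_interface_field(prof, rs, seed = seed + 1L)
  slopes <- t(diff(t(field$y))) / pixel_size
  truth_hw <- HWHM_FACTOR * stats::sd(atan(as.numeric(slopes))) * 180 / pi
  pad <- ceiling(3 * rs$blur_sd + 4)
  images <- vector("list", n_tiles)
  for (t in seq_len(n_tiles)) {
    cols <- ((t - 1) * tile_width + 1):(t * tile_width)
    sub <- field
    sub$y <- field$y[, cols, drop = FALSE]
    sub$x_nm <- field$x_nm[cols] - field$x_nm[cols[1]]
    sub$render$image_width <- tile_width
    rmin <- ceiling(max(sub$y[1, ]) / pixel_size) + pad
    rmax <- floor(min(sub$y[nrow(sub$y), ]) / pixel_size) - pad
    if (rmax - rmin < 20) stop("stack tilt leaves no interior window")
    smp <- render_micrograph(sub, seed = seed + 1L + t,
                             y_offset_nm = (rmin - 1) * pixel_size,
                             height_px = rmax - rmin + 1L)
    images[[t]] <- smp$image
  }
  list(images = images, pixel_size = pixel_size,
       truth_halfwidth_deg = truth_hw,
       d_mean_nm = mean(prof$thickness))
}

#' One-call synthetic nacre simulation
#'
#' Convenience wrapper: stage-preset thickness profile, interface field,
#' optional dislocations, rendered micrograph.
#'
#' @param stage \code{"early"}, \code{"mature"} or \code{"full_pearl"}.
#' @param n_layers number of layers (stage default if NULL).
#' @param seed master seed (profile, roughness and noise streams are derived
#'   from it).
#' @param render a \code{render_spec}; if NULL a stage-appropriate default is
#'   built (orientation half-width from \code{\link{preset_orientation}}).
#' @param dislocation_density areal defect density in m^-2 (0 = none).
#' @param as_transect if TRUE, render a 1D transect instead of a 2D image.
#' @return a \code{synthetic_sample}.
#' @export
simulate_nacre <- function(stage = "mature", n_layers = NULL, seed = 1L,
                           render = NULL, dislocation_density = 0,
                           as_transect = FALSE) {
  gs <- preset_growth(stage, n_layers = n_layers, seed = seed)
  prof <- make_thickness_profile(gs)
  if (is.null(render)) {
    # roughness correlation length capped to the field of view so the
    # orientation spread is expressible in narrow detection-scale images
    render <- render_spec(orientation_halfwidth = preset_orientation(stage))
    render$roughness_corr_length <- max(
      200, min(render$roughness_corr_length,
               render$image_width * render$pixel_size / 8))
  }
  if (as_transect) {
    return(render_transect(prof, render, seed = seed + 1L))
  }
  field <- make_interface_field(prof, render, seed = seed + 1L)
  if (dislocation_density > 0) {
    field <- insert_dislocations(field, dislocation_density,
                                 seed = seed + 2L)
  }
  render_micrograph(field, seed = seed + 3L)
}
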