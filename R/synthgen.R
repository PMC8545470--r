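#' Growth specification for the synthetic nacre stacker
#'
#' Parameters of the stochastic layer-stacking model. Tablet thicknesses are
#' generated as
#' \deqn{w_N = \max(\bar d + e_N + c_N, \mathrm{floor})}
#' where \eqn{c_N = \phi c_{N-1} + \epsilon_N} is a first-order
#' autoregressive "corrective growth" term (\eqn{\epsilon_N} i.i.d. Gaussian
#' with SD \code{sigma_local}; negative \code{phi} makes a thick tablet tend
#' to be followed by a thin one) and \eqn{e_N} is a long-range environmental
#' modulation synthesized in the frequency domain with power spectral density
#' proportional to \eqn{f^{-\alpha_{env}}}, rescaled to RMS \code{sigma_env}.
#'
#' @param n_layers number of tablets to generate (>= 1).
#' @param mean_thickness mean tablet thickness \eqn{\bar d} in nm.
#' @param sigma_local SD (nm) of the white innovation of the corrective term.
#' @param phi AR(1) corrective coefficient, in (-1, 1); negative values model
#'   corrective (compensating) growth.
#' @param sigma_env RMS amplitude (nm) of the environmental modulation.
#' @param alpha_env spectral exponent of the environmental modulation.
#' @param floor minimum admissible thickness (nm); thicknesses are clipped.
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return an object of class \code{growth_spec}.
#' @export
growth_spec <- function(n_layers,
                        mean_thickness = 340,
                        sigma_local = 100,
                        phi = -0.4,
                        sigma_env = 50,
                        alpha_env = 1.5,
                        floor = 50,
                        seed = 1L) {
  check_scalar(n_layers, "n_layers", lower = 1)
  check_scalar(mean_thickness, "mean_thickness", lower = 0)
  check_scalar(sigma_local, "sigma_local", lower = 0)
  check_scalar(phi, "phi", lower = -1 + 1e-9, upper = 1 - 1e-9)
  check_scalar(sigma_env, "sigma_env", lower = 0)
  check_scalar(alpha_env, "alpha_env", lower = 0, upper = 4)
  check_scalar(floor, "floor", lower = 0)
  check_scalar(seed, "seed")
  if (mean_thickness <= floor) {
    stop("parameter 'mean_thickness' must exceed 'floor'", call. = FALSE)
  }
  structure(list(n_layers = as.integer(n_layers),
                 mean_thickness = mean_thickness,
                 sigma_local = sigma_local,
                 phi = phi,
                 sigma_env = sigma_env,
                 alpha_env = alpha_env,
                 floor = floor,
                 seed = as.integer(seed)),
            class = "growth_spec")
}

#' Zero-mean Gaussian sequence with a power-law spectrum
#'
#' Frequency-domain synthesis: Fourier amplitudes proportional to
#' \eqn{f^{-\alpha/2}} with uniform random phases, inverse-transformed and
#' rescaled to the requested RMS. The amplitude profile is deterministic, so
#' the realized spectrum follows the target power law exactly in expectation.
#'
#' @param n length of the sequence.
#' @param alpha spectral exponent (power ~ f^-alpha).
#' @param rms root-mean-square amplitude of the output (exact, not expected).
#' @return numeric vector of length \code{n} with mean 0 and RMS \code{rms}.
#' @export
powerlaw_noise <- function(n, alpha, rms = 1) {
  n <- as.integer(n)
  if (n < 2L) return(rep(0, n))
  m <- n %/% 2L
  j <- seq_len(m)
  amp <- (j / n)^(-alpha / 2)
  ph <- stats::runif(m, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = rep(0, n))
  full[1 + j] <- spec
  # conjugate symmetry; Nyquist bin (if n even) must be real
  if (n %% 2L == 0L) full[1 + m] <- complex(real = amp[m], imaginary = 0)
  full[n + 1 - seq_len(n - m - 1L)] <- Conj(full[1 + seq_len(n - m - 1L)])
  e <- Re(stats::fft(full, inverse = TRUE)) / n
  e <- e - mean(e)
  s <- sqrt(mean(e^2))
  if (s > 0) e <- e * (rms / s)
  e
}

#' Generate a synthetic tablet-thickness profile
#'
#' Draws \code{n_layers} tablet thicknesses from the stacking model described
#' in \code{\link{growth_spec}}. Clipping events at the thickness floor are
#' counted in the \code{n_clipped} attribute.
#'
#' @param spec a \code{\link{growth_spec}}.
#' @return a \code{thickness_profile}: data frame with columns
#'   \code{layer} (1-based, chronological), \code{thickness} (nm) and
#'   \code{flag} (all \code{"ok"}), with the generating spec attached.
#' @export
make_thickness_profile <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_layers
    e <- if (spec$sigma_env > 0 && n >= 2) {
      powerlaw_noise(n, spec$alpha_env, spec$sigma_env)
    } else rep(0, n)
    c_term <- if (spec$sigma_local > 0) {
      eps <- stats::rnorm(n, sd = spec$sigma_local)
      if (spec$phi != 0) {
        as.numeric(stats::filter(eps, spec$phi, method = "recursive"))
      } else eps
    } else rep(0, n)
    w <- spec$mean_thickness + e + c_term
    n_clipped <- sum(w < spec$floor)
    w <- pmax(w, spec$floor)
    thickness_profile(w, spec = spec, n_clipped = n_clipped)
  })
}

#' Construct a thickness profile object
#'
#' @param thickness numeric vector of tablet thicknesses (nm), chronological
#'   (pearl center to edge), 1-based layer index.
#' @param flag per-layer flag, \code{"ok"} or \code{"merged_excluded"}.
#' @param spec optional generating \code{growth_spec} (ground truth).
#' @param n_clipped number of floor-clipping events during generation.
#' @return a data frame of class \code{thickness_profile}.
#' @export
thickness_profile <- function(thickness, flag = rep("ok", length(thickness)),
                              spec = NULL, n_clipped = NA_integer_) {
  stopifnot(is.numeric(thickness), all(is.finite(thickness)),
            all(thickness > 0), length(flag) == length(thickness))
  bad <- setdiff(unique(flag), c("ok", "merged_excluded"))
  if (length(bad)) {
    stop("unknown profile flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(layer = seq_along(thickness),
                    thickness = as.numeric(thickness),
                    flag = as.character(flag),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "n_clipped") <- n_clipped
  class(out) <- c("thickness_profile", "data.frame")
  out
}

#' @export
print.thickness_profile <- function(x, ...) {
  ok <- x$flag == "ok"
  cat(sprintf("<thickness_profile> %d layers, mean %.1f nm, SD %.1f nm, %d flagged\n",
              nrow(x), mean(x$thickness[ok]), stats::sd(x$thickness[ok]),
              sum(!ok)))
  invisible(x)
}

# Moments of Y = max(X, c) for X ~ N(mu, sigma^2) (clipped, not truncated).
clipped_normal_moments <- function(mu, sigma, c) {
  z <- (c - mu) / sigma
  Phi <- stats::pnorm(z)
  phi <- stats::dnorm(z)
  m1 <- mu + sigma * (phi + z * Phi)
  m2 <- c^2 * Phi + mu^2 * (1 - Phi) + 2 * mu * sigma * phi +
    sigma^2 * ((1 - Phi) + z * phi)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve for pre-clip (mu, sigma) such that the floored thickness
# distribution delivers the requested mean and SD.
calibrate_clipped <- function(target_mean, target_sd, floor) {
  obj <- function(p) {
    m <- clipped_normal_moments(p[1], exp(p[2]), floor)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Named growth-stage presets
#'
#' Stage presets deliver the observed stage statistics of nacre tablet
#' thickness: early nacre 500 +/- 300 nm, mature nacre 340 +/- 120 nm, and
#' \code{"full_pearl"}, a 2,615-layer profile with mature-stage statistics.
#' Because the generator clips thicknesses at the floor, the preset solves for
#' pre-clip parameters such that the delivered (post-clip) mean and SD equal
#' the stage values. The noise budget is split between the corrective AR term
#' and the f^-1.5 environmental modulation (environmental share about 17% of
#' the variance), with phi = -0.4.
#'
#' @param stage one of \code{"early"}, \code{"mature"}, \code{"full_pearl"}.
#' @param n_layers number of layers; defaults per stage (200 early, 500
#'   mature, 2615 full_pearl).
#' @param seed RNG seed.
#' @return a \code{\link{growth_spec}}.
#' @export
preset_growth <- function(stage = c("mature", "early", "full_pearl"),
                          n_layers = NULL, seed = 1L) {
  stage <- match.arg(stage)
  pars <- switch(stage,
    early = list(mean = 500, sd = 300, n = 200L),
    mature = list(mean = 340, sd = 120, n = 500L),
    full_pearl = list(mean = 340, sd = 120, n = 2615L))
  if (is.null(n_layers)) n_layers <- pars$n
  floor <- 50
  phi <- -0.4
  cal <- calibrate_clipped(pars$mean, pars$sd, floor)
  # variance split: environmental share ~1/6 of total, rest corrective AR
  env_var <- cal$sd^2 / 6
  ar_var <- cal$sd^2 - env_var
  growth_spec(n_layers = n_layers,
              mean_thickness = cal$mean,
              sigma_local = sqrt(ar_var * (1 - phi^2)),
              phi = phi,
              sigma_env = sqrt(env_var),
              alpha_env = 1.5,
              floor = floor,
              seed = seed)
}

#' Orientation presets for interface rendering
#'
#' Early nacre shows about +/-15 degrees of interface-orientation spread;
#' mature nacre about +/-5 degrees.
#'
#' @param stage \code{"early"} or \code{"mature"} (\code{"full_pearl"} uses
#'   mature orientation statistics).
#' @return orientation half-width in degrees.
#' @export
preset_orientation <- function(stage = c("mature", "early", "full_pearl")) {
  stage <- match.arg(stage)
  if (stage == "early") 15 else 5
}
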