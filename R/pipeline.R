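#' Default pipeline configuration
#'
#' Returns the full configuration list with all module parameters at their
#' defaults; override entries as needed and pass to
#' \code{\link{run_pipeline}}. The configuration round-trips losslessly
#' through YAML (\code{\link{write_config_yaml}}).
#'
#' @param input one of: \code{list(type = "simulate", stage, n_layers)},
#'   \code{list(type = "image", path, pixel_size)},
#'   \code{list(type = "profile", path)}.
#' @param seed master seed for all stochastic stages.
#' @param out_dir output directory for intermediate CSVs and the JSON
#'   report, or NULL to skip writing.
#' @return a config list.
#' @export
pipeline_config <- function(input = list(type = "simulate",
                                         stage = "mature",
                                         n_layers = NULL),
                            seed = 1L, out_dir = NULL) {
  list(input = input,
       seed = as.integer(seed),
       out_dir = out_dir,
       detect = list(n_transects = 9, sheath_width = 15),
       merged = list(tau = 1.8, window = 11),
       paircorr = list(bw = NULL, x_max = NULL, n_max = 10, r_star = 0.1),
       spectral = list(n_segments = 10, band = c(4e-4, 0.04),
                       f_threshold = 0.04),
       stages = list(windows = NULL),
       angular = list(annulus_frac = 0.3, bin_deg = 0.5),
       growth = list(days = NA_real_),
       defects = list(centers_csv = NULL, width_m = NA_real_,
                      height_m = NA_real_))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full nacre mesoscale-order pipeline
#'
#' Composes detection, growth statistics, pair-correlation / paracrystal
#' assessment, spectral analysis and (for image input) angular order into a
#' single report. Image-dependent results are marked not-computed for
#' profile-only input. Deterministic for a given (config, seed).
#'
#' @param config a config list from \code{\link{pipeline_config}}.
#' @return an \code{analysis_report} list; every numeric block names its
#'   units. Intermediate CSVs and \code{report.json} are written to
#'   \code{config$out_dir} when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  image <- NULL
  transect_in <- NULL
  pixel_size <- NA_real_
  truth <- NULL

  # ---- input stage -------------------------------------------------------
  profile <- run_stage("input", {
    inp <- config$input
    if (inp$type == "simulate") {
      # long simulated stacks are rendered as a single 1D transect; a 2D
      # micrograph at 3 nm/px would be needlessly large
      n_lay <- if (!is.null(inp$n_layers)) inp$n_layers
               else preset_growth(inp$stage)$n_layers
      as_tr <- isTRUE(inp$as_transect) || n_lay > 500
      sample <- simulate_nacre(stage = inp$stage,
                               n_layers = n_lay, seed = seed,
                               as_transect = as_tr)
      image <- sample$image
      transect_in <- sample$transect
      pixel_size <- sample$pixel_size
      truth <- sample$truth_profile
      NULL
    } else if (inp$type == "image") {
      image <- read_image(inp$path)
      pixel_size <- inp$pixel_size
      check_scalar(pixel_size, "pixel_size", lower = 1e-9)
      NULL
    } else if (inp$type == "profile") {
      read_profile_csv(inp$path)
    } else stop("unknown input type '", inp$type, "'")
  })

  # ---- detect stage ------------------------------------------------------
  interfaces <- NULL
  if (is.null(profile)) {
    profile <- run_stage("detect", {
      tr <- if (!is.null(transect_in)) transect_in
            else extract_transect(image, pixel_size)
      interfaces <- detect_sheaths(tr,
                                   sheath_width = config$detect$sheath_width)
      if (!is.null(out)) {
        write_interfaces_csv(interfaces, file.path(out, "interfaces.csv"))
      }
      thickness_from_interfaces(interfaces)
    })
  }
  profile <- run_stage("flag_merged", {
    flag_merged_layers(profile, tau = config$merged$tau,
                       window = config$merged$window)
  })
  if (!is.null(out)) write_profile_csv(profile, file.path(out, "profile.csv"))
  n <- nrow(profile)
  ok_th <- profile$thickness[profile$flag == "ok"]

  # ---- growth statistics -------------------------------------------------
  growthstats <- run_stage("growthstats", {
    devs <- rolling_deviation(profile)
    ac <- adjacent_correlation(devs)
    lag1 <- if (n >= 30) lag1_autocorrelation(profile) else NULL
    windows <- config$stages$windows
    if (is.null(windows)) {
      windows <- list(c(1, max(3, n %/% 4)), c(n - n %/% 2 + 1, n))
    }
    st <- stage_statistics(profile, windows,
                           labels = c("early", "mature")[seq_along(windows)])
    gr <- if (is.finite(config$growth$days)) {
      growth_rate(n, config$growth$days, mean(ok_th))
    } else NULL
    list(adjacent = ac, lag1 = lag1, stages = st, rate = gr)
  })

  # ---- pair correlation --------------------------------------------------
  paircorr <- run_stage("paircorr", {
    pc <- pair_correlation(profile, bw = config$paircorr$bw,
                           x_max = config$paircorr$x_max)
    pf <- fit_peaks(pc, n_max = config$paircorr$n_max)
    pa <- paracrystal_assessment(pf, r_star = config$paircorr$r_star,
                                 pc = pc)
    if (!is.null(out)) {
      utils::write.csv(data.frame(x_nm = pc$x, g = pc$g),
                       file.path(out, "paircorr.csv"), row.names = FALSE)
      utils::write.csv(cbind(pf$peaks, baseline = pf$baseline),
                       file.path(out, "peaks.csv"), row.names = FALSE)
    }
    list(correlogram = pc, fit = pf, assessment = pa)
  })

  # ---- spectral ----------------------------------------------------------
  spectral <- if (n >= 10 * config$spectral$n_segments) {
    run_stage("spectral", {
      se <- psd_profile(profile, n_segments = config$spectral$n_segments)
      # the power-law band needs segments long enough to resolve it
      pl <- if (se$segment_length >= 250) {
        fit_powerlaw(se, band = config$spectral$band)
      } else {
        list(alpha = NA_real_, alpha_stderr = NA_real_,
             band = config$spectral$band, n_bins = 0L)
      }
      fl <- detect_flattening(se, f_threshold = config$spectral$f_threshold)
      if (!is.null(out)) {
        utils::write.csv(data.frame(f = se$f, power = se$power),
                         file.path(out, "psd.csv"), row.names = FALSE)
      }
      list(estimate = se, powerlaw = pl, flattening = fl)
    })
  } else NULL

  # ---- morphology (image-dependent) --------------------------------------
  angular <- if (!is.null(image)) {
    run_stage("angular", {
      angular_spread(image, pixel_size,
                     annulus_frac = config$angular$annulus_frac,
                     bin_deg = config$angular$bin_deg)
    })
  } else NULL
  defects <- if (!is.null(config$defects$centers_csv)) {
    run_stage("defects", {
      cc <- utils::read.csv(config$defects$centers_csv)
      dm <- defect_map(cc$x_m, cc$y_m, cc$view,
                       config$defects$width_m, config$defects$height_m)
      defect_density(dm)
    })
  } else NULL

  report <- list(
    provenance = list(package = "nacremeso",
                      version = as.character(utils::packageVersion("nacremeso")),
                      seed = seed,
                      config = config[setdiff(names(config), "out_dir")]),
    profile = list(n_layers = n, n_flagged = sum(profile$flag != "ok"),
                   mean_thickness_nm = mean(ok_th),
                   sd_thickness_nm = stats::sd(ok_th),
                   units = "nm"),
    growth = list(
      adjacent_correlation = list(r = growthstats$adjacent$r,
                                  r2 = growthstats$adjacent$r2,
                                  p = growthstats$adjacent$p,
                                  n_pairs = growthstats$adjacent$n_pairs),
      lag1_autocorrelation = if (!is.null(growthstats$lag1))
        growthstats$lag1["r"] else "not computed",
      stages = growthstats$stages$stages,
      rate = if (!is.null(growthstats$rate)) {
        list(tablets_per_day = growthstats$rate$tablets_per_day,
             microns_per_day = growthstats$rate$microns_per_day)
      } else "not computed"),
    paircorr = list(
      sigma1_nm = paircorr$assessment$sigma1,
      beta = paircorr$assessment$beta,
      classification = paircorr$assessment$classification,
      correlation_length_layers = paircorr$assessment$correlation_length_layers,
      correlation_length_nm = paircorr$assessment$correlation_length_nm),
    spectral = if (!is.null(spectral)) {
      list(alpha = spectral$powerlaw$alpha,
           alpha_stderr = spectral$powerlaw$alpha_stderr,
           band_cycles_per_tablet = spectral$powerlaw$band,
           high_f_slope = spectral$flattening$slope,
           high_f_class = spectral$flattening$classification)
    } else "not computed",
    angular = if (!is.null(angular)) {
      list(half_width_deg = angular$half_width_deg,
           peak_azimuth_deg = angular$peak_azimuth_deg,
           criterion = angular$criterion)
    } else "not computed (profile-only input)",
    defects = if (!is.null(defects)) defects
              else "not computed (no centers supplied)")
  if (!is.null(truth)) {
    report$truth <- list(mean_thickness_nm = mean(truth$thickness),
                         sd_thickness_nm = stats::sd(truth$thickness))
  }
  class(report) <- "analysis_report"
  if (!is.null(out)) write_report_json(report, file.path(out, "report.json"))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  layers: %d (mean %.1f nm, SD %.1f nm)\n",
              x$profile$n_layers, x$profile$mean_thickness_nm,
              x$profile$sd_thickness_nm))
  cat(sprintf("  adjacent-deviation correlation r = %.3f\n",
              x$growth$adjacent_correlation$r))
  cat(sprintf("  paracrystal: sigma1 = %.3g nm, beta = %.2f (%s)\n",
              x$paircorr$sigma1_nm, x$paircorr$beta,
              x$paircorr$classification))
  if (is.list(x$spectral)) {
    cat(sprintf("  spectral alpha = %.2f (high-f: %s)\n",
                x$spectral$alpha, x$spectral$high_f_class))
  }
  if (is.list(x$angular)) {
    cat(sprintf("  angular half-width = %.2f deg\n",
                x$angular$half_width_deg))
  }
  invisible(x)
}
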