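#' Read a tablet-thickness profile from CSV
#'
#' Expected header: \code{layer_index, thickness_nm, flag} (flag optional;
#' 1-based chronological layer index, pearl center to edge).
#'
#' @param path CSV file path.
#' @return a \code{thickness_profile}.
#' @export
read_profile_csv <- function(path) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  need <- c("layer_index", "thickness_nm")
  if (!all(need %in% names(header))) {
    stop(sprintf("line 1 of '%s': missing header columns %s", path,
                 paste(setdiff(need, names(header)), collapse = ", ")),
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  bad <- which(!is.finite(df$thickness_nm) | df$thickness_nm <= 0)
  if (length(bad)) {
    stop(sprintf("malformed thickness at data line(s) %s of '%s'",
                 paste(utils::head(bad + 1L, 5), collapse = ", "), path),
         call. = FALSE)
  }
  o <- order(df$layer_index)
  flag <- if ("flag" %in% names(df)) as.character(df$flag[o])
          else rep("ok", nrow(df))
  thickness_profile(df$thickness_nm[o], flag)
}

#' Write a tablet-thickness profile to CSV
#'
#' @param profile a \code{thickness_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "thickness_profile"))
  utils::write.csv(data.frame(layer_index = profile$layer,
                              thickness_nm = profile$thickness,
                              flag = profile$flag),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected interfaces to CSV
#'
#' @param interfaces an \code{interface_set}.
#' @param path output path.
#' @param transect_id identifier recorded per row.
#' @return \code{path}, invisibly.
#' @export
write_interfaces_csv <- function(interfaces, path, transect_id = 1L) {
  utils::write.csv(data.frame(transect_id = transect_id,
                              N = seq_len(nrow(interfaces)),
                              position_nm = interfaces$position,
                              prominence = interfaces$prominence),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to grayscale. Intensities are returned
#' in [0, 1], rows = image rows.
#'
#' @param path image path (.tif/.tiff/.png).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image (16-bit TIFF or PNG)
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- pmin(pmax(image, 0), 1)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16),
    png = png::writePNG(image, path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param report a list (typically from \code{\link{run_pipeline}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      class(x) <- "data.frame"
      x
    } else if (is.list(x)) {
      lapply(unclass(x), strip)
    } else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

#' @rdname read_config_yaml
#' @param config config list.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
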