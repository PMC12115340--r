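## Image and configuration file I/O.

#' Read a PNG or JPEG image as an 8-bit RGB array
#'
#' Greyscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return H x W x 3 integer array with values in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    pg_config_error(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    pg_config_error(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(raw)) == 2L)
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L)
    raw <- raw[, , 1:3, drop = FALSE]
  img <- round_half_up(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param img H x W x 3 array with values in 0-255.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a binary mask as a black-and-white PNG
#'
#' @param mask logical matrix.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a segmentation configuration from JSON or YAML
#'
#' The file holds any subset of the [seg_config()] arguments; missing
#' entries take the package defaults. YAML support requires the `yaml`
#' package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a [seg_config()].
#' @export
read_seg_config <- function(path) {
  if (!file.exists(path))
    pg_config_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        pg_config_error("YAML configs require the 'yaml' package")
      yaml::read_yaml(path)
    },
    pg_config_error(sprintf("unsupported config format: .%s", ext))
  )
  known <- names(formals(seg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    pg_config_error(paste("unknown config fields:",
                          paste(unknown, collapse = ", ")))
  do.call(seg_config, vals)
}
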