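# Image and table I/O.
#
# Images travel as multi-page TIFF (one page per optical section; a 2D scene
# is a single page), stored 16-bit with the photon scale factor recorded in
# a JSON sidecar (<path>.json) so reads restore the photon scale exactly.
# Integer photon counts up to 65535 round-trip bit-identically. Tables are
# TSV with a header row, UTF-8, '.' decimal.

#' Write an image or z-stack as 16-bit multi-page TIFF
#'
#' @param data 2D matrix or 3D array `[section, row, col]`, non-negative.
#' @param path Output TIFF path; a sidecar `<path>.json` records the scale
#'   factor and any geometry supplied.
#' @param geometry Optional [zstack_geometry()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(data, path, geometry = NULL) {
  stopifnot(is.numeric(data), all(is.finite(data)), all(data >= 0))
  scale_factor <- max(65535, max(data))
  pages <- if (length(dim(data)) == 3L) {
    lapply(seq_len(dim(data)[1]), function(s) data[s, , ] / scale_factor)
  } else {
    list(as.matrix(data) / scale_factor)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(scale_factor = scale_factor,
               n_pages = length(pages),
               dim = dim(data))
  if (!is.null(geometry)) meta$geometry <- unclass(geometry)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image or z-stack written by [write_image_stack()]
#'
#' @param path TIFF path. Geometry and photon scale are taken from the JSON
#'   sidecar when present (never guessed); without a sidecar, raw `[0, 1]`
#'   TIFF values are returned.
#' @return List with `data` (matrix for one page, array `[section, row,
#'   col]` otherwise) and `metadata`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) {
    fishda_stop(sprintf("no such file: %s", path), "fishda_error_io")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      fishda_stop(sprintf("not a readable TIFF: %s", path),
                                  "fishda_error_io")
                    })
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    fishda_stop("TIFF pages have inconsistent shapes", "fishda_error_io")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(scale_factor = 1)
  }
  scale <- meta$scale_factor
  if (length(pages) == 1L) {
    data <- pages[[1]] * scale
  } else {
    d <- dim(pages[[1]])
    data <- array(0, dim = c(length(pages), d[1], d[2]))
    for (s in seq_along(pages)) data[s, , ] <- pages[[s]] * scale
  }
  list(data = data, metadata = meta)
}

#' Write a table as TSV (header, UTF-8, '.' decimal)
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
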