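# Plain-text I/O helpers: TSV tables, binary masks, JSON truth sidecars.

#' Write a data frame as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a binary mask image
#'
#' Reads a single-page TIFF or PNG and binarizes it at 0.5 of the normalized
#' intensity range.
#'
#' @param path Path to the image.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_classed("io_error", "no such file: %s", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img >= 0.5
}

#' Write a binary mask image
#' @param mask Logical matrix.
#' @param path Output path (`.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#'
#' Serializes a `sim_truth` object (dropping bulky masks) next to a synthetic
#' dataset as `<name>.truth.json`.
#'
#' @param truth A `sim_truth` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  slim <- unclass(truth)
  slim$myotube_masks <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
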