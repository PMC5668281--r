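#' Write / read a field as 16-bit grayscale TIFFs
#'
#' One file per channel, named `{plate}_{well}_f{field}_{channel}.tif`.
#' Pixel values are integer camera counts in `[0, 65535]`; the round trip is
#' lossless, so staged (on-disk) and in-memory pipeline runs are
#' bit-identical.
#'
#' @param field A `field_image` object.
#' @param dir Output directory.
#' @param plate_id Plate identifier used in the file names.
#' @return `write_field_tiffs()`: character vector of files written,
#'   invisibly. `read_field_tiffs()`: a `field_image` object.
#' @export
write_field_tiffs <- function(field, dir, plate_id) {
  paths <- character(0)
  for (ch in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s_f%d_%s.tif", plate_id,
                                field$well_id, field$field_index, ch))
    tiff::writeTIFF(field$channels[[ch]] / 65535, p, bits.per.sample = 16L,
                    compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_tiffs
#' @param well_id,field_index Field coordinates to read.
#' @param channels Channel names to load.
#' @param pixel_size_um Pixel size recorded in the returned object.
#' @export
read_field_tiffs <- function(dir, plate_id, well_id, field_index,
                             channels = c("nuclear_dye", "cyto_dye",
                                          "reporter"),
                             pixel_size_um = 0.65) {
  img <- list()
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_%s_f%d_%s.tif", plate_id, well_id,
                                field_index, ch))
    if (!file.exists(p)) stop("missing channel file: ", p)
    img[[ch]] <- round(tiff::readTIFF(p) * 65535)
  }
  structure(list(channels = img, pixel_size_um = pixel_size_um,
                 well_id = well_id, field_index = as.integer(field_index),
                 rng_seed = NA_integer_),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<field_image> well", x$well_id, "field", x$field_index, "-",
      d[1], "x", d[2], "px,", length(x$channels), "channel(s):",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}
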