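#' Measure polarity from image and mask files
#'
#' File-path front end to [measure_polarity()]: reads a two-channel TIFF
#' (as written by [write_image_tiff()]) and a label-mask TIFF and returns
#' the POME table.
#'
#' @param image_path Path to the two-channel image TIFF.
#' @param mask_path Path to the label-mask TIFF.
#' @param ... Passed to [measure_polarity()].
#' @return A POME table data frame.
#' @export
measure_image_files <- function(image_path, mask_path, ...) {
  if (!file.exists(image_path)) {
    stop("image file not found: ", image_path)
  }
  if (!file.exists(mask_path)) {
    stop("mask file not found: ", mask_path)
  }
  measure_polarity(read_image_tiff(image_path), read_mask_tiff(mask_path),
                   ...)
}
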