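# TIFF I/O for z-stacks (multi-page 8-bit grayscale) and integer cell
# masks (single-page 16-bit). The in-memory representation keeps the
# 8-bit intensity scale [0, 255] that the PLA thresholds refer to.

#' Read a z-stack from a multi-page grayscale TIFF
#' @param path TIFF path
#' @return list of numeric matrices with intensities on the 8-bit
#'   scale, one per z plane
#' @export
read_zstack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # drop extra channels
    round(pg * 255)
  })
}

#' Write a z-stack as a multi-page 8-bit grayscale TIFF
#' @param stack list of numeric matrices with values in [0, 255]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_zstack <- function(stack, path) {
  stopifnot(is.list(stack))
  tiff::writeTIFF(lapply(stack, function(pl) {
    stopifnot(all(pl >= 0), all(pl <= 255))
    pl / 255
  }), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an integer cell-label mask from a single-page TIFF
#' @param path TIFF path (16-bit grayscale; pixel value = cell id,
#'   0 = background)
#' @return integer matrix
#' @export
read_cell_mask <- function(path) {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
  m <- round(pg * 65535)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Write an integer cell-label mask as a 16-bit TIFF
#' @param mask integer matrix (0 = background, k > 0 = cell k)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cell_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 65535))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
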