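#' Write and read spectral volumes as raw binary plus JSON sidecar
#'
#' The interferogram array is stored as little-endian doubles in
#' `<prefix>.bin`; `<prefix>.json` records the dimensions, the wavenumber
#' grid and the generating parameters.
#'
#' @param vol a `spectral_volume`.
#' @param prefix path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_spectral_volume <- function(vol, prefix) {
  stopifnot(inherits(vol, "spectral_volume"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  meta <- vol$meta
  if (inherits(meta, "phantom_spec")) meta <- unclass(meta)
  jsonlite::write_json(list(dim = dim(vol$data), k_grid = vol$k_grid,
                            meta = meta),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_spectral_volume
#' @export
read_spectral_volume <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(side$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  data <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  dim(data) <- side$dim
  structure(list(data = data, k_grid = side$k_grid, meta = side$meta),
            class = "spectral_volume")
}

#' Write an angiogram as 16-bit grayscale TIFF
#'
#' Values are clipped to \[0,1\] (display-normalise first if needed).
#'
#' @param ang an `angiogram` or numeric matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_angiogram_tiff <- function(ang, path) {
  img <- if (inherits(ang, "angiogram")) ang$data else ang
  img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a grayscale angiogram image (TIFF or PNG)
#'
#' @param path input file.
#' @param pixel_pitch_mm lateral pitch to record.
#' @return an `angiogram`.
#' @export
read_angiogram <- function(path, pixel_pitch_mm = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                "tif" = , "tiff" = tiff::readTIFF(path),
                "png" = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  new_angiogram(img, pixel_pitch_mm, slab = "external", method = "external")
}

#' Write a binary mask as PNG
#'
#' @param mask logical or 0/1 matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}
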