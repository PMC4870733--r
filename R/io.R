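# Slice-image file I/O: 16-bit TIFF with a JSON sidecar describing the
# physical geometry (pixel size, slab thickness, plane placement, seed).

#' Write a slice image with its JSON sidecar
#'
#' The image is clipped to \[0, 1\] and stored as 16-bit grayscale TIFF; the
#' sidecar `<path>.json` records the `slice_spec` geometry so a reader can
#' reconstruct the physical mapping.
#' @param image numeric matrix from [render_slice()].
#' @param spec the `slice_spec` used to render it.
#' @param path TIFF output path.
#' @param seed seed recorded in the sidecar (provenance only).
#' @export
write_slice_image <- function(image, spec, path, seed = NULL) {
  img <- pmax(pmin(image, 1), 0)
  tiff::writeTIFF(img, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(pixel_size_mm = spec$pixel_size,
                  thickness_mm = spec$thickness,
                  matrix = spec$matrix,
                  origin = spec$origin, normal = spec$normal,
                  eu = spec$eu, ev = spec$ev,
                  noise_sigma = spec$noise_sigma,
                  blur_fwhm = spec$blur_fwhm,
                  n_depth = spec$n_depth,
                  seed = seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a slice image and its sidecar
#' @param path TIFF path written by [write_slice_image()].
#' @return list with `image` (matrix) and `spec` (`slice_spec`).
#' @export
read_slice_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- slice_spec(pixel_size = sc$pixel_size_mm, thickness = sc$thickness_mm,
                     matrix = sc$matrix, origin = sc$origin, normal = sc$normal,
                     eu = sc$eu, ev = sc$ev, noise_sigma = sc$noise_sigma,
                     blur_fwhm = sc$blur_fwhm, n_depth = sc$n_depth)
  list(image = img, spec = spec)
}
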