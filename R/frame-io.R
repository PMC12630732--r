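# Frame import/export as single-page 16-bit grayscale TIFF with a YAML
# sidecar carrying the pixel size and timestamp.

#' Write a frame as 16-bit grayscale TIFF
#'
#' Intensities are rounded and clipped to the 16-bit range. A YAML sidecar
#' (`<path>.yaml`) stores the pixel size (nm/px) and the timestamp.
#'
#' @param fr a [frame()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(fr, path) {
  stopifnot(inherits(fr, "vm_frame"))
  px <- pmin(pmax(round(fr$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  yaml::write_yaml(list(pixel_size_nm = fr$pixel_size,
                        timestamp_s = fr$timestamp),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame from a 16-bit grayscale TIFF
#'
#' @param path TIFF path; the YAML sidecar written by [write_frame_tiff()]
#'   is read when present.
#' @param pixel_size fallback nm/px when no sidecar exists.
#' @return a [frame()].
#' @export
read_frame_tiff <- function(path, pixel_size = 80) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  meta <- list(pixel_size_nm = pixel_size, timestamp_s = 0)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- utils::modifyList(meta, yaml::read_yaml(sidecar))
  frame(round(px * 65535), timestamp = meta$timestamp_s,
        pixel_size = meta$pixel_size_nm)
}
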