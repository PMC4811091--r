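# Reading and writing grey-scale images (8-bit PNG, NIfTI-1 slices).

guessFormat <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return("png")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("cannot guess image format from '", path, "'; pass format=", call. = FALSE)
}

#' Read a grey-scale image
#'
#' PNG images are mapped to the [0, 255] display range; multi-channel inputs
#' are collapsed by averaging the color channels (an alpha channel, if
#' present, is ignored). NIfTI volumes require an explicit \code{slice} index
#' when 3-D, and are rescaled to span [0, 255].
#'
#' @param path file to read.
#' @param format \code{"auto"} (from extension), \code{"png"} or
#'   \code{"nifti"}.
#' @param slice integer slice index for 3-D NIfTI volumes.
#' @return numeric matrix in [0, 255].
#' @export
readImage <- function(path, format = c("auto", "png", "nifti"), slice = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      nc <- dim(a)[3L]
      ch <- min(nc, 3L)           # drop alpha
      a <- apply(a[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
    }
    return(a * 255)
  }
  v <- RNifti::readNifti(path)
  v <- as.array(v)
  if (length(dim(v)) == 3L) {
    if (is.null(slice))
      stop("3-D NIfTI input requires an explicit 'slice' index", call. = FALSE)
    v <- v[, , slice]
  } else if (length(dim(v)) != 2L) {
    stop("only 2-D images or 3-D volumes with a slice index are supported",
         call. = FALSE)
  }
  rng <- range(v)
  if (rng[2L] > rng[1L]) v <- (v - rng[1L]) / (rng[2L] - rng[1L]) * 255
  matrix(as.numeric(v), nrow(v), ncol(v))
}

#' Write a grey-scale image
#'
#' Values are clipped to [0, 255] and, for PNG, quantized to 8 bits, so a
#' write/read round trip is the identity up to half a gray level.
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param format \code{"auto"}, \code{"png"} or \code{"nifti"}.
#' @return invisibly, the path written.
#' @export
writeImage <- function(image, path, format = c("auto", "png", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (is.logical(image)) image <- image * 255
  img <- clip255(image)
  if (format == "png") {
    png::writePNG(round(img) / 255, target = path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(round(img)), path)
  }
  invisible(path)
}
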