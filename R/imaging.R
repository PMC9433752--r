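# Images are plain base-R arrays of 8-bit intensities stored as numerics:
#   color image: H x W x 3 array, values in [0, 255]
#   gray image / binary mask: H x W matrix, values in [0, 255]
# Pixels are addressed row-major with origin at top-left; boxes are 0-based
# half-open [x0, x1) x [y0, y1) with x = column, y = row, so pixel (x, y)
# lives at m[y + 1, x + 1].

stop_sv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_color_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_sv("expected an H x W x 3 color image array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop_sv("image has degenerate dimensions %d x %d", dim(img)[2], dim(img)[1])
  invisible(img)
}

assert_gray_image <- function(img) {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop_sv("expected an H x W grayscale matrix")
  invisible(img)
}

#' Load an image file as an 8-bit color array
#'
#' Reads a PNG, JPEG or TIFF file and returns an H x W x 3 array of
#' intensities in \code{[0, 255]}. Grayscale files are replicated across the
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG (.png), JPEG (.jpg/.jpeg) or TIFF (.tif/.tiff)
#'   file.
#' @return An H x W x 3 numeric array with values in \code{[0, 255]}.
#' @seealso [save_image()], [to_grayscale()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_sv("path must be a single file path")
  if (!file.exists(path))
    stop_sv("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png  = png::readPNG,
    jpg  = ,
    jpeg = jpeg::readJPEG,
    tif  = ,
    tiff = tiff::readTIFF,
    stop_sv("unsupported image format '.%s' (need png, jpeg or tiff)", ext))
  raw <- tryCatch(reader(path),
    error = function(e) stop_sv("cannot decode %s: %s", path, conditionMessage(e)))
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3] >= 3L) {
    img <- raw[, , 1:3, drop = FALSE]
  } else {
    img <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  }
  round(img * 255)
}

#' Write a color or gray image to a PNG file
#'
#' @param img H x W x 3 array or H x W matrix with values in \code{[0, 255]}.
#' @param path Output path; written as PNG regardless of extension.
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path) {
  v <- pmin(pmax(img / 255, 0), 1)
  png::writePNG(v, target = path)
  invisible(path)
}

#' Convert a color image to 8-bit grayscale
#'
#' Uses the BT.601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded
#' half-up to the nearest integer. Already-gray input (r = g = b = v) maps
#' to v exactly, so the conversion is idempotent on gray content.
#'
#' @param img H x W x 3 color array with values in \code{[0, 255]}.
#' @return H x W matrix of integers in \code{[0, 255]}.
#' @export
to_grayscale <- function(img) {
  assert_color_image(img)
  luma <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  floor(luma + 0.5)
}

# Separable bilinear resampling with half-pixel-centred coordinates:
# destination pixel centre j + 0.5 maps to source coordinate
# (j + 0.5) * scale - 0.5. When downscaling, the triangular kernel is
# widened by the scale factor (antialiasing), so each output pixel averages
# its full source footprint instead of point-sampling it — the behavior of
# current deep-learning preprocessing stacks, and essential here because
# point-sampled bilinear turns thin strands into aliased dashes. Weights
# are renormalized at the edges and always sum to one, so constant images
# are fixed points.
resample_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  support <- max(1, scale)
  W <- matrix(0, n_dst, n_src)
  for (j in seq_len(n_dst)) {
    center <- (j - 0.5) * scale - 0.5
    lo <- max(0, floor(center - support))
    hi <- min(n_src - 1, ceiling(center + support))
    ii <- lo:hi
    wts <- pmax(0, 1 - abs(ii - center) / support)
    if (sum(wts) == 0) {
      ii <- min(max(round(center), 0), n_src - 1)
      wts <- 1
    }
    W[j, ii + 1] <- wts / sum(wts)
  }
  W
}

#' Bilinear resize of a gray matrix or color array
#'
#' Half-pixel-centred separable bilinear resampling; when downscaling, the
#' kernel support is widened by the scale factor (antialiasing) so the
#' output averages the source footprint.
#'
#' @param img H x W matrix or H x W x 3 array.
#' @param height,width Output dimensions in pixels.
#' @return Resized image of the same kind as the input.
#' @export
resize_bilinear <- function(img, height, width) {
  if (height < 1 || width < 1) stop_sv("output dimensions must be >= 1")
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L) stop_sv("input image has degenerate dimensions")
  Wy <- resample_weights(d[1], height)
  Wx <- resample_weights(d[2], width)
  resize_plane <- function(m) Wy %*% m %*% t(Wx)
  if (is.matrix(img)) return(resize_plane(img))
  out <- array(0, c(height, width, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- resize_plane(img[, , c])
  out
}

#' Resize to the network input size and normalize
#'
#' Bilinearly resamples a color image to \code{side} x \code{side} pixels and
#' applies the per-channel standardization (v/255 - 0.5)/0.5, so constant
#' white maps to 1 and constant black to -1; all outputs lie in
#' \code{[-1, 1]}.
#'
#' @param img H x W x 3 color array with values in \code{[0, 255]}.
#' @param side Output side length in pixels (default 224).
#' @return \code{side} x \code{side} x 3 numeric array in \code{[-1, 1]}.
#' @export
resize_normalize <- function(img, side = 224L) {
  assert_color_image(img)
  out <- resize_bilinear(img, side, side)
  (out / 255 - 0.5) / 0.5
}
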