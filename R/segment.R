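# Contour screening and square-ROI cropping. After binarization the shred
# should survive as one large connected component; tiny residue components
# are flagged, the largest contour is kept, its bounding box is squared so
# the later resize does not distort the shred's aspect ratio, and the crop
# is padded with white where the square overhangs the frame.

#' Connected foreground components of a binary mask
#'
#' Breadth-first labeling of foreground (nonzero) pixels under 4- or
#' 8-connectivity. 8-connectivity is the default: thin diagonal strands
#' fragment under 4-connectivity.
#'
#' @param mask Binary matrix (0 background, nonzero foreground).
#' @param connectivity 4 or 8.
#' @return List of components sorted by decreasing area (ties: smaller
#'   (row, col) bounding-box origin first). Each component is a list with
#'   `pixels` (1-based linear indices into the mask), `area`, and `bbox`,
#'   a 0-based half-open box `c(x0, x1, y0, y1)`.
#' @export
extract_components <- function(mask, connectivity = 8L) {
  assert_gray_image(mask)
  if (!connectivity %in% c(4L, 8L)) stop_sv("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  labels <- matrix(0L, h, w)
  comps <- list()
  todo <- which(fg)
  if (length(todo) == 0L) return(list())
  # neighbor column-offsets and the row-shift each implies (guards row wrap)
  if (connectivity == 4L) {
    offs <- c(-1L, 1L, -h, h); dr <- c(-1L, 1L, 0L, 0L)
  } else {
    offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
    dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  }
  n_px <- h * w
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    pixels <- seed
    while (length(frontier) > 0L) {
      rows <- ((frontier - 1L) %% h) + 1L
      nxt <- integer(0)
      for (k in seq_along(offs)) {
        cand <- frontier + offs[k]
        ok <- cand >= 1L & cand <= n_px
        if (dr[k] == -1L) ok <- ok & rows > 1L
        if (dr[k] == 1L) ok <- ok & rows < h
        cand <- cand[ok]
        cand <- cand[fg[cand] & labels[cand] == 0L]
        if (length(cand)) {
          labels[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      nxt <- unique(nxt)
      pixels <- c(pixels, nxt)
      frontier <- nxt
    }
    rows <- ((pixels - 1L) %% h) + 1L
    cols <- ((pixels - 1L) %/% h) + 1L
    comps[[lab]] <- list(pixels = sort(pixels), area = length(pixels),
                         bbox = c(min(cols) - 1L, max(cols), min(rows) - 1L, max(rows)))
  }
  ord <- order(-vapply(comps, `[[`, numeric(1), "area"),
               vapply(comps, function(c) c$bbox[3], numeric(1)),
               vapply(comps, function(c) c$bbox[1], numeric(1)))
  comps[ord]
}

#' Select the shred contour and flag residues
#'
#' Keeps the largest-area component; components smaller than
#' `min_area_frac` times the largest are classified as sieved residue.
#'
#' @param components Nonempty component list from [extract_components()].
#' @param min_area_frac Residue cut-off as a fraction of the largest area
#'   (default 0.05).
#' @return List with `main` (the selected component), `residues` (list of
#'   residue components) and `retained` (non-residue components other than
#'   the main one, which indicate a broken shred).
#' @export
screen_contours <- function(components, min_area_frac = 0.05) {
  if (length(components) == 0L) stop_sv("no foreground components to screen")
  main <- components[[1L]]
  rest <- components[-1L]
  areas <- vapply(rest, `[[`, numeric(1), "area")
  is_res <- areas < min_area_frac * main$area
  list(main = main, residues = rest[is_res], retained = rest[!is_res])
}

#' Square ROI around a bounding box
#'
#' Grows the box by `margin` on all sides, then expands the shorter
#' dimension symmetrically about the box center until the box is square.
#' If the square overhangs a frame edge it is translated inward; if the
#' side exceeds the frame it is kept as-is and the crop pads with white.
#'
#' @param bbox 0-based half-open box `c(x0, x1, y0, y1)` with positive area.
#' @param img_w,img_h Frame dimensions in pixels.
#' @param margin Pixels of margin added before squaring (default 0).
#' @return 0-based half-open square box `c(x0, x1, y0, y1)`.
#' @export
square_roi <- function(bbox, img_w, img_h, margin = 0L) {
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop_sv("degenerate bounding box")
  x0 <- bbox[1] - margin; x1 <- bbox[2] + margin
  y0 <- bbox[3] - margin; y1 <- bbox[4] + margin
  side <- max(x1 - x0, y1 - y0)
  fit_axis <- function(lo, hi, limit) {
    extra <- side - (hi - lo)
    lo <- lo - floor(extra / 2)
    hi <- lo + side
    if (side <= limit) {         # translate inward if it overhangs
      if (lo < 0) { hi <- hi - lo; lo <- 0 }
      if (hi > limit) { lo <- lo - (hi - limit); hi <- limit }
    }
    c(lo, hi)
  }
  xs <- fit_axis(x0, x1, img_w)
  ys <- fit_axis(y0, y1, img_h)
  as.integer(c(xs[1], xs[2], ys[1], ys[2]))
}

#' Crop a square ROI, padding out-of-bounds regions with white
#'
#' @param img H x W x 3 color array (or H x W gray matrix).
#' @param roi Square 0-based half-open box from [square_roi()].
#' @return Square image of side `roi[2] - roi[1]`; regions outside the
#'   frame are filled with white (255).
#' @export
crop_roi <- function(img, roi) {
  side <- roi[2] - roi[1]
  if (side != roi[4] - roi[3] || side < 1) stop_sv("roi must be a square box")
  gray <- is.matrix(img)
  h <- nrow(img); w <- ncol(img)
  out <- if (gray) matrix(255, side, side) else array(255, c(side, side, dim(img)[3]))
  sx0 <- max(roi[1], 0L); sx1 <- min(roi[2], w)
  sy0 <- max(roi[3], 0L); sy1 <- min(roi[4], h)
  if (sx1 > sx0 && sy1 > sy0) {
    dy <- (sy0 - roi[3] + 1L):(sy1 - roi[3])
    dx <- (sx0 - roi[1] + 1L):(sx1 - roi[1])
    if (gray) {
      out[dy, dx] <- img[(sy0 + 1L):sy1, (sx0 + 1L):sx1]
    } else {
      out[dy, dx, ] <- img[(sy0 + 1L):sy1, (sx0 + 1L):sx1, , drop = FALSE]
    }
  }
  out
}

#' Did the shred survive binarization as one complete contour?
#'
#' Operationalizes the "complete sample" criterion used to score
#' binarizers: the largest mask component must cover at least `cover` of
#' the ground-truth foreground, and no other retained (non-residue)
#' component may overlap the truth — i.e., the shred is neither eroded nor
#' broken into pieces.
#'
#' @param mask Binary mask produced by a binarizer.
#' @param truth Ground-truth binary mask of the same dimensions.
#' @param cover Required coverage fraction of the truth foreground
#'   (default 0.95).
#' @param min_area_frac Residue cut-off passed to [screen_contours()].
#' @return Logical scalar.
#' @export
is_complete <- function(mask, truth, cover = 0.95, min_area_frac = 0.05) {
  if (!all(dim(mask) == dim(truth))) stop_sv("mask and truth dimensions differ")
  truth_px <- which(truth != 0)
  if (length(truth_px) == 0L) stop_sv("truth mask has no foreground")
  comps <- extract_components(mask, 8L)
  if (length(comps) == 0L) return(FALSE)
  scr <- screen_contours(comps, min_area_frac)
  covered <- length(intersect(scr$main$pixels, truth_px)) / length(truth_px)
  if (covered < cover) return(FALSE)
  for (comp in scr$retained)
    if (length(intersect(comp$pixels, truth_px)) > 0L) return(FALSE)
  TRUE
}
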