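# Super-resolution summed images and fibril segmentation.
#
# Summing all sub-pixel localizations into a zoomed 2-D histogram traces
# the fibrils far more sharply than any raw frame; thresholding that image
# yields a fibril mask used to split events into on-fibril vs background.
# The mask can also be supplied by the user to reproduce hand-drawn masks.

#' Build a super-resolution summed image
#'
#' 2-D histogram of all localizations on a grid upsampled by `zoom`
#' (default 5, i.e. 44 nm bins at 220 nm pixels). A localization at
#' `(x, y)` lands in SR bin `(floor(x * zoom), floor(y * zoom))`.
#'
#' @param localizations Data frame with `x_px`, `y_px`.
#' @param zoom Integer zoom factor >= 1.
#' @param shape_px `c(height, width)` of the original field in pixels.
#' @return An object of class `sr_image`: list with `counts` (integer
#'   matrix, rows = y), `zoom`, and `n_outside`, the number of
#'   localizations falling outside the field (reported, not binned).
#' @export
build_sr_image <- function(localizations, zoom = 5L, shape_px) {
  if (zoom < 1) stop("`zoom` must be >= 1", call. = FALSE)
  m <- sr_histogram(localizations$x_px, localizations$y_px, zoom, shape_px)
  n_out <- nrow(localizations) - sum(m)
  structure(list(counts = m, zoom = as.integer(zoom), n_outside = n_out),
            class = "sr_image")
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("sr_image: %d x %d SR bins (zoom %d), %d localizations (%d outside field)\n",
              nrow(x$counts), ncol(x$counts), x$zoom, sum(x$counts), x$n_outside))
  invisible(x)
}

#' Segment fibrils from a super-resolution image
#'
#' Gaussian blur, threshold (Otsu on the blurred nonzero support, or a
#' quantile), removal of components smaller than `min_area_px`, then
#' morphological dilation by `dilation_px` to capture localization scatter
#' around the fibril backbone.
#'
#' @param sr An [build_sr_image()] result.
#' @param blur_sigma Blur sd in SR pixels.
#' @param threshold `"otsu"` or `"percentile"`.
#' @param percentile Quantile used when `threshold = "percentile"`.
#' @param dilation_px Dilation radius in SR pixels.
#' @param min_area_px Minimum component area (SR pixels) kept, applied
#'   before dilation.
#' @return A logical matrix of class `fibril_mask` on the SR grid with
#'   attributes `zoom` and `provenance = "auto"`. Warns when the mask
#'   covers more than half the field (likely bad threshold).
#' @export
segment_fibrils <- function(sr, blur_sigma = 2, threshold = c("otsu", "percentile"),
                            percentile = 0.995, dilation_px = 2L, min_area_px = 20L) {
  threshold <- match.arg(threshold)
  cnt <- sr$counts
  if (!any(cnt > 0)) return(new_fibril_mask(cnt > 0, sr$zoom, "auto"))
  bl <- as.matrix(EBImage::gblur(cnt / max(cnt), sigma = blur_sigma))
  thr <- if (threshold == "otsu") {
    EBImage::otsu(EBImage::Image(pmin(pmax(bl, 0), 1)))
  } else {
    stats::quantile(bl, percentile, names = FALSE)
  }
  mask <- bl > thr
  if (any(mask) && min_area_px > 0) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
    areas <- table(lab[lab > 0])
    small <- as.integer(names(areas)[areas < min_area_px])
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  if (any(mask) && dilation_px > 0) {
    mask <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                            EBImage::makeBrush(2L * as.integer(dilation_px) + 1L,
                                               shape = "disc")) > 0
  }
  if (mean(mask) > 0.5)
    warning("fibril mask covers > 50% of the field; check threshold settings")
  new_fibril_mask(mask, sr$zoom, "auto")
}

new_fibril_mask <- function(mask, zoom, provenance) {
  structure(mask, zoom = as.integer(zoom), provenance = provenance,
            class = c("fibril_mask", class(mask)))
}

#' Use a user-supplied binary mask
#'
#' Wraps a hand-drawn (or otherwise external) binary mask on the SR grid so
#' it can be used in place of the automatic segmentation, mirroring the
#' manual mask-drawing workflow.
#'
#' @param mask Logical (or 0/1) matrix on the SR grid.
#' @param zoom The SR zoom factor the mask was drawn at.
#' @return A `fibril_mask` with `provenance = "user"`.
#' @export
user_fibril_mask <- function(mask, zoom = 5L) {
  new_fibril_mask(mask > 0, zoom, "user")
}

#' Classify events as on-fibril vs background
#'
#' An event is `fibril` when its mean position falls inside the mask, and
#' `background` when it falls outside the mask dilated by `margin_px`
#' (SR pixels); positions in the buffer zone between the two are labeled
#' `unassigned` and excluded from both region analyses, so fibril-adjacent
#' molecules cannot contaminate the background class.
#'
#' @param events Event data frame with `mean_x_px`, `mean_y_px` (pixel units).
#' @param mask A `fibril_mask` (carries its `zoom`).
#' @param margin_px Buffer width in SR pixels (default 2).
#' @return `events` with the `region` column filled in.
#' @export
classify_events <- function(events, mask, margin_px = 2L) {
  if (!nrow(events)) return(events)
  zoom <- attr(mask, "zoom")
  buffer <- if (any(mask) && margin_px > 0) {
    EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                    EBImage::makeBrush(2L * as.integer(margin_px) + 1L,
                                       shape = "disc")) > 0
  } else mask
  h <- nrow(mask); w <- ncol(mask)
  ix <- floor(events$mean_x_px * zoom)
  iy <- floor(events$mean_y_px * zoom)
  inside <- ix >= 0 & ix < w & iy >= 0 & iy < h
  region <- rep("background", nrow(events))
  idx <- cbind(pmin(pmax(iy, 0), h - 1L) + 1L, pmin(pmax(ix, 0), w - 1L) + 1L)
  on_mask <- inside & mask[idx]
  on_buffer <- inside & buffer[idx]
  region[on_buffer & !on_mask] <- "unassigned"
  region[on_mask] <- "fibril"
  events$region <- region
  events
}

#' Write a mask or SR image as an 8-bit image file
#'
#' Masks are written as binary 8-bit TIFF/PNG; SR images are scaled to
#' their maximum count.
#'
#' @param x A `fibril_mask` or `sr_image`.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(x, path) {
  m <- if (inherits(x, "sr_image")) x$counts / max(max(x$counts), 1) else
    matrix(as.numeric(x), nrow(x))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(path)
}
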