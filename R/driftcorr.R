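# Lateral stage-drift estimation from the localization table itself
# (no fiducial markers): localizations are split into temporal blocks,
# each block is rendered as a super-resolution 2-D histogram, and every
# block is registered against block 0 by sub-pixel phase cross-correlation.
# Registering all blocks to the first (rather than chaining consecutive
# pairs) avoids error accumulation over a few-thousand-frame stack.

# 2-D histogram of localizations on a zoomed grid (rows = y, cols = x).
sr_histogram <- function(x, y, zoom, shape_px) {
  h <- shape_px[1] * zoom; w <- shape_px[2] * zoom
  ix <- floor(x * zoom); iy <- floor(y * zoom)
  ok <- ix >= 0 & ix < w & iy >= 0 & iy < h
  m <- matrix(0L, h, w)
  if (any(ok)) {
    idx <- iy[ok] * w + ix[ok]  # row-major key
    tb <- table(idx)
    key <- as.integer(names(tb))
    m[cbind(key %/% w + 1L, key %% w + 1L)] <- as.integer(tb)
  }
  m
}

# Sub-pixel shift of image b relative to image a (units: histogram bins),
# by FFT cross-correlation with 3-point parabolic peak interpolation.
# Histograms are Gaussian-smoothed first: localization scatter is often
# well below one SR bin, and correlating near-delta peaks locks the
# parabolic interpolation onto bin centers.
xcorr_shift <- function(a, b, blur_sigma = 1) {
  if (blur_sigma > 0) {
    a <- as.matrix(EBImage::gblur(a, sigma = blur_sigma))
    b <- as.matrix(EBImage::gblur(b, sigma = blur_sigma))
  }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cc <- Re(stats::fft(Conj(Fa) * Fb, inverse = TRUE))
  pk <- which.max(cc)
  h <- nrow(cc); w <- ncol(cc)
  pr <- (pk - 1L) %% h + 1L
  pc <- (pk - 1L) %/% h + 1L
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  # sub-bin refinement: baseline-subtracted centroid over a window around
  # the peak; robust when drift within a block flattens the peak top
  r <- 5L
  ri <- wrap(pr + (-r:r), h)
  ci <- wrap(pc + (-r:r), w)
  win <- cc[ri, ci]
  win <- pmax(win - min(win), 0)
  tot <- sum(win)
  dr <- sum(rowSums(win) * (-r:r)) / tot
  dc <- sum(colSums(win) * (-r:r)) / tot
  sr <- (pr - 1L) + dr; sc <- (pc - 1L) + dc
  if (sr > h / 2) sr <- sr - h
  if (sc > w / 2) sc <- sc - w
  c(dy = sr, dx = sc)
}

#' Estimate lateral stage drift from localizations
#'
#' Splits frames into temporal blocks (trailing frames join the last block),
#' builds a super-resolution histogram per block, registers each block
#' against block 0 by sub-pixel cross-correlation, interpolates the block
#' displacements linearly between block centers (extending the end segments
#' linearly), and anchors the trajectory at frame 0.
#'
#' @param localizations Localization data frame (`frame`, `x_px`, `y_px`).
#' @param block_frames Frames per registration block (default 250).
#' @param zoom Super-resolution zoom factor (default 5, i.e. 44 nm bins at
#'   220 nm pixels).
#' @param n_frames Total frames; default `max(frame) + 1`.
#' @param shape_px `c(height, width)` of the field in pixels; default from
#'   the localization extent.
#' @param min_locs_per_block Registration is refused (error) when any block
#'   holds fewer localizations than this.
#' @return A data frame of class `drift_trajectory` with one row per frame:
#'   `frame`, `dx_px`, `dy_px`, displacement relative to frame 0.
#' @export
estimate_drift <- function(localizations, block_frames = 250L, zoom = 5L,
                           n_frames = NULL, shape_px = NULL,
                           min_locs_per_block = 50L) {
  if (is.null(n_frames)) n_frames <- max(localizations$frame) + 1L
  n_blocks <- n_frames %/% block_frames
  if (n_blocks < 2L)
    stop("need at least 2 complete blocks of ", block_frames, " frames", call. = FALSE)
  if (is.null(shape_px))
    shape_px <- c(ceiling(max(localizations$y_px) + 1),
                  ceiling(max(localizations$x_px) + 1))
  blk <- pmin(localizations$frame %/% block_frames, n_blocks - 1L)
  counts <- tabulate(blk + 1L, nbins = n_blocks)
  if (any(counts < min_locs_per_block))
    stop("block(s) with fewer than ", min_locs_per_block,
         " localizations; drift registration unreliable", call. = FALSE)
  h0 <- NULL
  centers <- numeric(n_blocks)
  dx <- numeric(n_blocks); dy <- numeric(n_blocks)
  for (b in seq_len(n_blocks) - 1L) {
    sel <- blk == b
    hb <- sr_histogram(localizations$x_px[sel], localizations$y_px[sel],
                       zoom, shape_px)
    f0 <- b * block_frames
    f1 <- if (b == n_blocks - 1L) n_frames - 1L else (b + 1L) * block_frames - 1L
    centers[b + 1L] <- (f0 + f1) / 2
    if (b == 0L) {
      h0 <- hb
    } else {
      s <- xcorr_shift(h0, hb)
      dx[b + 1L] <- s[["dx"]] / zoom
      dy[b + 1L] <- s[["dy"]] / zoom
    }
  }
  frames <- 0:(n_frames - 1L)
  interp_extrap <- function(v) {
    out <- stats::approx(centers, v, xout = frames, rule = 2)$y
    # extend the outer segments linearly instead of holding them constant
    k <- length(centers)
    sl_lo <- (v[2] - v[1]) / (centers[2] - centers[1])
    sl_hi <- (v[k] - v[k - 1]) / (centers[k] - centers[k - 1])
    lo <- frames < centers[1]; hi <- frames > centers[k]
    out[lo] <- v[1] + sl_lo * (frames[lo] - centers[1])
    out[hi] <- v[k] + sl_hi * (frames[hi] - centers[k])
    out - (v[1] + sl_lo * (0 - centers[1]))  # anchor at frame 0
  }
  traj <- data.frame(frame = frames, dx_px = interp_extrap(dx),
                     dy_px = interp_extrap(dy))
  class(traj) <- c("drift_trajectory", "data.frame")
  traj
}

#' Apply (subtract) a drift trajectory from localizations
#'
#' @param localizations Localization data frame.
#' @param trajectory A `drift_trajectory` from [estimate_drift()] covering
#'   every frame present.
#' @return The localization table with `x_px`, `y_px` corrected
#'   (`x - dx[frame]`, `y - dy[frame]`); row order and count preserved.
#' @export
apply_drift <- function(localizations, trajectory) {
  idx <- match(localizations$frame, trajectory$frame)
  if (anyNA(idx))
    stop("trajectory does not cover all frames in the localization table",
         call. = FALSE)
  localizations$x_px <- localizations$x_px - trajectory$dx_px[idx]
  localizations$y_px <- localizations$y_px - trajectory$dy_px[idx]
  localizations
}

#' Write / read a drift trajectory as CSV
#'
#' @param trajectory A `drift_trajectory`.
#' @param path CSV path.
#' @return `path` invisibly, or the trajectory.
#' @export
write_drift_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drift_csv
#' @export
read_drift_csv <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("drift_trajectory", "data.frame")
  tr
}
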