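# Spot detection and sub-pixel localization.
#
# A transparent detect / fit / subtract loop in the spirit of high-density
# localization algorithms: per frame, candidate peaks are found on the
# background-subtracted image, fit with a pixel-integrated 2-D Gaussian,
# subtracted from a working copy, and the residual searched again so
# overlapping emitters can be recovered.

#' Estimate a smooth per-pixel background
#'
#' Median filter of the frame; the median is robust to the sparse bright
#' spots that would bias a mean filter.
#'
#' @param frame Numeric matrix (one movie frame).
#' @param window_px Odd filter window width in pixels, >= 3.
#' @return A background matrix of the same shape.
#' @export
estimate_background <- function(frame, window_px = 11L) {
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("`window_px` must be odd and >= 3", call. = FALSE)
  mx <- max(frame, 1e-12)
  mn <- min(frame, 0)
  sc <- (frame - mn) / (mx - mn + 1e-12)
  bg <- EBImage::medianFilter(sc, size = (window_px - 1L) %/% 2L)
  as.matrix(bg) * (mx - mn + 1e-12) + mn
}

# Robust noise sd of a residual image via the median absolute deviation.
robust_sd <- function(x) stats::mad(as.numeric(x), center = stats::median(as.numeric(x)))

#' Detect candidate spots in one frame
#'
#' Local maxima of the lightly smoothed, background-subtracted frame that
#' exceed `k_sigma` times the robust (MAD-based) noise standard deviation.
#' Peaks closer than 2 px are merged, keeping the brighter one.
#'
#' @param frame Numeric matrix.
#' @param background Matching background matrix (see [estimate_background()]).
#' @param k_sigma Detection threshold in noise standard deviations.
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels.
#' @return Data frame of integer candidate positions (`x_px`, `y_px`,
#'   0-based) and smoothed peak `value`, ordered by decreasing value.
#' @export
detect_candidates <- function(frame, background, k_sigma = 5, smooth_sigma = 1) {
  if (k_sigma <= 0) stop("`k_sigma` must be > 0", call. = FALSE)
  resid <- frame - background
  sm <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(resid, sigma = smooth_sigma)) else resid
  sd0 <- robust_sd(sm)
  thr <- k_sigma * max(sd0, 1e-12)
  h <- nrow(sm); w <- ncol(sm)
  # 3x3 neighborhood maximum by shifting
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- sm
  nbmax <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbmax <- pmax(nbmax, pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  }
  is_peak <- sm >= nbmax & sm > thr
  if (!any(is_peak)) {
    return(data.frame(x_px = integer(0), y_px = integer(0), value = numeric(0)))
  }
  idx <- which(is_peak)
  y <- (idx - 1L) %% h
  x <- (idx - 1L) %/% h
  v <- sm[idx]
  o <- order(-v)
  x <- x[o]; y <- y[o]; v <- v[o]
  # merge peaks closer than 2 px, keep brighter (earlier in sorted order)
  keep <- rep(TRUE, length(x))
  for (i in seq_along(x)) {
    if (!keep[i]) next
    if (i < length(x)) {
      j <- (i + 1L):length(x)
      close <- keep[j] & ((x[j] - x[i])^2 + (y[j] - y[i])^2) < 4
      keep[j[close]] <- FALSE
    }
  }
  data.frame(x_px = as.integer(x[keep]), y_px = as.integer(y[keep]),
             value = v[keep])
}

#' Fit one spot with a pixel-integrated 2-D Gaussian
#'
#' Least-squares fit of amplitude, sub-pixel center, local offset and
#' (optionally) PSF width to a square region of interest around an integer
#' peak position, on the background-subtracted frame. The model integrates
#' the Gaussian over each pixel, so fits remain unbiased at small widths.
#'
#' @param frame Numeric matrix.
#' @param background Matching background matrix.
#' @param peak Integer `c(x, y)` (0-based) candidate position.
#' @param roi_px Odd ROI width (default 7); shrunk (and flagged) at borders.
#' @param fixed_sigma PSF sd in pixels to hold fixed; `NULL` to fit it.
#' @return A one-row data frame (`frame` unset) with `x_px`, `y_px`,
#'   `photons`, `sigma_px`, `offset`, `rss`, `ok`, `reason`,
#'   `roi_shrunk`. Rejections (`ok = FALSE`) carry `reason` in
#'   `"diverged"`, `"out-of-roi"`, `"negative-amplitude"`.
#' @export
fit_spot <- function(frame, background, peak, roi_px = 7L, fixed_sigma = 1.3) {
  h <- nrow(frame); w <- ncol(frame)
  half <- roi_px %/% 2L
  cx <- as.integer(peak[1]); cy <- as.integer(peak[2])
  c0 <- max(0L, cx - half); c1 <- min(w - 1L, cx + half)
  r0 <- max(0L, cy - half); r1 <- min(h - 1L, cy + half)
  shrunk <- (c1 - c0 + 1L) < roi_px || (r1 - r0 + 1L) < roi_px
  roi <- frame[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE] -
    background[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE]
  rows <- r0:r1; cols <- c0:c1
  fail <- function(reason) data.frame(
    x_px = NA_real_, y_px = NA_real_, photons = NA_real_, sigma_px = NA_real_,
    offset = NA_real_, rss = NA_real_, ok = FALSE, reason = reason,
    roi_shrunk = shrunk, stringsAsFactors = FALSE)
  if (length(roi) < 9L) return(fail("diverged"))
  a0 <- max(sum(roi), 1)
  free_sigma <- is.null(fixed_sigma)
  s0 <- if (free_sigma) 1.3 else fixed_sigma
  par0 <- c(A = a0, x = cx, y = cy, b = stats::median(roi))
  if (free_sigma) par0 <- c(par0, ls = log(s0))
  model <- function(p) {
    s <- if (free_sigma) exp(p[["ls"]]) else fixed_sigma
    gauss_patch(p[["x"]], p[["y"]], s, p[["A"]], rows + 1L, cols + 1L) + p[["b"]]
  }
  res <- try(minpack.lm::nls.lm(
    par = par0, fn = function(p) as.numeric(roi - model(p)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(res, "try-error")) return(fail("diverged"))
  p <- res$par
  s <- if (free_sigma) exp(p[["ls"]]) else fixed_sigma
  if (!all(is.finite(unlist(p)))) return(fail("diverged"))
  if (p[["A"]] <= 0) return(fail("negative-amplitude"))
  if (p[["x"]] < c0 - 0.5 || p[["x"]] > c1 + 0.5 ||
      p[["y"]] < r0 - 0.5 || p[["y"]] > r1 + 0.5) return(fail("out-of-roi"))
  data.frame(x_px = p[["x"]], y_px = p[["y"]], photons = p[["A"]],
             sigma_px = s, offset = p[["b"]], rss = sum(res$fvec^2),
             ok = TRUE, reason = "", roi_shrunk = shrunk,
             stringsAsFactors = FALSE)
}

#' Default localization parameters
#'
#' @param k_sigma Detection threshold in robust noise sd units.
#' @param roi_px Fit ROI width, odd.
#' @param fixed_sigma PSF sd held fixed during fits (`NULL` = fit freely).
#' @param max_subtraction_rounds Detect/fit/subtract passes per frame.
#' @param bg_window_px Median-filter window for background estimation.
#' @param smooth_sigma Detection pre-smoothing sd, pixels.
#' @param refine_passes After all rounds, each localization is re-fit with
#'   the other fitted spots subtracted (add-back / refit / re-subtract),
#'   de-biasing overlapping pairs.
#' @param min_photons Fits below this integrated intensity are rejected.
#'   Guards later subtraction rounds against chasing the small residue left
#'   by earlier fits, which sits above any noise-based threshold when the
#'   background is very clean.
#' @return A named list of parameters for [localize_stack()].
#' @export
localize_params <- function(k_sigma = 5, roi_px = 7L, fixed_sigma = 1.3,
                            max_subtraction_rounds = 2L, bg_window_px = 11L,
                            smooth_sigma = 1, refine_passes = 1L,
                            min_photons = 50) {
  list(k_sigma = k_sigma, roi_px = roi_px, fixed_sigma = fixed_sigma,
       max_subtraction_rounds = max_subtraction_rounds,
       bg_window_px = bg_window_px, smooth_sigma = smooth_sigma,
       refine_passes = refine_passes, min_photons = min_photons)
}

# Subtract a fitted Gaussian (no offset) from a working frame, in place.
subtract_model <- function(work, x, y, photons, sigma) {
  h <- nrow(work); w <- ncol(work)
  half <- ceiling(5 * sigma) + 1L
  r0 <- max(1L, floor(y) - half + 1L); r1 <- min(h, ceiling(y) + half + 1L)
  c0 <- max(1L, floor(x) - half + 1L); c1 <- min(w, ceiling(x) + half + 1L)
  if (r0 > r1 || c0 > c1) return(work)
  work[r0:r1, c0:c1] <- work[r0:r1, c0:c1] -
    gauss_patch(x, y, sigma, photons, r0:r1, c0:c1)
  work
}

# Joint fit of a cluster of overlapping spots: sum of pixel-integrated
# Gaussians plus one shared offset over the cluster's bounding ROI.
# `work` must contain the cluster's signal (members added back). Returns a
# data frame of surviving spots; spots whose amplitude collapses below
# `min_photons` are pruned and the remainder refit.
fit_spots_joint <- function(work, bg, spots, roi_px, fixed_sigma, min_photons) {
  h <- nrow(work); w <- ncol(work)
  half <- roi_px %/% 2L
  c0 <- max(0L, floor(min(spots$x_px)) - half)
  c1 <- min(w - 1L, ceiling(max(spots$x_px)) + half)
  r0 <- max(0L, floor(min(spots$y_px)) - half)
  r1 <- min(h - 1L, ceiling(max(spots$y_px)) + half)
  rows <- r0:r1; cols <- c0:c1
  roi <- work[rows + 1L, cols + 1L, drop = FALSE] -
    bg[rows + 1L, cols + 1L, drop = FALSE]
  cur <- spots
  repeat {
    k <- nrow(cur)
    if (!k) return(cur)
    par0 <- c(b = 0, as.numeric(t(cur[, c("photons", "x_px", "y_px")])))
    model <- function(p) {
      mu <- matrix(p[1], length(rows), length(cols))
      for (j in seq_len(k)) {
        A <- p[3 * j - 1]; x <- p[3 * j]; y <- p[3 * j + 1]
        mu <- mu + gauss_patch(x, y, cur$sigma_px[j], A, rows + 1L, cols + 1L)
      }
      mu
    }
    res <- try(minpack.lm::nls.lm(
      par = par0, fn = function(p) as.numeric(roi - model(p)),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(res, "try-error") || !all(is.finite(unlist(res$par))))
      return(spots)  # keep the sequential fits if the joint fit fails
    p <- res$par
    for (j in seq_len(k)) {
      cur$photons[j] <- p[3 * j - 1]
      cur$x_px[j] <- p[3 * j]
      cur$y_px[j] <- p[3 * j + 1]
      cur$offset[j] <- p[1]
      cur$rss[j] <- sum(res$fvec^2)
    }
    ok <- cur$photons >= min_photons &
      cur$x_px >= c0 - 0.5 & cur$x_px <= c1 + 0.5 &
      cur$y_px >= r0 - 0.5 & cur$y_px <= r1 + 0.5
    # merge duplicates: two model spots within the 2 px detection-merge
    # radius describe one emitter, so drop the dimmer and refit
    if (all(ok) && nrow(cur) > 1L) {
      for (i in seq_len(nrow(cur) - 1L)) {
        for (j in (i + 1L):nrow(cur)) {
          if ((cur$x_px[i] - cur$x_px[j])^2 +
              (cur$y_px[i] - cur$y_px[j])^2 < 4) {
            ok[if (cur$photons[i] < cur$photons[j]) i else j] <- FALSE
          }
        }
      }
    }
    if (all(ok)) return(cur)
    cur <- cur[ok, , drop = FALSE]
  }
}

#' Localize every spot in a movie
#'
#' Per frame: estimate background, detect candidates, fit each with a
#' pixel-integrated Gaussian, subtract accepted fits from a working copy and
#' repeat up to `max_subtraction_rounds` so overlapping emitters missed in
#' the first pass are recovered; optional refinement passes re-fit each spot
#' against the residual of all others. Frames whose processing fails are
#' recorded in attribute `"skipped_frames"`, never silently dropped.
#'
#' @param stack A [frame_stack()].
#' @param params See [localize_params()].
#' @return Data frame `frame, x_px, y_px, photons, sigma_px, offset, rss`
#'   sorted by (frame, y, x); frame is 0-based.
#' @export
localize_stack <- function(stack, params = localize_params()) {
  d <- stack$data
  nt <- dim(d)[3]
  out <- vector("list", nt)
  skipped <- integer(0)
  for (f in seq_len(nt)) {
    res <- try({
      frame <- d[, , f]
      bg <- estimate_background(frame, params$bg_window_px)
      work <- frame
      accepted <- list()
      refine <- function() {
        # joint re-fit of clusters of mutually overlapping spots with a
        # shared offset: de-biases overlapping pairs, and prunes phantom
        # spots whose amplitude collapses once neighbors are modeled
        for (pass in seq_len(params$refine_passes)) {
          if (!length(accepted)) return()
          acc <- do.call(rbind, accepted)
          # single-linkage clusters within 3/4 of the ROI width
          thr2 <- (0.75 * params$roi_px)^2
          cl <- seq_len(nrow(acc))
          repeat {
            changed <- FALSE
            for (i in seq_len(nrow(acc))) for (j in seq_len(nrow(acc))) {
              if (cl[i] != cl[j] &&
                  (acc$x_px[i] - acc$x_px[j])^2 +
                  (acc$y_px[i] - acc$y_px[j])^2 <= thr2) {
                cl[cl == cl[j]] <- cl[i]; changed <- TRUE
              }
            }
            if (!changed) break
          }
          out <- list()
          for (g in unique(cl)) {
            members <- acc[cl == g, , drop = FALSE]
            for (j in seq_len(nrow(members)))
              work <<- subtract_model(work, members$x_px[j], members$y_px[j],
                                      -members$photons[j], members$sigma_px[j])
            refit <- fit_spots_joint(work, bg, members, params$roi_px,
                                     params$fixed_sigma, params$min_photons)
            for (j in seq_len(nrow(refit)))
              work <<- subtract_model(work, refit$x_px[j], refit$y_px[j],
                                      refit$photons[j], refit$sigma_px[j])
            if (nrow(refit)) out[[length(out) + 1L]] <- refit
          }
          accepted <<- if (length(out))
            split(do.call(rbind, out), seq_len(nrow(do.call(rbind, out)))) else list()
        }
      }
      for (round in seq_len(params$max_subtraction_rounds)) {
        cand <- detect_candidates(work, bg, params$k_sigma, params$smooth_sigma)
        if (!nrow(cand)) break
        if (length(accepted)) {
          acc <- do.call(rbind, accepted)
          keep <- vapply(seq_len(nrow(cand)), function(i) {
            min((acc$x_px - cand$x_px[i])^2 + (acc$y_px - cand$y_px[i])^2) > 1.5^2
          }, logical(1))
          cand <- cand[keep, , drop = FALSE]
          if (!nrow(cand)) break
        }
        new_any <- FALSE
        for (i in seq_len(nrow(cand))) {
          fit <- fit_spot(work, bg, c(cand$x_px[i], cand$y_px[i]),
                          params$roi_px, params$fixed_sigma)
          if (isTRUE(fit$ok) && fit$photons >= params$min_photons) {
            work <- subtract_model(work, fit$x_px, fit$y_px, fit$photons, fit$sigma_px)
            accepted[[length(accepted) + 1L]] <- fit
            new_any <- TRUE
          }
        }
        if (!new_any) break
        if (length(accepted) && params$refine_passes > 0) refine()
      }
      if (length(accepted)) {
        tab <- do.call(rbind, accepted)
        tab <- data.frame(frame = f - 1L, tab[c("x_px", "y_px", "photons",
                                                "sigma_px", "offset", "rss")])
        tab
      } else NULL
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      skipped <- c(skipped, f - 1L)
      message("localize_stack: frame ", f - 1L, " failed and was skipped")
    } else out[[f]] <- res
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      photons = numeric(0), sigma_px = numeric(0),
                      offset = numeric(0), rss = numeric(0))
  tab <- tab[order(tab$frame, tab$y_px, tab$x_px), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "skipped_frames") <- skipped
  attr(tab, "params") <- params
  tab
}

#' Write / read a localization table as CSV
#'
#' Positions are stored in pixel units; conversion to nm via the stack's
#' `pixel_nm` is applied only at reporting.
#'
#' @param localizations Data frame from [localize_stack()].
#' @param path CSV path.
#' @return `path` invisibly, or the localization data frame.
#' @export
write_localizations_csv <- function(localizations, path) {
  utils::write.csv(
    localizations[c("frame", "x_px", "y_px", "photons", "sigma_px", "offset", "rss")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
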