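#' Kinetic population specification
#'
#' One bound population of a dwell-time mixture. A population is either
#' exchanging, with exponentially distributed residence times of mean
#' `tau_s`, or `immobilized`: bound longer than the observation can resolve,
#' so its *observed* dwell is set entirely by fluorophore photobleaching.
#'
#' @param fraction Fraction of events belonging to this population, in (0, 1].
#' @param tau_s Characteristic residence time in seconds (`Inf` allowed, and
#'   implied, when `immobilized = TRUE`).
#' @param immobilized Logical; if `TRUE` the true dwell is infinite and the
#'   observed dwell is a photobleach survival draw.
#' @return An object of class `population_spec`.
#' @seealso [simulation_truth()], [bleach_model()]
#' @export
population_spec <- function(fraction, tau_s = Inf, immobilized = is.infinite(tau_s)) {
  stopifnot_scalar_pos(fraction, "fraction")
  if (fraction > 1) stop("`fraction` must be in (0, 1]", call. = FALSE)
  if (!immobilized) stopifnot_scalar_pos(tau_s, "tau_s")
  if (immobilized) tau_s <- Inf
  structure(list(fraction = fraction, tau_s = tau_s, immobilized = immobilized),
            class = "population_spec")
}

#' Photobleaching survival model
#'
#' Mixture-of-exponentials survival of the fluorescent label. Under
#' oxygen-scavenging imaging buffer Cy5 shows two decay lifetimes, 195 s and
#' 1100 s; without scavenging, 5 s and 20 s. Mixture weights are
#' configurable (equal by default) and echoed in all reports.
#'
#' @param lifetimes_s Positive exponential lifetimes in seconds. `Inf`
#'   disables bleaching.
#' @param weights Mixture weights, summing to 1; defaults to equal weights.
#' @return An object of class `bleach_model`.
#' @export
bleach_model <- function(lifetimes_s = c(195, 1100),
                         weights = rep(1 / length(lifetimes_s), length(lifetimes_s))) {
  if (length(lifetimes_s) < 1L || any(!is.numeric(lifetimes_s)) || any(lifetimes_s <= 0))
    stop("`lifetimes_s` must be positive", call. = FALSE)
  if (length(weights) != length(lifetimes_s) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must match `lifetimes_s` and sum to 1", call. = FALSE)
  structure(list(lifetimes_s = as.numeric(lifetimes_s), weights = as.numeric(weights)),
            class = "bleach_model")
}

# Draw n observed-photobleach survival times from the mixture.
draw_bleach <- function(bleach, n) {
  if (n == 0L) return(numeric(0))
  comp <- sample.int(length(bleach$lifetimes_s), n, replace = TRUE, prob = bleach$weights)
  lt <- bleach$lifetimes_s[comp]
  out <- rep(Inf, n)
  fin <- is.finite(lt)
  out[fin] <- stats::rexp(sum(fin), rate = 1 / lt[fin])
  out
}

#' Ground-truth parameters for a synthetic single-molecule experiment
#'
#' Collects every generative parameter of the simulator: the kinetic
#' population mixture, arrival rates on fibrils and on background glass, the
#' imaging geometry and cadence (1 s frames, 220 nm pixels by default,
#' matching EMCCD TIRFM acquisition), the point-spread function and photon
#' budget, camera noise, blinking, stage drift, and the photobleach model.
#'
#' @param populations List of [population_spec()]; fractions must sum to 1.
#' @param arrival_rate_fibril,arrival_rate_bg Expected new binding events per
#'   frame landing on the fibril support / on background.
#' @param n_frames Number of frames in the observation window (>= 2;
#'   2500 frames at 1 s is a typical experiment).
#' @param frame_interval_s Camera integration time per frame, seconds.
#' @param pixel_nm Physical pixel pitch, nanometres.
#' @param image_shape `c(height, width)` of the field of view in pixels.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param photons_per_frame Expected photons per emitter per frame.
#' @param bg_photons_px Expected background photons per pixel per frame.
#' @param read_noise Additive Gaussian camera noise standard deviation, counts.
#' @param shot_noise Apply Poisson shot noise to signal + background
#'   (default `TRUE`; disable for noiseless ground-truth renderings).
#' @param blink_off_prob Per-frame probability that an active emitter is dark.
#' @param drift_px_per_frame `c(dx, dy)` linear stage drift, pixels/frame.
#' @param bleach A [bleach_model()].
#' @param bleach_scope `"all"` (default): the photobleach clock competes
#'   with every population's dwell (min rule, standard photophysics), so
#'   even exchanging populations are slightly truncated. `"immobilized"`:
#'   only immobilized populations are observed through the bleach mixture;
#'   use this when the population characteristic times are meant as
#'   *observed* times (e.g. parameter-recovery experiments against fitted
#'   values).
#' @param seed Integer seed governing all randomness of the simulator.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(populations,
                             arrival_rate_fibril = 0.5,
                             arrival_rate_bg = 0.5,
                             n_frames = 2500,
                             frame_interval_s = 1.0,
                             pixel_nm = 220,
                             image_shape = c(128L, 128L),
                             psf_sigma_px = 1.3,
                             photons_per_frame = 500,
                             bg_photons_px = 5,
                             read_noise = 1,
                             shot_noise = TRUE,
                             blink_off_prob = 0,
                             drift_px_per_frame = c(0, 0),
                             bleach = bleach_model(),
                             bleach_scope = c("all", "immobilized"),
                             seed = 1L) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (!length(populations) || !all(vapply(populations, inherits, TRUE, "population_spec")))
    stop("`populations` must be a list of population_spec", call. = FALSE)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must sum to 1", call. = FALSE)
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  stopifnot_scalar_pos(arrival_rate_fibril, "arrival_rate_fibril", strict = FALSE)
  stopifnot_scalar_pos(arrival_rate_bg, "arrival_rate_bg", strict = FALSE)
  if (!inherits(bleach, "bleach_model")) stop("`bleach` must be a bleach_model", call. = FALSE)
  bleach_scope <- match.arg(bleach_scope)
  structure(list(
    populations = populations,
    arrival_rate_fibril = arrival_rate_fibril,
    arrival_rate_bg = arrival_rate_bg,
    n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    pixel_nm = pixel_nm,
    image_shape = as.integer(image_shape),
    psf_sigma_px = psf_sigma_px,
    photons_per_frame = photons_per_frame,
    bg_photons_px = bg_photons_px,
    read_noise = read_noise,
    shot_noise = isTRUE(shot_noise),
    blink_off_prob = blink_off_prob,
    drift_px_per_frame = as.numeric(drift_px_per_frame),
    bleach = bleach,
    bleach_scope = bleach_scope,
    seed = as.integer(seed)
  ), class = "simulation_truth")
}

#' Random fibril geometry
#'
#' Rasterizes `n_fibrils` straight line segments of width 1-2 px into a
#' binary support mask, emulating a field of long, thin cellulose fibrils
#' laid on a coverslip. Segments are rejection-sampled so they do not touch
#' (>= 3 px apart), giving one 8-connected component per fibril.
#'
#' @param seed Integer seed; identical seeds give identical geometries.
#' @param n_fibrils Number of segments.
#' @param image_shape `c(height, width)` in pixels.
#' @return A list with `mask` (logical height x width matrix) and `segments`
#'   (data frame of endpoints `x0, y0, x1, y1` and `width_px`, 0-based pixel
#'   coordinates).
#' @export
make_fibril_geometry <- function(seed, n_fibrils, image_shape) {
  if (any(image_shape <= 0)) stop("`image_shape` must be positive", call. = FALSE)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  mask <- matrix(FALSE, h, w)
  segs <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                     y1 = numeric(0), width_px = numeric(0))
  if (n_fibrils == 0L) return(list(mask = mask, segments = segs))
  with_seed(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < n_fibrils && tries < 200L * n_fibrils) {
      tries <- tries + 1L
      cx <- stats::runif(1, 0.15 * w, 0.85 * w)
      cy <- stats::runif(1, 0.15 * h, 0.85 * h)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 0.4, 0.8) * min(h, w)
      wid <- sample(1:2, 1L)
      x0 <- cx - cos(ang) * len / 2; x1 <- cx + cos(ang) * len / 2
      y0 <- cy - sin(ang) * len / 2; y1 <- cy + sin(ang) * len / 2
      cand <- rasterize_segment(x0, y0, x1, y1, wid, h, w)
      if (!any(cand)) next
      # enforce >= 3 px separation from already-placed fibrils
      if (placed > 0L) {
        dil <- EBImage::dilate(matrix(as.numeric(cand), h, w),
                               EBImage::makeBrush(7L, shape = "box")) > 0
        if (any(dil & mask)) next
      }
      mask <- mask | cand
      segs <- rbind(segs, data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                                     width_px = wid))
      placed <- placed + 1L
    }
    if (placed < n_fibrils)
      warning("placed only ", placed, " of ", n_fibrils, " fibrils")
  })
  list(mask = mask, segments = segs)
}

# Mark pixels within width/2 of the segment (0-based pixel-center coords).
rasterize_segment <- function(x0, y0, x1, y1, width_px, h, w) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  tt <- seq(0, 1, length.out = max(2L, ceiling(len * 4)))
  xs <- x0 + tt * (x1 - x0)
  ys <- y0 + tt * (y1 - y0)
  m <- matrix(FALSE, h, w)
  half <- max(0.72, width_px / 2)  # keeps diagonal lines 4-connected
  for (k in seq_along(tt)) {
    ci <- seq.int(max(1L, floor(xs[k] - half) + 1L), min(w, ceiling(xs[k] + half) + 1L))
    ri <- seq.int(max(1L, floor(ys[k] - half) + 1L), min(h, ceiling(ys[k] + half) + 1L))
    for (r in ri) for (cc in ci) {
      if ((cc - 1 - xs[k])^2 + (r - 1 - ys[k])^2 <= half^2) m[r, cc] <- TRUE
    }
  }
  m
}

#' Simulate a ground-truth binding event list
#'
#' Draws binding events under the generative model of [simulation_truth()]:
#' arrivals are Poisson in time (uniform over frames) and uniform over the
#' spatial support (fibril mask pixels for fibril events, the whole field for
#' background events); each event's true dwell is exponential with its
#' population's characteristic time (infinite for immobilized populations);
#' the observed dwell is the minimum of the true dwell and an independent
#' photobleach survival draw; dwells are discretized to whole frames by
#' `ceiling(dwell / frame_interval_s)` with a 1-frame minimum (a molecule
#' visible during any part of a frame is detected in that frame).
#'
#' @param truth A [simulation_truth()].
#' @param fibril_mask Optional logical matrix of the fibril support. If `NULL`
#'   and fibril arrivals are requested, a 3-fibril geometry is generated from
#'   `truth$seed`.
#' @return A data frame of events (`x_px`, `y_px`, `start_frame`,
#'   `true_dwell_s`, `observed_dwell_s`, `dwell_frames`, `population_id`,
#'   `region`) with the fibril mask attached as attribute `"fibril_mask"`.
#' @export
simulate_event_list <- function(truth, fibril_mask = NULL) {
  if (!inherits(truth, "simulation_truth")) stop("`truth` must be a simulation_truth")
  h <- truth$image_shape[1]; w <- truth$image_shape[2]
  if (is.null(fibril_mask) && truth$arrival_rate_fibril > 0)
    fibril_mask <- make_fibril_geometry(truth$seed, 3L, truth$image_shape)$mask
  with_seed(truth$seed, {
    n_fib <- stats::rpois(1, truth$arrival_rate_fibril * truth$n_frames)
    n_bg <- stats::rpois(1, truth$arrival_rate_bg * truth$n_frames)
    if (n_fib > 0 && (is.null(fibril_mask) || !any(fibril_mask)))
      stop("fibril arrivals requested but fibril mask is empty", call. = FALSE)
    n <- n_fib + n_bg
    if (n == 0L) {
      ev <- data.frame(x_px = numeric(0), y_px = numeric(0),
                       start_frame = integer(0), true_dwell_s = numeric(0),
                       observed_dwell_s = numeric(0), dwell_frames = integer(0),
                       population_id = integer(0), region = character(0),
                       stringsAsFactors = FALSE)
      attr(ev, "fibril_mask") <- fibril_mask
      return(ev)
    }
    # positions: uniform over support pixels plus sub-pixel jitter
    if (n_fib > 0) {
      idx <- which(fibril_mask)
      pick <- idx[sample.int(length(idx), n_fib, replace = TRUE)]
      fy <- (pick - 1L) %% h
      fx <- (pick - 1L) %/% h
      fx <- fx + stats::runif(n_fib, -0.5, 0.5)
      fy <- fy + stats::runif(n_fib, -0.5, 0.5)
    } else fx <- fy <- numeric(0)
    bx <- stats::runif(n_bg, -0.5, w - 0.5)
    by <- stats::runif(n_bg, -0.5, h - 0.5)
    x <- c(fx, bx); y <- c(fy, by)
    region <- c(rep("fibril", n_fib), rep("background", n_bg))

    start_frame <- sample.int(truth$n_frames, n, replace = TRUE) - 1L
    fracs <- vapply(truth$populations, `[[`, numeric(1), "fraction")
    pop <- sample.int(length(fracs), n, replace = TRUE, prob = fracs)
    taus <- vapply(truth$populations, `[[`, numeric(1), "tau_s")
    true_dwell <- rep(Inf, n)
    fin <- is.finite(taus[pop])
    true_dwell[fin] <- stats::rexp(sum(fin), rate = 1 / taus[pop[fin]])
    bl <- draw_bleach(truth$bleach, n)
    observed <- if (identical(truth$bleach_scope, "immobilized")) {
      ifelse(is.finite(true_dwell), true_dwell, bl)
    } else {
      pmin(true_dwell, bl)
    }
    if (any(!is.finite(observed)))
      observed[!is.finite(observed)] <- truth$n_frames * truth$frame_interval_s * 10
    dwell_frames <- pmax(1L, as.integer(ceiling(observed / truth$frame_interval_s)))
    ev <- data.frame(x_px = x, y_px = y, start_frame = start_frame,
                     true_dwell_s = true_dwell, observed_dwell_s = observed,
                     dwell_frames = dwell_frames, population_id = pop,
                     region = region, stringsAsFactors = FALSE)
    ev <- ev[order(ev$start_frame, ev$y_px, ev$x_px), , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "fibril_mask") <- fibril_mask
    ev
  })
}

#' Image stack container
#'
#' A movie as a `height x width x n_frames` array of non-negative
#' intensities with pixel pitch and frame cadence metadata.
#'
#' @param data Numeric 3-D array, `height x width x n_frames` (a single
#'   matrix is promoted to one frame).
#' @param pixel_nm Pixel pitch, nm (default 220).
#' @param frame_interval_s Frame interval, seconds (default 1).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, pixel_nm = 220, frame_interval_s = 1.0) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("`data` must be height x width x n_frames")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(data = data, pixel_nm = pixel_nm,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frames of %d x %d px (%g nm/px, %g s/frame)\n",
              d[3], d[1], d[2], x$pixel_nm, x$frame_interval_s))
  invisible(x)
}

# Pixel-integrated 2D Gaussian amplitudes on 0-based pixel grid.
# Returns the expected counts contributed by one emitter of total intensity
# `photons` at (x, y) to the pixels [rows, cols] (1-based matrix indices).
gauss_patch <- function(x, y, sigma, photons, rows, cols) {
  gx <- stats::pnorm(((cols - 1) + 0.5 - x) / sigma) -
        stats::pnorm(((cols - 1) - 0.5 - x) / sigma)
  gy <- stats::pnorm(((rows - 1) + 0.5 - y) / sigma) -
        stats::pnorm(((rows - 1) - 0.5 - y) / sigma)
  photons * outer(gy, gx)
}

#' Render a synthetic TIRFM movie
#'
#' Renders each active emitter as a pixel-integrated 2-D Gaussian PSF, adds
#' per-frame blinking, global linear stage drift, Poisson shot noise on
#' signal plus background, and additive Gaussian read noise (clamped at 0).
#'
#' @param events Event data frame from [simulate_event_list()].
#' @param truth The [simulation_truth()] used to generate `events`.
#' @return A [frame_stack()]; attribute `"n_clipped"` counts emitter-frames
#'   whose center drifted outside the field (rendered clipped, not an error).
#' @export
render_movie <- function(events, truth) {
  h <- truth$image_shape[1]; w <- truth$image_shape[2]
  nt <- truth$n_frames
  sig <- array(0, c(h, w, nt))
  n_clipped <- 0L
  with_seed(truth$seed + 1L, {
    if (nrow(events)) {
      end_frame <- pmin(events$start_frame + events$dwell_frames - 1L, nt - 1L)
      for (i in seq_len(nrow(events))) {
        frames <- events$start_frame[i]:end_frame[i]
        if (truth$blink_off_prob > 0) {
          on <- stats::runif(length(frames)) >= truth$blink_off_prob
          frames <- frames[on]
        }
        for (f in frames) {
          x <- events$x_px[i] + truth$drift_px_per_frame[1] * f
          y <- events$y_px[i] + truth$drift_px_per_frame[2] * f
          if (x < -0.5 || x > w - 0.5 || y < -0.5 || y > h - 0.5)
            n_clipped <- n_clipped + 1L
          half <- ceiling(5 * truth$psf_sigma_px) + 1L
          r0 <- max(1L, floor(y) - half + 1L); r1 <- min(h, ceiling(y) + half + 1L)
          c0 <- max(1L, floor(x) - half + 1L); c1 <- min(w, ceiling(x) + half + 1L)
          if (r0 > r1 || c0 > c1) next
          rows <- r0:r1; cols <- c0:c1
          sig[rows, cols, f + 1L] <- sig[rows, cols, f + 1L] +
            gauss_patch(x, y, truth$psf_sigma_px, truth$photons_per_frame, rows, cols)
        }
      }
    }
    lam <- sig + truth$bg_photons_px
    counts <- if (isTRUE(truth$shot_noise)) {
      array(stats::rpois(length(lam), lam), dim(lam))
    } else lam
    if (truth$read_noise > 0)
      counts <- counts + array(stats::rnorm(length(lam), 0, truth$read_noise), dim(lam))
    out <- pmax(counts, 0)
    st <- frame_stack(out, pixel_nm = truth$pixel_nm,
                      frame_interval_s = truth$frame_interval_s)
    attr(st, "n_clipped") <- n_clipped
    if (n_clipped > 0)
      warning(n_clipped, " emitter-frames drifted outside the field and were clipped")
    st
  })
}

#' Write a movie as multi-frame 16-bit TIFF
#'
#' Intensities are stored as 16-bit integers; values above 65535 saturate.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  d <- stack$data
  frames <- lapply(seq_len(dim(d)[3]), function(i) {
    m <- pmin(pmax(round(d[, , i]), 0), 65535) / 65535
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' @param path TIFF file written by [write_movie_tiff()] or any grayscale
#'   multi-frame TIFF.
#' @param pixel_nm,frame_interval_s Metadata to attach (TIFF stores neither).
#' @return A [frame_stack()] with intensities on the original count scale.
#' @export
read_movie_tiff <- function(path, pixel_nm = 220, frame_interval_s = 1.0) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  fr <- lapply(fr, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  d <- array(0, c(dim(fr[[1]]), length(fr)))
  for (i in seq_along(fr)) d[, , i] <- round(fr[[i]] * 65535)
  frame_stack(d, pixel_nm = pixel_nm, frame_interval_s = frame_interval_s)
}

#' Write / read a ground-truth event table as CSV
#'
#' @param events Event data frame from [simulate_event_list()].
#' @param path CSV path.
#' @return `path` invisibly, or the event data frame.
#' @export
write_truth_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
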