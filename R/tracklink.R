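# Linking localizations into per-molecule binding events.
#
# Bound enzymes are assumed stationary while bound, so linking is a greedy
# frame-to-frame nearest-neighbor association within a small radius
# (default 1 px = one 220 nm pixel), with a short gap tolerance for
# fluorophore blinking. Sparse fields make global assignment unnecessary.

#' Link localizations into binding events
#'
#' A localization in frame *f* joins the open event whose last position is
#' within `radius_px` and whose last supporting frame is at least
#' `f - 1 - max_gap_frames`; ties are broken by smallest distance, then
#' lowest event id. Unmatched localizations open new events; events
#' unmatched for more than `max_gap_frames` frames are closed. An event's
#' position is the mean over its supporting localizations.
#'
#' @param localizations Data frame with `frame`, `x_px`, `y_px` (0-based).
#' @param radius_px Association radius in pixels (default 1.0).
#' @param max_gap_frames Tolerated missing frames inside an event (default 1).
#' @param frame_interval_s Frame interval, seconds, for `duration_s`.
#' @param n_frames_total Total frames in the stack (default `max(frame)+1`),
#'   used for the `touches_start` / `touches_end` censoring flags.
#' @return Data frame of binding events: `event_id`, `mean_x_px`,
#'   `mean_y_px`, `start_frame`, `end_frame`, `n_frames`, `duration_s`,
#'   `n_gaps`, `n_locs`, `touches_start`, `touches_end`, `region`
#'   (initialized `"unassigned"`).
#' @export
link_events <- function(localizations, radius_px = 1.0, max_gap_frames = 1L,
                        frame_interval_s = 1.0, n_frames_total = NULL) {
  if (radius_px <= 0) stop("`radius_px` must be > 0", call. = FALSE)
  if (max_gap_frames < 0) stop("`max_gap_frames` must be >= 0", call. = FALSE)
  empty <- data.frame(event_id = integer(0), mean_x_px = numeric(0),
                      mean_y_px = numeric(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames = integer(0),
                      duration_s = numeric(0), n_gaps = integer(0),
                      n_locs = integer(0), touches_start = logical(0),
                      touches_end = logical(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(localizations)) return(empty)
  if (is.null(n_frames_total)) n_frames_total <- max(localizations$frame) + 1L
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  # open-event state
  oid <- integer(0); ox <- numeric(0); oy <- numeric(0)
  olast <- integer(0); osx <- numeric(0); osy <- numeric(0)
  on <- integer(0); ostart <- integer(0)
  next_id <- 1L
  closed <- list()
  close_events <- function(sel) {
    for (k in which(sel)) {
      closed[[length(closed) + 1L]] <<- data.frame(
        event_id = oid[k], mean_x_px = osx[k] / on[k], mean_y_px = osy[k] / on[k],
        start_frame = ostart[k], end_frame = olast[k],
        n_locs = on[k], stringsAsFactors = FALSE)
    }
    keep <- !sel
    oid <<- oid[keep]; ox <<- ox[keep]; oy <<- oy[keep]; olast <<- olast[keep]
    osx <<- osx[keep]; osy <<- osy[keep]; on <<- on[keep]; ostart <<- ostart[keep]
  }
  frames <- unique(loc$frame)
  r2 <- radius_px^2
  for (f in frames) {
    close_events(olast < f - 1L - max_gap_frames)
    sel <- loc$frame == f
    lx <- loc$x_px[sel]; ly <- loc$y_px[sel]
    nl <- length(lx)
    assigned_loc <- rep(FALSE, nl)
    if (length(oid) && nl) {
      d2 <- outer(ox, lx, function(a, b) (a - b)^2) +
            outer(oy, ly, function(a, b) (a - b)^2)
      adm <- which(d2 <= r2, arr.ind = TRUE)
      if (nrow(adm)) {
        ord <- order(d2[adm], oid[adm[, 1]])
        used_ev <- rep(FALSE, length(oid))
        for (k in ord) {
          ei <- adm[k, 1]; li <- adm[k, 2]
          if (used_ev[ei] || assigned_loc[li]) next
          used_ev[ei] <- TRUE; assigned_loc[li] <- TRUE
          ox[ei] <- lx[li]; oy[ei] <- ly[li]; olast[ei] <- f
          osx[ei] <- osx[ei] + lx[li]; osy[ei] <- osy[ei] + ly[li]
          on[ei] <- on[ei] + 1L
        }
      }
    }
    if (any(!assigned_loc)) {
      new <- which(!assigned_loc)
      oid <- c(oid, seq.int(next_id, next_id + length(new) - 1L))
      next_id <- next_id + length(new)
      ox <- c(ox, lx[new]); oy <- c(oy, ly[new])
      olast <- c(olast, rep(f, length(new)))
      osx <- c(osx, lx[new]); osy <- c(osy, ly[new])
      on <- c(on, rep(1L, length(new))); ostart <- c(ostart, rep(f, length(new)))
    }
  }
  close_events(rep(TRUE, length(oid)))
  ev <- do.call(rbind, closed)
  ev <- ev[order(ev$event_id), , drop = FALSE]
  ev$n_frames <- ev$end_frame - ev$start_frame + 1L
  ev$duration_s <- ev$n_frames * frame_interval_s
  ev$n_gaps <- ev$n_frames - ev$n_locs
  ev$touches_start <- ev$start_frame == 0L
  ev$touches_end <- ev$end_frame == n_frames_total - 1L
  ev$region <- "unassigned"
  ev <- ev[c("event_id", "mean_x_px", "mean_y_px", "start_frame", "end_frame",
             "n_frames", "duration_s", "n_gaps", "n_locs",
             "touches_start", "touches_end", "region")]
  rownames(ev) <- NULL
  ev
}

#' Censor events touching the observation window
#'
#' Events present in the first or last frame have unknowable total residence
#' times and are excluded from lifetime analysis; they are counted, not
#' silently discarded. An enzyme present in every frame of a 2500-frame
#' stack (duration 2500 s = 41.7 min) always touches both ends and is
#' always excluded.
#'
#' @param events Event data frame from [link_events()].
#' @param n_frames_total Total frames in the stack (>= 2).
#' @return List with `kept` (events data frame) and `n_excluded`.
#' @export
censor_events <- function(events, n_frames_total) {
  if (n_frames_total < 2) stop("`n_frames_total` must be >= 2", call. = FALSE)
  if (!nrow(events)) return(list(kept = events, n_excluded = 0L))
  events$touches_start <- events$start_frame == 0L
  events$touches_end <- events$end_frame == n_frames_total - 1L
  drop <- events$touches_start | events$touches_end
  list(kept = events[!drop, , drop = FALSE], n_excluded = sum(drop))
}

#' Event table in canonical order
#'
#' @param events Event data frame.
#' @return The same columns sorted by `start_frame`, then mean position
#'   (`mean_y_px`, `mean_x_px`).
#' @export
event_table <- function(events) {
  if (!nrow(events)) return(events)
  ev <- events[order(events$start_frame, events$mean_y_px, events$mean_x_px), ,
               drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write / read an event table as CSV
#'
#' @param events Event data frame.
#' @param path CSV path.
#' @return `path` invisibly, or the event data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
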