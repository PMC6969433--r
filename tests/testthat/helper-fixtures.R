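# Shared fixtures, built in code at test time.

# Dwell durations (whole frames) from a censored synthetic experiment:
# arrivals uniform over the window, first/last-frame events excluded.
sim_censored_durations <- function(populations, seed, n_frames = 2500,
                                   arrival_rate = 2, bleach = bleach_model(),
                                   ...) {
  truth <- simulation_truth(populations = populations,
                            arrival_rate_fibril = 0,
                            arrival_rate_bg = arrival_rate,
                            n_frames = n_frames, bleach = bleach, seed = seed,
                            ...)
  ev <- simulate_event_list(truth)
  end <- ev$start_frame + ev$dwell_frames - 1L
  keep <- ev$start_frame >= 1L & end <= n_frames - 2L
  ev$dwell_frames[keep]
}

# The two-population structure of an intact processive cellulase on
# cellulose: a short-lived majority and an immobilized minority whose
# observed dwell is the label's photobleach survival.
intact_populations <- function(f_short = 0.81, tau_short = 15) {
  list(population_spec(f_short, tau_short),
       population_spec(1 - f_short, Inf, immobilized = TRUE))
}

# The three-population structure of the isolated catalytic domain:
# short-lived majority, intermediate ~100 s population, small immobilized
# minority.
core_populations <- function(f = c(0.75, 0.20, 0.05), tau = c(15, 99)) {
  list(population_spec(f[1], tau[1]),
       population_spec(f[2], tau[2]),
       population_spec(f[3], Inf, immobilized = TRUE))
}

# A noiseless single-emitter frame rendered with the pixel-integrated
# Gaussian used by the simulator.
render_single_spot <- function(x, y, sigma = 1.3, photons = 1000,
                               shape = c(24L, 24L), offset = 0) {
  m <- matrix(offset, shape[1], shape[2])
  m + gauss_patch_test(x, y, sigma, photons, seq_len(shape[1]), seq_len(shape[2]))
}

# Independent re-implementation of the pixel-integrated Gaussian (oracle
# for rendering/fitting round trips), written from the definition.
gauss_patch_test <- function(x, y, sigma, photons, rows, cols) {
  fx <- pnorm(((cols - 1) + 0.5 - x) / sigma) - pnorm(((cols - 1) - 0.5 - x) / sigma)
  fy <- pnorm(((rows - 1) + 0.5 - y) / sigma) - pnorm(((rows - 1) - 0.5 - y) / sigma)
  photons * outer(fy, fx)
}

# Match localizations to true emitter positions within a radius; returns
# recall/precision (the truth-matching oracle).
match_localizations <- function(locs, truth_xy, radius_px = 1) {
  if (!nrow(locs)) return(list(recall = 0, precision = NA_real_))
  used <- rep(FALSE, nrow(truth_xy))
  matched <- 0L
  for (i in seq_len(nrow(locs))) {
    d2 <- (truth_xy[, 1] - locs$x_px[i])^2 + (truth_xy[, 2] - locs$y_px[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius_px^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = sum(used) / nrow(truth_xy), precision = matched / nrow(locs))
}
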