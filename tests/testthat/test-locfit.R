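# Background estimation, candidate detection, sub-pixel Gaussian fitting,
# and the full detect/fit/subtract localization loop.

test_that("median background is robust to isolated bright pixels and spots", {
  flat <- matrix(7, 32, 32)
  expect_equal(estimate_background(flat, 5), flat, tolerance = 1e-6)

  hot <- flat
  hot[16, 16] <- 1000
  bg <- estimate_background(hot, 5)
  expect_equal(bg[16, 16], 7, tolerance = 0.01)

  spot <- flat + render_single_spot(15.5, 16.5, sigma = 1.3, photons = 2000,
                                    shape = c(32L, 32L))
  peak <- max(spot - flat)
  bg2 <- estimate_background(spot, 11)
  expect_lt(max(abs(bg2 - flat)), 0.1 * peak)

  expect_error(estimate_background(flat, 4), "odd")
})

test_that("candidate detection finds isolated spots at their pixel positions", {
  frame <- matrix(0, 48, 48) +
    render_single_spot(12, 20, 1.3, 800, c(48L, 48L)) +
    render_single_spot(30, 20, 1.3, 600, c(48L, 48L))
  cand <- detect_candidates(frame, matrix(0, 48, 48), k_sigma = 5)
  expect_identical(nrow(cand), 2L)
  expect_setequal(cand$x_px, c(12L, 30L))
  expect_true(all(cand$y_px == 20L))
})

test_that("false positives on pure noise are rare at a 5-sigma threshold", {
  # Monte-Carlo oracle: count detections on Gaussian-noise-only frames
  set.seed(90)
  total_fp <- 0L
  for (i in 1:30) {
    fr <- matrix(rnorm(256 * 256, 100, 3), 256, 256)
    bg <- matrix(100, 256, 256)
    total_fp <- total_fp + nrow(detect_candidates(fr, bg, k_sigma = 5))
  }
  # < 1 expected false positive per 512^2 frame => < 7.5 over 30 quarter-frames
  expect_lt(total_fp, 8L)
})

test_that("spots below threshold are not detected", {
  set.seed(91)
  noise_sd <- 3
  fr <- matrix(rnorm(64 * 64, 50, noise_sd), 64, 64) +
    render_single_spot(32, 32, 1.3, 2 * noise_sd * 2 * pi * 1.3^2, c(64L, 64L))
  cand <- detect_candidates(fr, matrix(50, 64, 64), k_sigma = 5)
  if (nrow(cand)) {
    expect_true(all((cand$x_px - 32)^2 + (cand$y_px - 32)^2 > 9))
  } else {
    expect_identical(nrow(cand), 0L)
  }
})

test_that("noiseless Gaussian fits recover sub-pixel positions to 0.02 px", {
  frame <- render_single_spot(10.30, 12.70, 1.3, 1000, c(24L, 24L))
  fit <- fit_spot(frame, matrix(0, 24, 24), peak = c(10, 13), fixed_sigma = 1.3)
  expect_true(fit$ok)
  expect_lt(abs(fit$x_px - 10.30), 0.02)
  expect_lt(abs(fit$y_px - 12.70), 0.02)
  expect_equal(fit$photons, 1000, tolerance = 0.01)

  # exact pixel center: symmetric, so sub-pixel offsets vanish
  frame2 <- render_single_spot(12, 12, 1.3, 1000, c(24L, 24L))
  fit2 <- fit_spot(frame2, matrix(0, 24, 24), peak = c(12, 12), fixed_sigma = 1.3)
  expect_lt(abs(fit2$x_px - 12), 1e-6)
  expect_lt(abs(fit2$y_px - 12), 1e-6)
})

test_that("localization precision tracks the photon-count scaling bound", {
  set.seed(92)
  sigma <- 1.3; N <- 500; bgl <- 5
  errs <- replicate(200, {
    lam <- render_single_spot(11.3, 11.6, sigma, N, c(23L, 23L), offset = bgl)
    fr <- matrix(rpois(length(lam), lam), nrow(lam))
    fit <- fit_spot(fr, matrix(bgl, 23, 23), peak = c(11, 12), fixed_sigma = sigma)
    if (isTRUE(fit$ok)) sqrt((fit$x_px - 11.3)^2 + (fit$y_px - 11.6)^2) else NA
  })
  rmse <- sqrt(mean(errs^2, na.rm = TRUE))
  bound <- sigma / sqrt(N)          # per-axis shot-noise scaling
  expect_lt(rmse, 2 * sqrt(2) * bound)  # 2x the bound on the 2-D error
})

test_that("fit rejections carry their reason", {
  frame <- render_single_spot(12, 12, 1.3, -500, c(24L, 24L))
  fit <- fit_spot(frame, matrix(0, 24, 24), peak = c(12, 12), fixed_sigma = 1.3)
  expect_false(fit$ok)
  expect_true(fit$reason %in% c("negative-amplitude", "diverged", "out-of-roi"))
})

test_that("an empty movie localizes to an empty table", {
  st <- frame_stack(array(0, c(32, 32, 3)))
  locs <- localize_stack(st)
  expect_identical(nrow(locs), 0L)
  expect_named(locs, c("frame", "x_px", "y_px", "photons", "sigma_px",
                       "offset", "rss"))
})

test_that("overlapping emitters 3 px apart are both recovered accurately", {
  frame <- matrix(2, 32, 32) +
    render_single_spot(14.2, 16.0, 1.3, 1500, c(32L, 32L)) +
    render_single_spot(17.2, 16.0, 1.3, 1500, c(32L, 32L))
  st <- frame_stack(array(frame, c(32, 32, 1)))
  locs <- localize_stack(st, localize_params(k_sigma = 5, refine_passes = 2))
  expect_identical(nrow(locs), 2L)
  o <- order(locs$x_px)
  expect_lt(abs(locs$x_px[o[1]] - 14.2), 0.2)
  expect_lt(abs(locs$x_px[o[2]] - 17.2), 0.2)
  expect_lt(max(abs(locs$y_px - 16.0)), 0.2)
})

test_that("sparse high-SNR movies localize with near-perfect recall/precision", {
  truth <- simulation_truth(list(population_spec(1, Inf, TRUE)),
                            arrival_rate_fibril = 0, arrival_rate_bg = 0,
                            n_frames = 2, image_shape = c(128L, 128L),
                            photons_per_frame = 2000, bg_photons_px = 5,
                            read_noise = 1, seed = 17)
  set.seed(17)
  n_emit <- 50
  xy <- cbind(runif(n_emit, 6, 121), runif(n_emit, 6, 121))
  # enforce >= 6 px separation so emitters are resolvable
  keep <- rep(TRUE, n_emit)
  for (i in 1:(n_emit - 1)) {
    if (!keep[i]) next
    j <- (i + 1):n_emit
    keep[j[(xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2 < 36]] <- FALSE
  }
  xy <- xy[keep, , drop = FALSE]
  ev <- data.frame(x_px = xy[, 1], y_px = xy[, 2], start_frame = 0L,
                   true_dwell_s = Inf, observed_dwell_s = 10,
                   dwell_frames = 2L, population_id = 1L, region = "background")
  st <- render_movie(ev, truth)
  locs <- localize_stack(st)
  for (f in 0:1) {
    m <- match_localizations(locs[locs$frame == f, ], xy, radius_px = 1)
    expect_gte(m$recall, 0.99)
    expect_gte(m$precision, 0.99)
  }
})

test_that("median localization error shrinks as the photon budget grows", {
  med_err <- sapply(c(200, 800, 3200), function(N) {
    truth <- simulation_truth(list(population_spec(1, Inf, TRUE)),
                              arrival_rate_fibril = 0, arrival_rate_bg = 0,
                              n_frames = 6, image_shape = c(48L, 48L),
                              photons_per_frame = N, bg_photons_px = 5,
                              read_noise = 1, seed = 23)
    ev <- data.frame(x_px = c(14.3, 33.6), y_px = c(30.2, 15.8),
                     start_frame = 0L, true_dwell_s = Inf,
                     observed_dwell_s = 10, dwell_frames = 6L,
                     population_id = 1L, region = "background")
    st <- render_movie(ev, truth)
    locs <- localize_stack(st)
    err <- apply(locs, 1, function(r)
      sqrt(min((ev$x_px - as.numeric(r["x_px"]))^2 +
               (ev$y_px - as.numeric(r["y_px"]))^2)))
    median(err)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("localization is deterministic and bounded by candidates x rounds", {
  truth <- simulation_truth(list(population_spec(1, Inf, TRUE)),
                            arrival_rate_fibril = 0, arrival_rate_bg = 0,
                            n_frames = 2, image_shape = c(64L, 64L),
                            photons_per_frame = 1000, bg_photons_px = 5, seed = 29)
  ev <- data.frame(x_px = c(20.5, 40.2, 31.7), y_px = c(20.1, 44.9, 12.4),
                   start_frame = 0L, true_dwell_s = Inf, observed_dwell_s = 10,
                   dwell_frames = 2L, population_id = 1L, region = "background")
  st <- render_movie(ev, truth)
  l1 <- localize_stack(st)
  l2 <- localize_stack(st)
  expect_identical(l1, l2)
  expect_lte(nrow(l1), 2 * 3 * localize_params()$max_subtraction_rounds)
})
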