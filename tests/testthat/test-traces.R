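# Trace analysis: ROI masking, trace extraction, dF - F0 baseline,
# peak frequency, supra-threshold event detection.

test_that("ROI masking covers a flashing blob and nothing else", {
  ny <- 40; nx <- 40; nt <- 20
  movie <- array(5, c(ny, nx, nt))
  g <- expand.grid(i = 1:ny, j = 1:nx)
  blob <- matrix((g$i - 20)^2 + (g$j - 25)^2 <= 6^2, ny, nx)
  for (k in seq(2, nt, by = 3))
    movie[, , k] <- movie[, , k] + 100 * blob
  mask <- roi_mask_from_movie(movie)
  expect_identical(mask, blob)
  # threshold equals exhaustive Kapur enumeration on the projection
  mip <- apply(movie, c(1, 2), max)
  expect_identical(mip > oracle_kapur(mip), blob)

  expect_error(roi_mask_from_movie(array(3, c(10, 10, 5))), "degenerate")
})

test_that("mask area is monotone non-increasing in the size filter", {
  set.seed(8)
  movie <- array(rlnorm(30 * 30 * 10, 1, 0.5), c(30, 30, 10))
  movie[10:20, 10:20, ] <- movie[10:20, 10:20, ] + 50
  areas <- vapply(c(1, 5, 20, 60, 200), function(ms)
    sum(roi_mask_from_movie(movie, min_size_px = ms)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("trace extraction is a masked mean and is linear", {
  movie <- array(4, c(12, 12, 6))
  mask <- matrix(FALSE, 12, 12)
  mask[3:5, 3:5] <- TRUE
  tr <- extract_trace(movie, mask)
  expect_true(all(tr$value == 4))
  expect_equal(nrow(tr), 6)
  expect_equal(diff(tr$time_s)[1], 0.78)

  set.seed(2)
  movie2 <- array(runif(12 * 12 * 6), c(12, 12, 6))
  one <- matrix(FALSE, 12, 12)
  one[7, 9] <- TRUE
  expect_equal(extract_trace(movie2, one)$value, movie2[7, 9, ])
  expect_equal(extract_trace(3 * movie2, mask)$value,
               3 * extract_trace(movie2, mask)$value)
  expect_error(extract_trace(movie2, matrix(FALSE, 12, 12)), "empty mask")
})

test_that("baseline correction recovers a zero baseline", {
  const <- rq_trace(0:49 * 0.78, rep(42, 50))
  for (mode in c("percentile", "initial"))
    expect_true(all(baseline_correct(const, mode)$value == 0))

  # baseline + sparse transients: percentile F0 equals the true baseline
  tr <- make_gcamp_trace(300, peak_times = c(50, 150, 250), noise_sd = 0,
                         baseline = 80)
  bc <- baseline_correct(tr)
  expect_equal(attr(bc, "f0"), 80)
  expect_equal(min(abs(bc$value)), 0)
  expect_error(baseline_correct(tr, "nonsense"))
})

test_that("peak frequency: flat traces, exact noise-free recovery, limits", {
  flat <- rq_trace(0:99 * 0.78, rep(0, 100))
  pk <- peak_frequency(flat)
  expect_equal(pk$peak_count, 0)
  expect_equal(pk$frequency_per_min, 0)

  tr <- make_gcamp_trace(600, peak_times = seq(25, 575, length.out = 12),
                         noise_sd = 0)
  pk12 <- peak_frequency(baseline_correct(tr))
  expect_equal(pk12$peak_count, 12)
  expect_equal(pk12$frequency_per_min, 1.2)

  # two transients closer than one sample merge into one peak
  tr2 <- make_gcamp_trace(60, peak_times = c(30, 30.3), noise_sd = 0)
  expect_equal(peak_frequency(baseline_correct(tr2))$peak_count, 1)
})

test_that("peak recovery stays exact at signal-to-noise 5", {
  tr <- make_gcamp_trace(600, peak_times = seq(25, 575, length.out = 12),
                         noise_sd = 10, seed = 1)   # amplitude 50 -> SNR 5
  pk <- peak_frequency(baseline_correct(tr))
  expect_equal(pk$peak_count, 12)
  expect_equal(pk$frequency_per_min, 1.2)
})

test_that("event detection: rectangle AUC, spike trains, thresholds", {
  t <- seq(0, 2, by = 0.001)
  v <- rep(-70, length(t))
  v[t >= 0.5 & t <= 0.6] <- -20
  ev <- detect_events(rq_trace(t, v, kind = "voltage"))
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$auc_mVs, 5)           # 50 mV x 0.1 s
  expect_equal(ev$baseline_mV, -70)

  # never above threshold
  expect_equal(nrow(detect_events(rq_trace(t, rep(-50, length(t)),
                                           kind = "voltage"))$events), 0)

  # synthetic spike train: n events, AUC within 5% of the analytic integral
  tr <- make_voltage_trace(10, spike_times = seq(0.5, 9.5, by = 1), seed = 1)
  ev2 <- detect_events(tr)
  expect_equal(nrow(ev2$events), 10)
  expect_true(all(abs(ev2$events$auc_mVs - attr(tr, "spike_auc_true_mVs")) /
                    attr(tr, "spike_auc_true_mVs") < 0.05))
})

test_that("event count is monotone in threshold; AUC scales with amplitude", {
  # monotonicity holds for unimodal (noise-free) spikes; with noise a run
  # can split, which is a sampling artefact, not a property of the detector
  tr <- make_voltage_trace(20, spike_times = seq(1, 19, by = 2),
                           rmp_mV = -60, spike_peak_mV = -10, noise_sd = 0,
                           seed = 3)
  counts <- vapply(c(-50, -35, -20, -12, -5), function(th)
    nrow(detect_events(tr, threshold_mV = th)$events), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # adding a constant shifts nothing after the baseline step
  tr2 <- tr
  tr2$value <- tr$value + 7
  ev <- detect_events(tr, threshold_mV = -35)
  ev2 <- detect_events(tr2, threshold_mV = -35 + 7)
  expect_equal(ev2$events$auc_mVs, ev$events$auc_mVs, tolerance = 1e-9)

  # fixed shape, doubled amplitude above baseline -> doubled AUC
  mk <- function(a) {
    tt <- seq(0, 4, by = 1e-3)
    rq_trace(tt, -70 + a * exp(-0.5 * ((tt - 2) / 0.02)^2), kind = "voltage")
  }
  auc1 <- detect_events(mk(40), baseline_mode = -70)$events$auc_mVs
  auc2 <- detect_events(mk(80), baseline_mode = -70)$events$auc_mVs
  expect_equal(auc2 / auc1, 2, tolerance = 1e-6)
})
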