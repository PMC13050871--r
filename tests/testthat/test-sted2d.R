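# 2D-STED routine: blur, maximum-entropy threshold, watershed, size filter
# and ellipse fit, paired-area correlation.

test_that("gaussian blur preserves constants, impulses and total intensity", {
  const <- sted_frame(matrix(7, 21, 21))
  expect_equal(gaussian_blur(const)$intensity, const$intensity)

  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 1
  out <- gaussian_blur(sted_frame(imp), sigma_px = 1)$intensity
  expect_equal(out, oracle_gauss_blur_2d(imp, 1), tolerance = 1e-6)
  expect_lt(abs(sum(out) - 1), 1e-9)

  expect_error(gaussian_blur(sted_frame(imp), sigma_px = 0))
})

test_that("maximum-entropy threshold separates two-level frames", {
  m <- matrix(10, 30, 30)
  m[1:3, ] <- 200
  thr <- max_entropy_threshold(sted_frame(m))
  expect_gte(thr, 10)
  expect_lt(thr, 200)
  expect_identical(m > thr, m == 200)
  expect_error(max_entropy_threshold(sted_frame(matrix(5, 10, 10))),
               "degenerate")
})

test_that("maximum-entropy threshold equals exhaustive Kapur enumeration", {
  for (s in c(42, 7, 101)) {
    set.seed(s)
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    expect_equal(max_entropy_threshold(sted_frame(img)), oracle_kapur(img))
  }
  # continuous-valued frame as well
  set.seed(11)
  img <- matrix(rlnorm(40 * 40, 2, 1), 40, 40)
  expect_equal(max_entropy_threshold(sted_frame(img)), oracle_kapur(img))
})

test_that("watershed splits touching discs and partitions the mask", {
  g <- expand.grid(i = 1:60, j = 1:60)
  two <- matrix(sqrt((g$i - 30)^2 + (g$j - 22)^2) <= 10 |
                  sqrt((g$i - 30)^2 + (g$j - 38)^2) <= 10, 60, 60)
  lab <- watershed_split(two)
  expect_equal(length(setdiff(unique(c(lab)), 0L)), 2)
  expect_true(lab[30, 22] != lab[30, 38])
  expect_true(all(lab[30, 22] > 0, lab[30, 38] > 0))
  # distance-transform oracle: both disc centres are strict maxima regions
  edt <- oracle_edt_2d(two)
  expect_gte(edt[30, 22], 9)
  expect_gte(edt[30, 38], 9)

  one <- matrix(sqrt((g$i - 30)^2 + (g$j - 30)^2) <= 10, 60, 60)
  expect_equal(length(setdiff(unique(c(watershed_split(one))), 0L)), 1)

  empty <- matrix(FALSE, 20, 20)
  expect_true(all(watershed_split(empty) == 0L))
})

test_that("watershed labels partition arbitrary masks", {
  for (s in 1:5) {
    m <- random_blob_mask(s)
    lab <- watershed_split(m)
    expect_identical(lab > 0, m)          # union = mask, labels disjoint
    ids <- setdiff(unique(c(lab)), 0L)
    expect_identical(sort(ids), seq_along(ids))  # compact labels
  }
})

test_that("size filter is strictly 'larger than' and the disc fit is round", {
  # 50-px and 51-px objects: only the 51-px one survives
  m <- matrix(0L, 40, 80)
  m[1:5, 1:10] <- 1L    # 50 px
  m[20:22, 30:46] <- 2L # 51 px
  fr <- sted_frame(matrix(1, 40, 80), pixel_size_um = 0.015)
  out <- filter_and_fit(m, fr, min_px = 50)
  expect_equal(out$label, 2L)
  expect_equal(out$pixel_count, 51L)

  # filled disc radius 20 px: near-circular, area within 2% of pi r^2
  g <- expand.grid(i = 1:64, j = 1:64)
  disc <- matrix((g$i - 32)^2 + (g$j - 32)^2 <= 20^2, 64, 64) * 1L
  fr2 <- sted_frame(matrix(1, 64, 64), pixel_size_um = 0.015)
  fit <- filter_and_fit(disc, fr2)
  expect_equal(nrow(fit), 1)
  expect_lt(abs(fit$major_um / fit$minor_um - 1), 0.05)
  expect_lt(abs(fit$area_um2 - pi * 20^2 * 0.015^2) /
              (pi * 20^2 * 0.015^2), 0.02)
  expect_gte(fit$major_um, fit$minor_um)

  expect_equal(nrow(filter_and_fit(matrix(0L, 10, 10), sted_frame(
    matrix(1, 10, 10)))), 0)
})

test_that("blur and watershed agree with an independent image library", {
  # EBImage as an external reference: impulse responses match up to its
  # narrower kernel truncation, and the two-disc split yields the same
  # label count
  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 1
  ours <- gaussian_blur(sted_frame(imp), sigma_px = 2)$intensity
  theirs <- EBImage::imageData(EBImage::gblur(EBImage::Image(imp),
                                              sigma = 2))
  expect_lt(max(abs(ours - theirs)), 0.02 * max(ours))

  g <- expand.grid(i = 1:60, j = 1:60)
  two <- matrix(as.numeric(sqrt((g$i - 30)^2 + (g$j - 22)^2) <= 10 |
                             sqrt((g$i - 30)^2 + (g$j - 38)^2) <= 10),
                60, 60)
  ref <- EBImage::watershed(EBImage::distmap(two))
  expect_equal(length(setdiff(unique(c(watershed_split(two > 0))), 0L)),
               max(ref))
})

test_that("paired-area correlation handles rank-perfect and degenerate input", {
  p <- data.frame(ctbp2_area_um2 = c(1, 2, 3, 5), cav13_area_um2 = c(2, 4, 5, 9))
  expect_equal(correlate_pairs(p)$spearman_rho, 1)
  p$cav13_area_um2 <- rev(p$cav13_area_um2)
  expect_equal(correlate_pairs(p)$spearman_rho, -1)
  expect_error(correlate_pairs(p[1:2, ]), "insufficient")
})

test_that("noise-free end-to-end recovery correlates with true areas", {
  sim <- make_sted_pair_frames(30, rho = 0.35, seed = 2, noise_sd = 0)
  rec <- t(vapply(sim$frames, function(fr) {
    rc <- analyze_sted_frame(fr$ctbp2)
    rv <- analyze_sted_frame(fr$cav13)
    p <- pair_areas(rc$regions, rv$regions)
    c(p$ctbp2_area_um2, p$cav13_area_um2)
  }, numeric(2)))
  tru <- sim$manifest$pairs_true
  expect_equal(nrow(rec), nrow(tru))   # one recovered pair per frame
  expect_gte(cor(rec[, 1], tru$ctbp2_area_um2, method = "spearman"), 0.95)
  expect_gte(cor(rec[, 2], tru$cav13_area_um2, method = "spearman"), 0.95)
})

test_that("Monte-Carlo rho recovery at the study's n recovers the target", {
  rhos <- vapply(1:200, function(s) {
    m <- make_sted_pair_frames(99, 0.35, seed = s, render = FALSE)$manifest
    correlate_pairs(data.frame(ctbp2_area_um2 = m$pairs_true$ctbp2_area_um2,
                               cav13_area_um2 = m$pairs_true$cav13_area_um2)
                    )$spearman_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.35), 0.05)
})
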