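# 3D surface reconstruction: background subtraction, detection, splitting,
# quality filtering, measurement, physical-unit correctness.

# Gaussian spots with an isotropic PHYSICAL sigma (no PSF anisotropy), so
# unit-handling properties can be asserted directly.
make_spot_stack <- function(centers, sigma_um = 0.1, peak = 100, bg = 0,
                            dims = c(x = 48, y = 48, z = 24)) {
  cfg_vs <- c(x = 0.08, y = 0.08, z = 0.2)
  arr <- array(bg, unname(dims[c("y", "x", "z")]))
  d <- dim(arr)
  ys <- (seq_len(d[1]) - 0.5) * cfg_vs["y"]
  xs <- (seq_len(d[2]) - 0.5) * cfg_vs["x"]
  zs <- (seq_len(d[3]) - 0.5) * cfg_vs["z"]
  for (r in seq_len(nrow(centers))) {
    ey <- exp(-0.5 * ((ys - centers[r, 2]) / sigma_um)^2)
    ex <- exp(-0.5 * ((xs - centers[r, 1]) / sigma_um)^2)
    ez <- exp(-0.5 * ((zs - centers[r, 3]) / sigma_um)^2)
    arr <- arr + peak * (ey %o% ex %o% ez)
  }
  image_stack(arr, cfg_vs)
}

test_that("local background subtraction removes constants and clips at 0", {
  st <- image_stack(array(13, c(16, 16, 8)))
  out <- local_background_subtract(st, 0.28)
  expect_true(all(out$intensity == 0))

  # narrow spot, background scale well above the spot size (caller's
  # responsibility per the contract)
  sim <- make_spot_stack(matrix(c(1.9, 1.9, 2.4), 1), sigma_um = 0.1,
                         peak = 100, bg = 50)
  out2 <- local_background_subtract(sim, 0.56)
  expect_gte(min(out2$intensity), 0)
  # spot peak preserved within 20% of (peak - background)
  expect_lt(abs(max(out2$intensity) - max(sim$intensity - 50)) /
              max(sim$intensity - 50), 0.2)
  # direct separable-convolution oracle for the background estimate
  sp <- c(0.08, 0.08, 0.2)
  bg_oracle <- sim$intensity
  for (ax in 1:3) {
    sig <- (0.56 / 2) / sp[ax]
    r <- max(1L, as.integer(ceiling(4 * sig)))
    kern <- exp(-((-r:r)^2) / (2 * sig^2))
    kern <- kern / sum(kern)
    d <- dim(bg_oracle)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(bg_oracle, perm)
    dp <- dim(x)
    dim(x) <- c(dp[1], prod(dp[-1]))
    out <- matrix(0, dp[1], ncol(x))
    refl <- function(i, n) {
      j <- (i - 1L) %% (2L * n)
      ifelse(j < n, j + 1L, 2L * n - j)
    }
    for (t in seq_along(kern))
      out <- out + kern[t] * x[refl(seq_len(dp[1]) + t - 1L - r, dp[1]), ,
                               drop = FALSE]
    dim(out) <- dp
    bg_oracle <- aperm(out, order(perm))
  }
  expect_equal(out2$intensity, pmax(sim$intensity - bg_oracle, 0),
               tolerance = 1e-9)
})

test_that("reconstruction recovers isolated noise-free puncta exactly", {
  cfg <- synth_config(n_ribbons = 20, engaged_fraction = 0,
                      poisson_noise = FALSE, read_noise_sd = 0,
                      vol_vox = c(x = 96, y = 96, z = 40), seed = 12)
  sim <- make_confocal_stack(cfg)
  p <- reconstruct(sim$stacks$ribbon, recon_profile("ribbon-wt"))
  tru <- subset(sim$manifest$puncta_true, channel == "ribbon")
  expect_equal(nrow(p), 20)
  dm <- outer(seq_len(nrow(tru)), seq_len(nrow(p)), Vectorize(function(i, j)
    sqrt((tru$x_um[i] - p$x_um[j])^2 + (tru$y_um[i] - p$y_um[j])^2 +
           (tru$z_um[i] - p$z_um[j])^2)))
  vox_diag <- sqrt(sum(c(0.08, 0.08, 0.2)^2))
  expect_true(all(apply(dm, 1, min) <= vox_diag))
})

test_that("split distance separates touching puncta, merges close ones", {
  prm <- recon_params(0.048, 0.280, 0.150)
  # two equal spots, centre separation 0.50 um (> split + 2*detail)
  two <- make_spot_stack(rbind(c(1.65, 1.9, 2.5), c(2.15, 1.9, 2.5)),
                         sigma_um = 0.12)
  p2 <- reconstruct(two, prm)
  expect_equal(nrow(p2), 2)
  # same spots merged at 0.12 um separation (< split distance)
  one <- make_spot_stack(rbind(c(1.84, 1.9, 2.5), c(1.96, 1.9, 2.5)),
                         sigma_um = 0.12)
  p1 <- reconstruct(one, prm)
  expect_equal(nrow(p1), 1)
})

test_that("background-only stacks reconstruct to an empty table", {
  sim <- make_confocal_stack(synth_config(n_ribbons = 0, seed = 6))
  p <- reconstruct(sim$stacks$ribbon, recon_profile("ribbon-wt"))
  expect_equal(nrow(p), 0)
})

test_that("measurement arithmetic, linearity and bounds checking", {
  raw <- image_stack(array(3, c(10, 10, 5)))
  vox <- cbind(i = 1:10, j = rep(4L, 10), k = rep(2L, 10))
  m <- measure_punctum(vox, raw)
  expect_equal(m$volume_um3, 10 * 0.08 * 0.08 * 0.2)
  expect_equal(m$integrated_intensity, 3 * 10)

  raw2 <- image_stack(2 * raw$intensity)
  m2 <- measure_punctum(vox, raw2)
  expect_equal(m2$integrated_intensity, 2 * m$integrated_intensity)
  expect_equal(m2$volume_um3, m$volume_um3)

  bad <- cbind(i = 11L, j = 1L, k = 1L)
  expect_error(measure_punctum(bad, raw), "bounds")
  expect_error(measure_punctum(vox[0, , drop = FALSE], raw), "empty")
})

test_that("anisotropic voxels still yield isotropic physical extents", {
  st <- make_spot_stack(matrix(c(1.9, 1.9, 2.4), 1), sigma_um = 0.15)
  p <- reconstruct(st, recon_params(0.048, 0.560, 0.150))
  expect_equal(nrow(p), 1)
  lab <- attr(p, "labels")
  vox <- punctum_voxels(lab, 1L)
  ext_x <- diff(range(vox[, "j"])) * 0.08
  ext_z <- diff(range(vox[, "k"])) * 0.2
  # equal within one z-step despite the 2.5x coarser z sampling
  expect_lt(abs(ext_x - ext_z), 0.25)
})

test_that("raising the quality threshold never increases the object count", {
  sim <- make_confocal_stack(synth_config(seed = 21))
  base <- recon_profile("ribbon-wt")
  counts <- vapply(c(0, 20, 60, 120, 200), function(q) {
    prm <- recon_params(0.048, 0.280, 0.150, quality_threshold = q)
    nrow(reconstruct(sim$stacks$ribbon, prm))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("returned puncta voxel sets are pairwise disjoint", {
  sim <- make_confocal_stack(synth_config(seed = 33))
  p <- reconstruct(sim$stacks$ribbon, recon_profile("ribbon-wt"))
  lab <- attr(p, "labels")
  expect_equal(sum(lab > 0), sum(p$n_vox))  # one label per voxel
  for (id in p$id)
    expect_equal(nrow(punctum_voxels(lab, id)), p$n_vox[p$id == id])
})

test_that("recovery on default (moderate-noise) stacks exceeds 90%", {
  hits <- 0
  total <- 0
  fps <- 0
  found <- 0
  for (s in c(7, 11)) {
    sim <- make_confocal_stack(synth_config(seed = s))
    for (ch in c("ribbon", "psd")) {
      prof <- recon_profile(if (ch == "ribbon") "ribbon-wt" else "psd-wt")
      p <- reconstruct(sim$stacks[[ch]], prof)
      tru <- subset(sim$manifest$puncta_true, channel == ch)
      dm <- outer(seq_len(nrow(tru)), seq_len(nrow(p)),
                  Vectorize(function(i, j)
                    sqrt((tru$x_um[i] - p$x_um[j])^2 +
                           (tru$y_um[i] - p$y_um[j])^2 +
                           (tru$z_um[i] - p$z_um[j])^2)))
      hits <- hits + sum(apply(dm, 1, min) < 0.25)
      total <- total + nrow(tru)
      fps <- fps + sum(apply(dm, 2, min) >= 0.25)
      found <- found + nrow(p)
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(fps / found, 0.1)
})
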