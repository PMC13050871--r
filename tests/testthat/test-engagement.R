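# Engagement classification: surface distances, the strict 0.5 um rule,
# per-IHC normalization, invariances.

vox_at <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("i", "j", "k")
  m
}

# place voxel sets into a labelled array
lab_from <- function(dims, sets) {
  lab <- array(0L, dims)
  for (s in seq_along(sets)) lab[sets[[s]]] <- s
  lab
}

test_that("surface distance: overlap, axis-aligned gap, empty input", {
  a <- vox_at(c(5L, 5L, 3L), c(5L, 6L, 3L))
  expect_equal(surface_distance(a, a), 0)
  b <- vox_at(c(5L, 11L, 3L))        # 5 x-voxels away from (5,6,3)
  expect_equal(surface_distance(a, b), 5 * 0.08)
  expect_equal(surface_distance(a, vox_at(c(6L, 6L, 3L))), 0)  # adjacent
  expect_error(surface_distance(a[0, , drop = FALSE], b), "empty")
})

test_that("surface distance matches the O(n^2) brute-force oracle", {
  vs <- c(x = 0.08, y = 0.08, z = 0.2)
  set.seed(14)
  for (rep in 1:10) {
    mk <- function() {
      c0 <- sample(3:10, 3)
      n <- sample(1:25, 1)
      u <- unique(cbind(i = pmax(1L, c0[1] + sample(-2:2, n, TRUE)),
                        j = pmax(1L, c0[2] + sample(-2:2, n, TRUE)),
                        k = pmax(1L, c0[3] + sample(-2:2, n, TRUE))))
      u
    }
    va <- mk()
    vb <- mk()
    expect_equal(surface_distance(va, vb, vs),
                 oracle_surface_distance(va, vb, vs), tolerance = 1e-12)
  }
})

test_that("classification applies the strict < 0.5 um rule", {
  vs <- c(x = 0.1, y = 0.1, z = 0.1)
  dims <- c(20L, 40L, 5L)
  rib <- lab_from(dims, list(vox_at(c(10L, 5L, 3L))))
  # PSD at 4 voxels (0.4 um), 6 voxels (0.6), exactly 5 voxels (0.5)
  for (cse in list(list(4L, "synaptic"), list(6L, "cytoplasmic"),
                   list(5L, "cytoplasmic"))) {
    psd <- lab_from(dims, list(vox_at(c(10L, 5L + cse[[1]], 3L))))
    asg <- classify_ribbons(rib, psd, vs)
    expect_equal(asg$class, cse[[2]])
  }
  # no PSDs: everything cytoplasmic, no nearest id
  asg0 <- classify_ribbons(rib, array(0L, dims), vs)
  expect_equal(asg0$class, "cytoplasmic")
  expect_true(is.na(asg0$nearest_psd_id))
})

test_that("lowering the cutoff never increases the synaptic count", {
  sim <- make_confocal_stack(synth_config(n_ribbons = 12, seed = 4,
                                          poisson_noise = FALSE,
                                          read_noise_sd = 0))
  cuts <- c(0.1, 0.3, 0.5, 0.8, 1.2)
  ns <- vapply(cuts, function(cu)
    sum(classify_ribbons(sim$labels$ribbon, sim$labels$psd,
                         cutoff_um = cu)$class == "synaptic"), numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("classification is invariant to relabeling and translation", {
  sim <- make_confocal_stack(synth_config(n_ribbons = 8, seed = 5,
                                          poisson_noise = FALSE,
                                          read_noise_sd = 0))
  base <- classify_ribbons(sim$labels$ribbon, sim$labels$psd)

  # permute PSD label ids: classes and distances unchanged per ribbon
  perm <- sample(8)
  psd2 <- array(0L, dim(sim$labels$psd))
  for (id in 1:8) psd2[sim$labels$psd == id] <- perm[id]
  rel <- classify_ribbons(sim$labels$ribbon, psd2)
  expect_equal(rel$surface_distance_um, base$surface_distance_um)
  expect_equal(rel$class, base$class)
  expect_equal(rel$nearest_psd_id, perm[base$nearest_psd_id])

  # rigid translation of the whole volume by (2, 3, 1) voxels
  shift <- function(lab, di, dj, dk) {
    d <- dim(lab)
    out <- array(0L, d + c(di, dj, dk))
    out[(1:d[1]) + di, (1:d[2]) + dj, (1:d[3]) + dk] <- lab
    out
  }
  tra <- classify_ribbons(shift(sim$labels$ribbon, 2, 3, 1),
                          shift(sim$labels$psd, 2, 3, 1))
  expect_equal(tra$surface_distance_um, base$surface_distance_um)
  expect_equal(tra$class, base$class)
})

test_that("per-IHC summary normalizes counts", {
  asg <- data.frame(class = c(rep("synaptic", 30), rep("cytoplasmic", 6)))
  s <- summarize_engagement(asg, 3)
  expect_equal(s$synaptic_per_ihc, 10)
  expect_equal(s$cytoplasmic_per_ihc, 2)
  s0 <- summarize_engagement(asg[0, , drop = FALSE], 2)
  expect_equal(s0$n_synaptic + s0$n_cytoplasmic, 0)
  expect_equal(s0$synaptic_per_ihc, 0)
  expect_error(summarize_engagement(asg, 0), "n_ihc")
})

test_that("noise-free end-to-end confusion matrix is diagonal", {
  cfg <- synth_config(vol_vox = c(x = 110, y = 110, z = 48), n_ribbons = 50,
                      engaged_fraction = 0.8, poisson_noise = FALSE,
                      read_noise_sd = 0, seed = 5)
  sim <- make_confocal_stack(cfg)
  # generator manifest: exactly 40 engaged / 10 cytoplasmic
  expect_equal(sum(sim$manifest$pairs_true$engaged), 40)
  expect_equal(sum(!sim$manifest$pairs_true$engaged), 10)

  asg <- classify_ribbons(sim$labels$ribbon, sim$labels$psd,
                          cfg$voxel_size_um)
  expect_equal(asg$class == "synaptic", sim$manifest$pairs_true$engaged)
  s <- summarize_engagement(asg, sim$manifest$n_ihc)
  expect_equal(s$n_synaptic, 40)
  expect_equal(s$n_cytoplasmic, 10)
})
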