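# Synthetic-data generator: every input the pipeline consumes, with
# ground-truth manifests, so all downstream stages are testable without any
# raw recordings.
#
# The confocal generator emulates two-colour ribbon/PSD z-stacks at
# 80 x 80 x 200 nm voxels; the STED generator emulates paired 1 x 1 um
# CtBP2 / Cav1.3 crops at 15 nm pixels; the trace generators emulate GCaMP
# time-lapse (0.78 s sampling) and IHC current-clamp recordings.

#' Configuration for the synthetic confocal generator
#'
#' Defaults describe the emulated study conditions: a two-channel
#' (ribbon marker / PSD marker) confocal sub-volume of an organ-of-Corti
#' whole-mount plus a cell-context channel, with most ribbons synaptically
#' engaged.
#'
#' @param vol_vox volume shape in voxels, named `c(x=, y=, z=)`.
#' @param voxel_size_um physical voxel size `c(x=, y=, z=)` in um.
#' @param n_ribbons ribbons to place (one PSD is generated per ribbon).
#' @param engaged_fraction fraction of ribbons whose PSD is placed within
#'   the 0.5 um engagement distance, in `[0, 1]`.
#' @param ribbon_radius_meanlog,ribbon_radius_sdlog log-normal parameters of
#'   ribbon radius (um).
#' @param psd_radius_meanlog,psd_radius_sdlog log-normal parameters of PSD
#'   radius (um).
#' @param peak_meanlog,peak_sdlog log-normal parameters of spot peak
#'   intensity (a.u.).
#' @param background constant background level (a.u.).
#' @param poisson_noise apply Poisson (shot) noise to signal + background.
#' @param read_noise_sd additive Gaussian read-noise SD (a.u.).
#' @param psf_sigma_um PSF sigma per axis `c(x=, y=, z=)` in um; combined in
#'   quadrature with the spot's own Gaussian extent (sigma = radius / 2).
#' @param min_sep_um minimum centre separation within a channel (um);
#'   placement is by rejection sampling and fails explicitly after
#'   `max_attempts` draws.
#' @param engaged_gap_um,cyto_gap_um ranges (um) from which the
#'   surface-to-surface gap of engaged / cytoplasmic pairs is drawn. Kept
#'   clear of the 0.5 um rule by more than the voxelization error.
#' @param n_ihc number of inner hair cells in the emulated ROI (recorded in
#'   the manifest; the study counts cells manually).
#' @param max_attempts rejection-sampling budget per object.
#' @param seed RNG seed.
#' @return list of class `rq_synth_config`.
#' @export
synth_config <- function(vol_vox = c(x = 72, y = 72, z = 36),
                         voxel_size_um = c(x = 0.08, y = 0.08, z = 0.2),
                         n_ribbons = 16,
                         engaged_fraction = 0.8,
                         ribbon_radius_meanlog = log(0.18),
                         ribbon_radius_sdlog = 0.2,
                         psd_radius_meanlog = log(0.22),
                         psd_radius_sdlog = 0.2,
                         peak_meanlog = log(150),
                         peak_sdlog = 0.25,
                         background = 20,
                         poisson_noise = TRUE,
                         read_noise_sd = 3,
                         psf_sigma_um = c(x = 0.09, y = 0.09, z = 0.3),
                         min_sep_um = 0.6,
                         engaged_gap_um = c(0.05, 0.25),
                         cyto_gap_um = c(0.7, 1.5),
                         n_ihc = 3,
                         max_attempts = 10000L,
                         seed = 1L) {
  cfg <- list(vol_vox = round(vol_vox), voxel_size_um = voxel_size_um,
              n_ribbons = as.integer(n_ribbons),
              engaged_fraction = engaged_fraction,
              ribbon_radius_meanlog = ribbon_radius_meanlog,
              ribbon_radius_sdlog = ribbon_radius_sdlog,
              psd_radius_meanlog = psd_radius_meanlog,
              psd_radius_sdlog = psd_radius_sdlog,
              peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
              background = background, poisson_noise = poisson_noise,
              read_noise_sd = read_noise_sd, psf_sigma_um = psf_sigma_um,
              min_sep_um = min_sep_um, engaged_gap_um = engaged_gap_um,
              cyto_gap_um = cyto_gap_um, n_ihc = as.integer(n_ihc),
              max_attempts = as.integer(max_attempts),
              seed = as.integer(seed))
  .validate_synth_config(cfg)
  structure(cfg, class = "rq_synth_config")
}

.validate_synth_config <- function(cfg) {
  if (any(cfg$vol_vox < 1)) stop("volume shape must be positive")
  .check_voxel_size(cfg$voxel_size_um)
  if (cfg$n_ribbons < 0) stop("n_ribbons must be >= 0")
  if (cfg$engaged_fraction < 0 || cfg$engaged_fraction > 1)
    stop("engaged_fraction must lie in [0, 1]")
  if (cfg$background < 0 || cfg$read_noise_sd < 0)
    stop("background and noise levels must be >= 0")
  if (any(cfg$psf_sigma_um < 0)) stop("PSF sigma must be >= 0")
  if (cfg$min_sep_um <= 0) stop("min_sep_um must be > 0")
  if (cfg$n_ihc < 1) stop("n_ihc must be >= 1")
  invisible(cfg)
}

# physical box size c(x, y, z) in um
.box_um <- function(cfg) {
  unname(cfg$vol_vox[c("x", "y", "z")] *
           cfg$voxel_size_um[c("x", "y", "z")])
}

# render one additive Gaussian spot into arr (dims ny, nx, nz);
# center c(x,y,z) um, sigma c(x,y,z) um
.render_spot <- function(arr, voxel_size, center, sigma, peak) {
  d <- dim(arr)
  ax_centers <- list(
    y = (seq_len(d[1]) - 0.5) * voxel_size["y"],
    x = (seq_len(d[2]) - 0.5) * voxel_size["x"],
    z = (seq_len(d[3]) - 0.5) * voxel_size["z"])
  win <- function(cc, sig, coords) {
    which(abs(coords - cc) <= 4.5 * sig + max(diff(coords[1:2]), 0))
  }
  iy <- win(center[2], sigma[2], ax_centers$y)
  ix <- win(center[1], sigma[1], ax_centers$x)
  iz <- win(center[3], sigma[3], ax_centers$z)
  if (!length(iy) || !length(ix) || !length(iz)) return(arr)
  ey <- exp(-0.5 * ((ax_centers$y[iy] - center[2]) / sigma[2])^2)
  ex <- exp(-0.5 * ((ax_centers$x[ix] - center[1]) / sigma[1])^2)
  ez <- exp(-0.5 * ((ax_centers$z[iz] - center[3]) / sigma[3])^2)
  spot <- peak * (ey %o% ex %o% ez)
  arr[iy, ix, iz] <- arr[iy, ix, iz] + spot
  arr
}

# voxelize a sphere: label voxels whose centre lies within radius of center;
# the nearest voxel is always included so objects are never empty
.render_sphere <- function(lab, voxel_size, center, radius, id) {
  d <- dim(lab)
  cy <- (seq_len(d[1]) - 0.5) * voxel_size["y"]
  cx <- (seq_len(d[2]) - 0.5) * voxel_size["x"]
  cz <- (seq_len(d[3]) - 0.5) * voxel_size["z"]
  iy <- which(abs(cy - center[2]) <= radius + voxel_size["y"])
  ix <- which(abs(cx - center[1]) <= radius + voxel_size["x"])
  iz <- which(abs(cz - center[3]) <= radius + voxel_size["z"])
  dy2 <- (cy[iy] - center[2])^2
  dx2 <- (cx[ix] - center[1])^2
  dz2 <- (cz[iz] - center[3])^2
  d2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
  inside <- d2 <= radius^2
  if (!any(inside)) inside[which.min(d2)] <- TRUE
  sub <- lab[iy, ix, iz, drop = FALSE]
  sub[inside] <- id
  lab[iy, ix, iz] <- sub
  lab
}

#' Generate a synthetic confocal stack with ground truth
#'
#' Places ribbon and PSD puncta as Gaussian spots in a three-channel stack
#' (ribbon marker, PSD marker, cell context) and records a ground-truth
#' manifest. Each ribbon is given one partner PSD whose surface gap is drawn
#' below the 0.5 um engagement rule for the engaged subset and well above it
#' otherwise; the manifest's engagement flags are computed from the rendered
#' (pre-noise) label volumes by exact voxel surface distance, so they agree
#' with the classifier's definition by construction.
#'
#' @param config an [synth_config()] object.
#' @return list of class `rq_confocal_sim` with elements `stacks` (named
#'   list of [image_stack()]: ribbon, psd, context), `labels` (integer label
#'   arrays for ribbon and PSD channels, pre-noise ground truth), and
#'   `manifest` (class `rq_manifest`).
#' @export
make_confocal_stack <- function(config = synth_config()) {
  .validate_synth_config(config)
  set.seed(config$seed)
  vs <- config$voxel_size_um[c("x", "y", "z")]
  dims <- unname(config$vol_vox[c("y", "x", "z")])
  box <- .box_um(config)
  n <- config$n_ribbons

  rib_r <- rlnorm(n, config$ribbon_radius_meanlog, config$ribbon_radius_sdlog)
  psd_r <- rlnorm(n, config$psd_radius_meanlog, config$psd_radius_sdlog)
  rib_peak <- rlnorm(n, config$peak_meanlog, config$peak_sdlog)
  psd_peak <- rlnorm(n, config$peak_meanlog, config$peak_sdlog)

  n_eng <- round(config$engaged_fraction * n)
  engaged <- rep(FALSE, n)
  if (n > 0 && n_eng > 0) engaged[sample.int(n, n_eng)] <- TRUE

  # margin keeps puncta (and most of their blur) inside the volume
  place_one <- function(radius, existing, min_sep) {
    margin <- radius + 0.15
    if (any(box - 2 * margin <= 0))
      stop("placement failure: volume too small for requested objects")
    for (a in seq_len(config$max_attempts)) {
      p <- margin + runif(3) * (box - 2 * margin)
      if (is.null(existing) || nrow(existing) == 0 ||
          all(sqrt(colSums((t(existing) - p)^2)) >= min_sep))
        return(p)
    }
    stop("placement failure: could not satisfy minimum separation")
  }

  rib_c <- matrix(NA_real_, n, 3)
  psd_c <- matrix(NA_real_, n, 3)
  if (n > 0) {
    for (i in seq_len(n))
      rib_c[i, ] <- place_one(rib_r[i], rib_c[seq_len(i - 1), , drop = FALSE],
                              config$min_sep_um)
    # PSD for ribbon i at a controlled surface gap; far from all other ribbons
    for (i in seq_len(n)) {
      gap_rng <- if (engaged[i]) config$engaged_gap_um else config$cyto_gap_um
      ok <- FALSE
      for (a in seq_len(config$max_attempts)) {
        gap <- runif(1, gap_rng[1], gap_rng[2])
        dist <- rib_r[i] + psd_r[i] + gap
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        p <- rib_c[i, ] + dist * u
        margin <- psd_r[i] + 0.15
        if (any(p < margin) || any(p > box - margin)) next
        prev <- psd_c[seq_len(i - 1), , drop = FALSE]
        if (nrow(prev) > 0 &&
            any(sqrt(colSums((t(prev) - p)^2)) < config$min_sep_um)) next
        # keep this PSD unambiguously far from every other ribbon
        other <- setdiff(seq_len(n), i)
        if (length(other)) {
          g_other <- sqrt(colSums((t(rib_c[other, , drop = FALSE]) - p)^2)) -
            psd_r[i] - rib_r[other]
          if (any(g_other < max(0.7, gap_rng[1]))) next
        }
        psd_c[i, ] <- p
        ok <- TRUE
        break
      }
      if (!ok) stop("placement failure: could not place partner PSD")
    }
  }

  # render label volumes (pre-noise ground truth) and intensity channels
  rib_lab <- array(0L, dims)
  psd_lab <- array(0L, dims)
  rib_img <- array(0, dims)
  psd_img <- array(0, dims)
  psf <- config$psf_sigma_um[c("x", "y", "z")]
  if (n > 0) {
    for (i in seq_len(n)) {
      rib_lab <- .render_sphere(rib_lab, vs, rib_c[i, ], rib_r[i], i)
      psd_lab <- .render_sphere(psd_lab, vs, psd_c[i, ], psd_r[i], i)
      sig_r <- sqrt((rib_r[i] / 2)^2 + psf^2)
      sig_p <- sqrt((psd_r[i] / 2)^2 + psf^2)
      rib_img <- .render_spot(rib_img, vs, rib_c[i, ], sig_r, rib_peak[i])
      psd_img <- .render_spot(psd_img, vs, psd_c[i, ], sig_p, psd_peak[i])
    }
  }
  # cell context: broad smooth blobs, one per IHC, along x
  ctx_img <- array(0, dims)
  if (config$n_ihc > 0) {
    for (m in seq_len(config$n_ihc)) {
      cc <- c(box[1] * (m - 0.5) / config$n_ihc, box[2] / 2, box[3] / 2)
      ctx_img <- .render_spot(ctx_img, vs, cc,
                              c(box[1] / (3 * config$n_ihc), box[2] / 3,
                                box[3] / 3), 60)
    }
  }

  add_noise <- function(img) {
    out <- img + config$background
    if (config$poisson_noise)
      out <- array(rpois(length(out), pmax(out, 0)), dim(out))
    if (config$read_noise_sd > 0)
      out <- out + array(rnorm(length(out), 0, config$read_noise_sd),
                         dim(out))
    pmax(out, 0)
  }

  stacks <- list(
    ribbon = image_stack(add_noise(rib_img), config$voxel_size_um, "ribbon"),
    psd = image_stack(add_noise(psd_img), config$voxel_size_um, "psd"),
    context = image_stack(add_noise(ctx_img), config$voxel_size_um,
                          "context"))

  # exact voxel-surface audit on the pre-noise label volumes
  pairs <- if (n > 0) {
    sp <- .spacing(stacks$ribbon)
    vox_r <- lapply(seq_len(n), function(i) .label_voxels(rib_lab, i))
    vox_p <- lapply(seq_len(n), function(i) .label_voxels(psd_lab, i))
    dmat <- matrix(NA_real_, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        dmat[i, j] <- .min_voxel_dist(vox_r[[i]], vox_p[[j]], sp)
    nearest <- apply(dmat, 1, which.min)
    sdist <- dmat[cbind(seq_len(n), nearest)]
    data.frame(ribbon = seq_len(n), psd = as.integer(nearest),
               center_distance_um =
                 sqrt(rowSums((rib_c - psd_c[nearest, , drop = FALSE])^2)),
               surface_distance_um = sdist,
               engaged = sdist < 0.5)
  } else {
    data.frame(ribbon = integer(), psd = integer(),
               center_distance_um = numeric(),
               surface_distance_um = numeric(), engaged = logical())
  }

  puncta <- if (n > 0) {
    rbind(
      data.frame(channel = "ribbon", index = seq_len(n),
                 x_um = rib_c[, 1], y_um = rib_c[, 2], z_um = rib_c[, 3],
                 radius_um = rib_r, peak = rib_peak),
      data.frame(channel = "psd", index = seq_len(n),
                 x_um = psd_c[, 1], y_um = psd_c[, 2], z_um = psd_c[, 3],
                 radius_um = psd_r, peak = psd_peak))
  } else {
    data.frame(channel = character(), index = integer(), x_um = numeric(),
               y_um = numeric(), z_um = numeric(), radius_um = numeric(),
               peak = numeric())
  }

  manifest <- structure(list(puncta_true = puncta, pairs_true = pairs,
                             n_ihc = config$n_ihc, rho_true = NA_real_,
                             spike_times_true = numeric(),
                             seed = config$seed),
                        class = "rq_manifest")
  structure(list(stacks = stacks,
                 labels = list(ribbon = rib_lab, psd = psd_lab),
                 manifest = manifest, config = config),
            class = "rq_confocal_sim")
}

# voxel (i, j, k) coordinates of one label as an integer matrix
.label_voxels <- function(lab, id) {
  w <- which(lab == id)
  d <- dim(lab)
  i <- (w - 1L) %% d[1L]
  rem <- (w - 1L) %/% d[1L]
  j <- rem %% d[2L]
  k <- rem %/% d[2L]
  cbind(i = as.integer(i + 1L), j = as.integer(j + 1L),
        k = as.integer(k + 1L))
}

#' Generate paired synthetic 2D-STED frames
#'
#' Each pair emulates a 1 x 1 um two-colour STED crop of one synapse: one
#' ribbon (CtBP2) blob and one calcium-channel (Cav1.3) blob whose true
#' areas are drawn from a Gaussian copula calibrated to a target Spearman
#' correlation (Pearson latent r = 2 sin(pi * rho / 6)).
#'
#' @param n_pairs number of synapse crops (>= 2).
#' @param rho target Spearman correlation of the true areas, in `[-1, 1]`.
#' @param seed RNG seed.
#' @param frame_px frame edge in pixels (67 px ~ 1 um at 15 nm pixels).
#' @param pixel_size_um pixel edge (um).
#' @param area_meanlog,area_sdlog log-normal parameters of true blob area
#'   (um^2), shared by both channels.
#' @param peak,background blob peak and background intensity (a.u.).
#' @param noise_sd additive Gaussian noise SD; 0 disables noise.
#' @param render rasterize the frames; `FALSE` returns the manifest only
#'   (identical area draws), for correlation calibration studies.
#' @return list of class `rq_sted_sim`: `frames` (list of pairs, each with
#'   `ctbp2` and `cav13` [sted_frame()]s; `NULL` when `render = FALSE`) and
#'   `manifest` with `pairs_true` (true areas in um^2) and `rho_true`.
#' @export
make_sted_pair_frames <- function(n_pairs, rho, seed = 1L,
                                  frame_px = 67L, pixel_size_um = 0.015,
                                  area_meanlog = log(0.040),
                                  area_sdlog = 0.35,
                                  peak = 150, background = 5,
                                  noise_sd = 0, render = TRUE) {
  if (n_pairs < 2) stop("n_pairs must be >= 2 (correlation undefined)")
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]")
  set.seed(seed)
  r <- 2 * sin(pi * rho / 6)
  z1 <- rnorm(n_pairs)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n_pairs)
  a1 <- qlnorm(pnorm(z1), area_meanlog, area_sdlog)
  a2 <- qlnorm(pnorm(z2), area_meanlog, area_sdlog)

  rasterize <- function(area_um2, channel) {
    r_um <- sqrt(area_um2 / pi)
    ext <- runif(1, 0.85, 1.18)   # area-preserving ellipticity
    a <- r_um * ext
    b <- r_um / ext
    th <- runif(1, 0, pi)
    cx <- (frame_px / 2 + runif(1, -3, 3)) * pixel_size_um
    cy <- (frame_px / 2 + runif(1, -3, 3)) * pixel_size_um
    xs <- (seq_len(frame_px) - 0.5) * pixel_size_um
    ys <- (seq_len(frame_px) - 0.5) * pixel_size_um
    gx <- matrix(xs, frame_px, frame_px, byrow = TRUE) - cx
    gy <- matrix(ys, frame_px, frame_px) - cy
    u <- cos(th) * gx + sin(th) * gy
    v <- -sin(th) * gx + cos(th) * gy
    q <- (u / a)^2 + (v / b)^2
    img <- background + peak * exp(-q^2)   # flat-top (super-Gaussian) blob
    if (noise_sd > 0)
      img <- img + matrix(rnorm(frame_px^2, 0, noise_sd),
                          frame_px, frame_px)
    sted_frame(pmax(img, 0), pixel_size_um, channel)
  }

  frames <- if (render) {
    lapply(seq_len(n_pairs), function(i)
      list(ctbp2 = rasterize(a1[i], "ctbp2"), cav13 = rasterize(a2[i], "cav13")))
  } else {
    NULL
  }
  manifest <- structure(
    list(pairs_true = data.frame(frame = seq_len(n_pairs),
                                 ctbp2_area_um2 = a1, cav13_area_um2 = a2),
         rho_true = rho, seed = as.integer(seed)),
    class = "rq_manifest")
  structure(list(frames = frames, manifest = manifest),
            class = "rq_sted_sim")
}

#' Generate a synthetic GCaMP fluorescence trace
#'
#' Baseline + linear drift + a fast-rise / exponential-decay transient at
#' each requested peak time + Gaussian noise, sampled at the time-lapse
#' interval (default 0.78 s).
#'
#' @param duration_s recording duration (s), > 0.
#' @param peak_times transient onset times (s), all within `[0, duration_s]`.
#' @param drift linear drift slope (a.u. per second).
#' @param noise_sd Gaussian noise SD (a.u.); 0 disables noise.
#' @param seed RNG seed.
#' @param dt_s sampling interval (s).
#' @param baseline resting fluorescence (a.u.).
#' @param amplitude transient peak amplitude above baseline (a.u.).
#' @param tau_rise_s,tau_decay_s transient rise and decay time constants (s).
#' @return [rq_trace()] of kind "fluorescence"; ground truth in attributes
#'   `peak_times_true` and `amplitude_true`.
#' @export
make_gcamp_trace <- function(duration_s = 600, peak_times = numeric(),
                             drift = 0, noise_sd = 0, seed = 1L,
                             dt_s = 0.78, baseline = 100, amplitude = 50,
                             tau_rise_s = 0.5, tau_decay_s = 3) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (length(peak_times) &&
      (min(peak_times) < 0 || max(peak_times) > duration_s))
    stop("peak times must lie within [0, duration]")
  set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  v <- rep(baseline, length(t)) + drift * t
  if (length(peak_times)) {
    tpk <- tau_rise_s * log1p(tau_decay_s / tau_rise_s)
    peak_norm <- (1 - exp(-tpk / tau_rise_s)) * exp(-tpk / tau_decay_s)
    for (t0 in peak_times) {
      tau <- t - t0
      on <- tau >= 0
      v[on] <- v[on] + amplitude / peak_norm *
        (1 - exp(-tau[on] / tau_rise_s)) * exp(-tau[on] / tau_decay_s)
    }
  }
  if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
  tr <- rq_trace(t, v, kind = "fluorescence", duration_s = duration_s)
  attr(tr, "peak_times_true") <- as.numeric(peak_times)
  attr(tr, "amplitude_true") <- amplitude
  tr
}

#' Generate a synthetic IHC voltage trace
#'
#' Stereotyped Gaussian-shaped spikes on a resting membrane potential, as in
#' spontaneous current-clamp recordings of immature inner hair cells.
#'
#' @param duration_s recording duration (s), > 0.
#' @param spike_times spike peak times (s) within `[0, duration_s]`.
#' @param rmp_mV resting membrane potential (mV).
#' @param spike_peak_mV spike peak voltage (mV).
#' @param spike_sigma_s Gaussian spike half-width parameter (s).
#' @param dt_s sampling interval (s).
#' @param noise_sd Gaussian noise SD (mV); 0 disables noise.
#' @param seed RNG seed.
#' @return [rq_trace()] of kind "voltage"; attributes `spike_times_true` and
#'   `spike_auc_true_mVs` (analytic per-spike integral above the resting
#'   potential, `amplitude * sigma * sqrt(2*pi)`).
#' @export
make_voltage_trace <- function(duration_s = 10, spike_times = numeric(),
                               rmp_mV = -58, spike_peak_mV = -15,
                               spike_sigma_s = 0.01, dt_s = 2e-4,
                               noise_sd = 0, seed = 1L) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > duration_s))
    stop("spike times must lie within [0, duration]")
  if (spike_peak_mV <= rmp_mV) stop("spike peak must exceed the RMP")
  set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  v <- rep(rmp_mV, length(t))
  amp <- spike_peak_mV - rmp_mV
  for (t0 in spike_times)
    v <- v + amp * exp(-0.5 * ((t - t0) / spike_sigma_s)^2)
  if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
  tr <- rq_trace(t, v, kind = "voltage", duration_s = duration_s)
  attr(tr, "spike_times_true") <- as.numeric(spike_times)
  attr(tr, "spike_auc_true_mVs") <- amp * spike_sigma_s * sqrt(2 * pi)
  tr
}

#' Write a generator configuration as YAML
#' @param config an [synth_config()] object.
#' @param path output file.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path,
    precision = 15L)
  invisible(path)
}

#' Read a generator configuration from YAML
#' @param path YAML file written by [write_synth_config()].
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("vol_vox", "voxel_size_um", "psf_sigma_um"))
    raw[[f]] <- unlist(raw[[f]])
  for (f in c("engaged_gap_um", "cyto_gap_um"))
    raw[[f]] <- as.numeric(unlist(raw[[f]]))
  do.call(synth_config, raw)
}

# ---------------------------------------------------------------------------
# Manifest serialization: JSON, lossless round-trip.

#' Write a ground-truth manifest as JSON
#' @param manifest an `rq_manifest`.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a ground-truth manifest from JSON
#' @param path JSON file written by [write_manifest()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("puncta_true", "pairs_true"))
    if (!is.null(m[[f]])) m[[f]] <- as.data.frame(m[[f]])
  if (is.null(m$spike_times_true)) m$spike_times_true <- numeric()
  m$spike_times_true <- as.numeric(m$spike_times_true)
  structure(m, class = "rq_manifest")
}
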