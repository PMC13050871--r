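# 2D-STED cluster-area routine: Gaussian blur (sigma = 1 px) -> maximum-
# entropy dark thresholding -> watershed separation of touching objects ->
# size filter (> 50 px) -> moment-based ellipse fit -> calibrated area ->
# paired-area correlation between the ribbon (CtBP2) and calcium-channel
# (Cav1.3) channels.

#' Gaussian blur of a 2D frame
#'
#' Separable Gaussian low-pass filter with symmetric (reflective) boundary
#' handling; the default sigma of 1 px matches the cluster-area routine.
#'
#' @param frame an [sted_frame()].
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @return blurred [sted_frame()] of identical dimensions.
#' @export
gaussian_blur <- function(frame, sigma_px = 1) {
  stopifnot(inherits(frame, "rq_frame"), sigma_px > 0)
  out <- .gauss_smooth(frame$intensity, c(sigma_px, sigma_px))
  sted_frame(pmax(out, 0), frame$pixel_size_um, frame$channel)
}

#' Kapur maximum-entropy threshold
#'
#' Returns the intensity threshold maximizing the summed Shannon entropies
#' of the background and foreground histogram partitions (Kapur-Sahoo-Wong),
#' with the dark-background convention: foreground pixels are those strictly
#' above the returned threshold.
#'
#' @param frame an [sted_frame()] or numeric array.
#' @param n_bins number of equal-width histogram bins over the intensity
#'   range; candidate thresholds are the interior bin edges.
#' @return threshold (a.u.).
#' @export
max_entropy_threshold <- function(frame, n_bins = 256L) {
  v <- if (inherits(frame, "rq_frame")) frame$intensity else frame
  .kapur_threshold(v, n_bins)
}

#' Watershed separation of touching objects
#'
#' Distance-transform-seeded watershed on a binary mask: seeds are local
#' maxima of the Euclidean distance transform, greedily suppressed to a
#' minimum mutual separation; labels are flooded in order of decreasing
#' distance. Every connected component receives at least one seed, so the
#' labels partition the mask exactly.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_seed_sep_px minimum seed separation in pixels.
#' @return integer label matrix, 0 = background.
#' @export
watershed_split <- function(mask, min_seed_sep_px = 3) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab3 <- .seeded_watershed(array(mask, c(dim(mask), 1L)),
                            spacing = c(1, 1, 1),
                            min_seed_sep = min_seed_sep_px)
  matrix(lab3, nrow(mask), ncol(mask))
}

# Shared seeded-watershed core (2D masks are single-plane 3D arrays).
# Seeds = local maxima of the anisotropic EDT that lie more than one voxel
# diagonal inside the surface (boundary-roughness maxima cannot seed),
# greedily suppressed to min_seed_sep (physical units), ranked by distance
# value (ties: lowest linear index). Components left unseeded get their
# distance argmax, so each connected component yields at least one label.
.seeded_watershed <- function(mask3, spacing, min_seed_sep) {
  dims <- dim(mask3)
  mvec <- as.logical(mask3)
  d2 <- .edt_sq_3d(mvec, dims, spacing)
  dist <- sqrt(d2)
  comp <- .label_3d(mvec, dims)
  vox_diag <- sqrt(sum((spacing[dims > 1])^2))
  cand <- which(.local_max_3d(dist, mvec, dims) & dist > vox_diag)
  ord <- cand[order(-dist[cand], cand)]
  # physical coordinates of candidates (voxel centres)
  coords <- function(w) {
    i <- (w - 1L) %% dims[1L]
    rem <- (w - 1L) %/% dims[1L]
    j <- rem %% dims[2L]
    k <- rem %/% dims[2L]
    cbind((i + 0.5) * spacing[1L], (j + 0.5) * spacing[2L],
          (k + 0.5) * spacing[3L])
  }
  sel <- integer(0)
  if (length(ord)) {
    pc <- coords(ord)
    keep <- logical(length(ord))
    for (t in seq_along(ord)) {
      if (!length(sel)) {
        keep[t] <- TRUE
        sel <- t
      } else {
        dd <- sqrt(colSums((t(pc[sel, , drop = FALSE]) - pc[t, ])^2))
        if (all(dd >= min_seed_sep)) {
          keep[t] <- TRUE
          sel <- c(sel, t)
        }
      }
    }
    seeds_idx <- ord[keep]
  } else {
    seeds_idx <- integer(0)
  }
  # guarantee one seed per connected component
  seeded_comp <- unique(comp[seeds_idx])
  for (cid in setdiff(unique(comp[comp > 0]), seeded_comp)) {
    w <- which(comp == cid)
    seeds_idx <- c(seeds_idx, w[which.max(dist[w])])
  }
  seeds <- integer(length(mvec))
  seeds[sort(seeds_idx)] <- seq_along(seeds_idx)
  lab <- .watershed_3d(-dist, seeds, mvec, dims)
  lab <- .merge_by_dynamics(lab, dist, dims, h = min_seed_sep / 2)
  array(lab, dims)
}

# Merge watershed basins by dynamics: a basin whose distance-map peak rises
# less than h above its highest saddle to a neighbouring basin is merged
# into the neighbour across that saddle (weakest basin first). This removes
# splits driven by surface roughness while preserving genuine waists
# between touching objects. Labels are compacted to 1..n afterwards.
.merge_by_dynamics <- function(lab, dist, dims, h) {
  if (h <= 0) return(.compact_labels(lab))
  repeat {
    sad <- .label_saddles(lab, dist, dims)
    if (nrow(sad) == 0) break
    present <- sort(unique(lab[lab > 0L]))
    maxh <- vapply(present, function(l) max(dist[lab == l]), numeric(1))
    names(maxh) <- present
    best_sad <- vapply(present, function(l) {
      rows <- sad[, 1] == l | sad[, 2] == l
      if (!any(rows)) -Inf else max(sad[rows, 3])
    }, numeric(1))
    dyn <- maxh - best_sad
    cand <- which(is.finite(dyn) & dyn < h)
    if (!length(cand)) break
    victim <- present[cand[which.min(dyn[cand])]]
    rows <- which(sad[, 1] == victim | sad[, 2] == victim)
    r <- rows[which.max(sad[rows, 3])]
    target <- if (sad[r, 1] == victim) sad[r, 2] else sad[r, 1]
    lab[lab == victim] <- as.integer(target)
  }
  .compact_labels(lab)
}

.compact_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  lab
}

#' Size-filter labelled objects and fit ellipses
#'
#' Discards objects not larger than `min_px` pixels (strict inequality, per
#' the "> 50 pixels" rule) and fits each survivor with its moment-matched
#' ellipse (same centroid, orientation and aspect from second-order central
#' moments of the binary region, scaled to the region's area). The reported
#' `area_um2` is the calibrated mask area (pixel count x pixel area); the
#' ellipse parameters are shape descriptors.
#'
#' @param labels integer label matrix from [watershed_split()].
#' @param frame the [sted_frame()] the labels were derived from (supplies
#'   the pixel calibration).
#' @param min_px minimum pixel count; objects with `pixel_count <= min_px`
#'   are discarded.
#' @return data.frame with one row per surviving object: `label`,
#'   `pixel_count`, `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `major_um`, `minor_um` (full axis lengths), `orientation_rad`.
#' @export
filter_and_fit <- function(labels, frame, min_px = 50L) {
  stopifnot(is.matrix(labels), inherits(frame, "rq_frame"),
            all(dim(labels) == dim(frame$intensity)))
  px <- frame$pixel_size_um
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  rows <- lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    n <- nrow(w)
    if (n <= min_px) return(NULL)
    # pixel-centre coordinates in um; x = column, y = row
    xs <- (w[, 2] - 0.5) * px
    ys <- (w[, 1] - 0.5) * px
    cx <- mean(xs)
    cy <- mean(ys)
    # central second moments + 1/12 px^2 per-pixel (uniform square) term
    mu20 <- mean((xs - cx)^2) + px^2 / 12
    mu02 <- mean((ys - cy)^2) + px^2 / 12
    mu11 <- mean((xs - cx) * (ys - cy))
    tr <- mu20 + mu02
    det <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
    l1 <- (tr + det) / 2
    l2 <- (tr - det) / 2
    a <- 2 * sqrt(max(l1, 0))    # semi-axes of the equal-moment ellipse
    b <- 2 * sqrt(max(l2, 0))
    area <- n * px^2
    s <- if (a > 0 && b > 0) sqrt(area / (pi * a * b)) else 1
    data.frame(label = id, pixel_count = n, area_um2 = area,
               centroid_x_um = cx, centroid_y_um = cy,
               major_um = 2 * a * s, minor_um = 2 * b * s,
               orientation_rad = 0.5 * atan2(2 * mu11, mu20 - mu02))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(), pixel_count = integer(),
                      area_um2 = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), major_um = numeric(),
                      minor_um = numeric(), orientation_rad = numeric())
  out
}

#' Run the full 2D-STED cluster-area routine on one frame
#'
#' blur -> maximum-entropy threshold -> watershed -> size filter ->
#' ellipse fit.
#'
#' @inheritParams gaussian_blur
#' @inheritParams max_entropy_threshold
#' @inheritParams filter_and_fit
#' @param min_seed_sep_px watershed seed separation (pixels).
#' @return list: `regions` (as [filter_and_fit()]), `threshold`, `mask`.
#' @export
analyze_sted_frame <- function(frame, sigma_px = 1, n_bins = 256L,
                               min_px = 50L, min_seed_sep_px = 3) {
  bl <- gaussian_blur(frame, sigma_px)
  thr <- max_entropy_threshold(bl, n_bins)
  mask <- bl$intensity > thr
  labs <- watershed_split(mask, min_seed_sep_px)
  list(regions = filter_and_fit(labs, frame, min_px), threshold = thr,
       mask = mask)
}

#' Pair per-frame cluster areas across two channels
#'
#' One pair per cropped frame: when several objects survive in a channel the
#' largest is used and the frame is flagged (`multi = TRUE`).
#'
#' @param ctbp2_regions,cav13_regions region tables from
#'   [filter_and_fit()] for the two channels of one frame.
#' @param frame_id identifier stored with the pair.
#' @return one-row data.frame (`frame`, `ctbp2_area_um2`, `cav13_area_um2`,
#'   `multi`) or a zero-row frame when either channel has no object.
#' @export
pair_areas <- function(ctbp2_regions, cav13_regions, frame_id = 1L) {
  if (nrow(ctbp2_regions) == 0 || nrow(cav13_regions) == 0)
    return(data.frame(frame = integer(), ctbp2_area_um2 = numeric(),
                      cav13_area_um2 = numeric(), multi = logical()))
  data.frame(frame = frame_id,
             ctbp2_area_um2 = max(ctbp2_regions$area_um2),
             cav13_area_um2 = max(cav13_regions$area_um2),
             multi = nrow(ctbp2_regions) > 1 || nrow(cav13_regions) > 1)
}

#' Correlate paired cluster areas
#'
#' Spearman rank correlation (two-sided) plus an ordinary least-squares fit
#' of the calcium-channel area on the ribbon area with 95% confidence
#' intervals, as used to relate ribbon size to its calcium-channel
#' complement.
#'
#' @param pairs data.frame with columns `ctbp2_area_um2`,
#'   `cav13_area_um2` (e.g. rbind of [pair_areas()] rows).
#' @return list: `n`, `spearman_rho`, `spearman_p`, `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci` (95%).
#' @export
correlate_pairs <- function(pairs) {
  if (nrow(pairs) < 3) stop("insufficient data: need at least 3 pairs")
  x <- pairs$ctbp2_area_um2
  y <- pairs$cav13_area_um2
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  fit <- lm(y ~ x)
  ci <- confint(fit, level = 0.95)
  list(n = nrow(pairs),
       spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       slope_ci = unname(ci[2, ]),
       intercept_ci = unname(ci[1, ]))
}
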