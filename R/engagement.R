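# Synaptic-engagement classification: each reconstructed ribbon is assigned
# its nearest PSD by minimum surface-to-surface distance and classed as
# synaptically engaged (distance strictly < 0.5 um) or cytoplasmically
# floating; counts are normalized to the number of inner hair cells in the
# region of interest.
#
# Distance convention: minimum Euclidean distance between voxel centres of
# the two voxelized objects (0 when the voxel sets intersect or are
# 26-adjacent). This differs from a sub-voxel mesh distance by at most one
# voxel diagonal.

#' Surface-to-surface distance between two voxelized puncta
#'
#' @param voxels_a,voxels_b integer matrices of voxel coordinates (columns
#'   i, j, k, 1-based), e.g. from [punctum_voxels()].
#' @param voxel_size_um named physical voxel size `c(x=, y=, z=)` in um.
#' @return distance in um; 0 if the objects overlap or touch (26-adjacent).
#' @export
surface_distance <- function(voxels_a, voxels_b,
                             voxel_size_um = c(x = 0.08, y = 0.08, z = 0.2)) {
  stopifnot(is.matrix(voxels_a), is.matrix(voxels_b),
            ncol(voxels_a) == 3, ncol(voxels_b) == 3)
  if (nrow(voxels_a) == 0 || nrow(voxels_b) == 0) stop("empty punctum")
  vs <- .check_voxel_size(voxel_size_um)
  .min_voxel_dist(voxels_a, voxels_b, unname(vs[c("y", "x", "z")]))
}

#' Classify ribbons as synaptic or cytoplasmic
#'
#' Assigns each ribbon its nearest PSD by surface distance; a ribbon is
#' synaptically engaged iff that distance is strictly below the cutoff
#' (default 0.5 um). With no PSDs, every ribbon is cytoplasmic.
#'
#' @param ribbon_labels,psd_labels integer label arrays (congruent), e.g.
#'   from [reconstruct()] or the generator's ground-truth labels.
#' @param voxel_size_um physical voxel size `c(x=, y=, z=)` in um.
#' @param cutoff_um engagement cutoff (um), > 0.
#' @return data.frame: `ribbon_id`, `nearest_psd_id` (NA when no PSDs),
#'   `surface_distance_um` (Inf when no PSDs), `class` ("synaptic" or
#'   "cytoplasmic").
#' @export
classify_ribbons <- function(ribbon_labels, psd_labels,
                             voxel_size_um = c(x = 0.08, y = 0.08, z = 0.2),
                             cutoff_um = 0.5) {
  stopifnot(cutoff_um > 0, all(dim(ribbon_labels) == dim(psd_labels)))
  vs <- .check_voxel_size(voxel_size_um)
  sp <- unname(vs[c("y", "x", "z")])
  rib_ids <- setdiff(sort(unique(as.integer(ribbon_labels))), 0L)
  psd_ids <- setdiff(sort(unique(as.integer(psd_labels))), 0L)
  if (!length(rib_ids))
    return(data.frame(ribbon_id = integer(), nearest_psd_id = integer(),
                      surface_distance_um = numeric(), class = character()))
  psd_vox <- lapply(psd_ids, function(id) .label_voxels(psd_labels, id))
  rows <- lapply(rib_ids, function(rid) {
    rv <- .label_voxels(ribbon_labels, rid)
    if (!length(psd_ids)) {
      data.frame(ribbon_id = rid, nearest_psd_id = NA_integer_,
                 surface_distance_um = Inf, class = "cytoplasmic")
    } else {
      dd <- vapply(psd_vox, function(pv) .min_voxel_dist(rv, pv, sp),
                   numeric(1))
      k <- which.min(dd)
      data.frame(ribbon_id = rid, nearest_psd_id = psd_ids[k],
                 surface_distance_um = dd[k],
                 class = if (dd[k] < cutoff_um) "synaptic" else "cytoplasmic")
    }
  })
  do.call(rbind, rows)
}

#' Per-IHC count summary
#'
#' Ribbon counts normalized to the number of inner hair cells in the ROI
#' (an explicit input, mirroring manual cell counting).
#'
#' @param assignments data.frame from [classify_ribbons()].
#' @param n_ihc number of IHCs in the ROI, >= 1.
#' @return list: `n_synaptic`, `n_cytoplasmic`, `n_ihc`,
#'   `synaptic_per_ihc`, `cytoplasmic_per_ihc`.
#' @export
summarize_engagement <- function(assignments, n_ihc) {
  if (n_ihc < 1) stop("n_ihc must be >= 1")
  ns <- sum(assignments$class == "synaptic")
  nc <- sum(assignments$class == "cytoplasmic")
  list(n_synaptic = ns, n_cytoplasmic = nc, n_ihc = n_ihc,
       synaptic_per_ihc = ns / n_ihc, cytoplasmic_per_ihc = nc / n_ihc)
}
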