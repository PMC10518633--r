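#' Colocalization parameters
#'
#' The object-overlap rule: two objects are colocalized when their shared
#' voxel volume is at least `min_overlap_fraction` of a reference object
#' volume. The reference ("their whole structure") defaults to the smaller
#' object of the pair, which makes the rule symmetric and matches the
#' engulfed-punctum reading (puncta are tiny relative to glia); either
#' specific object can be selected instead.
#'
#' @param min_overlap_fraction Minimum overlap fraction in (0, 1]; default
#'   0.25 ("at least 25%").
#' @param denominator_rule `"min_object"` (default), `"object_a"` or
#'   `"object_b"`.
#' @param plaque_distance_um Distance threshold for plaque-proximity
#'   stratification, micrometres (default 10).
#' @return An object of class `ColocalizationParams`.
#' @export
coloc_params <- function(min_overlap_fraction = 0.25,
                         denominator_rule = c("min_object", "object_a",
                                              "object_b"),
                         plaque_distance_um = 10) {
  denominator_rule <- match.arg(denominator_rule)
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]", call. = FALSE)
  if (plaque_distance_um < 0)
    stop("plaque_distance_um must be >= 0", call. = FALSE)
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 denominator_rule = denominator_rule,
                 plaque_distance_um = plaque_distance_um),
            class = "ColocalizationParams")
}

#' Object-pair colocalization records
#'
#' Computes, for every pair of objects from two segmented channels that
#' share at least one voxel, the overlap volume, the overlap fraction of
#' each object, and the colocalization verdict under the minimum-overlap
#' rule.
#'
#' @param seg_a,seg_b `ChannelSegmentation` objects from the same stack
#'   (identical shapes).
#' @param params A [coloc_params()] object.
#' @return Data frame with one row per overlapping pair: `object_a`,
#'   `object_b`, `overlap_voxels`, `overlap_volume_um3`, `fraction_of_a`,
#'   `fraction_of_b`, `colocalized`.
#' @export
colocalize_pair <- function(seg_a, seg_b, params = coloc_params()) {
  stopifnot(inherits(seg_a, "ChannelSegmentation"),
            inherits(seg_b, "ChannelSegmentation"))
  if (!identical(dim(seg_a$labels), dim(seg_b$labels)))
    stop("segmentations come from different stack shapes", call. = FALSE)
  ov <- cpp_pair_overlaps(seg_a$labels, seg_b$labels)
  vox_vol <- voxel_volume_um3(seg_a$voxel_size_zyx)
  ca <- seg_a$objects$voxel_count[ov[, "a"]]
  cb <- seg_b$objects$voxel_count[ov[, "b"]]
  denom <- switch(params$denominator_rule,
                  min_object = pmin(ca, cb),
                  object_a = ca,
                  object_b = cb)
  n <- ov[, "n"]
  data.frame(
    object_a = ov[, "a"], object_b = ov[, "b"],
    overlap_voxels = n,
    overlap_volume_um3 = n * vox_vol,
    fraction_of_a = n / ca,
    fraction_of_b = n / cb,
    colocalized = n >= params$min_overlap_fraction * denom)
}

#' Voxel-level colocalized volume of two masks
#'
#' Volume (um^3) of the voxel-wise intersection of two binary masks.
#'
#' @param mask_a,mask_b Logical 3D arrays of identical shape (or
#'   `ChannelSegmentation` objects, whose foreground is used).
#' @param voxel_size_zyx Voxel size in micrometres.
#' @return Intersection volume in um^3.
#' @export
colocalized_volume <- function(mask_a, mask_b,
                               voxel_size_zyx = default_voxel_size()) {
  if (inherits(mask_a, "ChannelSegmentation")) {
    voxel_size_zyx <- mask_a$voxel_size_zyx
    mask_a <- seg_mask(mask_a)
  }
  if (inherits(mask_b, "ChannelSegmentation")) mask_b <- seg_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ", call. = FALSE)
  sum(mask_a & mask_b) * voxel_volume_um3(voxel_size_zyx)
}

#' Triple colocalized volume
#'
#' Volume (um^3) of voxels present in all three masks (synaptic, neurite
#' and glial foreground), the readout for co-engulfment of synapses and
#' neurite fragments.
#'
#' @param mask_syn,mask_neurite,mask_glia Logical 3D arrays of identical
#'   shape (or `ChannelSegmentation` objects).
#' @param voxel_size_zyx Voxel size in micrometres.
#' @return Triple-intersection volume in um^3.
#' @export
triple_colocalized_volume <- function(mask_syn, mask_neurite, mask_glia,
                                      voxel_size_zyx = default_voxel_size()) {
  conv <- function(m) if (inherits(m, "ChannelSegmentation")) seg_mask(m) else m
  if (inherits(mask_syn, "ChannelSegmentation"))
    voxel_size_zyx <- mask_syn$voxel_size_zyx
  a <- conv(mask_syn); b <- conv(mask_neurite); g <- conv(mask_glia)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(g)))
    stop("mask shapes differ", call. = FALSE)
  sum(a & b & g) * voxel_volume_um3(voxel_size_zyx)
}

#' Stratify objects by proximity to amyloid plaques
#'
#' Labels each object `"near"` when the minimum Euclidean distance (in
#' physical micrometres, anisotropic voxels respected) from any of its
#' voxels to the nearest plaque voxel is at most `distance_um`, and
#' `"far"` otherwise. Distances are voxel-centre to voxel-centre, so an
#' object overlapping the plaque mask has distance 0. A stack whose plaque
#' mask is empty is flagged plaque-free and its objects are left
#' unlabelled (`NA`), mirroring the exclusion of plaque-free tissue from
#' near/far contrasts.
#'
#' @param seg A `ChannelSegmentation` whose objects are stratified.
#' @param plaque_mask Logical 3D array of the stack's shape.
#' @param distance_um Proximity threshold, micrometres.
#' @return List with `stratum` (character vector along `seg$objects`,
#'   `"near"`/`"far"` or `NA`), `min_distance_um` per object, and
#'   `plaque_free` flag.
#' @export
plaque_stratify <- function(seg, plaque_mask, distance_um = 10) {
  stopifnot(inherits(seg, "ChannelSegmentation"))
  if (inherits(plaque_mask, "ChannelSegmentation"))
    plaque_mask <- seg_mask(plaque_mask)
  if (!identical(dim(seg$labels), dim(plaque_mask)))
    stop("plaque mask shape differs from segmentation", call. = FALSE)
  n <- nrow(seg$objects)
  if (!any(plaque_mask)) {
    return(list(stratum = rep(NA_character_, n),
                min_distance_um = rep(NA_real_, n), plaque_free = TRUE))
  }
  d2 <- cpp_edt3_sq(plaque_mask, dim(plaque_mask), seg$voxel_size_zyx)
  idx <- which(seg$labels > 0L)
  if (length(idx) == 0L)
    return(list(stratum = character(0), min_distance_um = numeric(0),
                plaque_free = FALSE))
  mind2 <- as.vector(tapply(d2[idx], seg$labels[idx], min))
  mind <- sqrt(mind2)
  list(stratum = ifelse(mind <= distance_um, "near", "far"),
       min_distance_um = mind, plaque_free = FALSE)
}

#' Per-stack burden and colocalization metrics
#'
#' Summarises one segmented stack the way each image stack of a cohort is
#' scored: per-channel stained volume fraction (burden), object-rule
#' colocalized volume for the requested channel pair together with its
#' normalizations (per stack volume and per glial stain volume), the
#' voxel-level pair and triple intersection volumes, and optional
#' plaque-proximity strata of the colocalized volume.
#'
#' @param stack The [image_stack()] the segmentations came from.
#' @param segs Named list of `ChannelSegmentation` objects (from
#'   [segment_stack()]).
#' @param pair Character length-2: the (target, glia) channel pair, default
#'   `c("syn", "glia")`.
#' @param triple_channel Optional third channel (e.g. `"neurite"`) for the
#'   triple intersection volume.
#' @param plaque_channel Optional channel name used as the plaque mask for
#'   near/far stratification of colocalized volume.
#' @param params A [coloc_params()] object.
#' @return One-row data frame of metrics. The glial-normalized metric is
#'   `NA` (flagged missing) when the glial stain volume is zero.
#' @export
compute_stack_metrics <- function(stack, segs, pair = c("syn", "glia"),
                                  triple_channel = NULL,
                                  plaque_channel = NULL,
                                  params = coloc_params()) {
  stopifnot(inherits(stack, "ImageStack"))
  vox_vol <- voxel_volume_um3(stack$voxel_size_zyx)
  n_vox <- prod(dim(stack))
  stack_vol <- n_vox * vox_vol

  out <- data.frame(stack_id = stack$stack_id, case_id = stack$case_id,
                    stack_volume_um3 = stack_vol)
  for (ch in names(segs))
    out[[paste0("burden_frac_", ch)]] <-
      sum(segs[[ch]]$objects$voxel_count) / n_vox

  a <- pair[1]; g <- pair[2]
  if (!all(pair %in% names(segs)))
    stop("pair channels not all segmented: ", paste(pair, collapse = ", "),
         call. = FALSE)
  rec <- colocalize_pair(segs[[a]], segs[[g]], params)
  coloc_vol <- sum(rec$overlap_volume_um3[rec$colocalized])
  glia_vol <- sum(segs[[g]]$objects$volume_um3)
  out$coloc_volume_um3 <- coloc_vol
  out$coloc_per_stack_volume <- coloc_vol / stack_vol
  out$coloc_per_glia_volume <- if (glia_vol > 0) coloc_vol / glia_vol
                               else NA_real_
  out$glia_volume_um3 <- glia_vol
  out$and_volume_um3 <- colocalized_volume(segs[[a]], segs[[g]])

  if (!is.null(triple_channel)) {
    out$triple_volume_um3 <-
      triple_colocalized_volume(segs[[a]], segs[[triple_channel]], segs[[g]])
  }

  if (!is.null(plaque_channel)) {
    strat <- plaque_stratify(segs[[a]], segs[[plaque_channel]],
                             params$plaque_distance_um)
    out$plaque_free <- strat$plaque_free
    if (strat$plaque_free) {
      out$coloc_volume_near_um3 <- NA_real_
      out$coloc_volume_far_um3 <- NA_real_
    } else {
      near_ids <- segs[[a]]$objects$id[strat$stratum == "near"]
      sel <- rec$colocalized & rec$object_a %in% near_ids
      out$coloc_volume_near_um3 <- sum(rec$overlap_volume_um3[sel])
      out$coloc_volume_far_um3 <- coloc_vol - out$coloc_volume_near_um3
    }
  }
  out
}
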