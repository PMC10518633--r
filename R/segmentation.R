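#' Segmentation parameters
#'
#' Settings for per-channel adaptive local-mean thresholding. A voxel is
#' foreground when its intensity exceeds the mean of a
#' `window_size` x `window_size` neighbourhood in its own z-slice minus
#' `c_offset`, with the offset applied on the image's native intensity
#' scale (8-bit by default in the simulator).
#'
#' @param window_size Side of the square local window, pixels (>= 1). Even
#'   sizes are allowed: the window spans `floor((w-1)/2)` pixels before and
#'   `ceil((w-1)/2)` after the centre pixel.
#' @param c_offset Offset subtracted from the local mean, native intensity
#'   units.
#' @param method Thresholding statistic; only `"mean"` is supported.
#' @param min_size Optional minimum object size in voxels; `NULL` keeps all
#'   objects.
#' @return An object of class `SegmentationParams`.
#' @seealso [seg_preset()] for the built-in marker presets.
#' @export
seg_params <- function(window_size, c_offset, method = "mean",
                       min_size = NULL) {
  if (!identical(method, "mean"))
    stop("unsupported method '", method, "'; only 'mean' is available",
         call. = FALSE)
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || window_size < 1L)
    stop("window_size must be a single integer >= 1", call. = FALSE)
  if (!is.null(min_size)) min_size <- as.integer(min_size)
  structure(list(window_size = window_size, c_offset = as.numeric(c_offset),
                 method = method, min_size = min_size),
            class = "SegmentationParams")
}

#' Built-in segmentation presets
#'
#' Per-marker auto-local-threshold settings used for all stacks of an
#' experiment: CD68 (window 70, C 0.2), Syn1 (window 10, C 1) and GFAP
#' (window 70, C 0.15), all with the mean method and no minimum size.
#' `MAP2` and `plaque` reuse the GFAP settings, a package choice for the
#' other filamentous/extended markers.
#'
#' @param marker One of `"CD68"`, `"Syn1"`, `"GFAP"`, `"MAP2"`, `"plaque"`.
#' @return A [seg_params()] object (or the full named list from
#'   [segmentation_presets()]).
#' @export
seg_preset <- function(marker = c("CD68", "Syn1", "GFAP", "MAP2", "plaque")) {
  marker <- match.arg(marker)
  segmentation_presets()[[marker]]
}

#' @rdname seg_preset
#' @export
segmentation_presets <- function() {
  gfap <- seg_params(70L, 0.15)
  list(CD68 = seg_params(70L, 0.2),
       Syn1 = seg_params(10L, 1),
       GFAP = gfap,
       MAP2 = gfap,
       plaque = gfap)
}

#' Adaptive local-mean threshold
#'
#' Binarizes an intensity volume slice by slice: a voxel is foreground iff
#' its intensity is strictly greater than the local window mean minus
#' `c_offset`. The local mean is computed per 2D z-slice over a square
#' window with edge-replicate padding; objects are then assembled in 3D by
#' [label_components()].
#'
#' Note the documented degenerate case: on a perfectly flat slice every
#' voxel equals its local mean, so a positive `c_offset` marks the whole
#' slice foreground and a negative one marks it background.
#'
#' @param x 3D intensity array (z, y, x) with finite values.
#' @param params A [seg_params()] object (or a preset name accepted by
#'   [seg_preset()]).
#' @return Logical 3D array of the same shape (class `BinaryMask` attribute
#'   kept as a plain logical array).
#' @export
local_mean_threshold <- function(x, params) {
  if (is.character(params)) params <- seg_preset(params)
  stopifnot(inherits(params, "SegmentationParams"))
  stopifnot_shape3(x)
  if (any(!is.finite(x)))
    stop("non-finite intensities", call. = FALSE)
  m <- cpp_local_mean_slices(as.numeric(x), dim(x), params$window_size)
  mask <- array(as.vector(x) > (as.vector(m) - params$c_offset), dim = dim(x))
  mask
}

#' Extract 3D connected components as segmented objects
#'
#' Labels maximal connected components of a binary mask under 6-, 18- or
#' 26-connectivity (default 6: at 0.18 um sampling, corner- or edge-only
#' contacts are below the optical resolution, and face connectivity keeps
#' chance single-voxel bridges from merging distinct structures) and returns per-object voxel counts,
#' physical volumes and bounding boxes.
#'
#' @param mask Logical 3D array (z, y, x).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size_zyx Voxel size in micrometres, for physical volumes.
#' @param min_size Optional minimum voxel count; smaller components are
#'   dropped (their voxels are cleared from the label volume).
#' @param channel Channel name recorded on the result.
#' @return An object of class `ChannelSegmentation`: list with `labels`
#'   (integer 3D array, 0 = background), `objects` (data frame: `id`,
#'   `voxel_count`, `volume_um3`, bounding-box columns, centroid columns),
#'   `channel`, `voxel_size_zyx`, `connectivity`.
#' @export
label_components <- function(mask, connectivity = 6L,
                             voxel_size_zyx = default_voxel_size(),
                             min_size = NULL, channel = NA_character_) {
  stopifnot_shape3(mask)
  if (!is.logical(mask)) mask <- array(as.logical(mask), dim = dim(mask))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  shape <- dim(mask)
  lab <- cpp_label3(mask, shape, as.integer(connectivity))
  n <- max(lab)
  vox_vol <- voxel_volume_um3(voxel_size_zyx)
  if (n == 0L) {
    objects <- data.frame(id = integer(0), voxel_count = integer(0),
                          volume_um3 = numeric(0),
                          z_min = integer(0), z_max = integer(0),
                          y_min = integer(0), y_max = integer(0),
                          x_min = integer(0), x_max = integer(0),
                          z_c = numeric(0), y_c = numeric(0), x_c = numeric(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    zyx <- index_to_zyx0(idx, shape) + 1L         # 1-based voxel coords
    counts <- tabulate(l, nbins = n)
    agg <- function(v, f) as.vector(tapply(v, l, f))
    objects <- data.frame(
      id = seq_len(n), voxel_count = counts,
      volume_um3 = counts * vox_vol,
      z_min = agg(zyx[, 1], min), z_max = agg(zyx[, 1], max),
      y_min = agg(zyx[, 2], min), y_max = agg(zyx[, 2], max),
      x_min = agg(zyx[, 3], min), x_max = agg(zyx[, 3], max),
      z_c = agg(zyx[, 1], mean), y_c = agg(zyx[, 2], mean),
      x_c = agg(zyx[, 3], mean))
    if (!is.null(min_size) && min_size > 1L) {
      drop <- objects$id[objects$voxel_count < min_size]
      if (length(drop)) {
        lab[lab %in% drop] <- 0L
        objects <- objects[!objects$id %in% drop, , drop = FALSE]
        # compact ids so labels stay 1..n
        remap <- integer(n)
        remap[objects$id] <- seq_len(nrow(objects))
        lab[lab > 0L] <- remap[lab[lab > 0L]]
        objects$id <- seq_len(nrow(objects))
        rownames(objects) <- NULL
      }
    }
  }
  structure(list(labels = lab, objects = objects, channel = channel,
                 voxel_size_zyx = voxel_size_zyx,
                 connectivity = as.integer(connectivity)),
            class = "ChannelSegmentation")
}

#' @export
print.ChannelSegmentation <- function(x, ...) {
  cat(sprintf("ChannelSegmentation '%s': %d objects, %d foreground voxels\n",
              x$channel, nrow(x$objects), sum(x$objects$voxel_count)))
  invisible(x)
}

#' Segment all requested channels of a stack
#'
#' Applies [local_mean_threshold()] followed by [label_components()] to each
#' channel named in `presets`, using the same parameters for every stack of
#' an experiment.
#'
#' @param stack An [image_stack()].
#' @param presets Named list mapping channel names to [seg_params()] objects
#'   (or preset names). Defaults to the built-in marker presets for a
#'   simulated stack: `glia` = GFAP, `syn` = Syn1, `neurite` = MAP2,
#'   `plaque` = plaque settings.
#' @param connectivity Connectivity passed to [label_components()].
#' @return Named list of `ChannelSegmentation` objects.
#' @export
segment_stack <- function(stack, presets = NULL, connectivity = 6L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.null(presets)) {
    defaults <- list(glia = "GFAP", syn = "Syn1", neurite = "MAP2",
                     plaque = "plaque")
    presets <- defaults[intersect(names(defaults), names(stack$channels))]
  }
  out <- list()
  for (ch in names(presets)) {
    p <- presets[[ch]]
    if (is.character(p)) p <- seg_preset(p)
    vol <- stack_channel(stack, ch)
    mask <- local_mean_threshold(vol, p)
    out[[ch]] <- label_components(mask, connectivity = connectivity,
                                  voxel_size_zyx = stack$voxel_size_zyx,
                                  min_size = p$min_size, channel = ch)
  }
  out
}

seg_mask <- function(seg) seg$labels > 0L
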