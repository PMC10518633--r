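#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D intensity volume with physical voxel
#' size. Channels are named 3D arrays in (z, y, x) order sharing one shape;
#' intensities must be finite and non-negative.
#'
#' @param channels Named list of 3D numeric arrays (z, y, x), all the same
#'   shape.
#' @param voxel_size_zyx Physical voxel size in micrometres, length 3
#'   (z, y, x). Defaults to [default_voxel_size()].
#' @param stack_id,case_id Identifiers carried through to output tables.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(channels, voxel_size_zyx = default_voxel_size(),
                        stack_id = "stack1", case_id = NA_character_) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list", call. = FALSE)
  dims <- lapply(channels, dim)
  for (ch in names(channels)) {
    stopifnot_shape3(channels[[ch]], paste0("channel '", ch, "'"))
    if (!identical(dims[[ch]], dims[[1L]]))
      stop("all channels must share one shape", call. = FALSE)
    v <- channels[[ch]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("channel '", ch, "' has non-finite or negative intensities",
           call. = FALSE)
  }
  voxel_size_zyx <- as.numeric(voxel_size_zyx)
  if (length(voxel_size_zyx) != 3L || any(voxel_size_zyx <= 0))
    stop("voxel_size_zyx must be 3 positive numbers", call. = FALSE)
  names(voxel_size_zyx) <- .zyx
  structure(list(channels = channels, voxel_size_zyx = voxel_size_zyx,
                 stack_id = stack_id, case_id = case_id),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("ImageStack '%s' (case %s): %d x %d x %d voxels (z,y,x), %s\n",
              x$stack_id, x$case_id, d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um; stack volume %.1f um^3\n",
              x$voxel_size_zyx[1], x$voxel_size_zyx[2], x$voxel_size_zyx[3],
              prod(d) * voxel_volume_um3(x$voxel_size_zyx)))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$channels[[1L]])

stack_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present in stack (has: ",
         paste(names(stack$channels), collapse = ", "), ")", call. = FALSE)
  stack$channels[[channel]]
}
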