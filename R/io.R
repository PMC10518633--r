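#' Write a stack as TIFF planes with OME companion metadata
#'
#' Writes the stack as a multi-plane TIFF (plane order: channel fastest,
#' then z, i.e. dimension order XYCZT) plus an OME companion-XML file
#' `<path without .tif>.companion.ome` carrying the pixel sizes
#' (micrometres), dimension sizes and channel names. Intensities are
#' stored at the stack's bit depth (8- or 16-bit); a write/read
#' round-trip is bit-identical.
#'
#' @param stack An [image_stack()].
#' @param path Output path (`.tif`).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "ImageStack"))
  top <- 2^bits - 1
  d <- dim(stack)
  planes <- list()
  for (z in seq_len(d[1]))
    for (ch in names(stack$channels))
      planes[[length(planes) + 1L]] <- stack$channels[[ch]][z, , ] / top
  tiff::writeTIFF(planes, path, bits.per.sample = as.integer(bits),
                  compression = "deflate", reduce = FALSE)
  xml2::write_xml(ome_companion_xml(stack, bits), companion_path(path))
  invisible(path)
}

companion_path <- function(path) paste0(sub("\\.tiff?$", "", path),
                                        ".companion.ome")

ome_companion_xml <- function(stack, bits) {
  d <- dim(stack)
  vs <- stack$voxel_size_zyx
  ch_xml <- paste0(sprintf('<Channel ID="Channel:0:%d" Name="%s"/>',
                           seq_along(stack$channels) - 1L,
                           names(stack$channels)), collapse = "")
  xml2::read_xml(sprintf(
    paste0('<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
           '<Image ID="Image:0" Name="%s">',
           '<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint%d" ',
           'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ',
           'PhysicalSizeX="%g" PhysicalSizeY="%g" PhysicalSizeZ="%g" ',
           'PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm" ',
           'PhysicalSizeZUnit="µm">%s</Pixels></Image></OME>'),
    stack$stack_id, bits, d[3], d[2], d[1], length(stack$channels),
    vs[3], vs[2], vs[1], ch_xml))
}

#' Read a stack written by [write_stack()]
#'
#' Reads the TIFF planes and the OME companion metadata; voxel size and
#' channel names come from the metadata unless overridden. Fails when
#' neither metadata nor an override supplies the voxel size, and when a
#' required channel is missing.
#'
#' @param path TIFF path.
#' @param channels Optional character vector of channel names that must
#'   be present (error names any missing one).
#' @param voxel_size_zyx Optional voxel-size override (z, y, x) in
#'   micrometres, used when metadata are absent.
#' @param channel_names Optional channel names override (needed when no
#'   companion metadata exist).
#' @param stack_id,case_id Identifiers for the returned stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channels = NULL, voxel_size_zyx = NULL,
                       channel_names = NULL, stack_id = NULL,
                       case_id = NA_character_) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  bits <- attr(planes[[1L]], "bits.per.sample")
  top <- 2^bits - 1
  meta <- NULL
  cp <- companion_path(path)
  if (file.exists(cp)) meta <- parse_ome_companion(cp)
  if (is.null(voxel_size_zyx)) {
    if (is.null(meta))
      stop("no OME companion metadata and no voxel_size_zyx override",
           call. = FALSE)
    voxel_size_zyx <- meta$voxel_size_zyx
  }
  if (is.null(channel_names))
    channel_names <- if (!is.null(meta)) meta$channel_names else
      stop("no OME companion metadata and no channel_names override",
           call. = FALSE)
  n_c <- length(channel_names)
  n_z <- length(planes) / n_c
  if (n_z != round(n_z))
    stop("plane count ", length(planes), " is not a multiple of the ",
         n_c, " channels", call. = FALSE)
  d2 <- dim(planes[[1L]])
  chans <- stats::setNames(
    lapply(seq_len(n_c), function(ci) {
      a <- array(0, dim = c(n_z, d2[1], d2[2]))
      for (z in seq_len(n_z))
        a[z, , ] <- round(planes[[(z - 1L) * n_c + ci]] * top)
      a
    }), channel_names)
  if (!is.null(channels)) {
    missing <- setdiff(channels, channel_names)
    if (length(missing))
      stop("channel(s) missing from file: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(stack_id))
    stack_id <- if (!is.null(meta) && nzchar(meta$name)) meta$name
                else sub("\\.tiff?$", "", basename(path))
  image_stack(chans, voxel_size_zyx, stack_id = stack_id, case_id = case_id)
}

parse_ome_companion <- function(path) {
  x <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(x), d1 = "ome")
  px <- xml2::xml_find_first(x, ".//ome:Pixels", ns)
  att <- function(a) xml2::xml_attr(px, a)
  list(
    voxel_size_zyx = as.numeric(c(att("PhysicalSizeZ"), att("PhysicalSizeY"),
                                  att("PhysicalSizeX"))),
    sizes = as.integer(c(att("SizeZ"), att("SizeY"), att("SizeX"),
                         att("SizeC"))),
    channel_names = xml2::xml_attr(
      xml2::xml_find_all(x, ".//ome:Channel", ns), "Name"),
    name = xml2::xml_attr(xml2::xml_find_first(x, ".//ome:Image", ns),
                          "Name"))
}

#' Write an integer label volume as 16-bit TIFF
#'
#' @param labels Integer 3D array (z, y, x); values must fit in 16 bits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot_shape3(labels)
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  planes <- lapply(seq_len(dim(labels)[1]),
                   function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF path.
#' @return Integer 3D array.
#' @export
read_labels <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  a <- array(0L, dim = c(length(planes), dim(planes[[1L]])))
  for (z in seq_along(planes)) a[z, , ] <- as.integer(round(planes[[z]] * 65535))
  a
}

#' Write ground truth (label TIFFs + JSON sidecar)
#'
#' Writes each ground-truth label volume as a 16-bit TIFF and a JSON
#' sidecar holding the punctum table, the planted parameters and the
#' seed.
#'
#' @param truth A `GroundTruth`.
#' @param base Output path prefix; files are `<base>_<channel>_labels.tif`
#'   and `<base>_truth.json`.
#' @return The JSON path, invisibly.
#' @export
write_ground_truth <- function(truth, base) {
  stopifnot(inherits(truth, "GroundTruth"))
  for (ch in names(truth$labels)) {
    v <- truth$labels[[ch]]
    if (is.logical(v)) v <- array(as.integer(v), dim = dim(v))
    write_labels(v, paste0(base, "_", ch, "_labels.tif"))
  }
  side <- list(stack_id = truth$stack_id, case_id = truth$case_id,
               seed = truth$seed, puncta = truth$puncta,
               params = unclass(truth$params))
  jp <- paste0(base, "_truth.json")
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(jp)
}
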