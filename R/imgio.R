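#' Write a multi-channel 3D stack to TIFF
#'
#' Pages are stored channel-fastest (all channels of z slice 1, then slice 2,
#' ...), matching the common XYCZT plane ordering of OME-TIFF exports.
#' Baseline TIFF writing in R stores 32-bit fixed point on `[0, 1]`, so
#' intensities are divided by a power-of-two scale before writing; the scale
#' is recorded in a JSON sidecar at `<path>.json` together with voxel size,
#' channel names, shape and provenance. Integer-valued data round-trip
#' bit-exactly (the sub-quantum quantisation error is rounded away on read);
#' float data round-trip to within the 32-bit quantum (`scale / (2^32 - 1)`).
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      pages[[p]] <- matrix(stack$data[ch, z, , ] / scale, d[3], d[4])
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    format = "phagoquant-stack",
    integer_data = all(stack$data == round(stack$data)),
    voxel = list(dx = stack$voxel$dx, dy = stack$voxel$dy, dz = stack$voxel$dz),
    channel_names = stack$channel_names,
    shape = as.integer(d),
    scale = scale,
    plane_order = "channel-fastest",
    provenance = stack$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Parse voxel size / dimensions from an OME-XML ImageDescription, if any.
parse_ome_description <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  ch <- xml2::xml_find_all(doc, ".//Channel")
  ch_names <- xml2::xml_attr(ch, "Name")
  list(
    dx = num("PhysicalSizeX"), dy = num("PhysicalSizeY"), dz = num("PhysicalSizeZ"),
    size_c = num("SizeC"), size_z = num("SizeZ"),
    dimension_order = xml2::xml_attr(px, "DimensionOrder"),
    channel_names = if (length(ch_names) && !anyNA(ch_names)) ch_names else NULL
  )
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(NULL)
  meta <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || !identical(meta$format, "phagoquant-stack")) return(NULL)
  meta
}

#' Read a multi-channel 3D stack from TIFF / OME-TIFF
#'
#' Pages must encode (channel, z) planes. Channel count and voxel size are
#' resolved in priority order: explicit arguments, then OME-XML metadata in
#' the ImageDescription (`PhysicalSizeX/Y/Z`, `SizeC`, `SizeZ`), then the
#' JSON sidecar written by [write_stack()]. A stack without any voxel-size
#' source is an error -- never a silent default.
#'
#' @param path TIFF path.
#' @param channel_names Optional channel labels; must match the file's
#'   channel count.
#' @param voxel Optional [voxel_size()] override; wins over file metadata.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, voxel = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages == 0) stop("TIFF contains no pages", call. = FALSE)
  if (length(dim(pages[[1]])) != 2) {
    stop("only single-sample (grayscale) TIFF pages are supported", call. = FALSE)
  }
  meta <- read_sidecar(path)
  ome <- parse_ome_description(attr(pages[[1]], "description"))

  # channel count
  n_chan <- NULL
  if (!is.null(channel_names)) {
    n_chan <- length(channel_names)
  } else if (!is.null(meta)) {
    channel_names <- meta$channel_names
    n_chan <- length(channel_names)
  } else if (!is.null(ome) && is.finite(ome$size_c)) {
    n_chan <- as.integer(ome$size_c)
    channel_names <- if (!is.null(ome$channel_names) &&
                         length(ome$channel_names) == n_chan) {
      ome$channel_names
    } else paste0("ch", seq_len(n_chan))
  } else {
    stop("channel count unknown: supply 'channel_names' or provide metadata",
         call. = FALSE)
  }
  file_chan <- if (!is.null(meta)) meta$shape[1]
               else if (!is.null(ome) && is.finite(ome$size_c)) as.integer(ome$size_c)
               else NULL
  if (!is.null(file_chan) && file_chan != n_chan) {
    stop(sprintf("channel count mismatch: file has %d channels, %d names given",
                 file_chan, n_chan), call. = FALSE)
  }
  if (n_pages %% n_chan != 0) {
    stop(sprintf("page count %d is not a multiple of channel count %d",
                 n_pages, n_chan), call. = FALSE)
  }
  nz <- n_pages %/% n_chan

  # voxel size
  if (!is.null(voxel)) {
    voxel <- as_voxel_size(voxel)
  } else if (!is.null(meta)) {
    voxel <- voxel_size(meta$voxel$dx, meta$voxel$dy, meta$voxel$dz)
  } else if (!is.null(ome) && all(is.finite(c(ome$dx, ome$dy, ome$dz)))) {
    voxel <- voxel_size(ome$dx, ome$dy, ome$dz)
  } else {
    stop("no voxel size in file metadata and no override supplied", call. = FALSE)
  }

  scale <- if (!is.null(meta)) meta$scale else 1
  z_fastest <- !is.null(ome) && is.null(meta) &&
    isTRUE(grepl("^XYZ", ome$dimension_order))
  dmyx <- dim(pages[[1]])
  arr <- array(0, c(n_chan, nz, dmyx[1], dmyx[2]))
  for (p in seq_len(n_pages)) {
    if (z_fastest) {
      z <- (p - 1L) %% nz + 1L
      ch <- (p - 1L) %/% nz + 1L
    } else {
      ch <- (p - 1L) %% n_chan + 1L
      z <- (p - 1L) %/% n_chan + 1L
    }
    arr[ch, z, , ] <- pages[[p]] * scale
  }
  # baseline TIFF stores 32-bit fixed point in [0, 1]; quantisation error is
  # < scale / (2^32 - 1), so integer-valued data are restored exactly
  if (!is.null(meta) && isTRUE(meta$integer_data)) arr <- round(arr)
  prov <- if (!is.null(meta) && !is.null(meta$provenance)) meta$provenance else path
  channel_stack(arr, voxel, channel_names, provenance = prov)
}
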