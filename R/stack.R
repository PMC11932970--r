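#' Multi-channel 3D image stack
#'
#' The unit of image analysis: an intensity array indexed `(channel, z, y, x)`
#' together with its physical voxel size and ordered channel labels. Slice 1
#' along z is the imaging surface by convention (stacks acquired the other way
#' up can be flipped with `flip_z`). Intensities must be non-negative
#' (raw photon counts or unit-scaled floats).
#'
#' @param data 4D numeric array with dimensions `(channel, z, y, x)`.
#'   A 3D array is promoted to a single channel.
#' @param voxel A [voxel_size()].
#' @param channel_names Character vector of unique channel labels, one per
#'   channel, e.g. `c("iba1", "cd68", "marker")`.
#' @param provenance Free-text source identifier carried through the analysis.
#' @return An object of class `channel_stack`.
#' @examples
#' a <- array(0, c(2, 4, 8, 8))
#' s <- channel_stack(a, voxel_preset_20x(), c("iba1", "cd68"))
#' dim(s$data)
#' @export
channel_stack <- function(data, voxel, channel_names, provenance = "") {
  if (length(dim(data)) == 3) {
    data <- array(data, c(1, dim(data)))
  }
  if (length(dim(data)) != 4) {
    stop("'data' must be a (channel, z, y, x) array", call. = FALSE)
  }
  if (!is.numeric(data)) stop("'data' must be numeric", call. = FALSE)
  if (any(data < 0)) stop("intensities must be non-negative", call. = FALSE)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[1]) {
    stop(sprintf("channel count mismatch: data has %d channels, %d names given",
                 dim(data)[1], length(channel_names)), call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  structure(
    list(data = data, voxel = as_voxel_size(voxel),
         channel_names = channel_names, provenance = provenance),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("channel_stack: %d channel(s) [%s], %d x %d x %d voxels (z, y, x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  print(x$voxel)
  if (nzchar(x$provenance)) cat("source:", x$provenance, "\n")
  invisible(x)
}

#' Extract one channel as a 3D array
#'
#' @param stack A [channel_stack()].
#' @param channel Channel name or integer index.
#' @return A 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) {
      stop(sprintf("no channel named '%s' (have: %s)", channel,
                   paste(stack$channel_names, collapse = ", ")), call. = FALSE)
    }
  } else {
    i <- as.integer(channel)
    if (i < 1 || i > dim(stack$data)[1]) stop("channel index out of range", call. = FALSE)
  }
  array(stack$data[i, , , ], dim(stack$data)[2:4])
}

#' Reverse the z axis of a stack
#'
#' Used when a stack was acquired with the imaging surface at the last slice;
#' the package convention puts the imaging surface at z slice 1.
#'
#' @param stack A [channel_stack()].
#' @return The stack with z order reversed.
#' @export
flip_z <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  nz <- dim(stack$data)[2]
  stack$data <- stack$data[, rev(seq_len(nz)), , , drop = FALSE]
  stack
}

# Pixel count for a physical crop target; tiny epsilon absorbs binary
# representation error in e.g. 192/0.3 so exact multiples stay exact.
.px_floor <- function(target_um, d_um) as.integer(floor(target_um / d_um + 1e-9))
.px_ceil  <- function(depth_um, d_um) as.integer(ceiling(depth_um / d_um - 1e-9))

#' Centred field-of-view crop in xy
#'
#' Crops all channels to a physical window of `target_um` x `target_um`
#' (micrometres), converted to `floor(target_um / dx)` x `floor(target_um / dy)`
#' pixels. The window is centred unless an explicit `offset` places it; voxel
#' size and channel order are unchanged. Standard use is restricting analysis
#' to a fixed 192 x 192 um field so volumes are comparable across sections.
#'
#' @param stack A [channel_stack()].
#' @param target_um Physical window edge length in micrometres (scalar, or
#'   length-2 `c(x, y)`).
#' @param offset Optional 1-based `c(y, x)` index of the window's first pixel;
#'   default centres the window.
#' @return The cropped [channel_stack()].
#' @export
crop_xy <- function(stack, target_um, offset = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  target_um <- rep(as.numeric(target_um), length.out = 2) # (x, y)
  d <- dim(stack$data)
  nx <- .px_floor(target_um[1], stack$voxel$dx)
  ny <- .px_floor(target_um[2], stack$voxel$dy)
  if (nx < 1 || ny < 1) stop("crop target smaller than one pixel", call. = FALSE)
  if (nx > d[4] || ny > d[3]) {
    stop(sprintf("crop target %g x %g um (%d x %d px) exceeds stack extent %d x %d px",
                 target_um[1], target_um[2], nx, ny, d[4], d[3]), call. = FALSE)
  }
  if (is.null(offset)) {
    y0 <- (d[3] - ny) %/% 2L + 1L
    x0 <- (d[4] - nx) %/% 2L + 1L
  } else {
    y0 <- as.integer(offset[1]); x0 <- as.integer(offset[2])
    if (y0 < 1 || x0 < 1 || y0 + ny - 1L > d[3] || x0 + nx - 1L > d[4]) {
      stop("offset places the crop window outside the stack", call. = FALSE)
    }
  }
  stack$data <- stack$data[, , y0:(y0 + ny - 1L), x0:(x0 + nx - 1L), drop = FALSE]
  stack
}

#' Keep only the top of the stack along z
#'
#' Retains the first `ceil(depth_um / dz)` slices from the imaging surface
#' (z slice 1), inclusive of a partial final slice. Used for adult tissue
#' where antibody penetration limits reliable staining to the top ~5 um of
#' the section.
#'
#' @param stack A [channel_stack()].
#' @param depth_um Physical depth to keep, in micrometres.
#' @param surface Either `"first"` (default; imaging surface is z slice 1) or
#'   `"last"` (stack acquired upside down; it is flipped before cropping).
#' @return The cropped [channel_stack()].
#' @export
crop_top_z <- function(stack, depth_um, surface = c("first", "last")) {
  stopifnot(inherits(stack, "channel_stack"))
  surface <- match.arg(surface)
  if (surface == "last") stack <- flip_z(stack)
  d <- dim(stack$data)
  nz <- .px_ceil(depth_um, stack$voxel$dz)
  if (nz < 1) stop("depth smaller than one slice", call. = FALSE)
  if (nz > d[2]) {
    stop(sprintf("depth %g um (%d slices) exceeds stack depth %d slices",
                 depth_um, nz, d[2]), call. = FALSE)
  }
  stack$data <- stack$data[, seq_len(nz), , , drop = FALSE]
  stack
}
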