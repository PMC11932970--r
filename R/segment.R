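#' Binary 3D mask
#'
#' A boolean voxel grid `(z, y, x)` with its physical voxel size and the
#' provenance of the segmentation that produced it (source channel, method,
#' applied threshold).
#'
#' @param grid Logical 3D array `(z, y, x)`.
#' @param voxel A [voxel_size()].
#' @param source_channel Label of the channel the mask was derived from.
#' @param threshold Numeric threshold applied (`image > threshold`), if any.
#' @param method Thresholding method name, if any.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, voxel, source_channel = NA_character_,
                        threshold = NA_real_, method = NA_character_) {
  if (is.numeric(grid)) grid <- grid > 0
  if (!is.logical(grid) || length(dim(grid)) != 3) {
    stop("'grid' must be a logical 3D array (z, y, x)", call. = FALSE)
  }
  structure(
    list(grid = grid, voxel = as_voxel_size(voxel),
         source_channel = source_channel,
         threshold = threshold, method = method),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "binary_mask [%s]: %d x %d x %d voxels (z, y, x), %d true (%.3g um^3)\n",
    x$source_channel, d[1], d[2], d[3], sum(x$grid), mask_volume_um3(x)))
  if (!is.na(x$threshold)) {
    cat(sprintf("threshold: %g (%s)\n", x$threshold, x$method))
  }
  invisible(x)
}

as_mask_grid <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$grid else mask
}

#' Binarise a single-channel 3D image
#'
#' Computes one global threshold over the whole volume (no per-slice
#' thresholding) and returns the mask `image > threshold`. Methods:
#' `"otsu"` minimises intra-class intensity variance over 256 candidate
#' levels spanning the data range (via [EBImage::otsu()] on the pooled
#' histogram); `"quantile"` uses an intensity quantile; `"fixed"` applies a
#' user-supplied threshold. The chosen threshold and method are recorded in
#' the returned mask for the run report.
#'
#' @param image 3D numeric array `(z, y, x)`, or a [channel_stack()] together
#'   with `channel`.
#' @param method One of `"otsu"`, `"fixed"`, `"quantile"`.
#' @param fixed_threshold Threshold value; required iff `method = "fixed"`.
#' @param probs Quantile for `method = "quantile"` (default 0.99, i.e. the
#'   brightest 1% of voxels).
#' @param voxel [voxel_size()]; required when `image` is a bare array.
#' @param channel Channel to binarise when `image` is a [channel_stack()].
#' @param source_channel Label recorded in the mask provenance.
#' @return A [binary_mask()].
#' @export
binarize <- function(image, method = c("otsu", "fixed", "quantile"),
                     fixed_threshold = NULL, probs = 0.99, voxel = NULL,
                     channel = NULL, source_channel = NULL) {
  method <- match.arg(method)
  if (inherits(image, "channel_stack")) {
    if (is.null(channel)) stop("supply 'channel' to binarise a channel_stack", call. = FALSE)
    if (is.null(source_channel)) {
      source_channel <- if (is.character(channel)) channel else image$channel_names[channel]
    }
    voxel <- image$voxel
    image <- get_channel(image, channel)
  }
  if (is.null(voxel)) stop("'voxel' is required for a bare array", call. = FALSE)
  if (length(dim(image)) != 3) stop("'image' must be a 3D array", call. = FALSE)
  if (is.null(source_channel)) source_channel <- NA_character_

  thr <- switch(method,
    fixed = {
      if (is.null(fixed_threshold)) {
        stop("method = 'fixed' requires 'fixed_threshold'", call. = FALSE)
      }
      as.numeric(fixed_threshold)
    },
    quantile = as.numeric(stats::quantile(image, probs, names = FALSE)),
    otsu = {
      rng <- range(image)
      if (rng[1] == rng[2]) {
        stop(sprintf(
          "degenerate histogram: image is constant at %g, Otsu threshold undefined",
          rng[1]), call. = FALSE)
      }
      xn <- (as.vector(image) - rng[1]) / (rng[2] - rng[1])
      tn <- EBImage::otsu(EBImage::Image(matrix(xn, ncol = 1L)),
                          range = c(0, 1), levels = 256L)
      rng[1] + as.numeric(tn) * (rng[2] - rng[1])
    }
  )
  binary_mask(image > thr, voxel, source_channel = source_channel,
              threshold = thr, method = method)
}

# Connected-component membership over the true voxels of a logical grid.
# Returns list(idx = linear indices of true voxels, comp = component id per
# voxel). Adjacency graph built from half-offsets, components via igraph.
label3d_core <- function(grid, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  dm <- dim(grid)
  idx <- which(grid)
  n <- length(idx)
  if (n == 0) return(list(idx = integer(), comp = integer()))
  pos <- integer(prod(dm))
  pos[idx] <- seq_len(n)
  coord <- arrayInd(idx, dm)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  if (connectivity == 6) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  } else {
    offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  }
  # keep one of each +/- pair
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
               (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z <- coord[, 1] + offs$dz[k]
    y <- coord[, 2] + offs$dy[k]
    x <- coord[, 3] + offs$dx[k]
    inb <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    if (!any(inb)) next
    nb_lin <- (x[inb] - 1L) * (dm[1] * dm[2]) + (y[inb] - 1L) * dm[1] + z[inb]
    nb_pos <- pos[nb_lin]
    hit <- nb_pos > 0L
    from <- c(from, which(inb)[hit])
    to <- c(to, nb_pos[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  comp <- igraph::components(g)$membership
  list(idx = idx, comp = as.integer(comp))
}

#' Label connected components of a 3D mask
#'
#' Finds connected components under 6- or 26-connectivity, discards those
#' below `min_voxels`, and returns one region of interest per surviving
#' component. Regions are ordered by descending voxel count, ties broken by
#' the lexicographic order of their centroids `(z, y, x)`. Centroids and
#' bounding boxes use 1-based voxel indices.
#'
#' @param mask A [binary_mask()] or logical 3D array (then supply `voxel`).
#' @param connectivity 6 (face neighbours) or 26 (face, edge and corner
#'   neighbours; the usual 3D-ROI convention and the default).
#' @param min_voxels Minimum component size kept (default 10, suppressing
#'   shot-noise specks).
#' @param voxel [voxel_size()] when `mask` is a bare array.
#' @return A data.frame with one row per component: `label`, `voxel_count`,
#'   `volume_um3`, `centroid_z/y/x`, and bounding box `z0,z1,y0,y1,x0,x1`.
#' @export
label_components <- function(mask, connectivity = 26, min_voxels = 10,
                             voxel = NULL) {
  if (inherits(mask, "binary_mask")) {
    voxel <- mask$voxel
    grid <- mask$grid
  } else {
    if (is.null(voxel)) stop("'voxel' is required for a bare array", call. = FALSE)
    grid <- mask
  }
  empty <- data.frame(
    label = integer(), voxel_count = integer(), volume_um3 = numeric(),
    centroid_z = numeric(), centroid_y = numeric(), centroid_x = numeric(),
    z0 = integer(), z1 = integer(), y0 = integer(), y1 = integer(),
    x0 = integer(), x1 = integer())
  lab <- label3d_core(grid, connectivity)
  if (length(lab$idx) == 0) return(empty)
  coord <- arrayInd(lab$idx, dim(grid))
  cnt <- tabulate(lab$comp)
  cen <- rowsum(coord, lab$comp) / cnt
  z0 <- tapply(coord[, 1], lab$comp, min); z1 <- tapply(coord[, 1], lab$comp, max)
  y0 <- tapply(coord[, 2], lab$comp, min); y1 <- tapply(coord[, 2], lab$comp, max)
  x0 <- tapply(coord[, 3], lab$comp, min); x1 <- tapply(coord[, 3], lab$comp, max)
  keep <- which(cnt >= min_voxels)
  if (length(keep) == 0) return(empty)
  ord <- keep[order(-cnt[keep], cen[keep, 1], cen[keep, 2], cen[keep, 3])]
  vv <- voxel_volume(as_voxel_size(voxel))
  data.frame(
    label = seq_along(ord),
    voxel_count = cnt[ord],
    volume_um3 = cnt[ord] * vv,
    centroid_z = cen[ord, 1], centroid_y = cen[ord, 2], centroid_x = cen[ord, 3],
    z0 = as.integer(z0[ord]), z1 = as.integer(z1[ord]),
    y0 = as.integer(y0[ord]), y1 = as.integer(y1[ord]),
    x0 = as.integer(x0[ord]), x1 = as.integer(x1[ord]),
    row.names = NULL)
}

#' Physical volume of a binary mask
#'
#' True-voxel count times the physical voxel volume; the unit of every
#' volumetric readout in the assay.
#'
#' @param mask A [binary_mask()] or logical 3D array (then supply `voxel`).
#' @param voxel [voxel_size()] when `mask` is a bare array.
#' @return Volume in cubic micrometres.
#' @export
mask_volume_um3 <- function(mask, voxel = NULL) {
  if (inherits(mask, "binary_mask")) {
    sum(mask$grid) * voxel_volume(mask$voxel)
  } else {
    if (is.null(voxel)) stop("'voxel' is required for a bare array", call. = FALSE)
    sum(mask) * voxel_volume(as_voxel_size(voxel))
  }
}
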