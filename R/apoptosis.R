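#' Detect labelled cells in a single-channel 3D image
#'
#' Automated replacement for manual widefield counting: binarise the channel,
#' label connected components, discard blobs below a minimum physical volume,
#' and report one detection per surviving component at its intensity-weighted
#' centroid. A blank (constant) image yields zero detections.
#'
#' @param image 3D numeric array `(z, y, x)` or a single-channel
#'   [channel_stack()].
#' @param voxel [voxel_size()] (taken from the stack if given).
#' @param min_blob_volume_um3 Minimum blob volume kept (default 5 um^3,
#'   well below a cell body but above shot-noise specks).
#' @param threshold_method Passed to [binarize()].
#' @param fixed_threshold For `threshold_method = "fixed"`.
#' @param connectivity Component connectivity (default 26).
#' @return A data.frame with one row per detection: `z`, `y`, `x`
#'   (intensity-weighted centroid, 1-based voxel units), `voxel_count`,
#'   `volume_um3`, `intensity` (summed intensity over the blob).
#' @export
detect_cells <- function(image, voxel = NULL, min_blob_volume_um3 = 5,
                         threshold_method = "otsu", fixed_threshold = NULL,
                         connectivity = 26) {
  if (inherits(image, "channel_stack")) {
    voxel <- image$voxel
    image <- get_channel(image, 1)
  }
  if (is.null(voxel)) stop("'voxel' is required for a bare array", call. = FALSE)
  voxel <- as_voxel_size(voxel)
  empty <- data.frame(z = numeric(), y = numeric(), x = numeric(),
                      voxel_count = integer(), volume_um3 = numeric(),
                      intensity = numeric())
  if (length(image) == 0 || max(image) == min(image)) return(empty)
  mask <- binarize(image, method = threshold_method,
                   fixed_threshold = fixed_threshold, voxel = voxel,
                   source_channel = "caspase3")
  lab <- label3d_core(mask$grid, connectivity)
  if (length(lab$idx) == 0) return(empty)
  min_vox <- max(1, ceiling(min_blob_volume_um3 / voxel_volume(voxel)))
  cnt <- tabulate(lab$comp)
  w <- image[lab$idx]
  coord <- arrayInd(lab$idx, dim(image))
  wsum <- rowsum(w, lab$comp)
  cen <- rowsum(coord * w, lab$comp) / as.vector(wsum)
  keep <- which(cnt >= min_vox)
  if (length(keep) == 0) return(empty)
  ord <- keep[order(-cnt[keep])]
  data.frame(z = cen[ord, 1], y = cen[ord, 2], x = cen[ord, 3],
             voxel_count = cnt[ord],
             volume_um3 = cnt[ord] * voxel_volume(voxel),
             intensity = as.vector(wsum)[ord],
             row.names = NULL)
}

#' Map detections to normalized hemisection coordinates
#'
#' Converts voxel-space detection centroids to the unit hemisection template
#' used by the generator and the density map: `u = (x - 1) / (nx - 1)`
#' (medio-lateral), `v = (y - 1) / (ny - 1)` (dorso-ventral), clipped to
#' `[0, 1]`. For real sections a landmark-based affine would replace this
#' direct scaling.
#'
#' @param detections Data.frame with `y`, `x` columns (from [detect_cells()]).
#' @param dim_yx Integer `(ny, nx)` image extent.
#' @return `detections` with `u`, `v` columns appended.
#' @export
hemisection_coords <- function(detections, dim_yx) {
  detections$u <- clip01((detections$x - 1) / max(dim_yx[2] - 1, 1))
  detections$v <- clip01((detections$y - 1) / max(dim_yx[1] - 1, 1))
  detections
}

#' Per-animal apoptosis summary
#'
#' Total cells over all counted sections, normalised to the number of
#' sections counted.
#'
#' @param counts Integer vector of per-section cell counts (or a list of
#'   per-section detection data.frames).
#' @param n_sections Number of sections counted; defaults to
#'   `length(counts)`. Must be >= 1.
#' @param animal_id Identifier carried into the summary.
#' @return A one-row data.frame of class `apoptosis_summary`: `animal_id`,
#'   `total_cells`, `n_sections`, `cells_per_section`.
#' @export
summarize_animal <- function(counts, n_sections = length(counts),
                             animal_id = NA_character_) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- vapply(counts, function(d) nrow(as.data.frame(d)), integer(1))
  }
  if (n_sections < 1) stop("n_sections must be >= 1", call. = FALSE)
  total <- sum(counts)
  out <- data.frame(animal_id = as.character(animal_id),
                    total_cells = total,
                    n_sections = as.integer(n_sections),
                    cells_per_section = total / n_sections,
                    stringsAsFactors = FALSE)
  class(out) <- c("apoptosis_summary", class(out))
  out
}

#' Superimposed apoptotic density map
#'
#' Gaussian-kernel density estimate of pooled cell locations from many
#' animals on the unit hemisection grid, scaled so the map integrates to a
#' target (by default the pooled mean cells per section, so the map reads as
#' a local rate). The overlay table lists every point with its animal id,
#' mirroring per-animal colour-coded superimposition figures.
#'
#' @param detections Data.frame with `u`, `v` and (optionally) `animal_id`.
#' @param n_sections Total number of sections contributing, used for the
#'   default normalization.
#' @param grid_shape `(n_v, n_u)` grid resolution (default 128 x 128).
#' @param kernel_sigma Gaussian kernel sd on the unit template (default 0.05,
#'   i.e. 5% of the hemisection width).
#' @param normalize_to Target integral of the map; default
#'   `nrow(detections) / n_sections` (mean cells per section), or 1 if
#'   `n_sections` is missing.
#' @return A list of class `density_map`: `u`, `v` (grid coordinates),
#'   `density` (matrix indexed `[u, v]`), `integral`, and `overlay`.
#' @export
density_map <- function(detections, n_sections = NULL,
                        grid_shape = c(128, 128), kernel_sigma = 0.05,
                        normalize_to = NULL) {
  detections <- as.data.frame(detections)
  if (nrow(detections) == 0) stop("no detections to map", call. = FALSE)
  if (is.null(normalize_to)) {
    normalize_to <- if (is.null(n_sections)) 1 else nrow(detections) / n_sections
  }
  n_u <- grid_shape[2]; n_v <- grid_shape[1]
  # MASS::kde2d parametrises bandwidth as h with kernel sd = h / 4
  kd <- MASS::kde2d(detections$u, detections$v, h = 4 * kernel_sigma,
                    n = c(n_u, n_v), lims = c(0, 1, 0, 1))
  du <- kd$x[2] - kd$x[1]; dv <- kd$y[2] - kd$y[1]
  raw_int <- sum(kd$z) * du * dv
  dens <- kd$z * (normalize_to / raw_int)
  structure(list(u = kd$x, v = kd$y, density = dens,
                 integral = normalize_to, kernel_sigma = kernel_sigma,
                 overlay = detections),
            class = "density_map")
}

#' Local maxima of a density map
#'
#' @param map A [density_map()].
#' @param n_peaks Number of highest local maxima to return.
#' @return A data.frame `u`, `v`, `height`, ordered by decreasing height.
#' @export
find_density_peaks <- function(map, n_peaks = 3) {
  z <- map$density
  nu <- nrow(z); nv <- ncol(z)
  peaks <- list()
  for (i in 2:(nu - 1)) {
    for (j in 2:(nv - 1)) {
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (z[i, j] == max(nb) && z[i, j] > 0) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          u = map$u[i], v = map$v[j], height = z[i, j])
      }
    }
  }
  if (length(peaks) == 0) {
    return(data.frame(u = numeric(), v = numeric(), height = numeric()))
  }
  out <- do.call(rbind, peaks)
  out <- out[order(-out$height), , drop = FALSE]
  # suppress shoulder maxima within a kernel width of a stronger peak
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    d <- sqrt((out$u[seq_len(i - 1)] - out$u[i])^2 +
              (out$v[seq_len(i - 1)] - out$v[i])^2)
    if (any(keep[seq_len(i - 1)] & d < map$kernel_sigma)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  utils::head(out, n_peaks)
}
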