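#' Physical voxel dimensions
#'
#' Stores the physical edge lengths of a voxel in micrometres. Confocal
#' stacks are anisotropic (the z step is usually 2-3x the xy pixel size), so
#' every volume and distance computation in the package carries these three
#' numbers along rather than assuming cubic voxels.
#'
#' @param dx,dy,dz Voxel edge length in micrometres along x, y and z;
#'   all strictly positive.
#' @return An object of class `voxel_size` (a named list with elements
#'   `dx`, `dy`, `dz`).
#' @examples
#' v <- voxel_size(0.3, 0.3, 0.67)
#' voxel_volume(v)
#' @export
voxel_size <- function(dx, dy, dz) {
  v <- c(dx = as.numeric(dx)[1], dy = as.numeric(dy)[1], dz = as.numeric(dz)[1])
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("voxel dimensions must be strictly positive and finite", call. = FALSE)
  }
  structure(as.list(v), class = "voxel_size")
}

#' @export
print.voxel_size <- function(x, ...) {
  cat(sprintf("voxel: %g x %g x %g um (x, y, z); voxel volume %g um^3\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}

as_voxel_size <- function(v) {
  if (inherits(v, "voxel_size")) return(v)
  if (is.numeric(v) && length(v) == 3) {
    nm <- names(v)
    if (!is.null(nm) && all(c("dx", "dy", "dz") %in% nm)) {
      return(voxel_size(v[["dx"]], v[["dy"]], v[["dz"]]))
    }
    return(voxel_size(v[1], v[2], v[3]))
  }
  if (is.list(v) && all(c("dx", "dy", "dz") %in% names(v))) {
    return(voxel_size(v$dx, v$dy, v$dz))
  }
  stop("cannot interpret 'voxel' as a voxel size", call. = FALSE)
}

#' Volume of one voxel in cubic micrometres
#'
#' @param voxel A [voxel_size()].
#' @return `dx * dy * dz` in um^3.
#' @export
voxel_volume <- function(voxel) {
  voxel <- as_voxel_size(voxel)
  voxel$dx * voxel$dy * voxel$dz
}

#' Common confocal acquisition presets
#'
#' Voxel sizes for the two acquisition regimes this assay is typically run
#' under: a 20x water-immersion objective (0.3 x 0.3 x 0.67 um, used for
#' large-field A-fibre imaging) and a 63x oil-immersion objective at Nyquist
#' sampling (0.07 x 0.07 x 0.23 um, used for synaptic puncta).
#'
#' @return A [voxel_size()].
#' @export
voxel_preset_20x <- function() voxel_size(0.3, 0.3, 0.67)

#' @rdname voxel_preset_20x
#' @export
voxel_preset_63x <- function() voxel_size(0.07, 0.07, 0.23)
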