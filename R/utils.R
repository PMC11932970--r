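# Internal numerical utilities: seeded RNG scoping, deterministic seed
# splitting, separable anisotropic Gaussian blur, and voxel-ball stamping.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the synthetic-data generator flows from one master seed
#' through this splitting scheme (a small multiplicative-congruential hash of
#' the master seed and the stream indices), so e.g. per-animal and per-section
#' draws are independent streams and a cohort can be extended without
#' disturbing earlier draws. Results are always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream indices (e.g. animal index, section index).
#' @return An integer sub-seed.
#' @export
split_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  for (k in c(...)) {
    s <- (s * 48271 + (abs(as.numeric(k)) + 1) * 16807) %% m
  }
  as.integer(max(1, s))
}

# Separable Gaussian blur along one array axis via a row-normalised banded
# kernel matrix (edges renormalised rather than padded).
blur_axis <- function(a, axis, sigma) {
  if (!is.finite(sigma) || sigma <= 0) return(a)
  d <- dim(a)
  n <- d[axis]
  if (n == 1) return(a)
  r <- min(n - 1L, as.integer(ceiling(4 * sigma)))
  delta <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-0.5 * (delta / sigma)^2)
  K[abs(delta) > r] <- 0
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  out <- array(K %*% matrix(ap, nrow = n), dim(ap))
  aperm(out, order(perm))
}

# sigma_vox: blur sd in voxel units per axis, order (z, y, x).
gaussian_blur_3d <- function(a, sigma_vox) {
  for (ax in 1:3) a <- blur_axis(a, ax, sigma_vox[ax])
  a
}

# Integer voxel offsets (dz, dy, dx) covering an anisotropic ball of physical
# radius r_um. Always contains the origin.
ball_offsets <- function(r_um, voxel) {
  voxel <- as_voxel_size(voxel)
  rz <- floor(r_um / voxel$dz); ry <- floor(r_um / voxel$dy); rx <- floor(r_um / voxel$dx)
  g <- expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx)
  keep <- (g$dz * voxel$dz)^2 + (g$dy * voxel$dy)^2 + (g$dx * voxel$dx)^2 <= r_um^2 + 1e-12
  m <- as.matrix(g[keep, , drop = FALSE])
  if (nrow(m) == 0) m <- matrix(0L, 1, 3, dimnames = list(NULL, c("dz", "dy", "dx")))
  m
}

# Stamp balls (offset sets) at integer centres into a logical grid,
# clipping at the boundary. centres: matrix with columns (z, y, x).
stamp_balls <- function(dm, centres, offsets, grid = NULL) {
  if (is.null(grid)) grid <- array(FALSE, dm)
  if (is.null(nrow(centres)) || nrow(centres) == 0) return(grid)
  z <- outer(centres[, 1], offsets[, 1], "+")
  y <- outer(centres[, 2], offsets[, 2], "+")
  x <- outer(centres[, 3], offsets[, 3], "+")
  ok <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
  grid[cbind(z[ok], y[ok], x[ok])] <- TRUE
  grid
}

# Linear indices of voxels in `mask` where the whole ball (offset set) stays
# inside `mask` -- i.e. erosion of the mask by the ball, as candidate centres.
erode_centres <- function(mask, offsets) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(integer())
  coord <- arrayInd(idx, dm)
  ok <- rep(TRUE, length(idx))
  for (k in seq_len(nrow(offsets))) {
    if (all(offsets[k, ] == 0)) next
    z <- coord[, 1] + offsets[k, 1]
    y <- coord[, 2] + offsets[k, 2]
    x <- coord[, 3] + offsets[k, 3]
    inb <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    good <- inb
    good[inb] <- mask[cbind(z[inb], y[inb], x[inb])]
    ok <- ok & good
    if (!any(ok)) return(integer())
  }
  idx[ok]
}

# As erode_centres but for candidate centres that must avoid `mask` entirely
# (ball fits in the complement), evaluated only at the supplied centres.
centres_avoiding <- function(mask, centres, offsets) {
  dm <- dim(mask)
  if (is.null(nrow(centres)) || nrow(centres) == 0) return(logical(0))
  ok <- rep(TRUE, nrow(centres))
  for (k in seq_len(nrow(offsets))) {
    z <- centres[, 1] + offsets[k, 1]
    y <- centres[, 2] + offsets[k, 2]
    x <- centres[, 3] + offsets[k, 3]
    inb <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    hit <- inb
    hit[inb] <- mask[cbind(z[inb], y[inb], x[inb])]
    ok <- ok & !hit
  }
  ok
}

runif_range <- function(n, range) {
  range <- rep(as.numeric(range), length.out = 2)
  stats::runif(n, range[1], range[2])
}

sample_int_range <- function(n, range) {
  range <- rep(as.integer(round(range)), length.out = 2)
  if (range[2] < range[1]) range[2] <- range[1]
  if (range[1] == range[2]) return(rep(range[1], n))
  range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1))
}
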