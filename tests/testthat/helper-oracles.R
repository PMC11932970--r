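# Independent oracles used across tests. Deliberately naive implementations
# that share no code with the package internals.

# Per-voxel enumeration of single and joint mask volumes: walks every voxel
# index explicitly instead of vectorised logic.
oracle_overlap_counts <- function(a, b, m) {
  n_a <- 0L; n_ab <- 0L; n_m <- 0L; n_abm <- 0L; n_am <- 0L
  for (i in seq_along(a)) {
    ai <- a[[i]]; bi <- b[[i]]; mi <- m[[i]]
    if (ai) n_a <- n_a + 1L
    if (mi) n_m <- n_m + 1L
    if (ai && bi) n_ab <- n_ab + 1L
    if (ai && mi) n_am <- n_am + 1L
    if (ai && bi && mi) n_abm <- n_abm + 1L
  }
  list(iba1 = n_a, cd68_in_iba1 = n_ab, marker = n_m,
       engulfed = n_abm, contact = n_am)
}

# Breadth-first flood fill connected-component labelling.
oracle_flood_fill <- function(grid, connectivity = 26) {
  dm <- dim(grid)
  lab <- array(0L, dm)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  idx <- which(grid)
  coords <- arrayInd(idx, dm)
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(coords[s, ], 1, 3)
    lab[idx[s]] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        if (grid[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: minimise intra-class variance over all 256 integer levels.
oracle_otsu_level <- function(x) {
  h <- tabulate(as.integer(x) + 1L, 256L)
  n <- sum(h)
  best <- Inf; best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    lo <- rep(0:t, h[1:(t + 1)])
    hi <- rep((t + 1):255, h[(t + 2):256])
    within <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (within < best) { best <- within; best_t <- t }
  }
  best_t
}

random_mask <- function(dm, p = 0.2) {
  array(stats::runif(prod(dm)) < p, dm)
}

# A tiny rendered blob image for detection tests (shares no code with the
# package renderer: hand-rolled Gaussian bumps + uniform noise).
render_blobs <- function(dm, centres, amp = 1, width = 1.5, noise = 0.01) {
  img <- array(0, dm)
  co <- arrayInd(seq_len(prod(dm)), dm)
  for (i in seq_len(nrow(centres))) {
    d2 <- (co[, 1] - centres[i, 1])^2 + (co[, 2] - centres[i, 2])^2 +
      (co[, 3] - centres[i, 3])^2
    img <- img + array(amp * exp(-d2 / (2 * width^2)), dm)
  }
  img + array(stats::runif(prod(dm), 0, noise), dm)
}
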