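vx <- voxel_size(1, 1, 1)

test_that("blank sections yield zero detections", {
  expect_equal(nrow(detect_cells(array(0, c(6, 20, 20)), voxel = vx)), 0)
  expect_equal(nrow(detect_cells(array(2.5, c(6, 20, 20)), voxel = vx)), 0)
})

test_that("well-separated blobs are each detected near their true centre", {
  set.seed(13)
  dm <- c(10, 60, 60)
  centres <- cbind(sample(3:8, 10, replace = TRUE),
                   c(10, 10, 25, 25, 40, 40, 55, 55, 18, 48),
                   c(10, 40, 25, 55, 10, 40, 25, 55, 52, 12))
  img <- render_blobs(dm, centres, amp = 1, width = 1.5, noise = 0.02)
  det <- detect_cells(img, voxel = vx, min_blob_volume_um3 = 5)
  expect_equal(nrow(det), 10)
  # each truth centre has a detection within one voxel
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((det$z - centres[i, 1])^2 + (det$y - centres[i, 2])^2 +
                (det$x - centres[i, 3])^2)
    expect_lt(min(d), 1)
  }
})

test_that("detection count is bounded by component count and monotone in the size filter", {
  set.seed(23)
  dm <- c(8, 40, 40)
  centres <- cbind(c(4, 4), c(20, 23), c(20, 23)) # two nearby blobs
  img <- render_blobs(dm, centres, width = 2.5, noise = 0.02)
  det <- detect_cells(img, voxel = vx, min_blob_volume_um3 = 5)
  expect_lte(nrow(det), 2)

  img2 <- render_blobs(dm, cbind(c(3, 6), c(10, 30), c(10, 30)),
                       width = 1.5, noise = 0.02)
  n_prev <- Inf
  for (v in c(1, 10, 50, 500)) {
    n <- nrow(detect_cells(img2, voxel = vx, min_blob_volume_um3 = v))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("per-animal summaries normalise by sections counted and conserve totals", {
  s <- summarize_animal(c(3, 0, 2, 1, 4, 0, 2, 0), animal_id = "a1")
  expect_equal(s$cells_per_section, 1.5) # 12 cells / 8 sections
  expect_equal(s$total_cells, 12)
  expect_equal(summarize_animal(c(0, 0, 0))$cells_per_section, 0)
  expect_error(summarize_animal(integer(0), n_sections = 0), "n_sections")

  dets <- list(data.frame(z = 1:2, y = 1:2, x = 1:2),
               data.frame(z = 1, y = 1, x = 1),
               data.frame(z = numeric(), y = numeric(), x = numeric()))
  s2 <- summarize_animal(dets)
  expect_equal(s2$total_cells, 3)
  expect_equal(s2$cells_per_section, 1)
})

test_that("poisson cohorts recover the generating rate within its 95% band", {
  ap <- make_apoptosis_sections(rate_control = 0.4, rate_incision = 0.8,
                                n_animals = 6, sections = 12, seed = 11,
                                render = FALSE)
  for (grp in c("control", "incision")) {
    secs <- Filter(function(s) s$group == grp, ap$sections)
    total <- sum(vapply(secs, function(s) nrow(s$truth), integer(1)))
    n_sec <- length(secs)
    # exact Poisson 95% CI for the rate given the observed total
    ci <- c(stats::qgamma(0.025, total), stats::qgamma(0.975, total + 1)) / n_sec
    rate <- if (grp == "control") 0.4 else 0.8
    expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
  }
})

test_that("density maps integrate to their target and localise mass", {
  # single point, tiny kernel: mass concentrated at that location
  one <- data.frame(u = 0.3, v = 0.6, animal_id = "a")
  m1 <- density_map(one, grid_shape = c(64, 64), kernel_sigma = 0.01,
                    normalize_to = 1)
  pk <- find_density_peaks(m1, 1)
  expect_lt(abs(pk$u - 0.3), 0.03); expect_lt(abs(pk$v - 0.6), 0.03)
  du <- m1$u[2] - m1$u[1]; dv <- m1$v[2] - m1$v[1]
  expect_equal(sum(m1$density) * du * dv, 1, tolerance = 1e-9)

  # normalization to mean cells/section
  set.seed(33)
  pts <- data.frame(u = runif(60), v = runif(60))
  m2 <- density_map(pts, n_sections = 30, grid_shape = c(64, 64),
                    kernel_sigma = 0.05)
  expect_equal(sum(m2$density) * (m2$u[2] - m2$u[1]) * (m2$v[2] - m2$v[1]),
               2, tolerance = 1e-9) # 60 cells / 30 sections

  # uniform points give an approximately flat interior
  set.seed(43)
  ptsu <- data.frame(u = runif(4000), v = runif(4000))
  mu <- density_map(ptsu, grid_shape = c(64, 64), kernel_sigma = 0.08,
                    normalize_to = 1)
  interior <- mu$density[16:48, 16:48]
  expect_lt(stats::sd(interior) / mean(interior), 0.25)
})

test_that("hotspot mixtures are recovered as density-map maxima", {
  hs <- default_hotspots()
  ap <- make_apoptosis_sections(rate_control = 6, rate_incision = 6,
                                n_animals = 3, sections = 15, seed = 17,
                                hotspots = hs, render = FALSE)
  pts <- do.call(rbind, lapply(ap$sections, function(s) {
    if (nrow(s$truth) == 0) return(NULL)
    cbind(s$truth, animal_id = s$animal_id)
  }))
  map <- density_map(pts, n_sections = 90, kernel_sigma = 0.05)
  peaks <- find_density_peaks(map, nrow(hs))
  for (k in seq_len(nrow(hs))) {
    d <- sqrt((peaks$u - hs$u[k])^2 + (peaks$v - hs$v[k])^2)
    expect_lt(min(d), 0.1) # within ~one kernel width + hotspot sigma
  }
})

test_that("detections map onto the unit hemisection template", {
  det <- data.frame(z = 1, y = c(1, 65, 128), x = c(1, 65, 128))
  hc <- hemisection_coords(det, c(128, 128))
  expect_equal(hc$u, c(0, 64 / 127, 1))
  expect_equal(hc$v, c(0, 64 / 127, 1))
})
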