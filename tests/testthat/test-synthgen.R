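small_shape <- c(12, 64, 64)

test_that("identical seeds give bit-identical stacks and truth", {
  a <- make_section(shape = small_shape, seed = 7)
  b <- make_section(shape = small_shape, seed = 7)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$masks$marker$grid, b$truth$masks$marker$grid)
  expect_identical(a$truth$true_engulfed_fraction, b$truth$true_engulfed_fraction)
  c <- make_section(shape = small_shape, seed = 8)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("ground truth is self-consistent and honours fraction extremes", {
  sec0 <- make_section(
    puncta_params = puncta_field_params(engulfed_fraction = 0),
    shape = small_shape, seed = 3)
  tm <- sec0$truth$masks
  expect_equal(sum(tm$marker$grid & tm$lysosome_in_cell$grid), 0)
  expect_equal(sec0$truth$true_engulfed_fraction, 0)

  sec1 <- make_section(
    puncta_params = puncta_field_params(engulfed_fraction = 1),
    shape = small_shape, seed = 3)
  expect_equal(sec1$truth$true_engulfed_fraction, 1.0)

  # self-consistency: recomputing the overlap on the masks gives the field
  tm1 <- sec1$truth$masks
  expect_equal(sum(tm1$marker$grid & tm1$lysosome_in_cell$grid) /
                 sum(tm1$marker$grid),
               sec1$truth$true_engulfed_fraction)
})

test_that("realized engulfed fraction is unbiased for the requested fraction", {
  # ~500 expected puncta per section; mean realized fraction over 30 seeds
  # should sit within +/-0.01 of the requested 0.05 (binomial expectation)
  vv <- voxel_volume(voxel_preset_20x())
  dens <- 500 / (prod(small_shape) * vv / 1000)
  fr <- vapply(1:30, function(s) {
    make_section(
      puncta_params = puncta_field_params(density_per_1000um3 = dens,
                                          radius_um = 0.35,
                                          engulfed_fraction = 0.05),
      shape = small_shape, seed = 100 + s)$truth$true_engulfed_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.01)
})

test_that("lysosomes sit strictly inside cells and puncta masks are disjoint by design", {
  sec <- make_section(shape = small_shape, seed = 5)
  tm <- sec$truth$masks
  expect_true(all(tm$cell$grid[tm$lysosome_in_cell$grid]))
  # non-engulfed puncta avoid the cell entirely: marker voxels are either
  # inside lysosomes or outside the cell mask
  leak <- tm$marker$grid & tm$cell$grid & !tm$lysosome_in_cell$grid
  expect_equal(sum(leak), 0)
})

test_that("degenerate cohort designs reproduce their construction", {
  d0 <- cohort_design(n_per_group = 2, sections_per_animal = 2,
                      between_animal_cv = 0, within_animal_cv = 0,
                      sexes = "F", seed = 2)
  co <- make_cohort(d0, render = "none")
  expect_true(all(abs(co$truth_table$true_engulfed_fraction -
                        co$truth_table$true_engulfed_fraction[1]) < 1e-12))

  d1 <- cohort_design(
    n_per_group = 5, sections_per_animal = 2,
    effects = list(engulfed_fraction = c(sex = 0, neonatal = 0.03, adult = 0)),
    between_animal_cv = 0, within_animal_cv = 0,
    sexes = "F", adult_levels = "-", seed = 2)
  co1 <- make_cohort(d1, render = "none")
  tt <- co1$truth_table
  m <- tapply(tt$true_engulfed_fraction, tt$neonatal_incision, mean)
  expect_equal(unname(m["+"] - m["-"]), 0.03, tolerance = 1e-12)
})

test_that("cohort generation is deterministic and extensible by seed stream", {
  d <- cohort_design(n_per_group = 2, sections_per_animal = 2, sexes = "F",
                     seed = 9)
  a <- make_cohort(d, render = "none")
  b <- make_cohort(d, render = "none")
  expect_identical(a$truth_table, b$truth_table)
  # same animal keeps its draw when more sections are requested
  d3 <- d; d3$sections_per_animal <- 3
  c3 <- make_cohort(d3, render = "none")
  expect_equal(c3$truth_table$true_engulfed_fraction,
               a$truth_table$true_engulfed_fraction)
})

test_that("apoptosis sections follow their Poisson rates and hotspot mixture", {
  # rate 0: every section empty
  ap0 <- make_apoptosis_sections(rate_control = 0, rate_incision = 0,
                                 n_animals = 1, sections = 3, seed = 1,
                                 render = FALSE)
  expect_true(all(vapply(ap0$sections, function(s) nrow(s$truth), integer(1)) == 0))

  # rate 2, 100 sections: mean count within the Poisson 95% band
  ap2 <- make_apoptosis_sections(rate_control = 2, rate_incision = 2,
                                 n_animals = 1, sections = 50, seed = 2,
                                 render = FALSE)
  counts <- vapply(ap2$sections, function(s) nrow(s$truth), integer(1))
  expect_gt(mean(counts), 1.6); expect_lt(mean(counts), 2.4)

  # equal-weight hotspots attract roughly equal mass
  hs <- default_hotspots()
  ap <- make_apoptosis_sections(rate_control = 10, rate_incision = 10,
                                n_animals = 2, sections = 20, seed = 3,
                                hotspots = hs, render = FALSE)
  pts <- do.call(rbind, lapply(ap$sections, function(s) s$truth))
  d2 <- sapply(seq_len(nrow(hs)), function(k) {
    (pts$u - hs$u[k])^2 + (pts$v - hs$v[k])^2
  })
  nearest <- max.col(-d2)
  share <- tabulate(nearest, nrow(hs)) / nrow(pts)
  expect_true(all(abs(share - 1 / 3) < 0.1))
})
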