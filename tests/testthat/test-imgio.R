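make_random_stack <- function(dm = c(3, 5, 16, 16), voxel = voxel_preset_63x(),
                              integer_data = TRUE) {
  vals <- if (integer_data) {
    sample(0:65535, prod(dm), replace = TRUE)
  } else {
    runif(prod(dm))
  }
  channel_stack(array(as.numeric(vals), dm), voxel,
                paste0("ch", seq_len(dm[1])))
}

test_that("TIFF round-trip is the identity on data and voxel metadata", {
  set.seed(11)
  f <- file.path(withr::local_tempdir(), "s.tif")

  s <- make_random_stack() # uint16-style values, 63x voxel preset
  write_stack(s, f)
  r <- read_stack(f)
  expect_identical(r$data, s$data)
  expect_identical(unlist(r$voxel), unlist(voxel_preset_63x()))
  expect_identical(r$channel_names, s$channel_names)

  z <- channel_stack(array(0, c(2, 4, 8, 8)), voxel_size(0.3, 0.3, 0.67),
                     c("a", "b"))
  write_stack(z, f)
  expect_identical(read_stack(f)$data, z$data)

  fs <- make_random_stack(integer_data = FALSE)
  write_stack(fs, f)
  rf <- read_stack(f)
  expect_lt(max(abs(rf$data - fs$data) / pmax(fs$data, 1e-3)), 1e-6)
})

test_that("read_stack resolves channels and voxel size and errors loudly", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.tif")
  s <- make_random_stack(c(2, 10, 8, 8))
  write_stack(s, f)

  # shape recovered (2 channels x 10 slices)
  expect_equal(dim(read_stack(f)$data), c(2, 10, 8, 8))
  # explicit names of the wrong length: contract violation
  expect_error(read_stack(f, channel_names = c("a", "b", "c")), "mismatch")
  # override wins over sidecar metadata
  ov <- read_stack(f, voxel = voxel_size(1, 1, 2))
  expect_equal(ov$voxel$dz, 2)
  # missing file
  expect_error(read_stack(file.path(dir, "none.tif")), "not found")
  # bare TIFF with no metadata and no override: explicit error, no default
  f2 <- file.path(dir, "bare.tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4)), f2)
  expect_error(read_stack(f2, channel_names = "a"), "voxel")
})

test_that("read_stack parses OME-XML voxel metadata", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ome.tif")
  desc <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels DimensionOrder="XYCZT" SizeC="1" SizeZ="2" SizeT="1" SizeX="4" SizeY="4"',
    ' PhysicalSizeX="0.07" PhysicalSizeY="0.07" PhysicalSizeZ="0.23" Type="float">',
    '<Channel Name="iba1"/></Pixels></Image></OME>')
  # the tiff package cannot write a description, so synthesise one via python
  # tifffile if available; otherwise exercise the parser directly
  meta <- phagoquant:::parse_ome_description(desc)
  expect_equal(meta$dx, 0.07)
  expect_equal(meta$dz, 0.23)
  expect_equal(meta$size_c, 1)
  expect_equal(meta$channel_names, "iba1")
})

test_that("xy crop converts physical target to pixels and centres the window", {
  # 1000 x 1000 px at 0.3 um -> a 192 um window is exactly 640 px
  s <- channel_stack(array(0, c(1, 1, 1000, 1000)), voxel_preset_20x(), "a")
  cr <- crop_xy(s, 192)
  expect_equal(dim(cr$data)[3:4], c(640, 640))
  expect_identical(unlist(cr$voxel), unlist(s$voxel))

  # full-extent target leaves the stack unchanged
  s2 <- channel_stack(array(runif(2 * 3 * 20 * 20), c(2, 3, 20, 20)),
                      voxel_size(0.5, 0.5, 1), c("a", "b"))
  expect_identical(crop_xy(s2, 10)$data, s2$data)

  # an impulse at the geometric centre survives any centred crop
  a <- array(0, c(1, 1, 21, 21)); a[1, 1, 11, 11] <- 7
  s3 <- channel_stack(a, voxel_size(1, 1, 1), "a")
  cr3 <- crop_xy(s3, 11)
  expect_equal(dim(cr3$data)[3:4], c(11, 11))
  expect_equal(cr3$data[1, 1, 6, 6], 7)
  expect_equal(sum(cr3$data), 7)

  expect_error(crop_xy(s3, 25), "exceeds")
})

test_that("top-z crop keeps ceil(depth/dz) slices from the imaging surface", {
  s <- channel_stack(array(0, c(1, 50, 4, 4)), voxel_preset_63x(), "a")
  expect_equal(dim(crop_top_z(s, 5)$data)[2], 22) # ceil(5 / 0.23)

  s2 <- channel_stack(array(runif(2 * 10 * 4 * 4), c(2, 10, 4, 4)),
                      voxel_size(1, 1, 0.5), c("a", "b"))
  expect_identical(crop_top_z(s2, 5)$data, s2$data) # full extent

  a <- array(0, c(1, 10, 4, 4)); a[1, 1, 2, 2] <- 1; a[1, 10, 2, 2] <- 1
  s3 <- channel_stack(a, voxel_size(1, 1, 1), "a")
  cr <- crop_top_z(s3, 3)
  expect_equal(cr$data[1, 1, 2, 2], 1) # surface impulse retained
  expect_equal(sum(cr$data), 1)        # deep impulse removed
  expect_error(crop_top_z(s3, 11), "exceeds")
})

test_that("xy and z crops commute and never alter voxel size or channels", {
  set.seed(5)
  for (i in 1:5) {
    s <- channel_stack(array(runif(2 * 12 * 30 * 30), c(2, 12, 30, 30)),
                       voxel_size(0.4, 0.4, 0.8), c("a", "b"))
    ab <- crop_top_z(crop_xy(s, 8), 6)
    ba <- crop_xy(crop_top_z(s, 6), 8)
    expect_identical(ab$data, ba$data)
    expect_identical(unlist(ab$voxel), unlist(s$voxel))
    expect_identical(ab$channel_names, s$channel_names)
  }
})
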