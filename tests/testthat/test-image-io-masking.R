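test_that("volume IO round trips exactly, both formats", {
  v <- hu_volume(array(round(rnorm(3 * 4 * 5), 6), c(3, 4, 5)),
                 c(0.4, 0.4, 1.0), c(1.5, -2, 3))
  for (ext in c(".nii.gz", ".nrrd")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(v, f)
    r <- read_volume(f)
    expect_equal(unname(r$values), unname(v$values), tolerance = 1e-12)
    expect_equal(r$spacing_mm, v$spacing_mm, tolerance = 1e-6)
    expect_equal(r$origin_mm, v$origin_mm, tolerance = 1e-6)
    expect_equal(r$direction, v$direction, tolerance = 1e-6)
  }
})

test_that("NRRD and NIfTI agree on the world coordinates of a voxel", {
  v <- hu_volume(array(0, c(6, 5, 4)), c(0.3, 0.3, 0.3), c(-1, 2, 0.5))
  v$values[4, 3, 2] <- 42
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  f2 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, f1); write_volume(v, f2)
  r1 <- read_volume(f1); r2 <- read_volume(f2)
  marked <- function(x) voxel_to_world(x, which(x$values == 42,
                                                arr.ind = TRUE) - 1)
  expect_equal(marked(r1), marked(r2), tolerance = 1e-6)
  # independent check: the known voxel index against origin + idx * spacing
  expect_equal(as.numeric(marked(r1)), c(-1, 2, 0.5) + c(3, 2, 1) * 0.3,
               tolerance = 1e-6)
})

test_that("mesh IO round trips (STL and PLY)", {
  fx <- fix_cylinder()
  mesh <- fx$analysis$lumen_mesh
  for (ext in c(".stl", ".ply")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mesh(mesh, f)
    r <- read_mesh(f)
    expect_equal(mesh_area(r), mesh_area(mesh), tolerance = 1e-6)
    expect_equal(mesh_volume(r), mesh_volume(mesh), tolerance = 1e-6)
  }
})

test_that("reading malformed or missing files fails loudly", {
  expect_error(read_volume("no_such_file.nii.gz"), "not found")
  f <- withr::local_tempfile(fileext = ".nrrd")
  writeLines("not an nrrd", f)
  expect_error(read_volume(f), "malformed")
  expect_error(read_volume("x.xyz"), "cannot infer")
})

test_that("HU thresholding reproduces the phantom lumen mask exactly", {
  fx <- fix_cylinder()
  lum <- threshold_lumen(fx$vox$volume)
  expect_identical(unname(lum$values), unname(fx$vox$lumen$values))
})

test_that("threshold window semantics are inclusive at both bounds", {
  vals <- array(c(99, 100, 300, 600, 601, 800), c(6, 1, 1))
  v <- hu_volume(vals, 1)
  m <- threshold_lumen(v)
  expect_equal(as.logical(m$values), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("seeded growth keeps the seeded component and drops distractors", {
  vals <- array(0, c(30, 10, 10))
  vals[2:10, 4:6, 4:6] <- 300    # target blob
  vals[20:28, 4:6, 4:6] <- 300   # disconnected distractor
  v <- hu_volume(vals, 1)
  seed <- voxel_to_world(v, c(5, 4, 4))
  m <- threshold_lumen(v, seeds = seed, iterations = 25)
  expect_true(m$values[5, 5, 5])
  expect_false(any(m$values[20:28, , ]))
  # a seed outside the window is refused by name
  bad <- voxel_to_world(v, c(15, 4, 4))
  expect_error(threshold_lumen(v, seeds = bad), "seed 1")
})

test_that("thresholding an all-background volume yields an empty mask", {
  v <- hu_volume(array(0, c(5, 5, 5)), 1)
  expect_false(any(threshold_lumen(v)$values))
})

test_that("calcification extraction keeps near components, drops far ones", {
  fx <- fix_cylinder()
  lum <- threshold_lumen(fx$vox$volume)
  calc <- extract_calcification(fx$vox$volume, lum)
  # the gap-0.2 wedge is fully retained
  expect_identical(unname(calc$values), unname(fx$vox$calcification$values))

  # a remote 800 HU cube 10 mm from the lumen is discarded
  vals <- array(0, c(60, 16, 16))
  vals[2:10, 6:10, 6:10] <- 300                    # lumen blob
  vals[11:12, 7:9, 7:9] <- 800                     # adjacent calcification
  vals[41:45, 7:9, 7:9] <- 800                     # >10 mm away at 0.5 mm voxels
  v <- hu_volume(vals, 0.5)
  lum2 <- threshold_lumen(v)
  calc2 <- extract_calcification(v, lum2, proximity_mm = 3)
  expect_true(all(calc2$values[11:12, 7:9, 7:9]))
  expect_false(any(calc2$values[41:45, , ]))
})

test_that("calcification threshold is strictly above 600 HU", {
  vals <- array(0, c(8, 5, 5))
  vals[2:3, 2:4, 2:4] <- 300
  vals[5, 3, 3] <- 600   # exactly 600: luminal contrast, not calcification
  vals[6, 3, 3] <- 601
  vals[7, 3, 3] <- 601
  v <- hu_volume(vals, 1)
  lum <- threshold_lumen(v)
  calc <- extract_calcification(v, lum, proximity_mm = 10)
  expect_false(calc$values[5, 3, 3])
  expect_true(calc$values[6, 3, 3])
})

test_that("calcification mask is always disjoint from the lumen mask", {
  fx <- fix_taper()
  lum <- threshold_lumen(fx$vox$volume)
  calc <- extract_calcification(fx$vox$volume, lum)
  expect_false(any(calc$values & lum$values))
  expect_error(
    extract_calcification(
      fx$vox$volume,
      binary_mask(array(FALSE, c(2, 2, 2)), 1, role = "lumen")),
    "grids differ")
})

test_that("thresholding is idempotent on its own output", {
  fx <- fix_cylinder()
  m1 <- threshold_lumen(fx$vox$volume)
  as_hu <- hu_volume(array(ifelse(m1$values, 300, 0), dim(m1$values)),
                     m1$spacing_mm, m1$origin_mm, m1$direction)
  m2 <- threshold_lumen(as_hu)
  expect_identical(m1$values, m2$values)
})
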