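test_that("curve arclengths and endpoints match closed forms", {
  semi <- curve_arc(40, 180)
  expect_equal(semi$length_mm, pi * 40)
  ev <- curve_eval(semi, c(0, semi$length_mm))
  expect_equal(sqrt(sum((ev$points[2, ] - ev$points[1, ])^2)), 80,
               tolerance = 1e-9)

  hx <- curve_helix(10, 20, 50)
  cs <- sample_curve(hx, ds = 0.01)
  polyline_len <- sum(sqrt(rowSums(diff(cs$points)^2)))
  expect_equal(polyline_len, 50, tolerance = 1e-4)

  ln <- curve_line(80)
  expect_equal(curve_eval(ln, 80)$points[1, ], c(0, 0, 80))
})

test_that("composite siphon curve is C1 with known junction arclengths", {
  cv <- carotid_siphon_curve()
  expect_s3_class(cv, "curve_spec")
  jn <- cv$params$junctions_mm
  for (s0 in jn) {
    ev <- curve_eval(cv, c(s0 - 1e-5, s0 + 1e-5))
    expect_lt(sqrt(sum((ev$points[2, ] - ev$points[1, ])^2)), 1e-3)
    expect_gt(sum(ev$tangents[1, ] * ev$tangents[2, ]), 1 - 1e-6)
  }
  # arclength parametrization is exact
  cs <- sample_curve(cv, ds = 0.01)
  expect_equal(sum(sqrt(rowSums(diff(cs$points)^2))), cv$length_mm,
               tolerance = 1e-4)
})

test_that("transported frames are orthonormal with minimal twist", {
  cv <- carotid_siphon_curve()
  cs <- sample_curve(cv, ds = 0.1)
  n <- nrow(cs$points)
  dots_tu <- rowSums(cs$tangents * cs$u)
  dots_uv <- rowSums(cs$u * cs$v)
  expect_lt(max(abs(dots_tu)), 1e-9)
  expect_lt(max(abs(dots_uv)), 1e-9)
  expect_equal(rowSums(cs$u^2), rep(1, n), tolerance = 1e-9)
  # adjacent in-plane rotation about the tangent stays below 1 degree
  twist <- sapply(seq_len(n - 1), function(i) {
    u2 <- cs$u[i + 1, ] - sum(cs$u[i + 1, ] * cs$tangents[i, ]) * cs$tangents[i, ]
    u2 <- u2 / sqrt(sum(u2^2))
    acos(pmin(1, sum(u2 * cs$u[i, ]))) * 180 / pi
  })
  expect_lt(max(twist), 1)
})

test_that("phantom truth matches tortuosity closed forms", {
  expect_equal(phantom_truth(phantom_spec(curve_line(80), 2))$tortuosity_index,
               0, tolerance = 1e-12)
  expect_equal(
    phantom_truth(phantom_spec(curve_arc(40, 180), 2))$tortuosity_index,
    pi / 2 - 1, tolerance = 1e-9)
  expect_equal(
    phantom_truth(phantom_spec(curve_arc(40, 90), 2))$tortuosity_index,
    pi / (2 * sqrt(2)) - 1, tolerance = 1e-9)
})

test_that("phantom truth records wedge parameters by construction", {
  w <- wedge_spec(10, 20, theta_center_deg = 45, arc_width_deg = 60,
                  thickness_mm = 0.5, gap_mm = 0.1)
  tr <- phantom_truth(phantom_spec(curve_line(80), 2, list(w)))
  expect_equal(tr$calc_count, 1)
  expect_equal(tr$wedges$extent_mm, 10)
  expect_equal(tr$wedges$arc_width_deg, 60)
  expect_equal(tr$wedges$thickness_mm, 0.5)
  expect_equal(tr$l_tot_mm, 10)
})

test_that("phantom lumen mesh area and volume match closed forms", {
  fx <- fix_cylinder()
  lat <- 2 * pi * 2 * 80
  caps <- 2 * pi * 4
  expect_equal(mesh_area(fx$meshes$lumen), lat + caps, tolerance = 0.01)
  expect_equal(mesh_volume(fx$meshes$lumen), pi * 4 * 80, tolerance = 0.01)
})

test_that("a full-ring wedge produces an annular sleeve mesh", {
  w <- wedge_spec(10, 20, theta_center_deg = 0, arc_width_deg = 360,
                  thickness_mm = 0.5, gap_mm = 0.2)
  spec <- phantom_spec(curve_line(40), 2, list(w))
  m <- build_phantom_meshes(spec)$calcifications[[1]]
  # lateral area of inner (r=2.2) + outer (r=2.7) shells over 10 mm
  shell <- 2 * pi * (2.2 + 2.7) * 10
  expect_equal(mesh_area(m), shell + 2 * pi * (2.7^2 - 2.2^2),
               tolerance = 0.02)
})

test_that("semicircular tube mesh endpoints are a diameter apart", {
  spec <- phantom_spec(curve_arc(40, 180), 2)
  ev <- curve_eval(spec$curve, c(0, spec$curve$length_mm))
  expect_equal(sqrt(sum((ev$points[2, ] - ev$points[1, ])^2)), 80,
               tolerance = 1e-9)
})

test_that("voxelization recovers volumes and separates HU classes", {
  fx <- fix_cylinder()
  vox <- fx$vox
  vol_lumen <- sum(vox$lumen$values) * 0.3^3
  expect_equal(vol_lumen, pi * 4 * 80, tolerance = 0.05)
  hu <- vox$volume$values
  # exactly three HU classes, no partial values
  expect_setequal(unique(as.numeric(hu)), c(0, 300, 800))
  expect_equal(sum(hu > 600 & hu < 800), 0)
  expect_identical(unname(vox$lumen$values), unname(hu == 300))
  expect_identical(unname(vox$calcification$values), unname(hu == 800))
})

test_that("voxelization of an empty wedge list yields an empty calc mask", {
  spec <- phantom_spec(curve_line(30), 2)
  vox <- voxelize_phantom(spec)
  expect_false(any(vox$calcification$values))
})

test_that("voxelization is deterministic and guards resolution and size", {
  spec <- phantom_spec(curve_line(20), 2)
  v1 <- voxelize_phantom(spec)
  v2 <- voxelize_phantom(spec)
  expect_identical(v1$volume$values, v2$volume$values)
  expect_error(voxelize_phantom(phantom_spec(curve_line(20), 0.6)),
               "too coarse")
  expect_error(voxelize_phantom(spec, max_voxels = 1000), "voxel cap")
})

test_that("phantom spec enforces the HU window invariants", {
  expect_error(phantom_spec(curve_line(10), 2, hu_lumen = 700), "hu_lumen")
  expect_error(phantom_spec(curve_line(10), 2, hu_calc = 500), "hu_calc")
  expect_error(phantom_spec(curve_line(10), 2, hu_background = 150),
               "hu_background")
  expect_error(
    phantom_spec(curve_line(10), 2,
                 list(wedge_spec(5, 15, 0, 60, 0.5))), "beyond")
})

test_that("analytic stenosis truth follows the area-deficit formula", {
  prof <- radius_profile(data.frame(
    s_start = c(0, 30), s_end = c(30, 60),
    shape = c("constant", "constant"), r_start = c(2, 1),
    r_end = c(2, 1)))
  w <- wedge_spec(30, 60, 0, 60, 0.5, 0.1)
  tr <- phantom_truth(phantom_spec(curve_line(60), prof, list(w)))
  # lumen halves in radius inside the region: A/A_ref = 1/4 everywhere
  expect_equal(tr$cumulative_stenosis_percent, 75, tolerance = 0.2)
  expect_equal(tr$max_local_stenosis_percent, 75, tolerance = 0.2)
  expect_equal(tr$severity_category, "70-90")
})
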