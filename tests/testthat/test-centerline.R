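analytic_centerline <- function(curve, ds = 0.05) {
  L <- curve$length_mm
  s <- seq(0, L, length.out = ceiling(L / ds) + 1L)
  new_centerline(curve_eval(curve, s)$points)
}

test_that("tortuosity index matches closed forms on analytic centerlines", {
  expect_lt(abs(tortuosity_index(analytic_centerline(curve_line(80)))), 1e-6)
  expect_equal(tortuosity_index(analytic_centerline(curve_arc(40, 180))),
               pi / 2 - 1, tolerance = 1e-3)
  expect_equal(tortuosity_index(analytic_centerline(curve_arc(40, 90))),
               pi / (2 * sqrt(2)) - 1, tolerance = 1e-3)
})

test_that("tortuosity is invariant under rigid motion and scaling", {
  cl <- analytic_centerline(curve_arc(25, 140))
  ti0 <- tortuosity_index(cl)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (fac in c(1, 2.5)) {
    moved <- new_centerline(sweep(fac * cl$points %*% t(R), 2, c(5, -3, 2), "+"))
    expect_equal(tortuosity_index(moved), ti0, tolerance = 1e-9)
  }
  # coincident endpoints are refused
  loop <- analytic_centerline(curve_arc(10, 360))
  expect_error(tortuosity_index(loop), "coincident")
})

test_that("resampling yields uniform spacing and the expected point count", {
  cl <- analytic_centerline(curve_line(80), ds = 0.37)
  rs <- resample_with_frames(cl, 0.2)
  expect_equal(nrow(rs$points), 401)
  expect_lt(max(abs(diff(rs$arclength) - 0.2)), 1e-6)
  # idempotence
  rs2 <- resample_with_frames(rs, 0.2)
  expect_lt(max(abs(rs2$points - rs$points)), 1e-9)
  expect_error(resample_with_frames(cl, 0), "positive")
})

test_that("frames never flip on a planar arc", {
  cl <- resample_with_frames(analytic_centerline(curve_arc(40, 180)), 0.2)
  # plane normal of the arc is +y; frame_u stays on one side
  sgn <- sign(cl$frame_u %*% c(0, 1, 0))
  sgn <- sgn[abs(cl$frame_u %*% c(0, 1, 0)) > 1e-6]
  if (length(sgn)) expect_true(all(sgn == sgn[1]))
  # orthonormality after resampling
  expect_lt(max(abs(rowSums(cl$frame_u * cl$tangent))), 1e-9)
})

test_that("extracted centerline recovers a straight axis within 0.1 mm RMS", {
  fx <- fix_cylinder()
  cl <- fx$analysis$centerline
  rms <- sqrt(mean(cl$points[, 1]^2 + cl$points[, 2]^2))
  expect_lt(rms, 0.1)
})

test_that("extracted centerline is radius-independent on straight tubes", {
  for (r in c(1.5, 3)) {
    spec <- phantom_spec(curve_line(40), r)
    vox <- voxelize_phantom(spec)
    ep <- curve_eval(spec$curve, c(0.2, 39.8))$points
    cl <- extract_centerline(vox$lumen, ep)
    expect_lt(sqrt(mean(cl$points[, 1]^2 + cl$points[, 2]^2)), 0.1)
  }
})

test_that("semicircular tube: arclength within 1% and curvature within 5%", {
  spec <- phantom_spec(curve_arc(40, 180), 2)
  vox <- voxelize_phantom(spec)
  ep <- curve_eval(spec$curve, c(0.2, spec$curve$length_mm - 0.2))$points
  cl <- extract_centerline(vox$lumen, ep)
  expect_equal(max(cl$arclength), pi * 40, tolerance = 0.01)
  mid <- cl$curvature[cl$arclength > 20 & cl$arclength < 100]
  expect_lt(max(abs(mid - 1 / 40) * 40), 0.05)
})

test_that("endpoint validation and connectivity are enforced", {
  fx <- fix_cylinder()
  lum <- fx$vox$lumen
  expect_error(
    extract_centerline(lum, rbind(c(50, 50, 0), fx$endpoints[2, ])),
    "not inside")
})

test_that("Bouthillier boundaries land within 2 mm of planted bends", {
  fx <- fix_siphon()
  labels <- fx$analysis$labels
  expect_false(labels$fallback)
  expect_lt(max(abs(labels$boundaries_mm - fx$boundaries_mm)), 2)
  # labels form contiguous ordered runs C2 -> C6
  r <- rle(as.character(labels$label))
  expect_equal(r$values, c("C2", "C3", "C4", "C5", "C6"))
  expect_identical(labels$petrous, labels$label %in% c("C2", "C3"))
})

test_that("straight tubes trigger the fixed-fraction fallback", {
  fx <- fix_cylinder()
  labels <- fx$analysis$labels
  expect_true(labels$fallback)
  r <- rle(as.character(labels$label))
  expect_equal(r$values, c("C2", "C3", "C4", "C5", "C6"))
})

test_that("explicit boundary overrides bypass peak picking", {
  fx <- fix_cylinder()
  cl <- fx$analysis$centerline
  lab <- label_bouthillier(cl, boundary_overrides_mm = c(10, 20, 40, 60))
  expect_equal(lab$boundaries_mm, c(10, 20, 40, 60))
  expect_false(lab$fallback)
})

test_that("non-petrous tortuosity uses the C4-C6 sub-polyline", {
  fx <- fix_siphon()
  cl <- fx$analysis$centerline
  labels <- fx$analysis$labels
  ti_np <- tortuosity_index(cl, labels, exclude_petrous = TRUE)
  keep <- !(labels$label %in% c("C2", "C3"))
  pts <- cl$points[keep, , drop = FALSE]
  L <- sum(sqrt(rowSums(diff(pts)^2)))
  D <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  expect_equal(ti_np, L / D - 1, tolerance = 1e-12)
  expect_error(tortuosity_index(cl, exclude_petrous = TRUE), "labels")
})
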