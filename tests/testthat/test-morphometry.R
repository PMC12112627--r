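test_that("3D body count: separated wedges split, overlapping wedges merge", {
  fx <- fix_siphon()
  expect_equal(nrow(fx$analysis$bodies), 2)

  # overlapping wedges in s and theta fuse into one component
  w1 <- wedge_spec(20, 30, 90, 60, 1.0, 0.2)
  w2 <- wedge_spec(28, 36, 110, 60, 1.0, 0.2)
  spec <- phantom_spec(curve_line(50), 2, list(w1, w2))
  vox <- voxelize_phantom(spec)
  lab <- calcimorph:::.label_components(vox$calcification$values,
                                        dim(vox$calcification$values), 26L)
  expect_equal(max(lab), 1)
})

test_that("longitudinal extent follows the consecutive-gap formula", {
  # contiguous body on 51 slices at 0.2 mm: L_j = 10
  cb <- synthetic_bodies(index = 1:51, body = rep(1L, 51))
  ext <- longitudinal_extent(cb)
  expect_equal(ext$per_body$l_j_mm, 10, tolerance = 1e-12)
  # single-slice body: L_j = 0
  cb1 <- synthetic_bodies(index = 7L, body = 1L)
  expect_equal(longitudinal_extent(cb1)$per_body$l_j_mm, 0)
  # two bodies 10 mm and 4 mm: L_TOT = 14
  cb2 <- synthetic_bodies(index = c(1:51, 100:120),
                          body = c(rep(1L, 51), rep(2L, 21)))
  expect_equal(longitudinal_extent(cb2)$l_tot_mm, 14, tolerance = 1e-12)
})

test_that("deleting one interior slice reduces L_TOT by exactly 0.4 mm", {
  whole <- synthetic_bodies(index = 1:51, body = rep(1L, 51))
  k <- 20L
  split <- synthetic_bodies(index = setdiff(1:51, k),
                            body = c(rep(1L, k - 1), rep(2L, 51 - k)))
  expect_equal(longitudinal_extent(whole)$l_tot_mm -
                 longitudinal_extent(split)$l_tot_mm, 2 * 0.2,
               tolerance = 1e-12)
})

test_that("surface contact matches the cylindrical patch area", {
  w <- wedge_spec(30, 40, 90, 60, 1.0, 0)  # gap 0: touching
  spec <- phantom_spec(curve_line(80), 2, list(w))
  vox <- voxelize_phantom(spec)
  mesh <- smooth_lumen_mesh(mask_to_mesh(vox$lumen))
  sc <- surface_contact(mesh, vox$calcification)
  expect_equal(sc, 60 / 360 * 2 * pi * 2 * 10, tolerance = 0.1)
  # gap 2 mm with a tight contact distance: no contact
  w2 <- wedge_spec(30, 40, 90, 60, 1.0, 2)
  vox2 <- voxelize_phantom(phantom_spec(curve_line(80), 2, list(w2)))
  expect_equal(surface_contact(mesh, vox2$calcification, 0.5), 0)
  # monotone in the contact distance
  sc_seq <- vapply(c(0.2, 0.4, 0.8), function(cm)
    surface_contact(mesh, vox$calcification, cm), numeric(1))
  expect_true(all(diff(sc_seq) >= 0))
})

test_that("stenosis: constant areas give zero, half areas give 50%", {
  xs <- synthetic_sections_table(rep(10, 100))
  cb <- synthetic_bodies(index = 40:60, body = rep(1L, 21))
  s0 <- stenosis(xs, cb)
  expect_equal(s0$regions$s_c_percent, 0, tolerance = 1e-12)
  expect_equal(s0$severity, "<30")

  areas <- rep(10, 100); areas[40:60] <- 5
  s1 <- stenosis(synthetic_sections_table(areas), cb)
  expect_equal(s1$regions$s_c_percent, 50, tolerance = 1e-12)
  expect_equal(s1$max_local_percent, 50, tolerance = 1e-12)
  # max s_i = 50 exactly: strict thresholds put this in the 30-50 band
  expect_equal(s1$severity, "30-50")
})

test_that("stenosis equals the mean of per-slice values (identity)", {
  areas <- c(rep(10, 39), seq(10, 5, length.out = 30), rep(10, 31))
  xs <- synthetic_sections_table(areas)
  cb <- synthetic_bodies(index = 40:69, body = rep(1L, 30))
  st <- stenosis(xs, cb)
  reg <- st$per_slice[st$per_slice$in_formula_set, ]
  expect_equal(st$regions$s_c_percent, mean(reg$s_i_percent),
               tolerance = 1e-12)
  # reference is the largest proximal area
  expect_equal(st$regions$a_ref_mm2, max(areas[1:39]))
})

test_that("stenosis without a proximal slice falls back with a flag", {
  xs <- synthetic_sections_table(rep(10, 20))
  cb <- synthetic_bodies(index = 1:5, body = rep(1L, 5))
  st <- stenosis(xs, cb)
  expect_true(st$regions$no_proximal_flag)
  expect_equal(st$regions$ref_index, 1)
  expect_error(stenosis(xs, synthetic_bodies(integer(0), integer(0))),
               "no calcified")
})

test_that("severity category is a step function of max local stenosis", {
  vals <- c(10, 31, 50.0001, 70.5, 91)
  cats <- vapply(vals, severity_category, character(1))
  expect_equal(cats, c("<30", "30-50", "50-70", "70-90", ">90"))
  expect_equal(severity_category(30), "<30")   # strict: must exceed
  expect_equal(severity_category(90), "70-90")
})

test_that("predominant segment follows the burden, ties go distal", {
  labels <- list(label = factor(rep(c("C2", "C3", "C4", "C5", "C6"),
                                    each = 20), levels = paste0("C", 2:6)))
  # 60/40 split C4 vs C5
  cb <- synthetic_bodies(index = c(45, 65), body = c(1L, 2L),
                         area = c(6, 4))
  expect_equal(as.character(predominant_segment(cb, labels)), "C4")
  # exact tie: distal pick with a flag
  cb2 <- synthetic_bodies(index = c(45, 65), body = c(1L, 2L),
                          area = c(5, 5))
  pick <- predominant_segment(cb2, labels)
  expect_equal(as.character(pick), "C5")
  expect_true(attr(pick, "tie"))
})

test_that("orientation classifies planted directions, mirrored by side", {
  # wedge along +y (anterior-inferior reference is (0,1,-1)/sqrt(2))
  cs <- synthetic_section(85:95, 2.2, 2.7)
  xs <- structure(list(sections = list(cs),
                       table = synthetic_sections_table(12)$table,
                       n_rays = 360L), class = "cross_sections")
  expect_equal(as.character(predominant_orientation(xs, "left")),
               "anteroinferior")
  # wedge along +x (patient right): toward the midline for a left ICA
  # (medial), away from it for a right ICA (lateral)
  cs2 <- synthetic_section(c(355:359, 0:5), 2.2, 2.7)
  xs2 <- structure(list(sections = list(cs2), table = xs$table,
                        n_rays = 360L), class = "cross_sections")
  expect_equal(as.character(predominant_orientation(xs2, "left")), "medial")
  expect_equal(as.character(predominant_orientation(xs2, "right")), "lateral")
})

test_that("exact posterosuperior direction classifies exactly", {
  fx <- fix_siphon()
  # both planted wedges are posterosuperior by construction
  expect_equal(unique(fx$truth$wedges$orientation), "posterosuperior")
  expect_equal(fx$analysis$record$predominant_orientation,
               "posterosuperior")
})

test_that("artery record: single-wedge phantom has mean ~ max thickness", {
  fx <- fix_cylinder()
  rec <- fx$analysis$record
  expect_equal(rec$calc_count, 1)
  expect_lt(abs(rec$max_thickness_mm - rec$mean_thickness_mm), 0.3)
  expect_lt(abs(rec$max_thickness_mm - 1.2), 0.3)
})

test_that("artery record without calcification keeps lumen fields only", {
  spec <- phantom_spec(curve_line(40), 2)
  vox <- voxelize_phantom(spec)
  ep <- curve_eval(spec$curve, c(0.2, 39.8))$points
  an <- analyze_artery(volume = vox$volume, side = "left", endpoints = ep)
  expect_equal(an$record$calc_count, 0)
  expect_true(is.na(an$record$l_tot_mm))
  expect_false(is.na(an$record$mean_lumen_diameter_mm))
  expect_equal(an$record$mean_lumen_diameter_mm, 4, tolerance = 0.02)
})
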