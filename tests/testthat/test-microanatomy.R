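test_that("Otsu binarization separates bimodal volumes", {
  arr <- array(7, dim = c(32, 32, 32))
  v <- voxel_volume(arr, 0.01, binary = FALSE)
  expect_true(all(binarize(v, 7)$grid))

  arr2 <- array(0, dim = c(32, 32, 32))
  arr2[1:16, , ] <- 100
  v2 <- voxel_volume(arr2, 0.01, binary = FALSE)
  b <- binarize(v2, "otsu")
  thr <- attr(b, "threshold")
  expect_gt(thr, 0); expect_lt(thr, 100)
  expect_equal(mean(b$grid), 0.5)
  expect_identical(unname(b$grid[1, 1, 1]), TRUE)
  expect_identical(unname(b$grid[20, 1, 1]), FALSE)

  # grayscale grf field + its calibrated threshold reproduces the phantom
  ph <- generate_phantom(phantom_spec("grf", 48, element_thickness = 0.05,
                                      target_bvtv = 0.4, seed = 5))
  gray <- attr(ph, "grayscale")
  b2 <- binarize(gray, attr(ph, "threshold"))
  expect_identical(b2$grid, ph$grid)
})

test_that("capitulum VOI centre follows the landmark rectangle rule", {
  lm <- list(lateral = 10, medial = 30, anterior = 5, posterior = 25,
             proximal = 0, distal = 40)
  expect_equal(unname(capitulum_voi_center(lm)), c(20, 15, 20))
  lm2 <- list(lateral = 0, medial = 10, anterior = 0, posterior = 6,
              proximal = 2, distal = 4)
  expect_equal(unname(capitulum_voi_center(lm2)), c(5, 3, 3))
  expect_error(capitulum_voi_center(modifyList(lm, list(medial = 10))),
               "degenerate")
  # property: centre always inside the bounding box
  set.seed(42)
  for (i in 1:100) {
    b <- sort(runif(2, 0, 50)); a <- sort(runif(2, 0, 50))
    z <- sort(runif(2, 0, 50))
    if (diff(b) == 0 || diff(a) == 0) next
    ctr <- capitulum_voi_center(list(lateral = b[1], medial = b[2],
                                     anterior = a[1], posterior = a[2],
                                     proximal = z[1], distal = z[2]))
    expect_true(ctr[1] >= b[1] && ctr[1] <= b[2])
    expect_true(ctr[2] >= a[1] && ctr[2] <= a[2])
    expect_true(ctr[3] >= z[1] && ctr[3] <= z[2])
  }
})

test_that("BV/TV counts bone voxels inside the VOI and honours exclusions", {
  arr <- array(FALSE, dim = c(32, 32, 32))
  arr[16:17, 16:17, 16] <- TRUE # 4 bone voxels
  v <- voxel_volume(arr, 0.01, binary = TRUE)
  voi <- voi_spec(center = c(15.5, 15.5, 15.5), extent = 0.02) # 2x2x2 cube
  expect_equal(bone_volume_fraction(v, voi), 0.5)

  # monotone: adding bone inside the VOI never decreases BV/TV
  arr2 <- arr; arr2[16, 16, 17] <- TRUE
  expect_gt(bone_volume_fraction(voxel_volume(arr2, 0.01), voi),
            bone_volume_fraction(v, voi))

  expect_error(bone_volume_fraction(v, voi_spec(c(1, 1, 1), extent = 0.2)),
               "outside")
  expect_error(
    bone_volume_fraction(v, voi_spec(c(15.5, 15.5, 15.5), 0.02,
                                     epiphyseal_line = TRUE)),
    class = "osteoconv_voi_excluded")
})

test_that("local thickness recovers plate, sphere and rod dimensions", {
  # plates 10 voxels thick at 0.01 mm/voxel -> 0.10 mm
  p <- generate_phantom(phantom_spec("plate_stack", 64,
                                     element_thickness = 0.1))
  expect_equal(mean_trabecular_thickness(p), 0.10, tolerance = 0.10)

  # sphere: interior thickness ~ diameter, max = fitted sphere diameter
  sv <- sphere_volume(15)
  tm <- local_thickness_map(sv)
  vals <- tm$grid[sv$grid]
  expect_equal(max(vals), 15 * 0.01, tolerance = 0.07)
  expect_equal(mean(vals), 15 * 0.01, tolerance = 0.07)

  # rods of diameter 6 voxels: thickness ~ 6 voxels away from junctions
  r <- generate_phantom(phantom_spec("rod_lattice", 64,
                                     element_thickness = 0.06))
  tmr <- local_thickness_map(r)
  vals_r <- tmr$grid[r$grid & tmr$grid > 0]
  # junctions inflate the mean; the mode of the distribution is the rod
  expect_equal(unname(quantile(vals_r, 0.5)), 0.06, tolerance = 0.15)

  # rotation robustness: plates stacked along z vs along x
  g <- p$grid
  p_rot <- voxel_volume(aperm(g, c(3, 2, 1)), p$voxel_size, binary = TRUE)
  expect_equal(mean_trabecular_thickness(p_rot),
               mean_trabecular_thickness(p), tolerance = 0.05)

  # no bone -> dedicated condition
  expect_error(mean_trabecular_thickness(
    generate_phantom(phantom_spec("empty", 32))),
    class = "osteoconv_no_bone")
})

test_that("diaphyseal compactness matches the annulus ground truth", {
  solid <- generate_phantom(phantom_spec("solid", 32))
  prof <- diaphysis_profile(solid, closing_radius = 0L)
  expect_true(all(prof$per_slice$compactness == 1))

  tube <- tube_phantom(64, r_out = 20, r_in = 10)
  prof2 <- diaphysis_profile(tube)
  expect_equal(prof2$mean_global_compactness, (20^2 - 10^2) / 20^2,
               tolerance = 0.02)
  expect_equal(prof2$mean_total_area, pi * 20^2 * 0.01^2, tolerance = 0.02)
  expect_true(all(prof2$per_slice$compactness >= 0 &
                    prof2$per_slice$compactness <= 1))

  # filling the medullary cavity drives compactness to 1
  filled <- tube_phantom(64, r_out = 20, r_in = 0)
  prof3 <- diaphysis_profile(filled)
  expect_equal(prof3$mean_global_compactness, 1.0, tolerance = 1e-9)

  # empty slices are flagged and excluded from the means
  g <- tube$grid; g[, , 1:4] <- FALSE
  part <- voxel_volume(g, 0.01, binary = TRUE)
  expect_warning(prof4 <- diaphysis_profile(part), "no bone")
  expect_identical(sum(prof4$per_slice$empty), 4L)
  expect_equal(prof4$mean_global_compactness, prof2$mean_global_compactness,
               tolerance = 1e-9)
})

test_that("microanatomy_record assembles the four comparative traits", {
  head_vol <- generate_phantom(phantom_spec("grf", 48,
                                            element_thickness = 0.05,
                                            target_bvtv = 0.5, seed = 11))
  voi <- voi_spec(c(23.5, 23.5, 23.5), extent = 0.24)
  rec <- microanatomy_record(head_vol, voi, tube_phantom(48, 15, 8))
  expect_named(rec, c("bvtv", "mean_tbth", "mean_global_compactness",
                      "mean_cross_sectional_area"))
  expect_true(rec$bvtv > 0.4 && rec$bvtv < 0.6)
  expect_true(rec$mean_tbth > 0)
  expect_equal(rec$mean_global_compactness, (15^2 - 8^2) / 15^2,
               tolerance = 0.03)
})
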