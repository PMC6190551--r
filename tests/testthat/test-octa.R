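test_that("Bennett scaling factor matches direct arithmetic", {
  expect_equal(bennett_scaling_factor(1.82), 0)
  expect_equal(round(bennett_scaling_factor(24.34), 4), 0.9948)
  expect_equal(round(bennett_scaling_factor(26.94), 4), 1.1097)
  expect_error(bennett_scaling_factor(1.5), ">= 1.82")
})

test_that("analysis-grid resize upsamples 245 to 1024 and round-trips", {
  a <- gen_angiogram(vessel_gen_params(seed = 3))
  big <- resize_to_analysis_grid(a)
  expect_equal(dim(big$pixels), c(1024, 1024))
  expect_equal(um_per_px(big), 3000 / 1024, tolerance = 1e-12)
  # constant image preserved up to interpolation tolerance
  cst <- angiogram(matrix(0.4, 49, 49))
  expect_lt(max(abs(resize_to_analysis_grid(cst, 128)$pixels - 0.4)), 1e-6)
  # nearest-neighbour downsample of the output correlates with the input
  idx <- round(seq(1, 1024, length.out = 245))
  back <- big$pixels[idx, idx]
  expect_gt(cor(c(back), c(a$pixels)), 0.95)
})

test_that("magnification correction scales features by the factor ratio", {
  ref <- bennett_scaling_factor(23.95)
  # identity at ratio 1
  a <- gen_angiogram(vessel_gen_params(seed = 4))
  a1024 <- resize_to_analysis_grid(a)
  expect_identical(magnification_correct(a1024, factor = ref)$pixels,
                   a1024$pixels)
  # a centered disc doubles in diameter at ratio 2
  g <- 512
  xs <- matrix(rep(seq_len(g), each = g), g, g)
  ys <- matrix(rep(seq_len(g), times = g), g, g)
  disc <- 1 * ((xs - g / 2)^2 + (ys - g / 2)^2 <= 50^2)
  ad <- angiogram(disc, axial_length_mm = 23.95)
  out <- magnification_correct(ad, factor = 2 * ref)
  width <- max(colSums(out$pixels > 0.5))
  expect_lt(abs(width - 200) / 200, 0.03)
  # shrink pads with background and keeps the grid size
  out2 <- magnification_correct(ad, factor = 0.5 * ref)
  expect_equal(dim(out2$pixels), c(g, g))
  width2 <- max(colSums(out2$pixels > 0.5))
  expect_lt(abs(width2 - 50) / 50, 0.05)
  expect_error(magnification_correct(ad, factor = -1), "positive")
})

test_that("high-myopia and control scenes differ by the Bennett factor ratio", {
  g <- 512
  xs <- matrix(rep(seq_len(g), each = g), g, g)
  ys <- matrix(rep(seq_len(g), times = g), g, g)
  disc <- 1 * ((xs - g / 2)^2 + (ys - g / 2)^2 <= 60^2)
  hm <- magnification_correct(angiogram(disc, axial_length_mm = 26.94))
  hc <- magnification_correct(angiogram(disc, axial_length_mm = 24.34))
  w_hm <- max(colSums(hm$pixels > 0.5))
  w_hc <- max(colSums(hc$pixels > 0.5))
  expected <- bennett_scaling_factor(26.94) / bennett_scaling_factor(24.34)
  expect_lt(abs(w_hm / w_hc - expected) / expected, 0.01)
})

test_that("vessel binarization recovers the generated network", {
  # contrast five times the noise SD
  p <- vessel_gen_params(contrast = 100, background_noise_sd = 20, seed = 13)
  a <- gen_angiogram(p)
  bin <- binarize_vessels(a)
  gt <- a$ground_truth$vessel_mask
  dice <- 2 * sum(bin & gt) / (sum(bin) + sum(gt))
  expect_gte(dice, 0.8)
  # polarity normalization: inverted input gives the identical binary map
  bin_inv <- binarize_vessels(1 - a$pixels)
  expect_identical(c(bin), c(bin_inv))
  # constant image flags and warns
  expect_warning(empty <- binarize_vessels(matrix(0.5, 64, 64)), "constant")
  expect_equal(sum(empty), 0)
  expect_true(attr(empty, "flag_constant"))
})

test_that("caliber separation splits micro and large vessels at 25 um", {
  upp <- 3000 / 245
  # uniform 15-um vessel: entirely micro
  thin <- make_bar(100, width = 1, len = 80)
  sep <- separate_by_diameter(thin, upp)
  expect_true(all(sep$micro[thin]))
  expect_equal(sum(sep$large), 0)
  # uniform 40-um vessel (3 px at this scale): entirely large
  wide <- make_bar(100, width = 3, len = 80)
  sep2 <- separate_by_diameter(wide, upp)
  expect_true(all(sep2$large[wide]))
  expect_equal(sum(sep2$micro), 0)
  expect_error(separate_by_diameter(thin, um_per_px = 0), "positive")
})

test_that("caliber classes partition the foreground and match generator labels", {
  for (seed in c(3, 17)) {
    a <- gen_angiogram(vessel_gen_params(seed = seed))
    gt <- a$ground_truth
    sep <- separate_by_diameter(gt$vessel_mask, um_per_px(a))
    # exact partition
    expect_identical(sep$micro | sep$large, gt$vessel_mask)
    expect_false(any(sep$micro & sep$large))
    agree <- sum((sep$micro & gt$class_map == 1L) |
                 (sep$large & gt$class_map == 2L)) / sum(gt$vessel_mask)
    expect_gte(agree, 0.9)
  }
})

test_that("projection-artifact removal subtracts the dilated large-vessel mask", {
  deep <- make_bar(64, 1, 40)
  empty <- matrix(FALSE, 64, 64)
  expect_identical(remove_projection_artifacts(deep, empty), deep)
  expect_equal(sum(remove_projection_artifacts(deep, deep, margin_px = 0)), 0)
  # stamped large-vessel contamination is cleaned below 5%
  a <- gen_angiogram(vessel_gen_params(seed = 31))
  gt <- a$ground_truth
  large <- gt$class_map == 2L
  deep_map <- gen_angiogram(vessel_gen_params(seed = 32))$ground_truth$vessel_mask
  contaminated <- deep_map | large
  cleaned <- remove_projection_artifacts(contaminated, large, margin_px = 1)
  leftover <- sum(cleaned & large) / max(sum(large), 1)
  expect_lt(leftover, 0.05)
  expect_error(remove_projection_artifacts(deep, matrix(FALSE, 32, 32)),
               "shape")
})

test_that("skeletonization thins to unit-width centerlines", {
  # a 9-px-wide bar of length 200 keeps nearly its full centerline length
  bar <- make_bar(220, width = 9, len = 200)
  sk <- skeletonize_map(bar)
  expect_lt(abs(sum(sk) - 200) / 200, 0.05)
  # idempotent on a 1-px line
  line <- make_bar(50, width = 1, len = 30)
  expect_identical(skeletonize_map(line), line)
  # empty in, empty out
  expect_equal(sum(skeletonize_map(matrix(FALSE, 10, 10))), 0)
})

test_that("skeletonization preserves 8-connected component count", {
  for (seed in 1:20) {
    m <- gen_angiogram(vessel_gen_params(n_micro = 25, n_large = 3,
                                         seed = seed))$ground_truth$vessel_mask
    expect_equal(count_components8(skeletonize_map(m)), count_components8(m))
  }
})

test_that("FAZ detection finds a centered dark disc and rejects flat images", {
  a <- gen_angiogram(vessel_gen_params(n_micro = 90, seed = 41))
  ctr <- detect_faz_center(a$pixels)
  g <- a$grid_px
  expect_lt(sqrt(sum((ctr - c((g + 1) / 2, (g + 1) / 2))^2)), 5)
  expect_error(detect_faz_center(matrix(0.5, 128, 128)), "FAZ detection failed")
})

test_that("left-eye flip is a horizontal mirror and an involution", {
  m <- matrix(runif(64), 8, 8)
  expect_identical(flip_if_left(m, "OD"), m)
  expect_identical(flip_if_left(flip_if_left(m, "OS"), "OS"), m)
  marker <- matrix(0, 8, 8); marker[4, 2] <- 1
  expect_equal(flip_if_left(marker, "OS")[4, 7], 1)
  expect_error(flip_if_left(m, "LEFT"), "laterality")
})

test_that("annulus mask has the analytic pixel area and respects radii", {
  upp <- 3000 / 1024
  # degenerate annulus is empty
  expect_equal(sum(annulus_mask(256, upp, inner_diameter_mm = 0.6,
                                outer_diameter_mm = 0.6)), 0)
  m <- annulus_mask(1024, upp)
  analytic <- pi * (1250^2 - 300^2) / upp^2
  expect_lt(abs(sum(m) - analytic) / analytic, 0.01)
  # definition check: all masked pixel centers lie within the radii
  ctr <- (1024 + 1) / 2
  pts <- which(m, arr.ind = TRUE)
  d <- sqrt((pts[, 2] - ctr)^2 + (pts[, 1] - ctr)^2)
  expect_true(all(d >= 300 / upp - 1e-9 & d <= 1250 / upp + 1e-9))
  expect_error(annulus_mask(128, upp), "does not fit")
})

test_that("single-grid box counts equal the brute-force counter exactly", {
  set.seed(5)
  blob <- matrix(runif(128 * 128) < 0.02, 128, 128)
  blob[64, 10:120] <- TRUE
  r <- box_counting_dimension(blob, max_box_px = 32, rotation_step_deg = 360)
  expect_equal(r$counts, brute_force_box_counts(blob, r$box_sizes))
  line <- make_bar(100, 1, 90)
  r2 <- box_counting_dimension(line, max_box_px = 24, rotation_step_deg = 360)
  expect_equal(r2$counts, brute_force_box_counts(line, r2$box_sizes))
})

test_that("box-counting dimension hits the closed forms on fixtures", {
  expect_lt(abs(box_counting_dimension(gen_fractal_fixture("line", 729))$dbox -
                1.0), 0.05)
  expect_lt(abs(box_counting_dimension(gen_fractal_fixture("sierpinski_carpet",
                                                           729))$dbox -
                log(8) / log(3)), 0.05)
  r <- box_counting_dimension(gen_fractal_fixture("filled_square", 729))
  expect_lt(abs(r$dbox - 2.0), 0.05)
  # counts non-increasing in box size
  expect_true(all(diff(r$counts) >= 0))  # sizes are decreasing
  expect_error(box_counting_dimension(matrix(FALSE, 50, 50)), "at least 10")
})

test_that("Dbox is robust to the rotation step on an isotropic network", {
  a <- gen_angiogram(vessel_gen_params(n_micro = 80, seed = 51))
  sk <- skeletonize_map(a$ground_truth$vessel_mask)
  d15 <- box_counting_dimension(sk, max_box_px = 48, rotation_step_deg = 15)$dbox
  d45 <- box_counting_dimension(sk, max_box_px = 48, rotation_step_deg = 45)$dbox
  expect_lt(abs(d15 - d45), 0.02)
  expect_true(d15 > 0 && d15 <= 2)
})

test_that("vessel-density pipeline is insensitive to laterality", {
  p <- vessel_gen_params(n_micro = 70, seed = 61)
  a_od <- gen_angiogram(p)
  a_os <- a_od
  a_os$laterality <- "OS"
  r_od <- vessel_density_pipeline(a_od, analysis_px = 512,
                                  rotation_step_deg = 45)
  r_os <- vessel_density_pipeline(a_os, analysis_px = 512,
                                  rotation_step_deg = 45)
  expect_lt(abs(r_od$dbox - r_os$dbox), 0.01)
})

test_that("pipeline errors informatively on an empty angiogram", {
  a <- gen_angiogram(vessel_gen_params(n_large = 0, n_micro = 0, seed = 7))
  expect_error(suppressWarnings(vessel_density_pipeline(a, analysis_px = 512)),
               "foreground")
})

test_that("Dbox increases with generated microvessel density", {
  levels <- seq(20, 110, by = 10)
  mean_dbox <- sapply(levels, function(nm) {
    mean(sapply(1:5, function(s) {
      a <- gen_angiogram(vessel_gen_params(n_micro = nm, seed = 100 * s + nm))
      vessel_density_pipeline(a, analysis_px = 512,
                              rotation_step_deg = 45)$dbox
    }))
  })
  expect_gt(cor(levels, mean_dbox, method = "spearman"), 0.9)
})

test_that("group-density ordering is recovered end to end", {
  # three density levels standing for the HC/MM/HM generative ordering
  n_micro <- c(HC = 85, MM = 60, HM = 35)
  means <- sapply(names(n_micro), function(g) {
    mean(sapply(1:6, function(s) {
      a <- gen_angiogram(vessel_gen_params(n_micro = n_micro[[g]],
                                           seed = 1000 + 10 * s + n_micro[[g]]))
      vessel_density_pipeline(a, analysis_px = 512,
                              rotation_step_deg = 45)$dbox
    }))
  })
  expect_true(means["HC"] > means["MM"] && means["MM"] > means["HM"])
})

test_that("deep-plexus deprojection uses the superficial companion", {
  sup <- gen_angiogram(vessel_gen_params(seed = 71, plexus = "superficial",
                                         n_large = 8))
  deep <- gen_angiogram(vessel_gen_params(seed = 72, plexus = "deep",
                                          n_large = 8, n_micro = 70))
  r_with <- vessel_density_pipeline(deep, companion = sup, analysis_px = 512,
                                    rotation_step_deg = 45)
  r_without <- vessel_density_pipeline(deep, analysis_px = 512,
                                       rotation_step_deg = 45)
  expect_lte(r_with$n_skeleton_px, r_without$n_skeleton_px)
  expect_identical(r_with$plexus, "deep")
})
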