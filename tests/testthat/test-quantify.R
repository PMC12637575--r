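test_that("the dual-box estimator matches its exact arithmetic contract", {
  u <- matrix(1, 21, 21)
  ci <- corrected_spot_intensity(u, c(11, 11))
  expect_equal(ci$inner_sum, 81)
  expect_equal(ci$outer_sum, 169)
  expect_equal(ci$corrected, 0)

  sp <- matrix(0, 21, 21); sp[11, 11] <- 100
  expect_equal(corrected_spot_intensity(sp, c(11, 11))$corrected, 100)

  spb <- sp + 2
  ci2 <- corrected_spot_intensity(spb, c(11, 11))
  expect_equal(ci2$inner_sum, 262)
  expect_equal(ci2$outer_sum, 438)
  expect_equal(ci2$corrected, 262 - 176 * 81 / 88)
  expect_equal(ci2$corrected, 100)

  expect_error(corrected_spot_intensity(u, c(2, 2)), "border")
  expect_error(corrected_spot_intensity(u, c(11, 11), inner_size = 8), "odd")
})

test_that("the dual-box estimator cancels any uniform offset exactly and is linear", {
  set.seed(10)
  m <- matrix(stats::rexp(31 * 31, 1 / 50), 31, 31)
  base <- corrected_spot_intensity(m, c(16, 16))$corrected
  for (c0 in c(-17.3, 0.5, 1000)) {
    expect_equal(corrected_spot_intensity(m + c0, c(16, 16))$corrected, base,
                 tolerance = 1e-10)
  }
  for (a in c(0.25, 3, 117)) {
    expect_equal(corrected_spot_intensity(a * m, c(16, 16))$corrected, a * base,
                 tolerance = 1e-10)
  }
})

test_that("detection finds a lone punctum at its true position and respects the threshold", {
  img <- imaging_spec()
  sp <- structure_spec("punctum", c(1500, 2560, 2560), amplitude = 20000)
  vg <- render_structure(sp, img, c(24, 128, 128))
  rois <- detect_centromeres(vg)
  expect_equal(nrow(rois), 1L)
  expect_lt(abs(rois$z - 1500), 125 / 2 + 1e-9)
  expect_lt(abs(rois$y - 2560), 20 + 1e-9)
  expect_lt(abs(rois$x - 2560), 20 + 1e-9)
  expect_equal(nrow(detect_centromeres(vg, threshold = Inf)), 0L)
  empty <- voxel_grid(array(0, c(8, 32, 32)), c(125, 40, 40))
  expect_equal(nrow(detect_centromeres(empty)), 0L)
})

test_that("detection on a generated nucleus has high recall and no stray hits", {
  ds <- fixture_dataset("cenpa", seed = 1)
  tr <- ds$truth[ds$truth$nucleus_id == 1, ]
  rois <- detect_centromeres(ds$nuclei[[1]]$marker)
  matched <- 0; stray <- 0
  for (j in seq_len(nrow(rois))) {
    dd <- sqrt((tr$z - rois$z[j])^2 + (tr$y - rois$y[j])^2 +
                 (tr$x - rois$x[j])^2)
    if (min(dd) <= 200) matched <- matched + 1 else stray <- stray + 1
  }
  expect_gte(matched, 14)
  expect_equal(stray, 0)
})

test_that("classification separates ideal annuli from blobs and is rotation/scale invariant", {
  px <- 40; n <- 41; ctr <- (n + 1) / 2
  x <- (seq_len(n) - ctr) * px
  r <- sqrt(outer(x^2, x^2, "+"))
  annulus <- exp(-(r - 130)^2 / (2 * 25^2))
  cls <- classify_structure(annulus, c((ctr - 1) * px, (ctr - 1) * px),
                            pixel_nm = px)
  expect_equal(cls$label, "ring")
  expect_lt(cls$central_dip_ratio, 0.1)
  expect_equal(cls$angular_coverage, 1)

  blob <- exp(-r^2 / (2 * 70^2))
  expect_equal(classify_structure(blob, c((ctr - 1) * px, (ctr - 1) * px),
                                  pixel_nm = px)$label, "punctum")

  # invariance under 90-degree rotation and intensity scaling
  rot <- t(annulus)[, rev(seq_len(n))]
  cr <- classify_structure(rot, c((ctr - 1) * px, (ctr - 1) * px), pixel_nm = px)
  cs <- classify_structure(13 * annulus, c((ctr - 1) * px, (ctr - 1) * px),
                           pixel_nm = px)
  expect_equal(cr$label, "ring")
  expect_equal(cr$central_dip_ratio, cls$central_dip_ratio, tolerance = 1e-9)
  expect_equal(cs$central_dip_ratio, cls$central_dip_ratio, tolerance = 1e-9)

  # a centroid at the border is flagged unresolved
  cb <- classify_structure(annulus, c(40, 40), pixel_nm = px)
  expect_equal(cb$label, "unresolved")
  expect_true(cb$border)
})

test_that("ring fractions reproduce direct arithmetic and handle edge cases", {
  cl <- data.frame(
    nucleus_id = rep(1:3, each = 10),
    label = c(rep("ring", 10),
              rep(c("ring", "punctum"), 5),
              c(rep("punctum", 8), "unresolved", "unresolved")))
  rf <- ring_fraction(cl)
  expect_equal(rf$per_nucleus$percent_rings, c(100, 50, 0))
  expect_equal(rf$mean, 50)
  expect_equal(rf$sd, stats::sd(c(100, 50, 0)))
  expect_equal(rf$per_nucleus$n_structures, c(10, 10, 8))

  allun <- data.frame(nucleus_id = c(1, 1, 2), label = c("unresolved",
                                                         "unresolved", "ring"))
  expect_warning(rf2 <- ring_fraction(allun), "excluded")
  expect_equal(rf2$per_nucleus$nucleus_id, 2)
})

test_that("condition comparisons recover exact scalings and degenerate cases", {
  set.seed(3)
  a <- stats::rnorm(200, 100, 5)
  same <- compare_conditions(a, a)
  expect_equal(same$percent_change, 0)
  expect_gt(same$p_value, 0.99)

  half <- compare_conditions(a, 0.5 * a)
  expect_equal(half$percent_change, -50)
  expect_lt(half$p_value, 1e-10)

  const <- compare_conditions(rep(2, 5), rep(2, 5))
  expect_equal(const$p_value, 1)
  expect_error(compare_conditions(c(-1, 1), c(1, 2)), "zero")
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})
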