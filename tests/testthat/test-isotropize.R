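test_that("interpolation to the working pixel follows the documented shape rule", {
  arr <- array(stats::runif(20 * 32 * 32), c(20, 32, 32))
  vg <- voxel_grid(arr, c(125, 40, 40))
  iso <- interpolate_isotropic(vg, 40)
  # round(n * voxel / target): z 20*125/40 = 62.5 -> 63, lateral unchanged
  expect_equal(dim(iso), c(63L, 32L, 32L))
  expect_equal(iso$voxel_size, rep(40, 3))

  already <- voxel_grid(arr, c(40, 40, 40))
  same <- interpolate_isotropic(already, 40)
  expect_lt(max(abs(same$data - arr)), 1e-6 * diff(range(arr)))

  const <- interpolate_isotropic(voxel_grid(array(2, c(20, 32, 32)),
                                            c(125, 40, 40)), 40)
  expect_true(all(const$data == 2))
  expect_error(interpolate_isotropic(arr, 40), "voxel_grid")
})

test_that("degrade is the identity when nothing is degraded, and blurs x as stated", {
  arr <- array(stats::runif(20 * 20 * 40), c(20, 20, 40))
  vg <- voxel_grid(arr, rep(40, 3))
  v <- degrade(vg, degradation_spec(sigma_x = 0, sigma_z = 0.5,
                                    downsample_factor_x = 1))
  expect_equal(v$input_view$data, v$target_view$data)

  imp <- array(0, c(11, 11, 61)); imp[6, 6, 31] <- 1
  vi <- voxel_grid(imp, rep(40, 3))
  v2 <- degrade(vi, degradation_spec(sigma_x = 2.4, sigma_z = 0,
                                     downsample_factor_x = 1))
  f <- fit_fwhm(v2$input_view$data[6, 6, ], 40)
  expect_lt(abs(f - 2.3548 * 2.4 * 40) / (2.3548 * 2.4 * 40), 0.02)

  # bead with 125 nm lateral FWHM -> sqrt(125^2 + 226^2) before downsampling
  img <- imaging_spec(125, 360, 40, 40, psf_model = "gaussian")
  bead <- render_bead(c(30 * 40, 30 * 40, 30 * 40), img, c(61, 61, 61))
  v3 <- degrade(bead, degradation_spec(sigma_x = 2.4, sigma_z = 0,
                                       downsample_factor_x = 1))
  w <- which(v3$input_view$data == max(v3$input_view$data), arr.ind = TRUE)[1, ]
  fx <- fit_fwhm(v3$input_view$data[w[1], w[2], ], 40)
  expected <- sqrt(125^2 + (2.3548 * 2.4 * 40)^2)
  expect_lt(abs(fx - expected) / expected, 0.03)
})

test_that("training pairs honor the validation split, the seed and the degradation", {
  set.seed(99)
  vg <- voxel_grid(array(stats::runif(70^3), c(70, 70, 70)), rep(40, 3))
  cfg <- training_pair_config(patch_size = 64, n_patches = 100, seed = 3)
  tp <- make_training_pairs(vg, degradation_spec(), cfg)
  expect_equal(sum(tp$split == "validation"), 15L)
  expect_equal(sum(tp$split == "train"), 85L)

  tp2 <- make_training_pairs(vg, degradation_spec(), cfg)
  expect_identical(tp$coords, tp2$coords)

  # every input patch equals the independently re-degraded volume at its crop
  views <- degrade(vg, degradation_spec())
  for (i in c(1, 7, 42)) {
    cc <- tp$coords[i, ]
    zz <- cc$z0:(cc$z0 + 63); yy <- cc$y0:(cc$y0 + 63); xx <- cc$x0:(cc$x0 + 63)
    expect_identical(tp$input[[i]], views$input_view$data[zz, yy, xx])
    expect_identical(tp$target[[i]], views$target_view$data[zz, yy, xx])
  }
  expect_error(make_training_pairs(vg, degradation_spec(),
                                   training_pair_config(patch_size = 80)),
               "exceeds")
})

test_that("restore_1d acts only along x and inverts a matched blur", {
  arr <- array(stats::runif(8 * 8 * 64), c(8, 8, 64))
  vg <- voxel_grid(arr, rep(40, 3))
  expect_identical(restore_1d(vg, restorer_spec("wiener_1d", 0))$data, arr)

  # separable pattern: y and z marginals must be untouched
  zi <- sin(seq_len(16)); yi <- cos(seq_len(16)) + 2; xi <- stats::dnorm(seq_len(64), 32, 5)
  sep <- outer(outer(zi + 2, yi, "*"), xi + 0.01, "*")
  vs <- voxel_grid(sep, rep(40, 3))
  rs <- restore_1d(vs, restorer_spec("wiener_1d", kernel_fwhm = 150,
                                     regularization = 1e-4))
  mz <- apply(rs$data, 1, sum) / apply(sep, 1, sum)
  my <- apply(rs$data, 2, sum) / apply(sep, 2, sum)
  expect_lt(diff(range(mz)) / mean(mz), 1e-6)
  expect_lt(diff(range(my)) / mean(my), 1e-6)

  # matched Wiener restoration: blur F = 8 px, restored substantially sharper,
  # improving as the regularization shrinks (numerical oracle: the restored
  # spectrum is H^2/(H^2+reg), a flat band whose width sets the main lobe)
  n <- 128
  f <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1))) / (n * 40)
  Fw <- 8 * 40
  H <- exp(-2 * pi^2 * (Fw / 2.3548)^2 * f^2)
  imp <- rep(0, n); imp[n / 2] <- 1
  blur <- pmax(Re(stats::fft(stats::fft(imp) * H, inverse = TRUE)) / n, 0)
  bvol <- voxel_grid(array(rep(blur, each = 1), c(1, 1, n)), rep(40, 3))
  prev <- Inf
  for (reg in c(1e-4, 1e-8, 1e-12)) {
    out <- restore_1d(bvol, restorer_spec("wiener_1d", kernel_fwhm = Fw,
                                          regularization = reg))
    fw <- fit_fwhm(out$data[1, 1, ], 40)
    expect_lt(fw, 0.6 * Fw)
    expect_lte(fw, prev + 1)
    prev <- fw
  }

  # Richardson-Lucy narrows a matched blur as well
  rl <- restore_1d(bvol, restorer_spec("richardson_lucy_1d", kernel_fwhm = Fw,
                                       iterations = 50))
  expect_lt(fit_fwhm(rl$data[1, 1, ], 40), 0.8 * Fw)
  expect_true(all(rl$data >= 0))
})

test_that("fusion with one angle and an identity restorer is the identity", {
  set.seed(5)
  arr <- array(stats::runif(16^3), c(16, 16, 16))
  vg <- voxel_grid(arr, rep(40, 3))
  fus <- fusion_spec(0, restorer_spec("wiener_1d", 0))
  out <- fuse_rotations(vg, fus)
  expect_lt(max(abs(out$data - abs(arr))), 1e-8)
})

test_that("the fused spectrum dominates every per-angle spectrum (small-grid exhaustive)", {
  set.seed(6)
  arr <- array(stats::runif(12 * 12 * 12), c(12, 12, 12))
  vg <- voxel_grid(arr, rep(40, 3))
  rs <- restorer_spec("wiener_1d", kernel_fwhm = 120, regularization = 1e-2)
  fus <- fusion_spec(c(0, 45, 90, 135), rs, method = "spatial")
  fused <- fuse_rotations(vg, fus)
  fmag <- attr(fused, "spectrum_magnitude")
  for (a in fus$angles) {
    rot <- centroshell:::rotate_about_y(vg$data, a)
    res <- restore_1d(voxel_grid(rot, rep(40, 3)), rs)
    back <- centroshell:::rotate_about_y(res$data, -a)
    amag <- Mod(stats::fft(back))
    expect_true(all(fmag >= amag - 1e-6 * max(amag)))
  }
})

test_that("angles {0} and {0,90} agree on a 4-fold symmetric pattern with an identity restorer", {
  n <- 24
  x <- seq_len(n) - (n + 1) / 2
  r2 <- outer(x^2, x^2, "+")
  ring <- exp(-(sqrt(r2) - 5)^2 / 4)
  arr <- array(0, c(n, 3, n))
  for (iy in 1:3) arr[, iy, ] <- ring   # symmetric in the z-x plane
  vg <- voxel_grid(arr, rep(40, 3))
  rs <- restorer_spec("wiener_1d", kernel_fwhm = 0)
  o1 <- fuse_rotations(vg, fusion_spec(0, rs, method = "fourier"))
  o2 <- fuse_rotations(vg, fusion_spec(c(0, 90), rs, method = "fourier"))
  expect_lt(max(abs(o1$data - o2$data)) / max(o1$data), 1e-6)
})

test_that("the full protocol restores bead axial resolution to near the lateral", {
  img <- imaging_spec(110, 360, 40, 40, psf_model = "gaussian",
                      background_level = 0)
  bead <- render_bead(c(37.5 * 40, 31.5 * 40, 31.5 * 40), img, c(76, 64, 64))
  deg <- degradation_spec()
  out <- isotropize_volume(bead, deg, fusion_for_imaging(img, deg))
  f <- fit_fwhm3(out)
  expect_lte(f[["z"]], 1.15 * f[["y"]])
  expect_equal(dim(out), dim(interpolate_isotropic(bead, 40)))

  # little to restore on an isotropic-resolution input: the axial width must
  # stay near its input value (the protocol itself injects a 1-px z blur and
  # the per-frequency maximum can mildly over-sharpen, so the band is wider
  # than for a no-op)
  imgi <- imaging_spec(110, 110, 40, 40, psf_model = "gaussian",
                       background_level = 0)
  beadi <- render_bead(c(37.5 * 40, 31.5 * 40, 31.5 * 40), imgi, c(76, 64, 64))
  outi <- isotropize_volume(beadi, deg = deg,
                            fusion = fusion_for_imaging(imgi, deg))
  fi <- fit_fwhm3(outi)
  f0 <- fit_fwhm3(beadi)
  expect_lt(abs(fi[["z"]] - f0[["z"]]) / f0[["z"]], 0.20)
})
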