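test_that("structure_spec validates geometry", {
  expect_error(structure_spec("shell", c(0, 0, 0), diameter = -10), "positive")
  expect_error(structure_spec("shell", c(0, 0, 0), diameter = 50,
                              shell_thickness = 80), "diameter > shell_thickness")
  expect_error(structure_spec("punctum", c(0, 0, 0), amplitude = 0), "> 0")
})

test_that("a rendered punctum reproduces the PSF within 2%", {
  img <- imaging_spec(125, 360, 40, 125, psf_model = "gaussian")
  sp <- structure_spec("punctum", c(1500, 2560, 2560), amplitude = 100)
  vg <- render_structure(sp, img, c(24, 128, 128))
  f <- fit_fwhm3(vg)
  expect_lt(abs(f[["y"]] - 125) / 125, 0.02)
  expect_lt(abs(f[["x"]] - 125) / 125, 0.02)
  expect_lt(abs(f[["z"]] - 360) / 360, 0.02)
})

test_that("with the PSF off, the shell's radial density peaks at half the diameter", {
  img <- imaging_spec(0, 0, 40, 125)
  sp <- structure_spec("shell", c(1500, 2560, 2560), diameter = 300,
                       shell_thickness = 60, amplitude = 100)
  vg <- render_structure(sp, img, c(24, 128, 128))
  iz <- which.max(apply(vg$data, 1, max))
  pl <- vg$data[iz, , ]
  ctr <- c(2560, 2560) / 40 + 1
  radii <- seq(0, 10) * 40
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  prof <- vapply(radii, function(r) {
    iy <- ctr[1] + r * sin(ang) / 40; ix <- ctr[2] + r * cos(ang) / 40
    mean(pl[cbind(round(iy), round(ix))])
  }, 0)
  expect_lt(abs(radii[which.max(prof)] - 150), 21)  # within half a pixel
})

test_that("the blurred shell midplane is bimodal and agrees with a fine-grid oracle", {
  # oracle: same density model rasterized at 10 nm and convolved with the
  # separable Gaussian directly (independent of the patch/decimation path)
  img <- imaging_spec(125, 125, 40, 125, psf_model = "gaussian")
  diam <- 191; th <- 80; obl <- 1.3
  sp <- structure_spec("shell", c(1500, 2560, 2560), diam, th, 100, obl)
  vg <- render_structure(sp, img, c(24, 128, 128))
  iz <- round(1500 / 125) + 1
  prof <- vg$data[iz, 2560 / 40 + 1, ]
  pos <- (seq_along(prof) - (2560 / 40 + 1)) * 40
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  sep_pkg <- diff(range(pos[pk[abs(pos[pk]) < 250]]))
  expect_gt(length(pk[abs(pos[pk]) < 250]), 1)  # bimodal

  px <- 10
  ext <- diam / 2 + th + 2.2 * 125
  n <- 2 * floor(ext / px) + 1; cc <- (n + 1) / 2
  xs <- (seq_len(n) - cc) * px
  sr <- th / (2 * sqrt(2 * log(2)))
  rho <- sqrt(outer(xs^2, xs^2, "+"))
  vol <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    vol[k, , ] <- exp(-((rho - diam / 2)^2 + (xs[k] / obl)^2) / (2 * sr^2))
  }
  gs <- 125 / (2 * sqrt(2 * log(2))) / px
  half <- ceiling(4 * gs)
  g <- stats::dnorm(seq(-half, half), sd = gs)
  g <- g / sum(g)
  blur1 <- function(a, ax) {
    p <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, p)
    m <- apply(matrix(ap, nrow = n), 2, function(col)
      stats::filter(col, g, sides = 2))
    m[is.na(m)] <- 0
    aperm(array(m, dim(ap)), order(p))
  }
  for (ax in 1:3) vol <- blur1(vol, ax)
  oprof <- vol[cc, cc, ]
  opk <- which(diff(sign(diff(oprof))) == -2) + 1
  sep_oracle <- diff(range(xs[opk[abs(xs[opk]) < 250]]))
  expect_lt(abs(sep_pkg - sep_oracle), 40)  # within one acquisition pixel
})

test_that("camera noise is seeded, unbiased in the photon-rich limit, and has the Poisson+read variance", {
  vg <- voxel_grid(array(100, c(10, 100, 100)), c(125, 40, 40))
  img <- imaging_spec(background_level = 0, read_noise_sd = 2)
  n1 <- add_noise(vg, img, seed = 9)
  n2 <- add_noise(vg, img, seed = 9)
  expect_identical(n1$data, n2$data)

  rich <- imaging_spec(background_level = 0, read_noise_sd = 0,
                       photon_scale = 1e6)
  nr <- add_noise(vg, rich, seed = 1)
  expect_lt(sqrt(mean((nr$data - 100)^2)) / 100, 0.01)

  s <- 2
  img2 <- imaging_spec(background_level = 0, read_noise_sd = 2,
                       photon_scale = s)
  nv <- add_noise(vg, img2, seed = 3)
  expect_lt(abs(stats::var(as.vector(nv$data)) - (100 / s + 4)) / (100 / s + 4),
            0.05)
})

test_that("doubling the amplitude doubles the rendered structure", {
  img <- imaging_spec()
  sp1 <- structure_spec("shell", c(1500, 2560, 2560), 227, 80, 100)
  sp2 <- structure_spec("shell", c(1500, 2560, 2560), 227, 80, 200)
  v1 <- render_structure(sp1, img, c(24, 128, 128))
  v2 <- render_structure(sp2, img, c(24, 128, 128))
  expect_lt(max(abs(v2$data - 2 * v1$data)) / max(v1$data), 1e-6)
  expect_lt(abs(sum(v1$data) - 100) / 100, 0.01)  # mass equals amplitude
})

test_that("a structure touching the boundary raises an error", {
  img <- imaging_spec()
  sp <- structure_spec("shell", c(100, 100, 100), 227, 80, 100)
  expect_error(render_structure(sp, img, c(24, 128, 128)), "boundary")
})

test_that("render_dataset truth matches its draws and the generator's statistics", {
  ds <- fixture_dataset("cenpa", seed = 1)
  tr <- ds$truth
  expect_equal(nrow(tr), 150)
  expect_true(all(tr$kind == "shell"))  # ring_probability 1
  # law-of-large-numbers check on the truncated-normal diameters
  se <- 30 / sqrt(150)
  expect_lt(abs(mean(tr$true_diameter) - 191), 3 * se + 1)

  ds0 <- render_dataset(condition_preset("puncta-only", 191, 30,
                                         ring_probability = 0),
                        n_nuclei = 1, structures_per_nucleus = 8,
                        imaging = imaging_spec(), seed = 2, dna = FALSE)
  expect_true(all(ds0$truth$kind == "punctum"))
})

test_that("noiseless structure centroids match the truth within half a voxel", {
  ds <- render_dataset(preset("cenpc"), n_nuclei = 1,
                       structures_per_nucleus = 6, imaging = imaging_spec(),
                       seed = 4, dna = FALSE, noise = FALSE)
  g <- ds$nuclei[[1]]$marker
  vs <- g$voxel_size
  tr <- ds$truth
  for (s in seq_len(nrow(tr))) {
    i0 <- round(c(tr$z[s] / vs[1], tr$y[s] / vs[2], tr$x[s] / vs[3])) + 1
    hw <- c(3, 8, 8)
    zz <- (i0[1] - hw[1]):(i0[1] + hw[1])
    yy <- (i0[2] - hw[2]):(i0[2] + hw[2])
    xx <- (i0[3] - hw[3]):(i0[3] + hw[3])
    blk <- g$data[zz, yy, xx]
    w <- sum(blk)
    cz <- sum(apply(blk, 1, sum) * (zz - 1) * vs[1]) / w
    cy <- sum(apply(blk, 2, sum) * (yy - 1) * vs[2]) / w
    cx <- sum(apply(blk, 3, sum) * (xx - 1) * vs[3]) / w
    expect_lt(abs(cz - tr$z[s]), vs[1] / 2)
    expect_lt(abs(cy - tr$y[s]), vs[2] / 2)
    expect_lt(abs(cx - tr$x[s]), vs[3] / 2)
  }
})

test_that("the DNA cavity carve attains the requested density ratio", {
  img0 <- imaging_spec(0, 0, 40, 125, read_noise_sd = 0, background_level = 0)
  ds <- render_dataset(preset("cenpo"), n_nuclei = 2,
                       structures_per_nucleus = 5, imaging = img0, seed = 6,
                       noise = FALSE, dna = TRUE)
  ratios <- c()
  for (i in 1:2) {
    dn <- ds$nuclei[[i]]$dna$data
    vs <- ds$nuclei[[i]]$dna$voxel_size
    tr <- ds$truth[ds$truth$nucleus_id == i & ds$truth$kind == "shell", ]
    # deep-cavity voxels vs far-field voxels
    d <- dim(dn)
    zc <- ((seq_len(d[1])) - 1) * vs[1]
    yc <- ((seq_len(d[2])) - 1) * vs[2]
    xc <- ((seq_len(d[3])) - 1) * vs[3]
    inside <- array(FALSE, d); near <- array(FALSE, d)
    for (s in seq_len(nrow(tr))) {
      rz <- outer(outer((zc - tr$z[s])^2 / 1.3^2, (yc - tr$y[s])^2, "+"),
                  (xc - tr$x[s])^2, "+")
      inside <- inside | rz < (0.5 * tr$true_diameter[s] / 2)^2
      near <- near | rz < (tr$true_diameter[s] / 2 + 120)^2
    }
    ratios <- c(ratios, mean(dn[inside]) / mean(dn[!near]))
  }
  expect_lt(abs(mean(ratios) - 0.4), 0.02)
})
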