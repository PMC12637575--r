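# Shared fixtures and small numeric helpers.  Datasets are cached per
# (preset, seed, imaging) so the acceptance tests and the unit tests can
# reuse renders.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(preset_name, seed, n_nuclei = 10,
                            structures_per_nucleus = 15,
                            imaging = imaging_spec(), dna = FALSE, ...) {
  key <- paste(preset_name, seed, n_nuclei, structures_per_nucleus, dna,
               imaging$psf_fwhm_lateral, imaging$psf_fwhm_axial,
               imaging$xy_pixel, imaging$psf_model, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ds <- render_dataset(preset(preset_name), n_nuclei = n_nuclei,
                       structures_per_nucleus = structures_per_nucleus,
                       imaging = imaging, seed = seed, dna = dna, ...)
  .fixture_cache[[key]] <- ds
  ds
}

# Gaussian FWHM of a sampled 1D profile by least squares (Nelder-Mead on
# (A, centre, log sigma); robust to exact zero-residual profiles where nls
# aborts)
fit_fwhm <- function(v, step) {
  x <- (seq_along(v) - which.max(v)) * step
  obj <- function(p) {
    sum((v - p[1] * exp(-(x - p[2])^2 / (2 * exp(2 * p[3]))))^2)
  }
  fit <- stats::optim(c(max(v), 0, log(step * 2)), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  exp(fit$par[3]) * 2 * sqrt(2 * log(2))
}

# FWHM by interpolated half-maximum crossings (model-free; appropriate for
# non-Gaussian profiles such as the band-limited SIM core)
fwhm_crossing <- function(v, step) {
  vn <- v / max(v)
  x <- (seq_along(v) - which.max(vn)) * step
  i <- which.max(vn)
  lo <- which(vn[1:i] < 0.5); hi <- which(vn[i:length(vn)] < 0.5)
  if (!length(lo) || !length(hi)) return(NA_real_)
  l <- max(lo); r <- i - 1 + min(hi)
  x1 <- stats::approx(vn[c(l, l + 1)], x[c(l, l + 1)], 0.5)$y
  x2 <- stats::approx(vn[c(r - 1, r)], x[c(r - 1, r)], 0.5)$y
  x2 - x1
}

# Fitted (z, y, x) FWHMs of the brightest spot in a volume
fit_fwhm3 <- function(grid) {
  arr <- grid$data
  w <- which(arr == max(arr), arr.ind = TRUE)[1, ]
  vs <- grid$voxel_size
  c(z = fit_fwhm(arr[, w[2], w[3]], vs[1]),
    y = fit_fwhm(arr[w[1], , w[3]], vs[2]),
    x = fit_fwhm(arr[w[1], w[2], ], vs[3]))
}

# Per-structure morphometry over a whole dataset via the detection path
dataset_morphometry <- function(ds, background = 10) {
  out <- list()
  for (i in seq_along(ds$nuclei)) {
    q <- quantify_structures(ds$nuclei[[i]]$marker, background = background)
    if (nrow(q)) {
      q$nucleus_id <- i
      out[[length(out) + 1L]] <- q
    }
  }
  do.call(rbind, out)
}

# Dual-box corrected intensities at truth positions on the MIP
truth_spot_intensities <- function(ds, n_max = Inf) {
  vals <- c()
  for (i in seq_along(ds$nuclei)) {
    g <- ds$nuclei[[i]]$marker
    mip <- max_projection(g)
    vs <- g$voxel_size
    tr <- ds$truth[ds$truth$nucleus_id == unique(ds$truth$nucleus_id)[i], ]
    for (s in seq_len(nrow(tr))) {
      px <- round(c(tr$y[s] / vs[2], tr$x[s] / vs[3])) + 1
      ci <- try(corrected_spot_intensity(mip, px), silent = TRUE)
      if (!inherits(ci, "try-error")) vals <- c(vals, ci$corrected)
    }
  }
  vals[seq_len(min(n_max, length(vals)))]
}

# noiseless bead volume for the resolution-enhancement tests
render_bead <- function(center, imaging, grid_shape, amplitude = 1000) {
  sp <- structure_spec("punctum", center, amplitude = amplitude,
                       axial_extent_scale = 1)
  render_structure(sp, imaging, grid_shape)
}
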