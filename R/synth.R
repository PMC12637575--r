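#' Specification of one simulated centromere structure
#'
#' A structure is either a `"shell"` (a semi-enclosed equatorial band: a
#' Gaussian tube of radial sigma `shell_thickness/2.3548` around the
#' equatorial circle of the stated diameter, with the axial tube width
#' multiplied by `axial_extent_scale` to give the slightly oblong axial
#' appearance) or a `"punctum"` (an unresolved point emitter).  The shell
#' `diameter` is the peak-to-peak distance of the density annulus, i.e. the
#' quantity the ring-diameter morphometry estimates.
#'
#' @param kind `"shell"` or `"punctum"`.
#' @param center Numeric `(z, y, x)` position in nm.
#' @param diameter Shell diameter in nm (ignored for puncta).
#' @param shell_thickness Shell thickness (FWHM of the tube cross-section)
#'   in nm; must be `< diameter` for shells.
#' @param amplitude Total integrated intensity of the structure, in
#'   intensity units; must be `> 0`.
#' @param axial_extent_scale Unitless axial oblongness factor `>= 1`.
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(kind = c("shell", "punctum"), center,
                           diameter = NA_real_, shell_thickness = 80,
                           amplitude = 1, axial_extent_scale = 1.3) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center)) {
    stop("`center` must be (z, y, x) in nm", call. = FALSE)
  }
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (axial_extent_scale < 1) stop("`axial_extent_scale` must be >= 1", call. = FALSE)
  if (kind == "shell") {
    if (!is.finite(diameter) || diameter <= 0) {
      stop("shells need a positive `diameter`", call. = FALSE)
    }
    if (shell_thickness <= 0 || shell_thickness >= diameter) {
      stop("need diameter > shell_thickness > 0", call. = FALSE)
    }
  }
  structure(list(kind = kind, center = center, diameter = diameter,
                 shell_thickness = shell_thickness, amplitude = amplitude,
                 axial_extent_scale = axial_extent_scale),
            class = "structure_spec")
}

#' Condition presets for the synthetic experiments
#'
#' `condition_preset()` builds a preset; `preset()` looks up a built-in by
#' name.  Built-ins encode the centromere/inner-kinetochore markers
#' (diameter means and SDs 191 +- 30, 227 +- 33, 267 +- 43 and 278 +- 42 nm
#' for `"cenpa"`, `"cenpc"`, `"cenpo"` and `"cenpt"`) and the perturbation
#' conditions: `"plk1i"` (PLK1-inhibition-like: marker intensity halved,
#' rings abolished, chromatin cavity lost) and `"p221a"` (hyperactive
#' chaperone: marker intensity x 1.64, architecture unchanged), plus
#' `"control"` and `"dhjurp"` (chaperone-depletion-like: rings largely lost,
#' marker level unchanged).
#'
#' @param name Preset label.
#' @param diameter_mean,diameter_sd Shell diameter distribution in nm.
#' @param intensity_factor Multiplier on structure amplitude (`> 0`).
#' @param ring_probability Probability that a structure is a shell rather
#'   than a punctum, in `[0, 1]`.
#' @param dna_cavity_fraction Multiplier on DNA density inside the shell
#'   cavity, in `[0, 1]`; 1 means no chromatin clearing.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, diameter_mean, diameter_sd,
                             intensity_factor = 1, ring_probability = 1,
                             dna_cavity_fraction = 0.4) {
  if (intensity_factor <= 0) stop("`intensity_factor` must be > 0", call. = FALSE)
  if (ring_probability < 0 || ring_probability > 1) {
    stop("`ring_probability` must be in [0, 1]", call. = FALSE)
  }
  if (dna_cavity_fraction < 0 || dna_cavity_fraction > 1) {
    stop("`dna_cavity_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd,
                 intensity_factor = intensity_factor,
                 ring_probability = ring_probability,
                 dna_cavity_fraction = dna_cavity_fraction),
            class = "condition_preset")
}

#' @rdname condition_preset
#' @export
preset <- function(name) {
  builtin <- list(
    cenpa   = condition_preset("cenpa", 191, 30, 1.00, 1.00, 0.4),
    cenpc   = condition_preset("cenpc", 227, 33, 1.00, 1.00, 0.4),
    cenpo   = condition_preset("cenpo", 267, 43, 1.00, 1.00, 0.4),
    cenpt   = condition_preset("cenpt", 278, 42, 1.00, 1.00, 0.4),
    control = condition_preset("control", 191, 30, 1.00, 0.90, 0.4),
    plk1i   = condition_preset("plk1i", 191, 30, 0.50, 0.05, 1.0),
    p221a   = condition_preset("p221a", 191, 30, 1.64, 0.90, 0.4),
    dhjurp  = condition_preset("dhjurp", 278, 42, 1.00, 0.10, 1.0)
  )
  if (!name %in% names(builtin)) {
    stop(sprintf("unknown preset '%s'; built-ins: %s", name,
                 paste(names(builtin), collapse = ", ")), call. = FALSE)
  }
  builtin[[name]]
}

# Default amplitude: total integrated intensity of one structure, chosen so
# that a typical (191 nm) shell at default imaging has a blurred peak of
# ~240 intensity units, i.e. peak SNR ~ 15 against the default Poisson +
# read-noise floor.  See shell_peak_per_unit_amplitude() for the geometry
# factor; the value here is the target peak.
DEFAULT_PEAK_TARGET <- 240

# Supersampling factors used when rasterizing the pre-PSF density; odd so
# that acquisition voxel centers coincide with fine-grid samples.
SUPERSAMPLE_LATERAL <- 3L
SUPERSAMPLE_AXIAL <- 3L

# Render one structure into `arr` (acquisition grid, (z,y,x)), returning the
# modified array.  The density is rasterized on a supersampled local patch,
# blurred with the PSF there, renormalized to the structure amplitude, and
# decimated back by point-sampling at voxel centers.
render_into <- function(arr, spec, imaging, clip_ok = FALSE) {
  vs <- c(imaging$z_step, imaging$xy_pixel, imaging$xy_pixel)
  d <- dim(arr)
  ctr <- spec$center
  obl <- spec$axial_extent_scale
  R <- if (spec$kind == "shell") spec$diameter / 2 else 0
  th <- if (spec$kind == "shell") spec$shell_thickness else 0
  core_z <- (R + th) * obl
  core_l <- R + th
  # boundary check on the structure core
  lo <- ctr - c(core_z, core_l, core_l)
  hi <- ctr + c(core_z, core_l, core_l)
  if (!clip_ok && (any(lo < 0) || any(hi > (d - 1) * vs))) {
    stop("structure touches the grid boundary", call. = FALSE)
  }
  marg_z <- core_z + 2.5 * imaging$psf_fwhm_axial
  marg_l <- core_l + 2.5 * max(imaging$psf_fwhm_lateral, 125)
  i0 <- pmax(1L, floor((ctr - c(marg_z, marg_l, marg_l)) / vs) + 1L)
  i1 <- pmin(d, ceiling((ctr + c(marg_z, marg_l, marg_l)) / vs) + 1L)
  f <- c(SUPERSAMPLE_AXIAL, SUPERSAMPLE_LATERAL, SUPERSAMPLE_LATERAL)
  nfine <- (i1 - i0 + 1L) * f
  fine_vs <- vs / f
  # fine-grid coordinates: coarse voxel i covers subsamples centred on it
  coords <- lapply(1:3, function(a) {
    ((i0[a] - 1) * vs[a]) + (seq_len(nfine[a]) - (f[a] + 1) / 2) * fine_vs[a] - ctr[a]
  })
  dens <- array(0, nfine)
  if (spec$kind == "shell") {
    sr <- spec$shell_thickness * FWHM_TO_SIGMA
    rho <- sqrt(outer(coords[[2]]^2, coords[[3]]^2, "+"))
    drho2 <- (rho - R)^2
    for (iz in seq_len(nfine[1])) {
      zeff <- coords[[1]][iz] / obl
      dens[iz, , ] <- exp(-(drho2 + zeff^2) / (2 * sr^2))
    }
  } else {
    # trilinear splat of a point emitter at the exact centre
    pos <- -sapply(coords, function(x) x[1]) / fine_vs + 1
    z0 <- floor(pos[1]); y0 <- floor(pos[2]); x0 <- floor(pos[3])
    dz <- pos[1] - z0; dy <- pos[2] - y0; dx <- pos[3] - x0
    for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
      w <- (if (az) dz else 1 - dz) * (if (ay) dy else 1 - dy) *
        (if (ax) dx else 1 - dx)
      iz <- z0 + az; iy <- y0 + ay; ix <- x0 + ax
      if (w > 0 && iz >= 1 && iz <= nfine[1] && iy >= 1 && iy <= nfine[2] &&
          ix >= 1 && ix <= nfine[3]) {
        dens[iz, iy, ix] <- dens[iz, iy, ix] + w
      }
    }
  }
  target_mass <- spec$amplitude * prod(f)
  dens <- dens * (target_mass / sum(dens))
  dens <- blur_density(dens, imaging, fine_vs)
  dens[dens < 0] <- 0
  dens <- dens * (target_mass / sum(dens))  # reconstruction renormalization
  # decimate: the centre subsample of each coarse voxel
  sub <- lapply(1:3, function(a) seq((f[a] + 1) / 2, nfine[a], by = f[a]))
  coarse <- dens[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
    arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + coarse
  arr
}

#' Render a single structure into an empty volume
#'
#' Rasterizes the pre-PSF density model of one structure (shell or punctum)
#' on a supersampled grid, blurs it with the PSF, and samples it onto the
#' acquisition grid.  The result is noiseless; total integrated intensity
#' equals the structure amplitude (within 1% for structures at least 3 PSF
#' FWHM from the edges).
#'
#' @param spec A [structure_spec].
#' @param imaging An [imaging_spec].
#' @param grid_shape Integer `(nz, ny, nx)`.
#' @return A [voxel_grid].
#' @export
render_structure <- function(spec, imaging, grid_shape) {
  stopifnot(inherits(spec, "structure_spec"), inherits(imaging, "imaging_spec"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be (nz, ny, nx)", call. = FALSE)
  }
  arr <- array(0, grid_shape)
  arr <- render_into(arr, spec, imaging)
  voxel_grid(arr, c(imaging$z_step, imaging$xy_pixel, imaging$xy_pixel))
}

#' Add Poisson + Gaussian camera noise
#'
#' Each voxel becomes a Poisson draw on
#' `(intensity + background_level) * photon_scale`, rescaled back to
#' intensity units, plus Gaussian read noise; negative results are clamped
#' to zero (camera offset).  Reproducible when `seed` is given.
#'
#' @param grid A [voxel_grid] (noiseless intensities).
#' @param imaging An [imaging_spec] carrying the noise parameters.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A noisy [voxel_grid].
#' @export
add_noise <- function(grid, imaging, seed = NULL) {
  stopifnot(is_voxel_grid(grid), inherits(imaging, "imaging_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lam <- (grid$data + imaging$background_level) * imaging$photon_scale
  n <- length(lam)
  out <- stats::rpois(n, lam) / imaging$photon_scale
  if (imaging$read_noise_sd > 0) {
    out <- out + stats::rnorm(n, 0, imaging$read_noise_sd)
  }
  out[out < 0] <- 0
  voxel_grid(array(out, dim(grid$data)), grid$voxel_size, grid$channel)
}

# Peak intensity of a unit-amplitude shell of given diameter under the
# imaging model; used to convert the target peak SNR into an amplitude.
shell_peak_per_unit_amplitude <- function(diameter, imaging,
                                          shell_thickness = 80,
                                          axial_extent_scale = 1.3) {
  ext <- diameter / 2 + shell_thickness + 2.5 * imaging$psf_fwhm_lateral
  extz <- (diameter / 2 + shell_thickness) * axial_extent_scale +
    2.5 * imaging$psf_fwhm_axial
  nl <- 2L * ceiling(ext / imaging$xy_pixel) + 3L
  nz <- 2L * ceiling(extz / imaging$z_step) + 3L
  ctr <- c((nz - 1) / 2 * imaging$z_step, (nl - 1) / 2 * imaging$xy_pixel,
           (nl - 1) / 2 * imaging$xy_pixel)
  sp <- structure_spec("shell", ctr, diameter, shell_thickness, 1,
                       axial_extent_scale)
  vg <- render_structure(sp, imaging, c(nz, nl, nl))
  max(vg$data)
}

#' Generate a seeded synthetic dataset of nuclei
#'
#' For each nucleus and condition preset, draws `structures_per_nucleus`
#' structures (shells with probability `ring_probability`, diameters from a
#' truncated normal), renders a marker channel, a DNA channel (smoothed
#' lognormal chromatin texture with density inside each shell cavity
#' multiplied by `dna_cavity_fraction`), and optionally a chaperone channel
#' (one punctum at each shell centre), then applies the PSF and, if
#' requested, camera noise.  Returns the volumes together with a ground
#' truth table.
#'
#' @param presets A [condition_preset] or list of them (one dataset per
#'   preset).
#' @param n_nuclei Nuclei per preset.
#' @param structures_per_nucleus Structures per nucleus.
#' @param imaging An [imaging_spec].
#' @param seed Integer seed controlling all randomness.
#' @param grid_shape Volume shape `(nz, ny, nx)` per nucleus.
#' @param noise Add camera noise? (default `TRUE`).
#' @param dna Render the DNA channel? (default `TRUE`).
#' @param chaperone Render the chaperone channel? (default `FALSE`).
#' @param dna_level Mean DNA intensity in intensity units.
#' @param min_separation_nm Minimum centre-to-centre distance; the default
#'   700 nm keeps neighbouring structures out of each other's outer
#'   background box.
#' @param amplitude_jitter_sd Lognormal SD of per-structure amplitude
#'   variation (0 disables).
#' @return A list with `nuclei` (list of per-nucleus channel lists of
#'   [voxel_grid]s) and `truth` (data frame: `nucleus_id`, `structure_id`,
#'   `condition`, `kind`, `true_diameter`, `true_amplitude`, `z`, `y`, `x`).
#' @export
render_dataset <- function(presets, n_nuclei, structures_per_nucleus = 15,
                           imaging = imaging_spec(), seed = 1,
                           grid_shape = c(24, 128, 128), noise = TRUE,
                           dna = TRUE, chaperone = FALSE, dna_level = 50,
                           min_separation_nm = 700,
                           amplitude_jitter_sd = 0.2) {
  if (inherits(presets, "condition_preset")) presets <- list(presets)
  stopifnot(n_nuclei >= 1, structures_per_nucleus >= 1)
  grid_shape <- as.integer(grid_shape)
  vs <- c(imaging$z_step, imaging$xy_pixel, imaging$xy_pixel)
  extent <- (grid_shape - 1) * vs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  shell_th <- 80; obl <- 1.3
  # Draw all ground-truth randomness up front: the noise draws below consume
  # a data-dependent amount of the RNG stream, and pre-drawing keeps the
  # truth tables of two conditions run at the same seed aligned structure
  # for structure (so intensity-factor comparisons are paired by design).
  plan <- list(); nid <- 0L
  for (pr in presets) {
    # amplitude giving the target blurred peak for this preset's mean shell
    peak1 <- shell_peak_per_unit_amplitude(pr$diameter_mean, imaging,
                                           shell_th, obl)
    base_amp <- DEFAULT_PEAK_TARGET / peak1
    for (i in seq_len(n_nuclei)) {
      nid <- nid + 1L
      # margins keep the structure core and both intensity boxes in-bounds
      marg_l <- max(pr$diameter_mean + 2 * pr$diameter_sd, 400) / 2 + 300
      marg_z <- marg_l * obl
      if (any(extent < 2 * c(marg_z, marg_l, marg_l))) {
        stop("grid too small for the requested structures", call. = FALSE)
      }
      centers <- matrix(NA_real_, structures_per_nucleus, 3)
      for (s in seq_len(structures_per_nucleus)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          cand <- c(stats::runif(1, marg_z, extent[1] - marg_z),
                    stats::runif(1, marg_l, extent[2] - marg_l),
                    stats::runif(1, marg_l, extent[3] - marg_l))
          if (s == 1L ||
              min(sqrt(colSums((t(centers[seq_len(s - 1), , drop = FALSE]) - cand)^2))) >=
              min_separation_nm) {
            centers[s, ] <- cand; ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place structures without overlap; enlarge the grid",
                      call. = FALSE)
      }
      kinds <- ifelse(stats::runif(structures_per_nucleus) < pr$ring_probability,
                      "shell", "punctum")
      diam_floor <- shell_th + imaging$xy_pixel
      diams <- vapply(kinds, function(k) {
        if (k == "punctum") return(NA_real_)
        d <- -Inf
        while (d < diam_floor) d <- stats::rnorm(1, pr$diameter_mean, pr$diameter_sd)
        d
      }, numeric(1))
      amps <- base_amp * pr$intensity_factor *
        if (amplitude_jitter_sd > 0) {
          stats::rlnorm(structures_per_nucleus,
                        -amplitude_jitter_sd^2 / 2, amplitude_jitter_sd)
        } else rep(1, structures_per_nucleus)
      plan[[nid]] <- list(pr = pr, centers = centers, kinds = kinds,
                          diams = diams, amps = amps)
    }
  }

  nuclei <- vector("list", nid); truth <- vector("list", nid)
  for (nid in seq_along(plan)) {
    pr <- plan[[nid]]$pr
    centers <- plan[[nid]]$centers; kinds <- plan[[nid]]$kinds
    diams <- plan[[nid]]$diams; amps <- plan[[nid]]$amps
    {
      marker <- array(0, grid_shape)
      for (s in seq_len(structures_per_nucleus)) {
        sp <- if (kinds[s] == "shell") {
          structure_spec("shell", centers[s, ], diams[s], shell_th, amps[s], obl)
        } else {
          structure_spec("punctum", centers[s, ], amplitude = amps[s],
                         axial_extent_scale = obl)
        }
        marker <- render_into(marker, sp, imaging)
      }
      chans <- list(marker = voxel_grid(marker, vs, "marker"))
      if (chaperone) {
        chap <- array(0, grid_shape)
        for (s in which(kinds == "shell")) {
          sp <- structure_spec("punctum", centers[s, ], amplitude = amps[s],
                               axial_extent_scale = obl)
          chap <- render_into(chap, sp, imaging)
        }
        chans$chaperone <- voxel_grid(chap, vs, "chaperone")
      }
      if (dna) {
        chans$dna <- render_dna_channel(grid_shape, vs, centers, kinds, diams,
                                        shell_th, obl, pr$dna_cavity_fraction,
                                        dna_level, imaging)
      }
      if (noise) {
        chans <- lapply(chans, add_noise, imaging = imaging)
        # a SIM reconstruction carries no content beyond the OTF support,
        # noise included; white post-noise volumes would overstate peak
        # jitter in downstream linescan measurements
        chans <- lapply(chans, project_otf_support, imaging = imaging)
      }
      nuclei[[nid]] <- chans
      truth[[nid]] <- data.frame(
        nucleus_id = nid, structure_id = seq_len(structures_per_nucleus),
        condition = pr$name, kind = kinds, true_diameter = diams,
        true_amplitude = amps,
        z = centers[, 1], y = centers[, 2], x = centers[, 3])
    }
  }
  list(nuclei = nuclei, truth = do.call(rbind, truth))
}

# Textured chromatin channel: lognormal random field with ~150 nm
# correlation length, with density inside each shell cavity multiplied by
# `cavity_fraction` (ramping back to 1 across the shell thickness), then
# blurred with the PSF.
render_dna_channel <- function(grid_shape, vs, centers, kinds, diams,
                               shell_th, obl, cavity_fraction, dna_level,
                               imaging) {
  g <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  corr_sigma <- 150
  g <- gauss_blur_axis(g, corr_sigma / vs[1], 1L)
  g <- gauss_blur_axis(g, corr_sigma / vs[2], 2L)
  g <- gauss_blur_axis(g, corr_sigma / vs[3], 3L)
  g <- (g - mean(g)) / stats::sd(g)
  field <- exp(0.35 * g)
  field <- field * (dna_level / mean(field))
  # carve cavities
  for (s in which(kinds == "shell")) {
    R <- diams[s] / 2
    reach <- (R + shell_th) * obl
    i0 <- pmax(1L, floor((centers[s, ] - reach) / vs) + 1L)
    i1 <- pmin(grid_shape, ceiling((centers[s, ] + reach) / vs) + 1L)
    zc <- ((i0[1]:i1[1]) - 1) * vs[1] - centers[s, 1]
    yc <- ((i0[2]:i1[2]) - 1) * vs[2] - centers[s, 2]
    xc <- ((i0[3]:i1[3]) - 1) * vs[3] - centers[s, 3]
    rho2 <- outer(yc^2, xc^2, "+")
    for (k in seq_along(zc)) {
      r <- sqrt(rho2 + (zc[k] / obl)^2)
      fac <- pmin(1, pmax(0, (r - R) / shell_th))
      fac <- cavity_fraction + (1 - cavity_fraction) * fac
      blk <- field[i0[1] + k - 1L, i0[2]:i1[2], i0[3]:i1[3]]
      field[i0[1] + k - 1L, i0[2]:i1[2], i0[3]:i1[3]] <- blk * fac
    }
  }
  field <- blur_density(field, imaging, vs)
  voxel_grid(pmax(field, 0), vs, "dna")
}
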