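#' Line intensity profile
#'
#' @param positions Strictly increasing, uniformly spaced offsets in nm from
#'   the line midpoint.
#' @param intensities Sampled intensities.
#' @param background_per_pixel Background already subtracted per sample.
#' @param normalized Has the profile been divided by its maximum?
#' @param center_index Index of the aligned central extremum (or `NA`).
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities, background_per_pixel = 0,
                         normalized = FALSE, center_index = NA_integer_) {
  positions <- as.numeric(positions); intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities) || length(positions) < 2L) {
    stop("positions and intensities must be equal length >= 2", call. = FALSE)
  }
  dp <- diff(positions)
  if (any(dp <= 0) || diff(range(dp)) > 1e-6 * mean(dp)) {
    stop("positions must be strictly increasing and uniformly spaced", call. = FALSE)
  }
  structure(list(positions = positions, intensities = intensities,
                 background_per_pixel = background_per_pixel,
                 normalized = normalized, center_index = center_index),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.0f nm%s%s\n",
              length(x$positions), diff(range(x$positions)),
              if (x$normalized) ", normalized" else "",
              if (x$background_per_pixel != 0)
                sprintf(", background %.3g/px subtracted", x$background_per_pixel)
              else ""))
  invisible(x)
}

# bilinear sample of matrix m (rows = y, cols = x) at pixel coordinates
# (iy, jx), 1-based, clamped to the valid interpolation range
bilinear_sample <- function(m, iy, jx) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- pmin(pmax(iy, 1), ny); jx <- pmin(pmax(jx, 1), nx)
  y0 <- pmin(floor(iy), ny - 1L); x0 <- pmin(floor(jx), nx - 1L)
  dy <- iy - y0; dx <- jx - x0
  m[cbind(y0, x0)] * (1 - dy) * (1 - dx) +
    m[cbind(y0 + 1, x0)] * dy * (1 - dx) +
    m[cbind(y0, x0 + 1)] * (1 - dy) * dx +
    m[cbind(y0 + 1, x0 + 1)] * dy * dx
}

#' Extract a line intensity profile from a lateral plane
#'
#' Samples intensities along the segment from `p0` to `p1` (nm, `(y, x)`)
#' at the pixel pitch via bilinear interpolation, averaging over `width_px`
#' parallel lines offset perpendicular to the segment.
#'
#' @param plane A y-by-x matrix or a single-plane [voxel_grid].
#' @param p0,p1 Endpoints `(y, x)` in nm (voxel centre of pixel `[1,1]` is
#'   at 0 nm).
#' @param width_px Odd integer line width in pixels (default 1).
#' @param pixel_nm Pixel size in nm (required when `plane` is a matrix).
#' @param z Plane index when `plane` is a multi-plane grid.
#' @return A [line_profile].
#' @export
extract_linescan <- function(plane, p0, p1, width_px = 1, pixel_nm = NULL,
                             z = NULL) {
  pl <- as_plane(plane, pixel_nm, z)
  m <- pl$m; px <- pl$pixel_nm
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  lims <- (c(nrow(m), ncol(m)) - 1) * px
  if (any(p0 < 0) || any(p1 < 0) || p0[1] > lims[1] || p1[1] > lims[1] ||
      p0[2] > lims[2] || p1[2] > lims[2]) {
    stop("endpoints must lie inside the plane", call. = FALSE)
  }
  if (width_px < 1 || width_px %% 2 == 0) {
    stop("`width_px` must be an odd positive integer", call. = FALSE)
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("endpoints must differ", call. = FALSE)
  n <- floor(len / px) + 1L
  t <- seq(0, by = px, length.out = n)
  dir <- (p1 - p0) / len
  perp <- c(-dir[2], dir[1])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * px
  acc <- numeric(n)
  for (o in offs) {
    yy <- p0[1] + t * dir[1] + o * perp[1]
    xx <- p0[2] + t * dir[2] + o * perp[2]
    acc <- acc + bilinear_sample(m, yy / px + 1, xx / px + 1)
  }
  line_profile(t - (n - 1) * px / 2, acc / width_px)
}

#' Subtract mean background per pixel from a profile
#'
#' Values may go negative; they are preserved, not clamped, so that
#' downstream averaging stays unbiased.
#'
#' @param profile A [line_profile].
#' @param background_mean_per_pixel Nonnegative background estimate.
#' @return The corrected [line_profile].
#' @export
correct_profile <- function(profile, background_mean_per_pixel) {
  stopifnot(inherits(profile, "line_profile"))
  if (background_mean_per_pixel < 0) {
    stop("background must be >= 0", call. = FALSE)
  }
  profile$intensities <- profile$intensities - background_mean_per_pixel
  profile$background_per_pixel <-
    profile$background_per_pixel + background_mean_per_pixel
  profile
}

#' Normalize, align and aggregate line profiles
#'
#' Each background-corrected profile is divided by its maximum, the central
#' extremum (minimum or maximum, per `mode`) within `window_px` of the
#' geometric midpoint becomes position 0, and the traces are resampled onto
#' a common nm grid (the pixel pitch of the first profile) where mean and
#' SD are computed per position over contributing traces.
#'
#' @param profiles List of [line_profile]s.
#' @param mode `"central_min"` (e.g. DNA across a cavity) or `"central_max"`.
#' @param window_px Half-width, in pixels, of the search window for the
#'   central extremum (default 5).
#' @return An `aggregate_profile`: list with `positions`, `mean`, `sd`, `n`.
#' @export
normalize_and_align <- function(profiles, mode = c("central_min", "central_max"),
                                window_px = 5) {
  mode <- match.arg(mode)
  if (inherits(profiles, "line_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  aligned <- list()
  for (p in profiles) {
    stopifnot(inherits(p, "line_profile"))
    mx <- max(p$intensities)
    if (mx <= 0) {
      warning("profile with nonpositive maximum excluded from aggregation")
      next
    }
    v <- p$intensities / mx
    n <- length(v)
    mid <- (n + 1) / 2
    win <- seq(max(1L, ceiling(mid - window_px)), min(n, floor(mid + window_px)))
    ci <- if (mode == "central_min") win[which.min(v[win])] else win[which.max(v[win])]
    step <- p$positions[2] - p$positions[1]
    aligned[[length(aligned) + 1L]] <-
      list(pos = p$positions - p$positions[ci], val = v, step = step)
  }
  if (!length(aligned)) stop("all profiles excluded (nonpositive maxima)", call. = FALSE)
  step <- aligned[[1]]$step
  lo <- min(vapply(aligned, function(a) min(a$pos), 0))
  hi <- max(vapply(aligned, function(a) max(a$pos), 0))
  grid <- seq(floor(lo / step) * step, ceiling(hi / step) * step, by = step)
  vals <- vapply(aligned, function(a) {
    stats::approx(a$pos, a$val, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n_tr <- rowSums(!is.na(vals))
  keep <- n_tr >= 1L
  structure(list(
    positions = grid[keep],
    mean = rowMeans(vals, na.rm = TRUE)[keep],
    sd = apply(vals, 1, stats::sd, na.rm = TRUE)[keep],
    n = n_tr[keep]
  ), class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("<aggregate_profile> %d positions, up to %d traces\n",
              length(x$positions), max(x$n)))
  invisible(x)
}

#' @export
plot.aggregate_profile <- function(x, ...) {
  graphics::plot(x$positions, x$mean, type = "l", lwd = 2,
                 xlab = "distance from centre (nm)",
                 ylab = "normalized intensity", ...)
  graphics::lines(x$positions, x$mean + x$sd, lty = 3)
  graphics::lines(x$positions, pmax(x$mean - x$sd, 0), lty = 3)
  invisible(x)
}

# strict local maxima (interior points exceeding both neighbours)
local_maxima <- function(v) which(diff(sign(diff(v))) == -2) + 1L

# 3-point parabolic sub-pixel refinement of peak position
refine_peak <- function(pos, val, i) {
  if (i <= 1L || i >= length(val)) return(pos[i])
  y1 <- val[i - 1]; y2 <- val[i]; y3 <- val[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(pos[i])
  pos[i] + (pos[2] - pos[1]) * 0.5 * (y1 - y3) / den
}

#' Measure ring diameter by the two-highest-peaks, longest-axis rule
#'
#' Takes linescans through the centroid at `n_orientations` evenly spaced
#' angles; for each angle, finds the highest local maximum on each side of
#' the centroid; the orientation with the largest peak separation is the
#' longest axis, and the separation at that orientation (with 3-point
#' parabolic sub-pixel refinement unless `refine = FALSE`) is the ring
#' diameter.
#'
#' @param plane A y-by-x matrix or single-plane [voxel_grid]
#'   (best-focus lateral plane of the structure).
#' @param centroid `(y, x)` in nm.
#' @param n_orientations Number of probe angles over 180 degrees
#'   (default 36; must be `>= 8`).
#' @param probe_length_nm Probe length centred on the centroid (default 800).
#' @param pixel_nm Pixel size when `plane` is a matrix.
#' @param z Plane index when `plane` is a multi-plane grid.
#' @param refine Apply sub-pixel peak refinement? (default `TRUE`).
#' @return A `diameter_measurement`: list with `diameter` (nm, `NA` unless
#'   `quality == "ok"`), `peak_positions`, `orientation` (degrees) and
#'   `quality` (`"ok"` or `"single_peak"`).
#' @export
measure_ring_diameter <- function(plane, centroid, n_orientations = 36,
                                  probe_length_nm = 800, pixel_nm = NULL,
                                  z = NULL, refine = TRUE) {
  pl <- as_plane(plane, pixel_nm, z)
  m <- pl$m; px <- pl$pixel_nm
  if (n_orientations < 8) stop("`n_orientations` must be >= 8", call. = FALSE)
  centroid <- as.numeric(centroid)
  lims <- (c(nrow(m), ncol(m)) - 1) * px
  half <- probe_length_nm / 2
  if (any(centroid - half < 0) || any(centroid + half > lims)) {
    stop("centroid too close to the border for this probe length", call. = FALSE)
  }
  t <- seq(-half, half, by = px)
  angles <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  best <- NULL
  for (a in angles) {
    yy <- centroid[1] + t * sin(a)
    xx <- centroid[2] + t * cos(a)
    v <- bilinear_sample(m, yy / px + 1, xx / px + 1)
    pk <- local_maxima(v)
    left <- pk[t[pk] < -1e-9]; right <- pk[t[pk] > 1e-9]
    if (!length(left) || !length(right)) next
    l <- left[which.max(v[left])]; r <- right[which.max(v[right])]
    pl_pos <- if (refine) refine_peak(t, v, l) else t[l]
    pr_pos <- if (refine) refine_peak(t, v, r) else t[r]
    sep <- pr_pos - pl_pos
    if (is.null(best) || sep > best$sep) {
      best <- list(sep = sep, peaks = c(pl_pos, pr_pos), angle = a)
    }
  }
  if (is.null(best)) {
    return(structure(list(diameter = NA_real_, peak_positions = c(NA_real_, NA_real_),
                          orientation = NA_real_, quality = "single_peak"),
                     class = "diameter_measurement"))
  }
  structure(list(diameter = best$sep, peak_positions = best$peaks,
                 orientation = best$angle * 180 / pi, quality = "ok"),
            class = "diameter_measurement")
}

#' @export
print.diameter_measurement <- function(x, ...) {
  if (x$quality == "ok") {
    cat(sprintf("<diameter_measurement> %.1f nm at %.0f deg\n",
                x$diameter, x$orientation))
  } else {
    cat(sprintf("<diameter_measurement> quality = %s\n", x$quality))
  }
  invisible(x)
}
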