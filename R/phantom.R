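#' Configuration for the synthetic cine phantom
#'
#' Defines the geometry, timing, velocity amplitudes and noise level of the
#' synthetic three-directional velocity-mapping cine phantom.  The phantom is
#' an annular "myocardium" between two concentric near-elliptical contours
#' that contracts and relaxes over one cardiac cycle.  Its three phase
#' channels encode a longitudinal (through-plane), radial and circumferential
#' velocity field whose spatial mean reproduces closed-form velocity--time
#' profiles, so velocity curves and their peak markers have analytically
#' known ground truth.
#'
#' Image coordinates are row-major with the origin at the top-left: `x` runs
#' rightward along columns, array `y` downward along rows.  Angles are
#' measured from the +x axis, increasing counter-clockwise in the physical
#' (y-up) convention.  The phase channels store velocities directly in cm/s;
#' velocity-encoding (VENC) wrap-around is not simulated.
#'
#' @param image_size Integer, pixels per side (square frames).  64 is the
#'   working scale; 512 reproduces the clinical reconstruction matrix.
#' @param n_frames Integer, frames per cardiac cycle (the clinical protocol
#'   reconstructs 50).
#' @param pixel_spacing_mm Pixel spacing in mm (isotropic).
#' @param rr_ms Cardiac cycle (R-R interval) duration in ms.
#' @param center_xy Annulus centre `c(x, y)` in pixels; default image centre.
#' @param r_endo_mm,r_epi_mm End-diastolic endocardial / epicardial radii, mm.
#' @param contraction_fraction Peak systolic fractional radius reduction,
#'   in (0, 1).
#' @param v_long_peaks_cm_s Signed longitudinal peak amplitudes
#'   `c(PS, PD, PAS)` in cm/s.
#' @param v_rad_peaks_cm_s Signed radial peak amplitudes `c(PS, PD, PAS)`
#'   in cm/s (positive = outward; systolic wall motion is inward, so a
#'   physiological systolic amplitude is negative).
#' @param v_circ_peaks_cm_s Signed circumferential peak amplitudes
#'   `c(C1, C2, C3)` in cm/s (positive = counter-clockwise).
#' @param ecc_jitter Amplitude of the frame-to-frame ellipse eccentricity
#'   modulation (0 gives exactly circular contours).
#' @param slice_jitter Relative spread of per-slice radius and velocity
#'   amplitude variation within a generated dataset.
#' @param noise_sd Additive Gaussian noise s.d. on the phase channels, cm/s.
#'   The magnitude channel receives noise of `noise_sd / 20` on its unit
#'   intensity scale.
#' @param mag_contrast If `TRUE` (default) the magnitude channel shows the
#'   anatomy (bright blood pool, mid-grey myocardium, dark background); if
#'   `FALSE` it is a featureless constant so only the phase channels carry
#'   the ring signal (useful for channel-relevance experiments).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `mvm_phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 64, n_frames = 50)
#' ph <- generate_phantom_dataset(cfg, n_slices = 1)
#' ph$slice[[1]]
phantom_config <- function(image_size = 64L,
                           n_frames = 50L,
                           pixel_spacing_mm = 1.0,
                           rr_ms = 1000,
                           center_xy = NULL,
                           r_endo_mm = 12,
                           r_epi_mm = 22,
                           contraction_fraction = 0.15,
                           v_long_peaks_cm_s = c(9, -12, -5),
                           v_rad_peaks_cm_s = c(-3.5, 3.5, 1.5),
                           v_circ_peaks_cm_s = c(2, -2.5, 2),
                           ecc_jitter = 0.06,
                           slice_jitter = 0.08,
                           noise_sd = 1.0,
                           mag_contrast = TRUE,
                           seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size),
    n_frames = as.integer(n_frames),
    pixel_spacing_mm = pixel_spacing_mm,
    rr_ms = rr_ms,
    center_xy = center_xy %||% rep((image_size + 1) / 2, 2),
    r_endo_mm = r_endo_mm,
    r_epi_mm = r_epi_mm,
    contraction_fraction = contraction_fraction,
    v_long_peaks_cm_s = v_long_peaks_cm_s,
    v_rad_peaks_cm_s = v_rad_peaks_cm_s,
    v_circ_peaks_cm_s = v_circ_peaks_cm_s,
    ecc_jitter = ecc_jitter,
    slice_jitter = slice_jitter,
    noise_sd = noise_sd,
    mag_contrast = isTRUE(mag_contrast),
    seed = as.integer(seed)
  )
  class(cfg) <- "mvm_phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (!is.finite(cfg$r_endo_mm) || !is.finite(cfg$r_epi_mm) ||
      cfg$r_endo_mm >= cfg$r_epi_mm || cfg$r_endo_mm <= 0) {
    config_error("phantom radii must satisfy 0 < r_endo_mm < r_epi_mm")
  }
  if (cfg$n_frames < 8L) config_error("n_frames must be >= 8")
  if (cfg$image_size < 16L) config_error("image_size must be >= 16")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0) {
    config_error("noise_sd must be finite and >= 0")
  }
  amps <- c(cfg$v_long_peaks_cm_s, cfg$v_rad_peaks_cm_s, cfg$v_circ_peaks_cm_s)
  if (length(cfg$v_long_peaks_cm_s) != 3L || length(cfg$v_rad_peaks_cm_s) != 3L ||
      length(cfg$v_circ_peaks_cm_s) != 3L || !all(is.finite(amps))) {
    config_error("velocity peak amplitudes must be finite length-3 vectors")
  }
  if (!is.finite(cfg$contraction_fraction) || cfg$contraction_fraction <= 0 ||
      cfg$contraction_fraction >= 1) {
    config_error("contraction_fraction must lie in (0, 1)")
  }
  if (cfg$rr_ms <= 0 || cfg$pixel_spacing_mm <= 0) {
    config_error("rr_ms and pixel_spacing_mm must be positive")
  }
  invisible(cfg)
}

# Marker timing of the closed-form profiles: bump centres and full widths as
# fractions of the R-R interval.  Centres sit inside the default systolic
# [0, 0.4), early-diastolic [0.4, 0.75) and atrial-systolic [0.75, 1) windows,
# and supports do not overlap, so each bump's extremum is the marker value.
marker_timing <- function() {
  list(
    longitudinal = data.frame(marker = c("PS", "PD", "PAS"),
                              center = c(0.15, 0.55, 0.85),
                              width = c(0.25, 0.20, 0.18)),
    radial = data.frame(marker = c("PS", "PD", "PAS"),
                        center = c(0.15, 0.55, 0.85),
                        width = c(0.25, 0.20, 0.18)),
    circumferential = data.frame(marker = c("C1", "C2", "C3"),
                                 center = c(0.08, 0.30, 0.55),
                                 width = c(0.12, 0.12, 0.16))
  )
}

# Raised-cosine bump of unit height centred at `center` with full width
# `width` on the periodic phase axis; identically 0 outside its support, so
# all profiles satisfy f(0) = f(1-) exactly.
cosine_bump <- function(t, center, width) {
  d <- phase_dist(t, center)
  ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

profile_value <- function(t, timing, amps) {
  v <- numeric(length(t))
  for (k in seq_len(nrow(timing))) {
    v <- v + amps[k] * cosine_bump(t, timing$center[k], timing$width[k])
  }
  v
}

#' Closed-form global velocity profiles of the phantom
#'
#' Evaluates the prescribed longitudinal, radial and circumferential global
#' velocity--time profiles at the given cardiac phase fractions.  Each profile
#' is a sum of non-overlapping raised-cosine bumps, one per clinical marker
#' (systolic PS, early-diastolic PD and atrial-systolic PAS for the
#' longitudinal and radial directions; the two systolic peaks C1, C2 and the
#' early-diastolic peak C3 for the circumferential direction), so the
#' profiles are periodic and their extrema are exactly the configured
#' amplitudes.
#'
#' @param phase_fraction Numeric vector of cardiac phases in `[0, 1)`.
#' @param config A [phantom_config()].
#' @param amp_scale Optional named list of per-direction amplitude
#'   multipliers (`longitudinal`, `radial`, `circumferential`).
#' @return A tibble with columns `phase`, `v_long`, `v_rad`, `v_circ` (cm/s).
#' @export
velocity_profiles <- function(phase_fraction, config, amp_scale = NULL) {
  if (any(phase_fraction < 0 | phase_fraction >= 1)) {
    abort("phase_fraction must lie in [0, 1)",
          class = c("mvm_domain_error", "mvm_error"))
  }
  tm <- marker_timing()
  sc <- amp_scale %||% list(longitudinal = 1, radial = 1, circumferential = 1)
  tibble::tibble(
    phase = phase_fraction,
    v_long = profile_value(phase_fraction, tm$longitudinal,
                           config$v_long_peaks_cm_s * sc$longitudinal),
    v_rad = profile_value(phase_fraction, tm$radial,
                          config$v_rad_peaks_cm_s * sc$radial),
    v_circ = profile_value(phase_fraction, tm$circumferential,
                           config$v_circ_peaks_cm_s * sc$circumferential)
  )
}

#' Phantom velocity field at a pixel
#'
#' Evaluates the noise-free phantom velocity field at one or more pixels for
#' a given cardiac phase.  The in-plane part is the radial profile along the
#' unit vector from the annulus centre to the pixel plus the circumferential
#' profile along that vector rotated +90 degrees (counter-clockwise, y-up);
#' the through-plane part is the longitudinal profile.  All three components
#' are spatially uniform in the local radial/circumferential frame, so the
#' mask mean of each decomposed component equals the prescribed profile.
#'
#' @param phase_fraction Scalar cardiac phase in `[0, 1)`.
#' @param config A [phantom_config()].
#' @param pixel `c(x, y)` pixel coordinates (or a 2-column matrix).
#' @return A tibble with columns `v_x`, `v_y`, `v_z` in cm/s (`v_y` is the
#'   physical, y-up component).
#' @export
velocity_field <- function(phase_fraction, config, pixel) {
  prof <- velocity_profiles(phase_fraction, config)
  p <- matrix(pixel, ncol = 2)
  dx <- p[, 1] - config$center_xy[1]
  dyp <- -(p[, 2] - config$center_xy[2])   # physical y points up
  r <- sqrt(dx^2 + dyp^2)
  rx <- ifelse(r > 0, dx / r, 0)
  ry <- ifelse(r > 0, dyp / r, 0)
  tibble::tibble(
    v_x = prof$v_rad * rx - prof$v_circ * ry,
    v_y = prof$v_rad * ry + prof$v_circ * rx,
    v_z = rep(prof$v_long, nrow(p))
  )
}

# Systolic contraction shape: 0 at end-diastole, peaking at phase 0.35,
# recovered by 0.7, flat during diastasis/atrial systole.  Periodic.
contraction_shape <- function(t) {
  ifelse(t < 0.7, sin(pi * t / 0.7)^2, 0)
}

# Annulus (ring) mask between two concentric co-oriented ellipses.
ellipse_ring_mask <- function(h, w, cx, cy, a_epi, b_epi, a_endo, b_endo, psi) {
  g <- pixel_grid(h, w)
  dx <- g$x - cx
  dyp <- -(g$y - cy)
  u <- cos(psi) * dx + sin(psi) * dyp
  v <- -sin(psi) * dx + cos(psi) * dyp
  in_epi <- (u / a_epi)^2 + (v / b_epi)^2 <= 1
  in_endo <- (u / a_endo)^2 + (v / b_endo)^2 <= 1
  list(ring = in_epi & !in_endo, cavity = in_endo)
}

#' Generate a synthetic 3-directional velocity-mapping cine dataset
#'
#' Creates `n_slices` synthetic short-axis cine slices with analytically
#' known myocardium masks, velocity curves and peak markers.  Each slice is a
#' 4-channel image time series (magnitude plus three orthogonal phase
#' velocity channels).  Slice geometry (radii, centre, ellipse eccentricity
#' phase and orientation) and velocity amplitudes receive mild per-slice
#' jitter so a generated dataset has realistic between-slice variability;
#' the per-slice ground truth reflects the jittered values.
#'
#' @param config A [phantom_config()].
#' @param n_slices Number of cine slices to generate (grouped into synthetic
#'   subjects of up to 4 slices, mirroring the 3--5 slices per study of a
#'   clinical acquisition).
#' @return A tibble of class `mvm_phantom` with one row per slice and list
#'   columns `slice` ([cine_slice()] objects), `mask` ([myo_mask()] ground
#'   truth), `truth_curves` (global velocity--time tibbles) and `truth_peaks`
#'   (marker tibbles).
#' @export
generate_phantom_dataset <- function(config, n_slices = 1L) {
  validate_phantom_config(config)
  if (n_slices < 1L) config_error("n_slices must be >= 1")
  with_seed(config$seed, {
    rows <- lapply(seq_len(n_slices), function(s) generate_phantom_slice(config, s))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("mvm_phantom", class(out))
  out
}

generate_phantom_slice <- function(cfg, s) {
  n <- cfg$image_size
  nf <- cfg$n_frames
  sp <- cfg$pixel_spacing_mm
  scale <- stats::runif(1, 1 - cfg$slice_jitter, 1 + cfg$slice_jitter)
  r_endo <- cfg$r_endo_mm * scale / sp
  r_epi <- cfg$r_epi_mm * scale / sp
  cx <- cfg$center_xy[1] + stats::runif(1, -1.5, 1.5)
  cy <- cfg$center_xy[2] + stats::runif(1, -1.5, 1.5)
  phi <- stats::runif(1, 0, 2 * pi)      # eccentricity modulation phase
  psi <- stats::runif(1, 0, pi)          # ellipse orientation
  amp <- list(
    longitudinal = stats::runif(1, 1 - cfg$slice_jitter, 1 + cfg$slice_jitter),
    radial = stats::runif(1, 1 - cfg$slice_jitter, 1 + cfg$slice_jitter),
    circumferential = stats::runif(1, 1 - cfg$slice_jitter, 1 + cfg$slice_jitter)
  )

  t <- (seq_len(nf) - 1) / nf
  prof <- velocity_profiles(t, cfg, amp)
  g <- pixel_grid(n, n)
  dx <- g$x - cx
  dyp <- -(g$y - cy)
  r <- sqrt(dx^2 + dyp^2)
  rx <- ifelse(r > 0, dx / r, 0)
  ry <- ifelse(r > 0, dyp / r, 0)

  frames <- array(0, c(n, n, nf, 4))
  labels <- array(0L, c(n, n, nf))
  for (f in seq_len(nf)) {
    e <- 1 + cfg$ecc_jitter * sin(2 * pi * t[f] + phi)
    rho <- 1 - cfg$contraction_fraction * contraction_shape(t[f])
    mk <- ellipse_ring_mask(n, n, cx, cy,
                            r_epi * rho * e, r_epi * rho / e,
                            r_endo * rho * e, r_endo * rho / e, psi)
    labels[, , f] <- mk$ring * 1L
    mag <- matrix(0.5, n, n)
    if (cfg$mag_contrast) {
      mag[!mk$ring & !mk$cavity] <- 0.15
      mag[mk$cavity] <- 0.85
    }
    # moving tissue only: the velocity signal is supported on the myocardium,
    # static background and (modelled as stationary) blood pool carry none
    ring <- mk$ring * 1
    vx <- (prof$v_rad[f] * rx - prof$v_circ[f] * ry) * ring
    vy <- (prof$v_rad[f] * ry + prof$v_circ[f] * rx) * ring
    vz <- matrix(prof$v_long[f], n, n) * ring
    if (cfg$noise_sd > 0) {
      mag <- mag + matrix(stats::rnorm(n * n, 0, cfg$noise_sd / 20), n, n)
      vx <- vx + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
      vy <- vy + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
      vz <- vz + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
    }
    frames[, , f, 1] <- mag
    frames[, , f, 2] <- vx
    frames[, , f, 3] <- vy
    frames[, , f, 4] <- vz
  }

  slice_id <- sprintf("slice%03d", s)
  subject_id <- sprintf("sub%02d", ceiling(s / 4))
  sl <- cine_slice(frames, pixel_spacing_mm = c(sp, sp), rr_ms = cfg$rr_ms,
                   slice_id = slice_id, subject_id = subject_id)
  msk <- myo_mask(labels, provenance = "manual")

  curves <- tibble::tibble(
    region = "global",
    direction = rep(c("longitudinal", "radial", "circumferential"), each = nf),
    frame = rep(seq_len(nf), 3),
    time_ms = rep(t * cfg$rr_ms, 3),
    velocity_cm_s = c(prof$v_long, prof$v_rad, prof$v_circ)
  )
  peaks <- truth_peaks_from_profiles(cfg, amp, nf)

  tibble::tibble(slice_id = slice_id, subject_id = subject_id,
                 slice = list(sl), mask = list(msk),
                 truth_curves = list(curves), truth_peaks = list(peaks))
}

# Ground-truth markers: for each bump, the extremum of the frame-sampled
# analytic profile over the bump's support (so truth peaks are exactly the
# extrema of the sampled truth curves).
truth_peaks_from_profiles <- function(cfg, amp, nf) {
  t <- (seq_len(nf) - 1) / nf
  tm <- marker_timing()
  amps <- list(longitudinal = cfg$v_long_peaks_cm_s * amp$longitudinal,
               radial = cfg$v_rad_peaks_cm_s * amp$radial,
               circumferential = cfg$v_circ_peaks_cm_s * amp$circumferential)
  out <- lapply(names(tm), function(dir) {
    timing <- tm[[dir]]
    vals <- lapply(seq_len(nrow(timing)), function(k) {
      inside <- phase_dist(t, timing$center[k]) < timing$width[k] / 2
      v <- amps[[dir]][k] * cosine_bump(t, timing$center[k], timing$width[k])
      f <- which(inside)[which.max(abs(v[inside]))]
      tibble::tibble(direction = dir, marker = timing$marker[k],
                     value_cm_s = v[f], time_ms = t[f] * cfg$rr_ms,
                     frame = f)
    })
    dplyr::bind_rows(vals)
  })
  dplyr::bind_rows(out)
}

#' Corrupt a myocardium ring mask
#'
#' Produces fixture masks that violate the closed-ring topology expected of
#' a healthy short-axis myocardium segmentation, emulating the "broken"
#' predictions (semi-ellipses, unclosed rings, scattered islands) that the
#' ellipse-repair stage must fix.
#'
#' @param mask_frame Binary matrix, a valid closed myocardium ring.
#' @param mode One of `"wedge_gap"` (remove a `gap_deg`-degree angular wedge),
#'   `"open_ring"` (a thin 10-degree cut that opens the ring), or
#'   `"speckle"` (random pixel dropout plus scattered false-positive
#'   islands).
#' @param rng_seed Integer seed; the corruption is deterministic given the
#'   seed.
#' @param gap_deg Wedge width in degrees for `mode = "wedge_gap"`.
#' @return The corrupted binary mask frame.
#' @export
corrupt_mask <- function(mask_frame, mode = c("wedge_gap", "open_ring", "speckle"),
                         rng_seed = 1L, gap_deg = 60) {
  m <- as_mask_frame(mask_frame)
  if (sum(m) == 0L) data_error("cannot corrupt an empty mask")
  mode <- tryCatch(match.arg(mode),
                   error = function(e) config_error(
                     paste0("unknown corruption mode: ",
                            paste(mode, collapse = "/"))))
  h <- nrow(m); w <- ncol(m)
  g <- pixel_grid(h, w)
  cx <- mean(g$x[m == 1L]); cy <- mean(g$y[m == 1L])
  ang <- atan2(-(g$y - cy), g$x - cx)
  with_seed(rng_seed, {
    if (mode %in% c("wedge_gap", "open_ring")) {
      gap <- if (mode == "open_ring") 10 else gap_deg
      theta0 <- stats::runif(1, 0, 2 * pi)
      rel <- (ang - theta0) %% (2 * pi)
      m[rel < gap * pi / 180 & m == 1L] <- 0L
    } else {
      fg <- which(m == 1L)
      drop <- fg[stats::runif(length(fg)) < 0.15]
      m[drop] <- 0L
      rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      far <- which(m == 0L & rr > max(sqrt((g$x[fg] - cx)^2 + (g$y[fg] - cy)^2)) + 2)
      if (length(far) > 0) m[sample(far, min(12L, length(far)))] <- 1L
    }
  })
  m
}
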