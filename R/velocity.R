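#' Left-ventricular centroid of a mask frame
#'
#' Returns the centroid of the endocardial cavity (the enclosed hole of the
#' ring), which anchors the radial/circumferential decomposition; if the
#' frame has no enclosed cavity the foreground centroid is used instead.
#'
#' @param mask_frame Binary matrix.
#' @return Named numeric `c(x, y)` in pixel coordinates.
#' @export
lv_centroid <- function(mask_frame) {
  m <- as_mask_frame(mask_frame)
  if (sum(m) == 0L) data_error("empty mask has no centroid")
  bg <- cc_label(1L - m, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(seq_len(attr(bg, "n")), border)
  g <- pixel_grid(nrow(m), ncol(m))
  if (length(holes) > 0L) {
    sizes <- tabulate(bg[bg > 0L], nbins = attr(bg, "n"))[holes]
    sel <- bg == holes[which.max(sizes)]
  } else {
    sel <- m == 1L
  }
  c(x = mean(g$x[sel]), y = mean(g$y[sel]))
}

#' Decompose in-plane velocities into radial and circumferential components
#'
#' For each pixel, the radial unit vector points from the centroid to the
#' pixel (y-up physical convention) and the circumferential unit vector is
#' the radial one rotated +90 degrees (counter-clockwise).  The longitudinal
#' component is the through-plane channel unchanged.  A pixel exactly at the
#' centroid gets zero radial and circumferential components.
#'
#' @param phase Numeric array `[H, W, 3]`: channels `v_x`, `v_y` (physical
#'   y-up), `v_z` in cm/s.
#' @param mask_frame Binary matrix; components are meaningful on mask pixels.
#' @param centroid `c(x, y)` from [lv_centroid()].
#' @return A list of `[H, W]` matrices: `longitudinal`, `radial`,
#'   `circumferential`.
#' @export
decompose_velocity <- function(phase, mask_frame, centroid) {
  d <- dim(phase)
  if (length(d) != 3L || d[3] != 3L) data_error("phase must be [H, W, 3]")
  if (!identical(d[1:2], dim(mask_frame))) data_error("phase/mask shape mismatch")
  g <- pixel_grid(d[1], d[2])
  dx <- g$x - centroid[["x"]]
  dyp <- -(g$y - centroid[["y"]])
  r <- sqrt(dx^2 + dyp^2)
  rx <- ifelse(r > 0, dx / r, 0)
  ry <- ifelse(r > 0, dyp / r, 0)
  vx <- phase[, , 1]
  vy <- phase[, , 2]
  list(longitudinal = phase[, , 3],
       radial = vx * rx + vy * ry,
       circumferential = vx * (-ry) + vy * rx)
}

#' Six-sector AHA-style regional masks
#'
#' Partitions the myocardium ring into six 60-degree angular sectors about
#' the centroid, ordered anterior (A), anteroseptal (AS), inferoseptal (IS),
#' inferior (I), inferolateral (IL), anterolateral (AL) counter-clockwise
#' from the reference angle.  With no anatomical landmark available the
#' reference angle defaults to "up" (+90 degrees, the anterior direction in
#' a conventionally oriented short-axis view).
#'
#' @param mask_frame Binary matrix.
#' @param centroid `c(x, y)` from [lv_centroid()].
#' @param reference_angle Start angle in radians (physical y-up convention).
#' @return Integer matrix: 0 outside the mask, otherwise the sector index
#'   1..6 in the order of [aha_region_labels()].
#' @export
regional_masks <- function(mask_frame, centroid, reference_angle = pi / 2) {
  m <- as_mask_frame(mask_frame)
  g <- pixel_grid(nrow(m), ncol(m))
  ang <- atan2(-(g$y - centroid[["y"]]), g$x - centroid[["x"]])
  rel <- (ang - reference_angle) %% (2 * pi)
  sector <- pmin(as.integer(floor(rel / (pi / 3))) + 1L, 6L)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m == 1L] <- sector[m == 1L]
  out
}

#' Region labels of the six-sector model
#' @return Character vector of the sector labels in order.
#' @export
aha_region_labels <- function() c("A", "AS", "IS", "I", "IL", "AL")

#' Compute global and regional velocity--time curves
#'
#' Converts a cine slice and its myocardium mask sequence into velocity
#' curves: for every frame, the mean of each decomposed velocity component
#' over the myocardium pixels (globally and per six-sector region).  Frames
#' flagged as failed repairs are excluded.
#'
#' @param slice An [cine_slice()].
#' @param masks An [myo_mask()] with one frame per cine frame.
#' @param exclude_frames Optional integer vector of frames to drop (e.g.
#'   failed repairs from [postprocess_mask()]).
#' @param reference_angle Sector reference angle, see [regional_masks()].
#' @return A tibble of class `mvm_curves` with columns `region` (`"global"`
#'   plus the six sector labels), `direction`, `frame`, `time_ms`,
#'   `velocity_cm_s`, `n_pixels`.
#' @export
compute_curves <- function(slice, masks, exclude_frames = integer(),
                           reference_angle = pi / 2) {
  stopifnot(inherits(slice, "mvm_cine_slice"), inherits(masks, "mvm_myo_mask"))
  d <- dim(slice$frames)
  if (!identical(dim(masks$labels), d[1:3])) {
    data_error("mask shape does not match the cine slice")
  }
  frames <- setdiff(seq_len(d[3]), exclude_frames)
  frames <- frames[vapply(frames, function(f) sum(masks$labels[, , f]) > 0, logical(1))]
  if (length(frames) == 0L) {
    abort("no usable frames: all masks empty or excluded",
          class = c("mvm_computation_error", "mvm_error"))
  }
  t_ms <- (seq_len(d[3]) - 1) / d[3] * slice$rr_ms
  dirs <- c("longitudinal", "radial", "circumferential")
  labels <- aha_region_labels()
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    m <- masks$labels[, , f]
    cen <- lv_centroid(m)
    comp <- decompose_velocity(slice$frames[, , f, 2:4], m, cen)
    sect <- regional_masks(m, cen, reference_angle)
    sel <- m == 1L
    per_dir <- lapply(dirs, function(dd) {
      v <- comp[[dd]]
      glob <- tibble::tibble(region = "global", direction = dd, frame = f,
                             time_ms = t_ms[f], velocity_cm_s = mean(v[sel]),
                             n_pixels = sum(sel))
      reg <- tibble::tibble(
        region = labels,
        direction = dd,
        frame = f,
        time_ms = t_ms[f],
        velocity_cm_s = vapply(1:6, function(s) {
          if (any(sect == s)) mean(v[sect == s]) else NA_real_
        }, numeric(1)),
        n_pixels = vapply(1:6, function(s) sum(sect == s), integer(1))
      )
      dplyr::bind_rows(glob, reg)
    })
    rows[[i]] <- dplyr::bind_rows(per_dir)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$region, .data$direction, .data$frame)
  attr(out, "rr_ms") <- slice$rr_ms
  attr(out, "n_frames") <- d[3]
  class(out) <- c("mvm_curves", class(out))
  out
}

#' Cardiac-phase windows for peak search
#'
#' Fractions of the R-R interval bounding the systolic, early-diastolic and
#' atrial-systolic phases in which the clinical markers are sought.
#'
#' @param systole,diastole,atrial Half-open `[lo, hi)` windows as fractions
#'   of the cycle.
#' @return A named list of windows.
#' @export
peak_windows <- function(systole = c(0, 0.4), diastole = c(0.4, 0.75),
                         atrial = c(0.75, 1)) {
  list(systole = systole, diastole = diastole, atrial = atrial)
}

# Circular local extrema of a sampled curve: points whose value is a strict
# one-sided extremum against both neighbours (plateaus collapse to their
# first point).  A constant curve has none.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L || max(v) == min(v)) return(integer())
  prev <- v[c(n, seq_len(n - 1))]
  nxt <- v[c(2:n, 1)]
  is_max <- (v > prev & v >= nxt) | (v >= prev & v > nxt)
  is_min <- (v < prev & v <= nxt) | (v <= prev & v < nxt)
  which(is_max | is_min)
}

in_window <- function(phase, w) phase >= w[1] & phase < w[2]

#' Extract clinical peak markers from velocity curves
#'
#' Finds the signed extrema of the longitudinal and radial curves in the
#' systolic (PS), early-diastolic (PD) and atrial-systolic (PAS) windows,
#' and of the circumferential curve the two largest-magnitude systolic
#' local extrema ordered by time (C1, C2) plus the early-diastolic extremum
#' (C3).  Only genuine local extrema of the (circularly continued) curve are
#' candidates; a window without one yields a missing marker rather than a
#' fabricated value.
#'
#' @param curves An `mvm_curves` tibble from [compute_curves()].
#' @param windows A [peak_windows()] list.
#' @return A tibble of class `mvm_peaks` with columns `region`, `direction`,
#'   `marker`, `value_cm_s`, `time_ms`, `frame` (missing markers have `NA`
#'   values).
#' @export
extract_peaks <- function(curves, windows = peak_windows()) {
  if (!all(is.finite(curves$velocity_cm_s) | is.na(curves$velocity_cm_s))) {
    data_error("curves contain non-finite velocities")
  }
  rr <- attr(curves, "rr_ms")
  nf <- attr(curves, "n_frames") %||% max(curves$frame)
  groups <- dplyr::group_split(dplyr::group_by(curves, .data$region, .data$direction))
  out <- lapply(groups, function(gr) {
    gr <- dplyr::arrange(gr, .data$frame)
    gr <- gr[!is.na(gr$velocity_cm_s), ]
    dir <- gr$direction[1]
    region <- gr$region[1]
    v <- gr$velocity_cm_s
    phase <- (gr$frame - 1) / nf
    ex <- local_extrema(v)
    pick <- function(w, n_take = 1L) {
      cand <- ex[in_window(phase[ex], w)]
      if (length(cand) == 0L) return(integer())
      ord <- cand[order(-abs(v[cand]))]
      sort(ord[seq_len(min(n_take, length(ord)))])
    }
    miss <- function(marker) tibble::tibble(
      region = region, direction = dir, marker = marker,
      value_cm_s = NA_real_, time_ms = NA_real_, frame = NA_integer_)
    mk <- function(marker, i) tibble::tibble(
      region = region, direction = dir, marker = marker,
      value_cm_s = v[i], time_ms = gr$time_ms[i], frame = gr$frame[i])
    if (dir == "circumferential") {
      sys2 <- pick(windows$systole, 2L)
      dia <- pick(windows$diastole, 1L)
      dplyr::bind_rows(
        if (length(sys2) >= 1L) mk("C1", sys2[1]) else miss("C1"),
        if (length(sys2) >= 2L) mk("C2", sys2[2]) else miss("C2"),
        if (length(dia) == 1L) mk("C3", dia) else miss("C3")
      )
    } else {
      ps <- pick(windows$systole); pd <- pick(windows$diastole)
      pas <- pick(windows$atrial)
      dplyr::bind_rows(
        if (length(ps)) mk("PS", ps) else miss("PS"),
        if (length(pd)) mk("PD", pd) else miss("PD"),
        if (length(pas)) mk("PAS", pas) else miss("PAS")
      )
    }
  })
  out <- dplyr::bind_rows(out)
  attr(out, "rr_ms") <- rr
  class(out) <- c("mvm_peaks", class(out))
  out
}
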