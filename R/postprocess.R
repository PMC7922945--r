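#' Test whether a segmentation frame is a broken ring
#'
#' A healthy short-axis myocardium segmentation is a closed, approximately
#' elliptical ring.  Operationally a frame passes when its foreground is
#' exactly one 8-connected component and its background has exactly two
#' 4-connected components -- the exterior and one enclosed cavity -- with
#' only the exterior touching the image border.  Anything else (empty frames,
#' solid disks, open rings, scattered islands) is reported broken.
#'
#' @param mask_frame Binary matrix.
#' @return Logical: `TRUE` if the frame violates the closed-ring topology.
#' @export
is_broken <- function(mask_frame) {
  m <- as_mask_frame(mask_frame)
  if (sum(m) == 0L) return(TRUE)
  fg <- cc_label(m, 8L)
  if (attr(fg, "n") != 1L) return(TRUE)
  bg <- cc_label(1L - m, 4L)
  if (attr(bg, "n") != 2L) return(TRUE)
  border <- c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])
  length(setdiff(unique(border), 0L)) == 2L  # both bg components reach outside
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2-D points by the numerically stable partitioned
#' scatter-matrix formulation of the direct conic least-squares method,
#' which constrains the solution to be a true ellipse.  Points are centred
#' on their centroid before fitting for conditioning.
#'
#' @param points A matrix or data frame with two columns (x, y); at least 5
#'   non-degenerate points are required.
#' @return An object of class `mvm_ellipse`: `center_xy`, `semi_major`,
#'   `semi_minor` (pixels) and `angle` (major-axis orientation, radians in
#'   `[0, pi)`).
#' @export
fit_ellipse <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) fit_error("points must have two columns")
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < 5L) fit_error("at least 5 points are required to fit an ellipse")
  mx <- mean(p[, 1]); my <- mean(p[, 2])
  x <- p[, 1] - mx; y <- p[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) fit_error("degenerate point configuration"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) fit_error("no elliptical solution for these points")
  a1 <- vecs[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))   # A, B, C, D, E, F in centred coords
  geom <- conic_to_geometry(conic)
  geom$center_xy <- geom$center_xy + c(mx, my)
  structure(geom, class = "mvm_ellipse")
}

conic_to_geometry <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) fit_error("conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  Fp <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)           # values in decreasing order
  ax <- -Fp / eg$values
  if (any(ax <= 0)) fit_error("degenerate ellipse (non-positive axis)")
  semi <- sqrt(ax)                           # semi-axis along each eigenvector
  major <- which.max(semi)
  v <- eg$vectors[, major]
  list(center_xy = c(x0, y0),
       semi_major = max(semi), semi_minor = min(semi),
       angle = atan2(v[2], v[1]) %% pi)
}

#' @export
print.mvm_ellipse <- function(x, ...) {
  cat(sprintf("<mvm_ellipse: center (%.2f, %.2f), axes %.2f x %.2f, angle %.1f deg>\n",
              x$center_xy[1], x$center_xy[2], x$semi_major, x$semi_minor,
              x$angle * 180 / pi))
  invisible(x)
}

# Boundary pixels of the foreground: foreground with a 4-neighbour in the
# background (or on the image border).
boundary_pixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  nb <- pad[1:h, 2:(w + 1)] + pad[3:(h + 2), 2:(w + 1)] +
    pad[2:(h + 1), 1:w] + pad[2:(h + 1), 3:(w + 2)]
  which(m == 1L & nb < 4L, arr.ind = TRUE)
}

# Rasterise an ellipse outline of the given total thickness (pixels) using
# the gradient-normalised implicit distance approximation.
rasterize_ellipse_ring <- function(ellipse, dim, width = 3) {
  g <- pixel_grid(dim[1], dim[2])
  dx <- g$x - ellipse$center_xy[1]
  dy <- g$y - ellipse$center_xy[2]
  u <- cos(ellipse$angle) * dx + sin(ellipse$angle) * dy
  v <- -sin(ellipse$angle) * dx + cos(ellipse$angle) * dy
  a <- ellipse$semi_major; b <- ellipse$semi_minor
  f <- (u / a)^2 + (v / b)^2 - 1
  gn <- pmax(2 * sqrt(u^2 / a^4 + v^2 / b^4), 1e-9)
  matrix(as.integer(abs(f) / gn <= width / 2), dim[1], dim[2])
}

#' Repair a broken myocardium segmentation
#'
#' Regresses the boundary pixels of the predicted segmentation into an
#' ellipse by the direct least-squares fit and overlays a 3-pixel-wide
#' rasterised ellipse ring on top of the original prediction, closing gaps
#' so the result satisfies the ring topology.  A frame that already passes
#' [is_broken()] is returned unchanged.  If the fit fails or the overlay
#' still does not close the ring, the returned mask carries a
#' `repair_failed` attribute and should be excluded downstream.
#'
#' @param mask_frame Binary matrix.
#' @param width Thickness of the overlaid ellipse ring in pixels.
#' @return The repaired binary mask (always a superset of the input);
#'   inspect [repair_failed()] for the failure flag.
#' @export
repair_mask <- function(mask_frame, width = 3) {
  m <- as_mask_frame(mask_frame)
  if (!is_broken(m)) {
    attr(m, "repair_failed") <- FALSE
    return(m)
  }
  fail <- function() {
    attr(m, "repair_failed") <- TRUE
    m
  }
  bp <- boundary_pixels(m)
  if (nrow(bp) < 5L) return(fail())
  el <- tryCatch(fit_ellipse(cbind(bp[, "col"], bp[, "row"])),
                 error = function(e) NULL)
  if (is.null(el)) return(fail())
  ring <- rasterize_ellipse_ring(list(center_xy = el$center_xy,
                                      semi_major = el$semi_major,
                                      semi_minor = el$semi_minor,
                                      angle = el$angle),
                                 dim(m), width = width)
  out <- as_mask_frame(pmax(m, ring))
  if (is_broken(out)) {
    attr(m, "repair_failed") <- TRUE
    return(m)
  }
  attr(out, "repair_failed") <- FALSE
  out
}

#' Did a repair fail?
#' @param mask_frame A frame returned by [repair_mask()].
#' @return Logical.
#' @export
repair_failed <- function(mask_frame) {
  isTRUE(attr(mask_frame, "repair_failed"))
}

#' Extract epicardial and endocardial contours
#'
#' Traces the closed boundary contours of a (repaired) ring segmentation and
#' ranks them by enclosed pixel area: the largest becomes the epicardium,
#' the second largest the endocardium (traced along the cavity boundary).
#' Boundary following uses 8-connectivity for the foreground and
#' 4-connectivity for the background cavity.
#'
#' @param mask_frame Binary matrix forming a closed ring (see [is_broken()]).
#' @return A tibble of class `mvm_contours` with columns `contour`
#'   (`"epicardium"`/`"endocardium"`), `vertex`, `x_px`, `y_px`; the
#'   enclosed pixel areas are in `attr(, "areas")`.
#' @export
extract_contours <- function(mask_frame) {
  m <- as_mask_frame(mask_frame)
  fg <- cc_label(m, 8L)
  if (attr(fg, "n") == 0L) {
    abort("empty mask: no contours", class = c("mvm_extract_error", "mvm_error"))
  }
  sizes <- tabulate(fg[fg > 0L], nbins = attr(fg, "n"))
  main <- which.max(sizes)
  comp <- matrix(as.integer(fg == main), nrow(m), ncol(m))
  bg <- cc_label(1L - comp, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(seq_len(attr(bg, "n")), border)
  if (length(holes) == 0L) {
    abort("segmentation has no enclosed cavity: fewer than two contours",
          class = c("mvm_extract_error", "mvm_error"))
  }
  hole_sizes <- tabulate(bg[bg > 0L], nbins = attr(bg, "n"))[holes]
  hole <- holes[which.max(hole_sizes)]
  hole_m <- matrix(as.integer(bg == hole), nrow(m), ncol(m))

  epi <- trace_boundary(comp)
  endo <- trace_boundary(hole_m)
  out <- dplyr::bind_rows(
    tibble::tibble(contour = "epicardium", vertex = seq_len(nrow(epi)),
                   x_px = epi[, 2], y_px = epi[, 1]),
    tibble::tibble(contour = "endocardium", vertex = seq_len(nrow(endo)),
                   x_px = endo[, 2], y_px = endo[, 1])
  )
  attr(out, "areas") <- c(epicardium = sizes[main] + sum(hole_sizes),
                          endocardium = max(hole_sizes))
  class(out) <- c("mvm_contours", class(out))
  out
}

#' Post-process a predicted mask sequence
#'
#' Applies the broken-ring test to every frame and repairs broken frames by
#' the ellipse overlay.  Frames whose repair fails are flagged for exclusion
#' from velocity analysis.
#'
#' @param mask An [myo_mask()].
#' @return A list: `mask` (an `mvm_myo_mask` with provenance
#'   `"postprocessed"`) and `log`, a tibble (`frame`, `broken`, `repaired`,
#'   `failed`).
#' @export
postprocess_mask <- function(mask) {
  stopifnot(inherits(mask, "mvm_myo_mask"))
  d <- dim(mask$labels)
  out <- mask$labels
  log <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    fr <- mask$labels[, , f]
    broken <- is_broken(fr)
    failed <- FALSE
    if (broken) {
      rep <- repair_mask(fr)
      failed <- repair_failed(rep)
      out[, , f] <- rep
    }
    log[[f]] <- tibble::tibble(frame = f, broken = broken,
                               repaired = broken && !failed, failed = failed)
  }
  list(mask = myo_mask(out, provenance = "postprocessed"),
       log = dplyr::bind_rows(log))
}
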