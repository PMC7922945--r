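test_that("the LV centroid tracks the cavity, not the ring", {
  ring <- ring_frame(h = 64, r_in = 8, r_out = 14, cx = 32, cy = 32)
  cen <- lv_centroid(ring)
  expect_lt(max(abs(cen - c(32, 32))), 0.5)
  shifted <- ring_frame(h = 64, r_in = 8, r_out = 14, cx = 37, cy = 29)
  cen2 <- lv_centroid(shifted)
  expect_equal(cen2 - cen, c(x = 5, y = -3), tolerance = 0.5)
  # off-centre cavity: centroid follows the hole, not the foreground
  x <- matrix(rep(1:64, each = 64), 64, 64)
  y <- matrix(rep(1:64, times = 64), 64, 64)
  fg <- (sqrt((x - 32)^2 + (y - 32)^2) <= 16) &
    !(sqrt((x - 38)^2 + (y - 32)^2) <= 5)
  cen3 <- lv_centroid(matrix(as.integer(fg), 64, 64))
  expect_lt(abs(cen3[["x"]] - 38), 0.5)
  expect_lt(abs(cen3[["y"]] - 32), 0.5)
  expect_error(lv_centroid(matrix(0L, 16, 16)), class = "mvm_data_error")
})

test_that("velocity decomposition separates radial and rotational fields", {
  ring <- ring_frame(h = 48, r_in = 8, r_out = 14)
  cen <- lv_centroid(ring)
  x <- matrix(rep(1:48, each = 48), 48, 48)
  y <- matrix(rep(1:48, times = 48), 48, 48)
  dx <- x - cen[["x"]]; dyp <- -(y - cen[["y"]])
  r <- sqrt(dx^2 + dyp^2); r[r == 0] <- 1
  sel <- ring == 1L
  # uniform outward field
  phase <- array(0, c(48, 48, 3))
  phase[, , 1] <- 3 * dx / r
  phase[, , 2] <- 3 * dyp / r
  d <- decompose_velocity(phase, ring, cen)
  expect_lt(max(abs(d$circumferential[sel])), 1e-10)
  expect_equal(d$radial[sel], rep(3, sum(sel)), tolerance = 1e-10)
  # rigid rotation with angular rate omega
  omega <- 0.5
  phase2 <- array(0, c(48, 48, 3))
  phase2[, , 1] <- -omega * dyp
  phase2[, , 2] <- omega * dx
  d2 <- decompose_velocity(phase2, ring, cen)
  expect_lt(max(abs(d2$radial[sel])), 1e-10)
  expect_equal(d2$circumferential[sel], (omega * sqrt(dx^2 + dyp^2))[sel],
               tolerance = 1e-10)
})

test_that("the decomposition preserves in-plane kinetic energy per pixel", {
  withr::local_seed(12)
  ring <- ring_frame()
  cen <- lv_centroid(ring)
  phase <- array(rnorm(48 * 48 * 3), c(48, 48, 3))
  d <- decompose_velocity(phase, ring, cen)
  lhs <- d$radial^2 + d$circumferential^2
  rhs <- phase[, , 1]^2 + phase[, , 2]^2
  sel <- ring == 1L
  expect_lt(max(abs(lhs[sel] - rhs[sel]) / pmax(rhs[sel], 1e-12)), 1e-6)
})

test_that("sector masks partition the ring and rotate cyclically", {
  ring <- ring_frame(h = 64, r_in = 10, r_out = 18, cx = 32.5, cy = 32.5)
  cen <- lv_centroid(ring)
  sect <- regional_masks(ring, cen)
  expect_identical(sort(unique(sect[ring == 1L])), 1:6)
  expect_true(all(sect[ring == 0L] == 0L))
  expect_identical(sum(sect > 0L), sum(ring))      # exact partition
  counts <- tabulate(sect[sect > 0L], 6)
  expect_lt(diff(range(counts)) / mean(counts), 0.1)
  # rotating the reference by 60 degrees permutes the sectors cyclically
  rot <- regional_masks(ring, cen, reference_angle = pi / 2 + pi / 3)
  sel <- ring == 1L
  expect_true(all(((sect[sel] - 2) %% 6) + 1L == rot[sel]))
})

test_that("phantom curves reproduce the prescribed profiles and are linear", {
  ph <- phantom_clean()
  sl <- ph$slice[[1]]; mk <- ph$mask[[1]]
  cur <- compute_curves(sl, mk)
  truth <- ph$truth_curves[[1]]
  glob <- dplyr::filter(cur, region == "global") |>
    dplyr::arrange(direction, frame)
  tr <- dplyr::arrange(truth, direction, frame)
  scale <- max(abs(tr$velocity_cm_s))
  expect_lt(max(abs(glob$velocity_cm_s - tr$velocity_cm_s)) / scale, 0.01)
  # zero phase channels give identically zero curves
  z <- sl
  z$frames[, , , 2:4] <- 0
  curz <- compute_curves(z, mk)
  expect_true(all(abs(curz$velocity_cm_s) < 1e-12))
  # doubling the phase channels doubles every curve
  d <- sl
  d$frames[, , , 2:4] <- 2 * d$frames[, , , 2:4]
  curd <- compute_curves(d, mk)
  expect_equal(curd$velocity_cm_s, 2 * cur$velocity_cm_s, tolerance = 1e-9)
})

test_that("the global curve is the pixel-weighted mean of the regional curves", {
  ph <- phantom_jittered()
  cur <- compute_curves(ph$slice[[2]], ph$mask[[2]])
  check <- cur |>
    dplyr::filter(region != "global") |>
    dplyr::group_by(direction, frame) |>
    dplyr::summarise(v = sum(velocity_cm_s * n_pixels) / sum(n_pixels),
                     .groups = "drop")
  glob <- cur |>
    dplyr::filter(region == "global") |>
    dplyr::arrange(direction, frame)
  expect_equal(glob$velocity_cm_s,
               dplyr::arrange(check, direction, frame)$v, tolerance = 1e-9)
})

test_that("peak extraction recovers phantom markers and degenerate cases", {
  ph <- phantom_clean()
  cur <- compute_curves(ph$slice[[1]], ph$mask[[1]])
  pk <- extract_peaks(cur) |> dplyr::filter(region == "global")
  truth <- ph$truth_peaks[[1]]
  m <- dplyr::inner_join(pk, truth, by = c("direction", "marker"),
                         suffix = c("_got", "_truth"))
  expect_identical(nrow(m), 9L)
  expect_true(all(abs(m$value_cm_s_got - m$value_cm_s_truth) /
                    abs(m$value_cm_s_truth) < 0.05))

  # a pure sinusoid peaks at its amplitude inside the systolic window
  sine <- tibble::tibble(
    region = "global", direction = "longitudinal", frame = 1:40,
    time_ms = (0:39) * 25, velocity_cm_s = 7 * sin(2 * pi * (0:39) / 40),
    n_pixels = 100L)
  attr(sine, "rr_ms") <- 1000; attr(sine, "n_frames") <- 40
  class(sine) <- c("mvm_curves", class(sine))
  ps <- extract_peaks(sine) |>
    dplyr::filter(marker == "PS")
  expect_equal(ps$value_cm_s, 7, tolerance = 1e-9)

  # a flat curve yields only missing markers
  flat <- dplyr::mutate(sine, velocity_cm_s = 0)
  attr(flat, "rr_ms") <- 1000; attr(flat, "n_frames") <- 40
  class(flat) <- c("mvm_curves", class(flat))
  pf <- extract_peaks(flat)
  expect_true(all(is.na(pf$value_cm_s)))
})

test_that("peak extraction is equivariant under curve negation", {
  ph <- phantom_jittered()
  cur <- compute_curves(ph$slice[[1]], ph$mask[[1]])
  neg <- dplyr::mutate(cur, velocity_cm_s = -velocity_cm_s)
  attr(neg, "rr_ms") <- attr(cur, "rr_ms")
  attr(neg, "n_frames") <- attr(cur, "n_frames")
  class(neg) <- class(cur)
  p1 <- extract_peaks(cur) |> dplyr::arrange(region, direction, marker)
  p2 <- extract_peaks(neg) |> dplyr::arrange(region, direction, marker)
  expect_equal(p2$value_cm_s, -p1$value_cm_s, tolerance = 1e-12)
  expect_equal(p2$frame, p1$frame)
})

test_that("frames excluded for failed repair are dropped from the curves", {
  ph <- phantom_tiny(seed = 51, n_slices = 1)
  cur <- compute_curves(ph$slice[[1]], ph$mask[[1]], exclude_frames = c(2, 5))
  expect_false(any(cur$frame %in% c(2, 5)))
  empty <- myo_mask(array(0L, dim(ph$mask[[1]]$labels)), "model")
  expect_error(compute_curves(ph$slice[[1]], empty),
               class = "mvm_computation_error")
})
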