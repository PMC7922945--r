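test_that("identical seeds give bit-identical phantom datasets", {
  cfg <- phantom_config(image_size = 32, n_frames = 10, r_endo_mm = 6,
                        r_epi_mm = 11, seed = 5)
  a <- generate_phantom_dataset(cfg, n_slices = 2)
  b <- generate_phantom_dataset(cfg, n_slices = 2)
  expect_identical(a$slice[[1]]$frames, b$slice[[1]]$frames)
  expect_identical(a$mask[[2]]$labels, b$mask[[2]]$labels)
  expect_identical(a$truth_peaks, b$truth_peaks)
})

test_that("phantom config validation rejects inconsistent geometry", {
  expect_error(phantom_config(r_endo_mm = 25, r_epi_mm = 15),
               class = "mvm_config_error")
  expect_error(phantom_config(n_frames = 4), class = "mvm_config_error")
  expect_error(phantom_config(noise_sd = -1), class = "mvm_config_error")
  expect_error(phantom_config(v_long_peaks_cm_s = c(1, 2)),
               class = "mvm_config_error")
})

test_that("noise-free longitudinal channel reproduces the prescribed profile", {
  ph <- phantom_clean()
  cfg <- attr(ph, "config")
  sl <- ph$slice[[1]]
  mk <- ph$mask[[1]]
  truth <- ph$truth_curves[[1]]
  long_truth <- truth$velocity_cm_s[truth$direction == "longitudinal"]
  for (f in c(1, 8, 20, 35, 50)) {
    sel <- mk$labels[, , f] == 1L
    expect_equal(mean(sl$frames[, , f, 4][sel]), long_truth[f],
                 tolerance = 1e-6)
  }
})

test_that("end-diastolic mask area matches the analytic annulus area", {
  cfg <- phantom_config(r_endo_mm = 15, r_epi_mm = 25, pixel_spacing_mm = 1,
                        image_size = 64, slice_jitter = 0, noise_sd = 0,
                        seed = 9)
  ph <- generate_phantom_dataset(cfg, n_slices = 1)
  area <- sum(ph$mask[[1]]$labels[, , 1])
  expect_lt(abs(area - pi * (25^2 - 15^2)) / (pi * (25^2 - 15^2)), 0.03)
})

test_that("prescribed profiles are periodic and vanish at the cycle boundary", {
  cfg <- phantom_config()
  p0 <- velocity_profiles(0, cfg)
  p1 <- velocity_profiles(1 - 1e-12, cfg)
  expect_equal(unlist(p0[, -1]), unlist(p1[, -1]), tolerance = 1e-9)
})

test_that("velocity field is orthogonal to the unused in-plane direction", {
  base <- list(image_size = 64, seed = 2)
  pix <- cbind(runif(50, 20, 44), runif(50, 20, 44))
  # pure rotation: no radial amplitude
  cfg_rot <- phantom_config(v_rad_peaks_cm_s = c(0, 0, 0))
  v <- velocity_field(0.15, cfg_rot, pix)
  dx <- pix[, 1] - cfg_rot$center_xy[1]
  dyp <- -(pix[, 2] - cfg_rot$center_xy[2])
  r <- sqrt(dx^2 + dyp^2)
  expect_lt(max(abs(v$v_x * dx / r + v$v_y * dyp / r)), 1e-10)
  # pure contraction: no circumferential amplitude
  cfg_con <- phantom_config(v_circ_peaks_cm_s = c(0, 0, 0))
  v2 <- velocity_field(0.15, cfg_con, pix)
  expect_lt(max(abs(v2$v_x * (-dyp) / r + v2$v_y * dx / r)), 1e-10)
  expect_error(velocity_field(1.2, cfg_rot, pix), class = "mvm_domain_error")
})

test_that("sign changes of the longitudinal profile match the closed form", {
  # the profile is a sequence of disjoint bumps, so its sign pattern over the
  # cycle is exactly the sign pattern of the amplitudes in time order
  for (amps in list(c(9, -12, -5), c(-3, 4, -2), c(1, 2, 3))) {
    cfg <- phantom_config(v_long_peaks_cm_s = amps)
    t <- seq(0, 1 - 1e-9, length.out = 20000)
    v <- velocity_profiles(t, cfg)$v_long
    signs <- rle(sign(v[v != 0]))$values
    expected <- rle(sign(amps))$values
    expect_identical(signs, expected)
  }
})

test_that("corrupt_mask breaks rings in the requested way, deterministically", {
  m <- ring_frame()
  w <- corrupt_mask(m, "wedge_gap", rng_seed = 4, gap_deg = 60)
  expect_lt(sum(w), sum(m))             # removal only deletes
  expect_true(all(w <= m))
  # open ring: one foreground component whose cavity leaks to the exterior
  o <- corrupt_mask(m, "open_ring", rng_seed = 4)
  fg <- mvmseg:::cc_label(o, 8L)
  expect_identical(attr(fg, "n"), 1L)
  bg <- mvmseg:::cc_label(1L - o, 4L)
  expect_identical(attr(bg, "n"), 1L)   # hole merged with the exterior
  s1 <- corrupt_mask(m, "speckle", rng_seed = 11)
  s2 <- corrupt_mask(m, "speckle", rng_seed = 11)
  expect_identical(s1, s2)
  expect_error(corrupt_mask(m, "melt"), class = "mvm_config_error")
})

test_that("corrupted masks are classified broken and intact ones are not", {
  ph <- phantom_jittered()
  for (i in seq_len(nrow(ph))) {
    for (f in c(1, 25)) {
      fr <- ph$mask[[i]]$labels[, , f]
      expect_false(is_broken(fr))
      for (mode in c("wedge_gap", "open_ring", "speckle")) {
        expect_true(is_broken(corrupt_mask(fr, mode, rng_seed = i * 100 + f)))
      }
    }
  }
})

test_that("truth peaks are the extrema of the sampled truth curves", {
  ph <- phantom_jittered()
  tp <- ph$truth_peaks[[1]]
  tc <- ph$truth_curves[[1]]
  for (r in seq_len(nrow(tp))) {
    cur <- tc$velocity_cm_s[tc$direction == tp$direction[r]]
    expect_equal(cur[tp$frame[r]], tp$value_cm_s[r], tolerance = 1e-12)
  }
  # each marker's value is the curve extremum nearest its window
  long <- tc$velocity_cm_s[tc$direction == "longitudinal"]
  expect_equal(max(abs(long)),
               max(abs(tp$value_cm_s[tp$direction == "longitudinal"])),
               tolerance = 1e-12)
})
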