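# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A clean circular ring frame (closed-ring topology).
ring_frame <- function(h = 48, r_in = 8, r_out = 14,
                       cx = (h + 1) / 2, cy = (h + 1) / 2) {
  x <- matrix(rep(seq_len(h), each = h), h, h)
  y <- matrix(rep(seq_len(h), times = h), h, h)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  m <- matrix(as.integer(r >= r_in & r <= r_out), h, h)
  m
}

# Small noise-free phantom with deterministic geometry, reused across tests.
phantom_clean <- function() {
  fixture("phantom_clean", {
    cfg <- phantom_config(noise_sd = 0, ecc_jitter = 0, slice_jitter = 0,
                          seed = 20)
    generate_phantom_dataset(cfg, n_slices = 2)
  })
}

# Small noise-free phantom with the default eccentricity/slice jitter.
phantom_jittered <- function() {
  fixture("phantom_jittered", {
    cfg <- phantom_config(noise_sd = 0, seed = 21)
    generate_phantom_dataset(cfg, n_slices = 3)
  })
}

# Tiny fast phantom for training smoke tests (32 px, 10 frames).
phantom_tiny <- function(seed = 30, n_slices = 4, noise_sd = 0.5,
                         mag_contrast = TRUE) {
  cfg <- phantom_config(image_size = 32, n_frames = 10, r_endo_mm = 6,
                        r_epi_mm = 11, pixel_spacing_mm = 1,
                        noise_sd = noise_sd, mag_contrast = mag_contrast,
                        seed = seed)
  generate_phantom_dataset(cfg, n_slices = n_slices)
}

# Sample points on an ellipse boundary.
ellipse_points <- function(n, a, b, angle, cx, cy, noise_sd = 0) {
  th <- stats::runif(n, 0, 2 * pi)
  x <- cx + a * cos(th) * cos(angle) - b * sin(th) * sin(angle)
  y <- cy + a * cos(th) * sin(angle) + b * sin(th) * cos(angle)
  cbind(x + stats::rnorm(n, 0, noise_sd), y + stats::rnorm(n, 0, noise_sd))
}

# Mean frame Dice between a predicted and a truth mask stack.
mean_frame_dice <- function(pred, truth) {
  nf <- dim(truth$labels)[3]
  mean(vapply(seq_len(nf),
              function(f) dice(pred$labels[, , f], truth$labels[, , f]),
              numeric(1)))
}
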