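# Independent layer-by-layer parameter tally of the documented architectures.
# Counts: a 3x3 conv has cin*cout*9 weights (no bias, batch norm follows);
# each batch norm has 2*C; a transposed 2x2 up-convolution has cin*cout*4 + cout;
# attention gates use three biased 1x1 convolutions; the head is a biased 1x1.
tally_params <- function(variant, depth, base) {
  ch <- base * 2^(0:(depth - 1))
  conv <- function(ci, co) ci * co * 9
  bn <- function(c) 2 * c
  block <- function(ci, co) conv(ci, co) + bn(co) + conv(co, co) + bn(co)
  gate <- function(c) {
    fi <- max(c %/% 2, 1)
    (c * fi + fi) * 2 + (fi * 1 + 1)
  }
  up <- function(ci, co) ci * co * 4 + co
  total <- 0
  if (variant == "amu_mp") {
    cm <- 1; cp <- 3
    for (i in seq_len(depth)) {
      total <- total + block(cm, ch[i]) + block(cp, ch[i])
      cm <- cp <- ch[i]
    }
    for (i in seq_len(depth - 1)) {
      total <- total + block(2 * ch[i], ch[i]) + gate(ch[i])
    }
    total <- total + block(2 * ch[depth], ch[depth])
  } else {
    cin <- switch(variant, u_m = 1, u_p = 3, u_mp = 4)
    for (i in seq_len(depth)) {
      total <- total + block(cin, ch[i])
      cin <- ch[i]
    }
  }
  for (i in seq_len(depth - 1)) {
    total <- total + up(ch[i + 1], ch[i]) + block(2 * ch[i], ch[i])
  }
  total + (ch[1] * 2 + 2)   # head
}

test_that("all variants obey the output shape and normalisation contracts", {
  for (var in c("u_m", "u_p", "u_mp", "amu_mp")) {
    spec <- net_spec(var, depth = 3, base_filters = 8)
    set.seed(1)
    m <- build_model(spec)
    nc <- length(mvmseg:::model_channels(spec))
    x <- array(rnorm(32 * 32 * nc * 2), c(32, 32, nc, 2))
    p <- forward(m, x)
    expect_identical(dim(p), c(32L, 32L, 2L, 2L))
    expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-5)
    expect_true(all(p >= 0 & p <= 1))
    # wrong channel count is a shape error
    expect_error(forward(m, array(0, c(32, 32, nc + 1, 1))), "channels")
    expect_error(forward(m, array(NaN, c(32, 32, nc, 1))),
                 class = "mvm_data_error")
  }
})

test_that("construction is deterministic and parameter counts match the hand tally", {
  for (var in c("u_m", "u_p", "u_mp", "amu_mp")) {
    spec <- net_spec(var, depth = 3, base_filters = 8)
    m1 <- build_model(spec)
    m2 <- build_model(spec)
    expect_identical(model_param_count(m1), model_param_count(m2))
    expect_identical(model_param_count(m1),
                     as.numeric(tally_params(var, 3, 8)))
  }
  expect_identical(model_param_count(build_model(net_spec("amu_mp", 4, 16))),
                   as.numeric(tally_params("amu_mp", 4, 16)))
})

test_that("skip connections have the documented widths at every depth", {
  m <- build_model(net_spec("amu_mp", depth = 4, base_filters = 8))
  sw <- model_skip_widths(m)
  expect_identical(sw$depth, 1:3)
  expect_identical(sw$skip_channels, c(8L, 16L, 32L))
})

test_that("inference is deterministic and batch-order equivariant", {
  spec <- net_spec("amu_mp", depth = 2, base_filters = 4)
  set.seed(3)
  m <- build_model(spec)
  x <- array(rnorm(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  p1 <- forward(m, x)
  p2 <- forward(m, x)
  expect_identical(p1, p2)
  perm <- c(3, 1, 2)
  p3 <- forward(m, x[, , , perm, drop = FALSE])
  expect_equal(p3, p1[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences of the loss", {
  withr::local_seed(8)
  for (var in c("u_mp", "amu_mp")) {
    spec <- net_spec(var, depth = 2, base_filters = 4)
    m <- build_model(spec)
    x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
    y <- array(sample(0:1, 8 * 8 * 2, TRUE), c(8, 8, 2))
    g <- mvmseg:::nn_grad(m$ptr, x, y)
    p0 <- mvmseg:::nn_get_params(m$ptr)
    # directional derivative along a random direction (robust to the
    # single-precision arithmetic of the engine)
    d <- rnorm(length(p0)); d <- d / sqrt(sum(d^2))
    eps <- 5e-3
    mvmseg:::nn_set_params(m$ptr, p0 + eps * d)
    lp <- mvmseg:::nn_loss(m$ptr, x, y)
    mvmseg:::nn_set_params(m$ptr, p0 - eps * d)
    lm <- mvmseg:::nn_loss(m$ptr, x, y)
    mvmseg:::nn_set_params(m$ptr, p0)
    expect_equal(sum(g * d), (lp - lm) / (2 * eps), tolerance = 0.05)
  }
})

test_that("the training loss is the mean per-pixel cross-entropy", {
  spec <- net_spec("u_mp", depth = 2, base_filters = 4)
  set.seed(5)
  m <- build_model(spec)
  x <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  y <- array(sample(0:1, 16 * 16 * 2, TRUE), c(16, 16, 2))
  loss <- mvmseg:::nn_loss(m$ptr, x, y)
  p <- forward(m, x, training = TRUE)
  ptrue <- ifelse(y == 1, p[, , 2, ], p[, , 1, ])
  expect_equal(loss, mean(-log(ptrue)), tolerance = 1e-5)
})

test_that("predict_mask takes the strict-majority class, ties to background", {
  ph <- phantom_tiny(seed = 35, n_slices = 1)
  spec <- net_spec("u_mp", depth = 2, base_filters = 4)
  set.seed(2)
  m <- build_model(spec)
  # zero weights: logits identical, myocardium probability exactly 0.5
  mvmseg:::nn_set_params(m$ptr, rep(0, model_param_count(m)))
  pm <- predict_mask(m, ph$slice[[1]])
  expect_identical(sum(pm$labels), 0L)
  expect_identical(pm$provenance, "model")
})

test_that("each variant consumes only its own channels", {
  ph <- phantom_tiny(seed = 36, n_slices = 1)
  sl <- ph$slice[[1]]
  scrambled_phase <- scrambled_mag <- sl
  set.seed(4)
  scrambled_phase$frames[, , , 2:4] <- rnorm(length(sl$frames[, , , 2:4]), 0, 5)
  scrambled_mag$frames[, , , 1] <- abs(rnorm(length(sl$frames[, , , 1]), 0.5, 0.2))
  m_mag <- build_model(net_spec("u_m", depth = 2, base_filters = 4))
  m_phs <- build_model(net_spec("u_p", depth = 2, base_filters = 4))
  # magnitude-only predictions ignore the phase channels and vice versa
  expect_identical(predict_mask(m_mag, sl)$labels,
                   predict_mask(m_mag, scrambled_phase)$labels)
  expect_identical(predict_mask(m_phs, sl)$labels,
                   predict_mask(m_phs, scrambled_mag)$labels)
})

test_that("phase-only networks learn rings that magnitude-only networks cannot see", {
  # featureless magnitude channel: the ring signal lives in the phase
  # channels only, and only at cardiac phases with appreciable velocity
  ph <- phantom_tiny(seed = 36, n_slices = 4, noise_sd = 0.25,
                     mag_contrast = FALSE)
  pool <- build_training_pool(ph[1:3, ], n_aug = 0, seed = 1)
  cfg <- train_config(epochs = 20, batch_size = 8, seed = 9)
  fit_m <- train_model(net_spec("u_m", depth = 2, base_filters = 8), pool, cfg)
  fit_p <- train_model(net_spec("u_p", depth = 2, base_filters = 8), pool, cfg)
  tc <- ph$truth_curves[[4]]
  fast <- which(vapply(seq_len(10), function(f) {
    max(abs(tc$velocity_cm_s[tc$frame == f]))
  }, numeric(1)) > 4)
  frame_dice <- function(fit) {
    pm <- predict_mask(fit$model, ph$slice[[4]])
    mean(vapply(fast, function(f) {
      dice(pm$labels[, , f], ph$mask[[4]]$labels[, , f])
    }, numeric(1)))
  }
  d_p <- frame_dice(fit_p)
  d_m <- frame_dice(fit_m)
  expect_gt(d_p, 0.8)       # the moving ring is visible in phase
  expect_lt(d_m, d_p - 0.1) # magnitude alone has at best a position prior
})
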