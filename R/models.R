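#' Segmentation network specification
#'
#' Describes one of the four myocardium segmentation networks:
#'
#' * `"u_m"` — standard U-Net on the single magnitude channel;
#' * `"u_p"` — standard U-Net on the three phase-velocity channels;
#' * `"u_mp"` — standard U-Net on all four stacked channels;
#' * `"amu_mp"` — the dual-encoder attention network: separate magnitude and
#'   phase encoders whose outputs are fused at every depth by a
#'   multi-channel attention block (MCAB: concatenate, an encoder-style
#'   convolution block, then an additive attention gate driven by the
#'   decoder feature of the level below) feeding a single standard decoder.
#'
#' Every network uses encoder blocks of two 3x3 convolutions with batch
#' normalisation and ReLU, 2x2 max-pooling, transposed-convolution
#' upsampling, and a final 1x1 convolution to two classes (background,
#' myocardium) with per-pixel softmax scores.
#'
#' @param variant One of `"u_m"`, `"u_p"`, `"u_mp"`, `"amu_mp"`.
#' @param depth Number of encoder levels (>= 2); the deepest level is the
#'   bottleneck.
#' @param base_filters Channel width of the first level (>= 4); width doubles
#'   per level.
#' @param velocity_bound_cm_s Fixed scale used to normalise the phase
#'   channels to roughly `[-1, 1]` (the magnitude channel is scaled by its
#'   per-slice maximum).
#' @return An object of class `mvm_net_spec`.
#' @export
net_spec <- function(variant = c("amu_mp", "u_m", "u_p", "u_mp"),
                     depth = 4L, base_filters = 16L,
                     velocity_bound_cm_s = 20) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  if (depth < 2L) config_error("depth must be >= 2")
  if (base_filters < 4L) config_error("base_filters must be >= 4")
  structure(list(variant = variant, depth = depth, base_filters = base_filters,
                 in_channels_mag = 1L, in_channels_phase = 3L, out_classes = 2L,
                 velocity_bound_cm_s = velocity_bound_cm_s),
            class = "mvm_net_spec")
}

#' @export
print.mvm_net_spec <- function(x, ...) {
  cat(sprintf("<mvm_net_spec %s: depth %d, base %d filters>\n",
              x$variant, x$depth, x$base_filters))
  invisible(x)
}

# Which of the 4 slice channels a variant consumes.
model_channels <- function(spec) {
  switch(spec$variant, u_m = 1L, u_p = 2:4, 1:4)
}

#' Build a segmentation model
#'
#' Instantiates the network described by a [net_spec()] and initialises its
#' weights (He initialisation for convolutions, unit gain / zero shift for
#' batch normalisation, zero biases) from the current R random number
#' stream, so construction is reproducible under [set.seed()].
#'
#' @param spec A [net_spec()].
#' @return An object of class `mvm_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "mvm_net_spec"))
  ptr <- nn_create(spec$variant, spec$depth, spec$base_filters)
  info <- nn_param_info(ptr)
  init <- lapply(seq_len(nrow(info)), function(i) {
    n <- info$nrow[i] * info$ncol[i]
    nm <- info$name[i]
    if (endsWith(nm, ".gamma")) rep(1, n)
    else if (endsWith(nm, ".beta") || endsWith(nm, ".b")) rep(0, n)
    else stats::rnorm(n) * sqrt(2 / info$fan_in[i])
  })
  nn_set_params(ptr, unlist(init))
  structure(list(ptr = ptr, spec = spec), class = "mvm_model")
}

#' @export
print.mvm_model <- function(x, ...) {
  cat(sprintf("<mvm_model %s: depth %d, base %d, %s parameters>\n",
              x$spec$variant, x$spec$depth, x$spec$base_filters,
              format(model_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model An `mvm_model`.
#' @return Numeric parameter count.
#' @export
model_param_count <- function(model) nn_param_count(model$ptr)

#' Skip-connection widths of a model
#'
#' Structural introspection: the channel width delivered to the decoder at
#' each depth (for the dual-encoder variant, the MCAB output width).
#'
#' @param model An `mvm_model`.
#' @return A tibble (`depth`, `skip_channels`).
#' @export
model_skip_widths <- function(model) {
  tibble::as_tibble(nn_skip_widths(model$ptr))
}

# Normalise a [H, W, 4(, N)] stack: magnitude by the per-slice maximum,
# phase channels by the fixed velocity bound; then keep the variant's
# channels.
normalize_input <- function(x, spec, mag_max) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x[, , 1, ] <- x[, , 1, ] / mag_max
  x[, , 2:4, ] <- x[, , 2:4, ] / spec$velocity_bound_cm_s
  x[, , model_channels(spec), , drop = FALSE]
}

#' Run a model forward to per-pixel class probabilities
#'
#' @param model An `mvm_model`.
#' @param frames A normalised, channel-selected input array `[H, W, C]` or
#'   `[H, W, C, N]` (see [predict_mask()] for the full pipeline from a cine
#'   slice).
#' @param training Logical; `FALSE` (default) uses batch-norm running
#'   statistics, making inference deterministic.
#' @return Probability array `[H, W, 2(, N)]`; the two class scores sum to 1
#'   at every pixel.
#' @export
forward <- function(model, frames, training = FALSE) {
  if (!all(is.finite(frames))) data_error("non-finite values in network input")
  x <- frames
  squeeze <- length(dim(x)) == 3L
  if (squeeze) x <- array(x, c(dim(x), 1L))
  p <- nn_forward(model$ptr, x, training)
  if (squeeze) p <- array(p, dim(p)[1:3])
  p
}

#' Predict a myocardium mask for a cine slice
#'
#' Normalises the slice, selects the channels consumed by the model variant,
#' runs inference frame by frame and takes the per-pixel argmax.  A pixel is
#' labelled myocardium only when its myocardium probability strictly exceeds
#' 0.5; exact ties go to background.
#'
#' @param model An `mvm_model`.
#' @param slice An [cine_slice()].
#' @param batch_frames Frames per inference batch.
#' @return An [myo_mask()] with provenance `"model"`.
#' @export
predict_mask <- function(model, slice, batch_frames = 16L) {
  stopifnot(inherits(model, "mvm_model"), inherits(slice, "mvm_cine_slice"))
  d <- dim(slice$frames)
  mag_max <- max(abs(slice$frames[, , , 1]), 1e-12)
  labels <- array(0L, d[1:3])
  for (start in seq(1L, d[3], by = batch_frames)) {
    idx <- start:min(start + batch_frames - 1L, d[3])
    x <- slice$frames[, , idx, , drop = FALSE]
    x <- aperm(x, c(1, 2, 4, 3))               # [H, W, C, N]
    x <- normalize_input(x, model$spec, mag_max)
    p <- forward(model, x, training = FALSE)
    if (length(dim(p)) == 3L) p <- array(p, c(dim(p), 1L))
    labels[, , idx] <- (p[, , 2, ] > 0.5) * 1L
  }
  myo_mask(labels, provenance = "model")
}

#' Save or load a model checkpoint
#'
#' The checkpoint is an RDS file holding the flattened parameters and
#' batch-norm state, accompanied by a JSON sidecar with the network
#' specification.
#'
#' @param model An `mvm_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = unclass(model$spec),
               params = nn_get_params(model$ptr),
               state = nn_get_state(model$ptr)),
          path)
  jsonlite::write_json(unclass(model$spec), sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  chk <- readRDS(path)
  spec <- do.call(net_spec, chk$spec[c("variant", "depth", "base_filters",
                                       "velocity_bound_cm_s")])
  ptr <- nn_create(spec$variant, spec$depth, spec$base_filters)
  nn_set_params(ptr, chk$params)
  nn_set_state(ptr, chk$state)
  structure(list(ptr = ptr, spec = spec), class = "mvm_model")
}
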