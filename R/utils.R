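# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort
config_error <- function(msg, ...) {
  abort(msg, class = c("mvm_config_error", "mvm_error"), ...)
}
data_error <- function(msg, ...) {
  abort(msg, class = c("mvm_data_error", "mvm_error"), ...)
}
format_error <- function(msg, field, ...) {
  abort(paste0(msg, " (field: ", field, ")"),
        class = c("mvm_format_error", "mvm_data_error", "mvm_error"),
        field = field, ...)
}
fit_error <- function(msg, ...) {
  abort(msg, class = c("mvm_fit_error", "mvm_error"), ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Circular (periodic) distance between phase fractions in [0, 1).
phase_dist <- function(t, c) {
  d <- abs(t - c) %% 1
  pmin(d, 1 - d)
}

# Column (x) and row (y) index grids for an H x W image.
pixel_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

is_binary_frame <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L, 0, 1))
}

as_mask_frame <- function(m) {
  if (!is_binary_frame(m)) data_error("mask frame must be a binary matrix")
  storage.mode(m) <- "integer"
  m
}

# Even-odd ray-casting point-in-polygon (polygon given as closed or open ring).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    hit <- cross & (px < xint)
    inside[hit] <- !inside[hit]
    j <- i
  }
  inside
}
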