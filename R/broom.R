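#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mvm_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n = x$n, method = x$method)
}

#' @exportS3Method generics::glance
glance.mvm_wilcoxon <- function(x, ...) tidy.mvm_wilcoxon(x)

#' @exportS3Method generics::tidy
tidy.mvm_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, icc_class = classify_icc(x$icc),
                 type = x$type, n = x$n,
                 ms_rows = x$ms_rows, ms_raters = x$ms_raters,
                 ms_error = x$ms_error)
}

#' @exportS3Method generics::tidy
tidy.mvm_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd_diff = x$sd_diff, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.mvm_ellipse <- function(x, ...) {
  tibble::tibble(center_x = x$center_xy[1], center_y = x$center_xy[2],
                 semi_major = x$semi_major, semi_minor = x$semi_minor,
                 angle = x$angle)
}

#' @exportS3Method generics::tidy
tidy.mvm_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.mvm_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$model$spec$variant,
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$mean_loss[nrow(x$history)] else NA_real_,
    n_frames = x$n_frames,
    n_params = model_param_count(x$model)
  )
}

#' @exportS3Method generics::tidy
tidy.mvm_cv <- function(x, level = "frame", ...) {
  dice_aggregate(cv_frame_table(x), level = level)
}

#' @exportS3Method generics::glance
glance.mvm_cv <- function(x, ...) {
  per_frame <- dice_aggregate(cv_frame_table(x), "frame")
  tibble::tibble(
    variant = x$spec$variant,
    n_slices = nrow(x$data),
    n_folds = length(x$fits),
    mean_frame_dice = mean(per_frame$dice),
    sd_frame_dice = stats::sd(per_frame$dice)
  )
}
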