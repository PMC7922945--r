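#' Dice similarity coefficient
#'
#' Overlap between two binary segmentations:
#' \deqn{DSC(A, B) = 2|A \cap B| / (|A| + |B|).}
#' Two empty masks agree perfectly on absence and score 1; an empty versus a
#' non-empty mask scores 0 by the formula.
#'
#' @param mask_a,mask_b Binary arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    data_error("masks must have identical shape")
  }
  a <- sum(mask_a == 1)
  b <- sum(mask_b == 1)
  if (a + b == 0) return(1.0)
  2 * sum(mask_a == 1 & mask_b == 1) / (a + b)
}

#' Dice scores at frame, slice or subject level
#'
#' Frame level scores every frame separately; slice level pools the voxel
#' counts of all frames of a slice (Dice on the voxel union); subject level
#' pools all slices of a subject.
#'
#' @param data A tibble with columns `subject_id`, `slice_id`, `frame` and
#'   list columns `pred`, `truth` holding binary mask frames.
#' @param level `"frame"`, `"slice"` or `"subject"`.
#' @return A tibble (`level`, `id`, `dice`).
#' @export
dice_aggregate <- function(data, level = c("frame", "slice", "subject")) {
  level <- tryCatch(match.arg(level),
                    error = function(e) config_error(
                      paste0("unknown aggregation level: ",
                             paste(level, collapse = "/"))))
  counts <- data |>
    dplyr::mutate(
      inter = purrr::map2_dbl(.data$pred, .data$truth,
                              ~ sum(.x == 1 & .y == 1)),
      n_pred = purrr::map_dbl(.data$pred, ~ sum(.x == 1)),
      n_truth = purrr::map_dbl(.data$truth, ~ sum(.x == 1))
    )
  key <- switch(level,
                frame = c("subject_id", "slice_id", "frame"),
                slice = c("subject_id", "slice_id"),
                subject = "subject_id")
  pooled <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(inter = sum(.data$inter), n_pred = sum(.data$n_pred),
                     n_truth = sum(.data$n_truth), .groups = "drop")
  pooled |>
    dplyr::mutate(
      level = level,
      id = do.call(paste, c(lapply(unclass(pooled[key]), as.character),
                            sep = "/")),
      dice = ifelse(.data$n_pred + .data$n_truth == 0, 1,
                    2 * .data$inter / (.data$n_pred + .data$n_truth))
    ) |>
    dplyr::select("level", "id", "dice")
}

#' Frame table of a cross-validation result
#'
#' Expands an [cross_validate()] result into the per-frame prediction/truth
#' table consumed by [dice_aggregate()].
#'
#' @param cv An `mvm_cv` object.
#' @return A tibble (`subject_id`, `slice_id`, `frame`, `pred`, `truth`).
#' @export
cv_frame_table <- function(cv) {
  stopifnot(inherits(cv, "mvm_cv"))
  purrr::pmap_dfr(
    list(cv$data$subject_id, cv$data$slice_id, cv$data$pred, cv$data$mask),
    function(subj, sid, pred, truth) {
      nf <- dim(truth$labels)[3]
      tibble::tibble(
        subject_id = subj, slice_id = sid, frame = seq_len(nf),
        pred = lapply(seq_len(nf), function(f) pred$labels[, , f]),
        truth = lapply(seq_len(nf), function(f) truth$labels[, , f])
      )
    })
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired signed-rank test.  Zero differences are discarded
#' (Wilcoxon convention); for n <= 15 effective pairs the exact conditional
#' null distribution of the positive-rank sum is enumerated (ties handled by
#' mid-ranks), above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Equal-length paired measurement vectors.
#' @param exact_max Largest n for which the exact distribution is enumerated.
#' @return An object of class `mvm_wilcoxon`: `statistic` (positive-rank
#'   sum), `p_value`, `n` (pairs after zero removal), `method`, and
#'   `undefined` (`TRUE` when all differences are zero, in which case the
#'   p value is `NA`).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 15L) {
  if (length(x) != length(y)) data_error("paired samples must have equal length")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                          method = "undefined", undefined = TRUE),
                     class = "mvm_wilcoxon"))
  }
  if (n < 5L) data_error("need at least 5 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))      # doubled ranks are integers with ties
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(tot + 1 - rr)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * W))
    lower <- sum(f[seq_len(w2 + 1)])
    upper <- sum(f[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = W, p_value = p, n = n, method = method,
                 undefined = FALSE),
            class = "mvm_wilcoxon")
}

#' @export
print.mvm_wilcoxon <- function(x, ...) {
  if (x$undefined) {
    cat("<mvm_wilcoxon: undefined (all differences zero)>\n")
  } else {
    cat(sprintf("<mvm_wilcoxon: W+ = %g, n = %d, p = %.4g (%s)>\n",
                x$statistic, x$n, x$p_value, x$method))
  }
  invisible(x)
}

#' Intraclass correlation coefficient, two-way mixed, single score
#'
#' Computes the single-score ICC of a two-way mixed model from the ANOVA
#' mean squares.  The default consistency form is
#' \deqn{ICC(3,1) = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)}
#' with k = 2 raters, which ignores a fixed offset between raters; the
#' absolute-agreement form (ICC(2,1)-style, adding the rater mean square)
#' is available via `type = "agreement"`.
#'
#' @param x,y Paired measurements from the two raters/sources.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return An object of class `mvm_icc`: `icc`, `type`, `n`, mean squares,
#'   and `undefined` (`TRUE` when the table has no variance at all).
#' @export
icc_single_score <- function(x, y, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) data_error("need at least 3 paired observations for ICC")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  sub_means <- rowMeans(dat)
  rat_means <- colMeans(dat)
  ss_total <- sum((dat - grand)^2)
  ss_rows <- k * sum((sub_means - grand)^2)
  ss_cols <- n * sum((rat_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- if (type == "consistency") {
    msr + (k - 1) * mse
  } else {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  }
  undefined <- !is.finite(denom) || denom <= 0 || msr == 0
  icc <- if (undefined) NA_real_ else (msr - mse) / denom
  structure(list(icc = icc, type = type, n = n, ms_rows = msr,
                 ms_raters = msc, ms_error = mse, undefined = undefined),
            class = "mvm_icc")
}

#' @export
print.mvm_icc <- function(x, ...) {
  cat(sprintf("<mvm_icc (%s): %s, n = %d>\n", x$type,
              if (x$undefined) "undefined" else sprintf("%.4f", x$icc), x$n))
  invisible(x)
}

#' Classify an ICC value
#'
#' Bands: excellent (> 0.75), good (0.6, 0.75], fair \[0.4, 0.6\], poor
#' (< 0.4).  The published bands leave exactly 0.4 unassigned; it is placed
#' in "fair" here.
#'
#' @param value Numeric ICC value(s).
#' @return Character vector of categories (`NA` input gives `NA`).
#' @export
classify_icc <- function(value) {
  out <- rep(NA_character_, length(value))
  out[which(value > 0.75)] <- "excellent"
  out[which(value > 0.6 & value <= 0.75)] <- "good"
  out[which(value >= 0.4 & value <= 0.6)] <- "fair"
  out[which(value < 0.4)] <- "poor"
  out
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference `y - x`) and 95% limits of agreement
#' `bias +/- 1.96 * SD` of the differences (sample SD, n - 1 denominator).
#'
#' @param x,y Paired measurements (n >= 2).
#' @return An object of class `mvm_bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and the per-pair `means`/`diffs` used by
#'   the plot method.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) data_error("Bland-Altman needs at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d),
                 means = (x + y) / 2, diffs = d),
            class = "mvm_bland_altman")
}

#' @export
print.mvm_bland_altman <- function(x, ...) {
  cat(sprintf("<mvm_bland_altman: bias %.4g, LoA [%.4g, %.4g], n = %d>\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Agreement report between two sources of a marker
#'
#' Combines the ICC (with its classification band) and the Bland-Altman
#' statistics for one peak-velocity marker measured by two sources (e.g.
#' manual versus automated segmentation).
#'
#' @param x,y Paired marker values from the two sources.
#' @param icc_type Passed to [icc_single_score()].
#' @return A one-row tibble: `n`, `icc`, `icc_class`, `bias`, `loa_low`,
#'   `loa_high`.
#' @export
agreement_report <- function(x, y, icc_type = "consistency") {
  icc <- icc_single_score(x, y, type = icc_type)
  ba <- bland_altman(x, y)
  icc_value <- icc$icc
  tibble::tibble(n = ba$n, icc = icc_value,
                 icc_class = classify_icc(icc_value),
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high)
}
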