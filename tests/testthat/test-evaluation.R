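test_that("Dice handles the canonical cases and empty-mask conventions", {
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L          # |A| = 4
  b <- matrix(0L, 8, 8); b[3:4, 2:3] <- 1L          # |B| = 4, overlap 2
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, matrix(0L, 8, 8)), 0)
  expect_identical(dice(matrix(0L, 8, 8), matrix(0L, 8, 8)), 1)
  expect_identical(dice(a, b), 0.5)
  expect_identical(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(0L, 4, 4)), class = "mvm_data_error")
})

test_that("Dice matches brute-force pixel counting on random masks", {
  withr::local_seed(20)
  for (i in 1:100) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    inter <- 0
    for (p in 1:64) inter <- inter + (a[p] == 1 && b[p] == 1)
    expected <- if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b))
    expect_identical(dice(a, b), expected)
  }
})

test_that("growing the intersection at fixed total size never decreases Dice", {
  a <- matrix(0L, 10, 10); a[1:5, 1:5] <- 1L
  scores <- sapply(0:5, function(shift) {
    b <- matrix(0L, 10, 10); b[1:5, (1 + shift):(5 + shift)] <- 1L
    dice(a, b)
  })
  expect_true(all(diff(rev(scores)) >= 0))
})

test_that("aggregated Dice pools voxel counts at slice and subject level", {
  f1 <- matrix(0L, 6, 6); f1[2:4, 2:4] <- 1L
  data <- tibble::tibble(
    subject_id = "s1", slice_id = c("a", "a"), frame = c(1L, 2L),
    pred = list(f1, matrix(0L, 6, 6)),
    truth = list(f1, f1))
  # frame scores: 1 and 0; pooled slice score from raw counts:
  # 2 * 9 / (9 + 18) = 2/3
  fr <- dice_aggregate(data, "frame")
  expect_equal(sort(fr$dice), c(0, 1))
  sl <- dice_aggregate(data, "slice")
  expect_equal(sl$dice, 2 / 3)
  # a subject made of identical slices scores the same as one slice
  data2 <- dplyr::mutate(data, slice_id = c("a", "b"), frame = 1L,
                         pred = list(f1, f1), truth = list(f1, f1))
  expect_equal(dice_aggregate(data2, "subject")$dice, 1)
  # single-frame slices: slice score equals frame score
  expect_equal(dice_aggregate(data[1, ], "slice")$dice,
               dice_aggregate(data[1, ], "frame")$dice)
  expect_error(dice_aggregate(data, "voxel"), class = "mvm_config_error")
})

test_that("the signed-rank test matches exact enumeration and R's reference", {
  x <- 1:10
  w <- wilcoxon_signed_rank(x, x + 3)
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_equal(w$statistic, 55)
  # all-zero differences are undefined, not an error
  u <- wilcoxon_signed_rank(x, x)
  expect_true(u$undefined)
  expect_true(is.na(u$p_value))
  # two-sided p is symmetric in the sample order
  withr::local_seed(21)
  for (i in 1:25) {
    a <- rnorm(12); b <- a + rnorm(12, 0.3)
    p1 <- wilcoxon_signed_rank(a, b)$p_value
    p2 <- wilcoxon_signed_rank(b, a)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
    # untied exact case agrees with the reference implementation
    expect_equal(p1, stats::wilcox.test(b, a, paired = TRUE,
                                        exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("the exact signed-rank null handles ties via full sign enumeration", {
  withr::local_seed(22)
  for (i in 1:20) {
    d <- sample(c(-3:-1, 1:3), 9, replace = TRUE)   # heavy ties
    x <- rep(0, 9); y <- d
    got <- wilcoxon_signed_rank(x, y)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    # enumerate all 2^9 sign assignments of the tied rank vector
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 9)))
    Ws <- signs %*% r
    p_exact <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
    expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  }
})

test_that("the large-sample signed-rank path matches the corrected normal", {
  withr::local_seed(23)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.2)
  got <- wilcoxon_signed_rank(x, y)
  expect_identical(got$method, "normal")
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-9)
})

test_that("ICC(3,1) has its defining invariances and matches the ANOVA oracle", {
  x <- c(9, 7, 5, 10, 6, 8)
  expect_equal(icc_single_score(x, x)$icc, 1)
  expect_equal(icc_single_score(x, x + 2.5)$icc, 1)   # consistency form
  # independent oracle from aov() mean squares on 100 random tables
  withr::local_seed(24)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- rnorm(n, 10, 3)
    b <- a + rnorm(n, 0, runif(1, 0.1, 3))
    got <- icc_single_score(a, b)$icc
    df <- data.frame(y = c(a, b),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][, "Mean Sq"]
    oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  # degenerate table is undefined
  expect_true(icc_single_score(rep(1, 5), rep(1, 5))$undefined)
})

test_that("ICC classification bands follow the published thresholds", {
  expect_identical(classify_icc(0.76), "excellent")
  expect_identical(classify_icc(0.75), "good")
  expect_identical(classify_icc(0.61), "good")
  expect_identical(classify_icc(0.6), "fair")
  expect_identical(classify_icc(0.4), "fair")          # boundary closed here
  expect_identical(classify_icc(0.39), "poor")
  expect_identical(classify_icc(c(0.9, NA, 0.1)),
                   c("excellent", NA, "poor"))
})

test_that("Bland-Altman bias and limits follow the direct formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(unlist(tidy(bland_altman(x, x))[, 1:3]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  ba3 <- bland_altman(x, x + 3)
  expect_equal(c(ba3$bias, ba3$loa_low, ba3$loa_high), c(3, 3, 3))
  withr::local_seed(25)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1))
    b <- a + rnorm(length(a), 0.5, 0.8)
    ba <- bland_altman(a, b)
    d <- b - a
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    expect_lte(ba$loa_low, ba$bias)
    expect_gte(ba$loa_high, ba$bias)
  }
  expect_error(bland_altman(1, 2), class = "mvm_data_error")
})

test_that("agreement reports combine ICC classification with Bland-Altman", {
  withr::local_seed(26)
  a <- rnorm(12, 8, 2)
  b <- a + rnorm(12, 0, 0.2)
  rep <- agreement_report(a, b)
  expect_identical(rep$icc_class, classify_icc(rep$icc))
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
})
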