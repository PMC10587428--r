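test_that("paired comparison handles identical, shifted, and real data", {
  a <- c(1, 2, 3, 4, 5)
  r <- paired_compare(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  # constant non-zero shift: zero variance in differences, flagged
  r2 <- paired_compare(a + 2, a)
  expect_true(r2$degenerate)
  expect_equal(r2$mean_diff, 2)
  set.seed(8)
  x <- rnorm(10); y <- x + rnorm(10, 0.5, 0.3)
  rt <- paired_compare(x, y, "t")
  expect_equal(rt$p_value, t.test(x, y, paired = TRUE)$p.value)
  rw <- paired_compare(x, y, "wilcoxon")
  expect_lt(rw$p_value, 0.05)
  expect_error(paired_compare(1:4, 1:5), "equal length")
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
})

test_that("paired t-test maintains its nominal type-I error at n = 10", {
  set.seed(2026)
  reject <- vapply(seq_len(2000), function(i) {
    a <- rnorm(10); b <- rnorm(10)
    paired_compare(a, b, "t")$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("Pearson correlation equals the covariance-formula oracle", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(10); b <- 0.4 * a + rnorm(10)
    r <- correlate(a, b)
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_lt(abs(r$r - oracle), 1e-12)
    expect_equal(r$r2, r$r^2)
  }
  expect_equal(correlate(1:5, 2 * (1:5))$r, 1)
  b <- -(1:10) + rnorm(10, 0, 0.1)
  expect_lt(correlate(1:10, b)$r, 0)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("null correlations average to zero over replicates", {
  set.seed(77)
  rs <- vapply(seq_len(1000), function(i)
    correlate(rnorm(10), rnorm(10))$r, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(1000))
})

test_that("repeated-measures ANOVA with Tukey behaves on simple designs", {
  subj <- rep(sprintf("S%02d", 1:10), each = 3)
  cond <- rep(c("A", "B", "C"), times = 10)
  set.seed(12)
  base <- rnorm(10)
  # identical conditions: F ~ 0, nothing significant
  d0 <- data.frame(subject = subj, condition = cond,
                   value = rep(base, each = 3))
  r0 <- rm_anova_tukey(d0)
  expect_lt(r0$F, 1e-20)
  expect_true(all(r0$tukey$p_adj > 0.9))
  # one condition shifted by ~10 SD: its comparisons significant
  d1 <- d0
  d1$value <- d1$value + rnorm(30, 0, 0.2) +
    ifelse(d1$condition == "C", 10 * 0.2, 0)
  r1 <- rm_anova_tukey(d1)
  sigc <- grepl("C", r1$tukey$comparison)
  expect_true(all(r1$tukey$p_adj[sigc] < 0.001))
  expect_error(rm_anova_tukey(d1[-1, ]), "incomplete")
})

test_that("repeated-measures ANOVA p-value agrees with a permutation
          oracle", {
  set.seed(99)
  n <- 10
  subj <- rep(sprintf("S%02d", 1:n), each = 3)
  cond <- rep(c("A", "B", "C"), times = n)
  value <- rnorm(3 * n) + rep(rnorm(n), each = 3) +
    ifelse(cond == "B", 0.8, 0)
  d <- data.frame(subject = subj, condition = cond, value = value)
  r <- rm_anova_tukey(d)
  # permutation oracle: F statistic recomputed from sums of squares with
  # condition labels shuffled within subject
  f_stat <- function(v) {
    m <- matrix(v, nrow = 3)           # conditions x subjects
    grand <- mean(m)
    ss_cond <- n * sum((rowMeans(m) - grand)^2)
    ss_subj <- 3 * sum((colMeans(m) - grand)^2)
    ss_tot <- sum((m - grand)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    (ss_cond / 2) / (ss_err / (2 * (n - 1)))
  }
  obs <- f_stat(value)
  expect_equal(obs, r$F, tolerance = 1e-8)
  perm <- replicate(2000, {
    v <- as.vector(apply(matrix(value, nrow = 3), 2, sample))
    f_stat(v)
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - r$p_value),
            0.02 + 3 * sqrt(r$p_value * (1 - r$p_value) / 2000))
})

test_that("fold summaries report both conventions", {
  x <- c(2, 4, 6); ref <- c(1, 2, 3)
  fsu <- fold_summary(x, ref)
  expect_equal(fsu$mean_of_ratios, 2)
  expect_equal(fsu$ratio_of_means, 2)
  expect_equal(fsu$sd_of_ratios, 0)
  # identical subjects: both conventions equal
  expect_equal(fold_summary(ref, ref)$mean_of_ratios, 1)
  # skewed ratios: conventions differ
  x2 <- c(1, 10); r2 <- c(1, 2)
  f2 <- fold_summary(x2, r2)
  expect_false(isTRUE(all.equal(f2$mean_of_ratios, f2$ratio_of_means)))
  expect_error(fold_summary(1:3, c(1, 0, 2)), "> 0")
})

test_that("summary table aggregates, marks significance, and matches a
          re-aggregation oracle", {
  set.seed(21)
  n <- 10
  metrics <- rbind(
    data.frame(subject_id = sprintf("S%02d", 1:n), tracer = "acac",
               region = "myocardium", metric = "k2",
               value = rnorm(n, 0.063, 0.02)),
    data.frame(subject_id = sprintf("S%02d", 1:n), tracer = "ac",
               region = "myocardium", metric = "k2",
               value = rnorm(n, 0.081, 0.02)))
  st <- build_summary_table(metrics)
  expect_s3_class(st, "summary_table")
  for (tr in c("acac", "ac")) {
    sel <- metrics$value[metrics$tracer == tr]
    row <- st[st$tracer == tr, ]
    expect_equal(row$mean, mean(sel))
    expect_equal(row$sd, sd(sel))
    expect_equal(row$n, n)
  }
  # marker backed by the stored paired test
  pref <- paired_compare(metrics$value[metrics$tracer == "acac"],
                         metrics$value[metrics$tracer == "ac"])
  expect_equal(st$p_vs_ref[st$tracer == "acac"], pref$p_value)
  expect_equal(st$marker[st$tracer == "acac"],
               significance_marker(pref$p_value))
  expect_equal(st$marker[st$tracer == "ac"], "")
  # single subject: SD empty, no tests
  st1 <- build_summary_table(metrics[metrics$subject_id == "S01", ])
  expect_true(is.na(st1$sd[1]))
  expect_true(all(is.na(st1$p_vs_ref)))
  # missing reference arm rejected
  expect_error(build_summary_table(metrics[metrics$tracer == "acac", ]),
               "reference tracer")
})

test_that("significance markers follow the conventional tiers", {
  expect_equal(significance_marker(c(0.0005, 0.005, 0.05, 0.2, NA)),
               c("***", "**", "*", "", ""))
})
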