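test_that("weighted mean perfusion uses duration weights", {
  s30a <- ldf_trace(seq(0, 29.9, 0.1), rep(10, 300))
  s30b <- ldf_trace(seq(0, 29.9, 0.1), rep(20, 300))
  expect_equal(weighted_mean_perfusion(list(s30a, s30b))$mean_pu, 15)
  s60 <- ldf_trace(seq(0, 59.9, 0.1), rep(19, 600))
  expect_equal(weighted_mean_perfusion(list(s30a, s60))$mean_pu, 16)
  one <- weighted_mean_perfusion(list(s30a))
  expect_equal(one$mean_pu, 10)
  expect_equal(one$n_segments, 1L)
  # empty segments are dropped with a warning; all-empty errors
  empty <- ldf_trace(1:5, rep(NA_real_, 5))
  expect_warning(r <- weighted_mean_perfusion(list(s30a, empty)), "excluded")
  expect_equal(r$mean_pu, 10)
  expect_error(suppressWarnings(weighted_mean_perfusion(list(empty))),
               "all segments")
  # equal durations reduce to the arithmetic mean
  expect_equal(weighted_mean_perfusion(list(s30a, s30b))$mean_pu,
               mean(c(10, 20)))
})

test_that("trace slopes are OLS in PU per minute", {
  flat <- ldf_trace(0:100, rep(7, 101))
  expect_equal(trace_slope(flat)$slope_pu_per_min, 0)
  ramp <- ldf_trace(seq(0, 1800, 10), 10 + seq(0, 1800, 10) / 60)
  expect_equal(trace_slope(ramp)$slope_pu_per_min, 1)
  expect_error(trace_slope(ldf_trace(1:2, 1:2)), "3 samples")
  # scale equivariance
  tr <- generate_ldf_trace(600, 4, 20, -0.3, 0.5, seed = 11)
  s1 <- trace_slope(tr)
  tr2 <- tr; tr2$perfusion_pu <- tr2$perfusion_pu * 4
  expect_equal(trace_slope(tr2)$slope_pu_per_min, 4 * s1$slope_pu_per_min)
})

test_that("signed-rank p values equal exhaustive enumeration for n <= 10", {
  # independent oracle: literal sign-flip enumeration written here
  enum_p <- function(x) {
    x <- x[x != 0]
    r <- rank(abs(x))
    v <- sum(r[x > 0])
    n <- length(x)
    vs <- sapply(0:(2^n - 1), function(mask)
      sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]))
    min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
  }
  set.seed(23)
  for (n in c(4, 6, 8, 10)) {
    x <- round(rnorm(n, 0.4), 3)
    got <- slope_stability_test(x, "signed_rank")
    expect_equal(got$p_value, enum_p(x))
    # tie-free samples also match the exact distribution in wilcox.test
    w <- suppressWarnings(wilcox.test(x, mu = 0, exact = TRUE))
    expect_equal(got$p_value, w$p.value)
  }
})

test_that("degenerate slope samples are handled by convention", {
  expect_equal(slope_stability_test(rep(0, 6), "signed_rank")$p_value, 1)
  expect_error(slope_stability_test(rep(1, 4), "t"), "zero variance")
  expect_error(slope_stability_test(1, "t"), "at least 2")
  # the one-sample t path agrees with stats::t.test
  set.seed(31)
  x <- rnorm(9, 0.2)
  expect_equal(slope_stability_test(x, "t")$p_value,
               t.test(x, mu = 0)$p.value)
})

test_that("group summaries match an independent aggregation oracle", {
  set.seed(41)
  rec <- data.frame(
    surgery = rep(c("sham", "stroke"), each = 8),
    limb = rep(c("affected", "unaffected"), 8),
    week = rep(1:2, each = 4),
    mean_pu = rnorm(16, 10, 2))
  g <- group_summary(rec, c("surgery", "limb", "week"))
  for (i in seq_len(nrow(g))) {
    sel <- rec$surgery == g$surgery[i] & rec$limb == g$limb[i] &
      rec$week == g$week[i]
    if (g$n[i] > 0) {
      expect_equal(g$mean_pu[i], mean(rec$mean_pu[sel]))
      expect_equal(g$sd_pu[i], sd(rec$mean_pu[sel]))
    }
  }
  # an absent cell is flagged missing, not zero
  rec2 <- rec[!(rec$surgery == "stroke" & rec$week == 2), ]
  g2 <- group_summary(rec2, c("surgery", "week"))
  miss <- g2[g2$surgery == "stroke" & g2$week == 2, ]
  expect_equal(miss$n, 0)
  expect_true(is.na(miss$mean_pu))
})

test_that("percent differences follow the reference convention", {
  expect_equal(percent_difference(7.7, 10), -23)
  expect_equal(percent_difference(5, 5), 0)
})
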