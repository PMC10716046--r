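test_that("DIP calling applies the strict majority rule", {
  yc <- rbind(p1 = c(1.5, 1.2, 0.4))
  yr <- rbind(p1 = c(2, 3, 5))
  expect_true(call_dips(yc, yr)[["p1"]])  # 2 of 3 qualify, 2 > 1.5

  # exactly 1 TPM never qualifies (strict >)
  yc2 <- rbind(p = c(1, 1, 1)); yr2 <- rbind(p = c(5, 5, 5))
  expect_false(call_dips(yc2, yr2)[["p"]])

  # single qualifying sample with n = 1 is a DIP
  expect_true(call_dips(rbind(p = 2), rbind(p = 2))[["p"]])

  # absolute majority override
  expect_false(call_dips(yc, yr, majority_n = 3)[["p1"]])
})

test_that("DIP calling matches the per-row brute-force oracle", {
  for (seed in 1:20) {
    set.seed(300 + seed)
    n <- sample(5:60, 1); s <- sample(1:8, 1)
    yc <- matrix(rexp(n * s, 1 / 2), n, s,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:s)))
    yr <- matrix(rexp(n * s, 1 / 2), n, s, dimnames = dimnames(yc))
    p <- dip_params(min_class_tpm = 1, majority_fraction = 0.5)
    expect_equal(unname(call_dips(yc, yr, p)),
                 oracle_call_dips(yc, yr, 1, 0.5))
  }
})

test_that("ratios normalize to unit mean per promoter", {
  yc <- rbind(g1 = c(4, 1), g2 = c(3, 3))
  yr <- rbind(g1 = c(2, 2), g2 = c(3, 3))
  rr <- yc_yr_ratio(yc, yr, eps = 0)
  expect_equal(unname(rr$r["g2", ]), c(1, 1))        # YC = YR -> r = 1
  expect_equal(unname(rr$r_norm["g1", ]), c(1.6, 0.4))  # r (2, .5), mean 1.25
  expect_equal(unname(rowMeans(rr$r_norm)), c(1, 1), tolerance = 1e-12)
  # pseudocount keeps ratios finite
  rr2 <- yc_yr_ratio(rbind(g = 10), rbind(g = 0), eps = 0.01)
  expect_true(is.finite(rr2$r))
  expect_gt(rr2$r, 100)
})

test_that("paired ratio test handles signal, degeneracy and tiny n", {
  # constant nonzero shift: degenerate, p = 0
  r <- cbind(a = rep(2, 5), b = rep(1, 5))
  rownames(r) <- paste0("g", 1:5)
  pr <- paired_ratio_test(r, data.frame(condition = "a", reference = "b"))
  expect_true(pr$degenerate)
  expect_equal(pr$p, 0)
  expect_equal(pr$mean_log2fc, 1)

  # strong consistent shift with tiny noise
  set.seed(4)
  ra <- 2^(1 + rnorm(20, 0, 0.01)); rb <- rep(1, 20)
  r2 <- cbind(a = ra, b = rb); rownames(r2) <- paste0("g", 1:20)
  pr2 <- paired_ratio_test(r2, data.frame(condition = "a", reference = "b"))
  expect_lt(pr2$p, 0.001)
  expect_equal(pr2$mean_log2fc, 1, tolerance = 0.05)

  # fewer than 3 promoters: warning, mean reported, no test
  r3 <- cbind(a = c(2, 4), b = c(1, 1)); rownames(r3) <- c("g1", "g2")
  expect_warning(pr3 <- paired_ratio_test(r3, data.frame(condition = "a",
                                                         reference = "b")),
                 "skipped")
  expect_true(is.na(pr3$p))
  expect_equal(pr3$mean_log2fc, 1.5)
})

test_that("paired ratio test is calibrated under the null", {
  set.seed(77)
  ps <- replicate(200, {
    r <- cbind(a = 2^rnorm(40), b = 2^rnorm(40))
    rownames(r) <- paste0("g", 1:40)
    paired_ratio_test(r, data.frame(condition = "a", reference = "b"))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("class-total chi-squared matches the textbook 2x2 formula", {
  # identical class proportions: statistic 0, p 1
  yc <- rbind(g = c(a1 = 30, b1 = 60)); yr <- rbind(g = c(a1 = 70, b1 = 140))
  eq <- class_total_chisq(yc, yr, "a1", "b1")
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)

  yc2 <- rbind(g = c(a1 = 300, b1 = 150))
  yr2 <- rbind(g = c(a1 = 700, b1 = 850))
  got <- class_total_chisq(yc2, yr2, "a1", "b1")
  o <- c(300, 700, 150, 850); n <- sum(o)
  e <- c(450 * 1000, 1550 * 1000, 450 * 1000, 1550 * 1000) / n
  expect_equal(got$statistic, sum((o - e)^2 / e), tolerance = 1e-9)
  expect_equal(got$odds_ratio, (300 * 850) / (700 * 150))
  expect_error(class_total_chisq(yc2, yr2, character(0), "b1"), "empty")
})

test_that("trajectory selection requires strict monotonicity in cohort order", {
  cohorts <- c(e1 = "enr", e2 = "enr", n1 = "neu", n2 = "neu",
               d1 = "dep", d2 = "dep")
  mk <- function(means) {
    r <- matrix(rep(rep(means, each = 2), each = 1), nrow = 1)
    colnames(r) <- names(cohorts); rownames(r) <- "g1"
    r
  }
  sel <- trajectory_select(mk(c(2, 1, 0.5)), cohorts, c("enr", "neu", "dep"))
  expect_equal(sel$selected, "g1")
  sel2 <- trajectory_select(mk(c(2, 0.4, 0.5)), cohorts, c("enr", "neu", "dep"))
  expect_length(sel2$selected, 0L)
  expect_error(trajectory_select(mk(c(2, 1, 0.5)), cohorts,
                                 c("enr", "neu", "missing")), "zero samples")
})

test_that("null trajectory selection rate is about 1/6 for three cohorts", {
  set.seed(12)
  cohorts <- stats::setNames(rep(c("a", "b", "c"), each = 2),
                             paste0("s", 1:6))
  r <- matrix(2^rnorm(3000 * 6), 3000, 6,
              dimnames = list(paste0("g", 1:3000), names(cohorts)))
  sel <- trajectory_select(r, cohorts, c("a", "b", "c"))
  rate <- length(sel$selected) / 3000
  ci <- 2.58 * sqrt(1 / 6 * 5 / 6 / 3000)
  expect_lt(abs(rate - 1 / 6), ci + 1e-9)
})

test_that("treatment-delta trajectory metric uses pairs", {
  cohorts <- c(a_t = "a", b_t = "b")
  r <- cbind(a_c = c(g1 = 1), a_t = 4, b_c = 1, b_t = 2)
  sel <- trajectory_select(r, cohorts, c("a", "b"), metric = "delta",
                          pairs = data.frame(condition = c("a_t", "b_t"),
                                             reference = c("a_c", "b_c")))
  expect_equal(sel$selected, "g1")
  expect_equal(unname(sel$cohort_means["g1", ]), c(2, 1))
})

test_that("set intersections enumerate exact Venn regions", {
  out <- intersect_sets(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(unname(out$intersection_counts["A&B"]), 1L)
  expect_equal(out$intersections[["A&B"]], "Y")

  disj <- intersect_sets(list(A = "a", B = "b", C = "c"))
  expect_true(all(disj$intersection_counts == 0))

  three <- intersect_sets(list(P = c("g1", "g2", "g3"),
                               Q = c("g2", "g3", "g4"),
                               R = c("g3", "g5")))
  expect_equal(unname(three$intersection_counts[c("P&Q", "P&Q&R")]), c(2L, 1L))
  expect_equal(unname(three$region_counts[["P&Q"]]), 1L)  # g2 exclusively P&Q
  # case normalization
  expect_equal(unname(intersect_sets(list(A = "abc", B = "ABC")
                                     )$intersection_counts[["A&B"]]), 1L)
})

test_that("qPCR subtraction clips negatives and flags inconsistency", {
  x <- qpcr_yc_estimate(10, 4)
  expect_equal(x$yc, 6)
  expect_equal(x$ratio, 1.5)
  expect_equal(qpcr_yc_estimate(4, 4)$yc, 0)
  y <- qpcr_yc_estimate(3.9, 4.2, tolerance = 0.05)
  expect_equal(y$yc, 0)
  expect_true(y$flag_inconsistent)
  expect_false(qpcr_yc_estimate(3.9, 4, tolerance = 0.05)$flag_inconsistent)
})

test_that("doubling time follows the seeded-growth closed form", {
  expect_equal(doubling_time(4, 100000), 4)
  expect_equal(doubling_time(9, 400000), 3)
  expect_error(doubling_time(4, 50000), "no growth")
})

test_that("relative survival propagates replicate error", {
  expect_equal(relative_survival(c(5, 5, 5), c(100, 100, 100))$fraction, 0.05)
  same <- relative_survival(c(7, 7), c(7, 7))
  expect_equal(same$fraction, 1)
  one <- relative_survival(5, c(10, 10))
  expect_true(one$flag_single_replicate)
  expect_true(is.na(one$se))
  expect_error(relative_survival(5, 0), "positive")
})

test_that("ratio frequency table uses fixed log2 bins over [-5, 5]", {
  ft <- ratio_freq_table(c(1, 2, 0.5, 1000, 1e-4))
  expect_equal(nrow(ft), 32L)
  expect_equal(sum(ft$count), 5L)
  expect_equal(ft$count[1], 1L)   # clamped low outlier
  expect_equal(ft$count[32], 1L)  # clamped high outlier
})
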