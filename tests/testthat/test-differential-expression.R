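# Fold changes, the moderated t and its limiting forms, BH adjustment,
# the DE rule and its monotonicity, constitutive calls, and time-course
# summaries.

test_that("fold changes are differences of day-mean log2 values", {
  expr <- make_expr(list(gA = c(5, 5, 5, 7, 7, 7), gB = c(8, 8, 8, 8, 8, 8)),
                    days = 0:1, reps = 3)
  fc <- fold_change_table(expr)
  expect_equal(fc$lfc_day0["gA", "1"], 2)      # linear FC 4
  expect_equal(fc$lfc_day0["gB", "1"], 0)
  expect_equal(fc$lfc_prev[, "1"], fc$lfc_day0[, "1"])  # same baseline on day 1
  no_day0 <- expr
  colnames(no_day0) <- sub("day0", "day2", colnames(no_day0))
  expect_error(fold_change_table(no_day0), "day 0")
})

test_that("moderated t has the stated limiting forms", {
  set.seed(2)
  expr <- make_expr(stats::setNames(lapply(1:40, function(i)
    rnorm(6, 8, 0.5)), sprintf("g%02d", 1:40)), days = 0:1, reps = 3)
  # d0 = 0: ordinary pooled two-sample t
  mt0 <- moderated_t_test(expr, 1, d0 = 0, s0_sq = 1)
  ord <- apply(expr, 1, function(x)
    t.test(x[4:6], x[1:3], var.equal = TRUE)$statistic)
  expect_lt(max(abs(mt0$t - ord)), 1e-12)
  # d0 = Inf: z against s0, normal p
  mtI <- moderated_t_test(expr, 1, d0 = Inf, s0_sq = 0.25)
  z <- (rowMeans(expr[, 4:6]) - rowMeans(expr[, 1:3])) / (0.5 * sqrt(2 / 3))
  expect_lt(max(abs(mtI$t - z)), 1e-12)
  expect_lt(max(abs(mtI$p - 2 * pnorm(-abs(z)))), 1e-12)
  # zero mean difference: t = 0, p = 1
  flat <- make_expr(list(g1 = c(4, 5, 6, 6, 5, 4), g2 = rnorm(6)),
                    days = 0:1, reps = 3)
  mt <- moderated_t_test(flat, 1)
  expect_equal(unname(mt$t["g1"]), 0)
  expect_equal(unname(mt$p["g1"]), 1)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(5)
  sds <- sqrt(0.25 * stats::rf(200, 10, 8))
  expr <- t(sapply(sds, function(s) c(rnorm(3, 8, s), rnorm(3, 8.5, s))))
  dimnames(expr) <- list(sprintf("g%03d", 1:200),
                         sprintf("day%d_rep%d", rep(0:1, each = 3), rep(1:3, 2)))
  fit <- limma::eBayes(limma::lmFit(expr, cbind(1, rep(0:1, each = 3))))
  mt <- moderated_t_test(expr, 1)
  expect_equal(mt$params$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(mt$params$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mt$t), unname(fit$t[, 2]), tolerance = 1e-10)
})

test_that("single-replicate groups degrade to fold-change-only calling", {
  expr <- make_expr(list(gA = c(5, 7.5), gB = c(8, 8)), days = 0:1, reps = 1)
  expect_warning(mt <- moderated_t_test(expr, 1), "fewer than 2 replicates")
  expect_true(all(is.na(mt$t)))
  det <- suppressWarnings(de_analysis(expr))
  expect_true(det$is_de[["gA"]])
  expect_false(det$is_de[["gB"]])
})

test_that("BH adjustment matches hand step-up and is permutation invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.1)), c(0.015, 0.1, 0.1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_false(is.unsorted(bh_adjust(p)[order(p)]))  # monotone in sorted-p order
})

test_that("the DE rule requires FC and FDR on the same day and is monotone", {
  det <- list(genes = c("a", "b", "c"),
              lfc_day0 = rbind(a = c(0, 0, 1.5), b = c(3, 3, 3),
                               c = c(0.926, 0, 0)),
              q_day0 = rbind(a = c(0.5, 0.5, 0.05), b = c(0.5, 0.6, 0.7),
                             c = c(0.001, 0.5, 0.5)))
  flags <- call_de(det, fc_threshold = 2, q_threshold = 0.1)
  expect_true(flags[["a"]])    # |lfc| 1.5 with q 0.05 on the same day
  expect_false(flags[["b"]])   # large FC but never significant
  expect_false(flags[["c"]])   # linear FC 1.9 < 2 despite tiny q
  set.seed(3)
  rnd <- list(genes = sprintf("g%02d", 1:50),
              lfc_day0 = matrix(rnorm(350, 0, 1.5), 50,
                                dimnames = list(sprintf("g%02d", 1:50), 1:7)),
              q_day0 = matrix(runif(350), 50))
  base <- call_de(rnd, 2, 0.1)
  expect_true(all(base <= call_de(rnd, 1.5, 0.1)))  # lower FC keeps flags
  expect_true(all(base <= call_de(rnd, 2, 0.3)))    # higher q keeps flags
})

test_that("constitutive calls use the min day mean with inclusive boundary", {
  expr <- make_expr(list(
    hi = log2(c(420, 420, 500, 500, 460, 460)),
    lo = log2(c(399, 399, 500, 500, 460, 460)),
    edge = c(4, 4, 5, 5, 6, 6)),       # min day mean 2^4 = 16 exactly
    days = 0:2, reps = 2)
  flags <- detect_constitutive(expr, background_level = 100)
  expect_true(flags[["hi"]])
  expect_false(flags[["lo"]])
  flags4 <- detect_constitutive(expr, background_level = 4)
  expect_true(flags4[["edge"]])        # exactly 4 * 4 = 16: inclusive
  expect_error(detect_constitutive(expr, background_level = 0), "> 0")
})

test_that("time-course summaries count single-comparison DE events", {
  cfg <- synthetic_config(
    n_genes = 60, rep_sigma = 0, seed = 8,
    module_spec = list(module_entry("immediate_persistent", 10,
                                    amp_meanlog = log(2), amp_sdlog = 0)))
  sim <- generate_timecourse(cfg)
  det <- de_analysis(sim$expr)
  counts <- summarize_time_course(det)
  d1_0 <- counts[counts$day == 1 & counts$baseline == "day0", ]
  d2_p <- counts[counts$day == 2 & counts$baseline == "prev", ]
  expect_equal(d1_0$n_up, 10)
  expect_equal(d2_p$n_up, 0)           # persistent step: no day-2 change
  d1_p <- counts[counts$day == 1 & counts$baseline == "prev", ]
  expect_equal(d1_0$n_up, d1_p$n_up)   # same baseline on day 1
  # all-flat matrix: all counts zero
  flat <- sim$expr[11:60, ]
  det_f <- de_analysis(flat)
  cf <- summarize_time_course(det_f)
  expect_true(all(cf$n_up == 0) && all(cf$n_down == 0))
})

test_that("group fold-change comparison separates boosted groups", {
  cfg <- synthetic_config(
    n_genes = 200, rep_sigma = 0.2, seed = 12,
    module_spec = list(module_entry("immediate_persistent", 200,
                                    ppe_fraction = 0.5)))
  sim <- generate_timecourse(cfg)
  det <- de_analysis(sim$expr)
  ppe <- sim$annotation$gene[sim$annotation$is_ppe]
  expect_gte(length(ppe), 50)
  cmp <- group_fc_comparison(det, ppe)
  expect_gt(cmp$ratio, 1)
  expect_lt(cmp$p, 0.01)
  # identical groups: ratio 1 and p near 1 (split one homogeneous pool)
  half <- det$genes[seq(1, 200, by = 2)]
  cmp2 <- group_fc_comparison(det, half)
  expect_equal(cmp2$ratio, 1, tolerance = 0.3)
  expect_gt(cmp2$p, 0.05)
  expect_error(group_fc_comparison(det, det$genes), "each side")
})
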