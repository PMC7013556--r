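# Day-mean profiles, soft-power scan, topological overlap, static-cut
# module detection and trajectory summaries.

test_that("day-mean profiles average replicates per day", {
  expr <- make_expr(list(gA = c(5, 6, 7, 1, 2, 3), gB = rep(4, 6)),
                    days = 0:1, reps = 3)
  prof <- day_mean_profiles(expr)
  expect_equal(prof["gA", ], c(`0` = 6, `1` = 2))
  single <- make_expr(list(gA = c(5, 7)), days = 0:1, reps = 1)
  expect_equal(day_mean_profiles(single)["gA", ], c(`0` = 5, `1` = 7))
  expect_equal(day_mean_profiles(expr, type = "lfc")["gA", "1"], -4)
  expect_error(day_mean_profiles(expr, genes = "nope"), "unknown gene")
})

test_that("TOM matches hand computations and stays in bounds", {
  # complete graph: TOM all ones
  a <- matrix(1, 5, 5)
  expect_true(all(tom_matrix(adjacency = a) == 1))
  # shared-neighbor case: a12 = a13 = 1, a23 = 0 -> TOM_23 = 0.5
  a3 <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  tom <- tom_matrix(adjacency = a3)
  expect_equal(tom[2, 3], 0.5)
  # isolated pair: no adjacency, no shared neighbors -> 0
  a4 <- diag(0, 4); a4[1, 2] <- a4[2, 1] <- 1
  expect_equal(tom_matrix(adjacency = a4)[3, 4], 0)
  # fuzz: random adjacencies give symmetric TOM in [0, 1] with unit diagonal
  set.seed(7)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    tom <- tom_matrix(adjacency = m)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("soft-power scan matches an independent recomputation", {
  sim <- generate_timecourse(recovery_config(11, n_genes = 300))
  prof <- day_mean_profiles(sim$expr)
  beta <- pick_soft_power(prof)
  # straightforward re-computation of the same scan
  rescan <- function(profiles, powers = 1:20, target_r2 = 0.8, n_bins = 10) {
    cc <- abs(cor(t(profiles)))
    for (b in powers) {
      adj <- cc^b; diag(adj) <- 0
      k <- rowSums(adj); k <- k[k > 0]
      if (length(unique(k)) < 5) next
      bins <- cut(log10(k), n_bins)
      pk <- tapply(k, bins, length) / length(k)
      km <- tapply(log10(k), bins, mean)
      keep <- !is.na(pk) & pk > 0
      if (sum(keep) < 5) next
      if (summary(lm(log10(pk[keep]) ~ km[keep]))$r.squared >= target_r2)
        return(b)
    }
    9
  }
  expect_equal(as.numeric(beta), rescan(prof))
  # degenerate all-|r|=1 profiles: fallback with warning
  ident <- matrix(rep(c(0, 1, 2, 3, 4, 5, 5, 5), each = 6), nrow = 6) *
    (1:6)
  rownames(ident) <- paste0("g", 1:6)
  expect_warning(fb <- pick_soft_power(ident), "falling back")
  expect_equal(as.numeric(fb), 9)
  # target R^2 of zero accepts the first candidate power
  prof_ok <- prof[1:100, ]
  expect_equal(as.numeric(pick_soft_power(prof_ok, target_r2 = 0)), 1)
  expect_error(pick_soft_power(prof[1:2, ]), "at least 3")
})

test_that("noise-free planted blocks are recovered exactly", {
  cfg <- synthetic_config(
    n_genes = 120, rep_sigma = 0, seed = 4,
    module_spec = list(module_entry("immediate_persistent", 60),
                       module_entry("mid_transient", 60)))
  sim <- generate_timecourse(cfg)
  prof <- day_mean_profiles(sim$expr)
  tom <- tom_matrix(prof, beta = 6)
  ms <- detect_modules(tom)
  expect_equal(length(ms$sizes), 2)
  expect_equal(adjusted_rand_index(ms$labels, sim$truth$module), 1)
  # labels ordered by size, with module colors attached
  expect_true(all(diff(ms$sizes) <= 0))
  expect_equal(unname(ms$colors["M1"]), "turquoise")
})

test_that("module detection is invariant to gene input order", {
  sim <- generate_timecourse(recovery_config(3, n_genes = 300))
  prof <- day_mean_profiles(sim$expr)
  tom <- tom_matrix(prof, beta = 6)
  ms1 <- detect_modules(tom, min_size = 20)
  set.seed(1)
  perm <- sample(nrow(prof))
  ms2 <- detect_modules(tom_matrix(prof[perm, ], beta = 6), min_size = 20)
  common <- names(ms1$labels)
  expect_equal(adjusted_rand_index(ms1$labels[common], ms2$labels[common]), 1)
})

test_that("min_size larger than n leaves everything unassigned", {
  prof <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  expect_warning(ms <- detect_modules(tom_matrix(prof, beta = 2),
                                      min_size = 30), "unassigned")
  expect_true(all(ms$labels == "unassigned"))
})

test_that("module groups are placental only with significant PPE excess", {
  universe <- sprintf("g%03d", 1:300)
  rich <- universe[1:60]     # 50% PPE
  poor <- universe[61:300]   # ~5% PPE
  ppe <- c(rich[1:30], poor[seq(1, 240, by = 20)])
  grp <- classify_module_groups(list(M1 = rich, M2 = poor), ppe,
                                universe = universe)
  expect_equal(unname(grp["M1"]), "placental")
  expect_equal(unname(grp["M2"]), "non-placental")
  expect_warning(none <- classify_module_groups(list(M1 = rich), "absent",
                                                universe = universe),
                 "no PPE")
  expect_equal(unname(none["M1"]), "non-placental")
  # OR < 1 is never placental regardless of p
  depleted <- classify_module_groups(list(M1 = poor, M2 = rich), ppe,
                                     universe = universe)
  expect_equal(unname(depleted["M1"]), "non-placental")
})

test_that("trajectories track planted shapes and group averages", {
  cfg <- synthetic_config(
    n_genes = 120, rep_sigma = 0, seed = 9,
    module_spec = list(module_entry("slow_persistent", 60),
                       module_entry("immediate_persistent", 60)))
  sim <- generate_timecourse(cfg)
  det <- de_analysis(sim$expr)
  mods <- list(M1 = names(sim$truth$module)[sim$truth$module == "M1"],
               M2 = names(sim$truth$module)[sim$truth$module == "M2"])
  tr <- module_trajectories(mods, det,
                            groups = c(M1 = "placental", M2 = "non-placental"))
  slow <- tr$module_curves["M1", ]
  expect_true(all(diff(slow[1:5]) > 0))          # rises through day 5
  flat_after <- tr$module_curves["M2", ]
  expect_equal(unname(diff(flat_after))[2:6], rep(0, 5), tolerance = 1e-12)
  # group curve equals the size-weighted mean of member module curves
  expect_equal(tr$group_curves["placental", ], tr$module_curves["M1", ])
  # slower placental group: lower at day 1, at its maximum by day 5
  rel_pl <- tr$group_curves["placental", ] / max(tr$group_curves["placental", ])
  rel_np <- tr$group_curves["non-placental", ] /
    max(tr$group_curves["non-placental", ])
  expect_lt(rel_pl[["1"]], rel_np[["1"]])
  expect_equal(rel_pl[["5"]], 1)
  expect_error(module_trajectories(list(M1 = character(0)), det), "empty")
})
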