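# Co-expression network construction, DE-timing partition, footprint
# interval logic, coverage arithmetic, the disease overlay and the
# tightness permutation test.

test_that("co-expression network edges match a brute-force recomputation", {
  sim <- generate_timecourse(recovery_config(6, n_genes = 150))
  prof <- day_mean_profiles(sim$expr)
  det <- de_analysis(sim$expr)
  de <- det$genes[det$is_de]
  tr <- sim$annotation$gene[sim$annotation$is_tr]
  net <- build_tr_coexpression_network(prof, de, tr, r_min = 0.9)
  tr_de <- intersect(tr, de)
  brute <- 0L
  for (t in tr_de) for (g in de) {
    if (t < g || !(g %in% tr_de)) {  # count unordered TR pairs once
      if (t != g && abs(cor(prof[t, ], prof[g, ])) >= 0.9) brute <- brute + 1L
    }
  }
  expect_equal(nrow(net$edges), brute)
  expect_true(all(net$edges$tr %in% tr_de))
  expect_true(all(abs(net$edges$r) >= 0.9))
  # connectivity equals degree
  for (t in head(net$tr_genes, 5)) {
    nb <- unique(c(net$edges$gene[net$edges$tr == t],
                   net$edges$tr[net$edges$gene == t]))
    expect_equal(unname(net$connectivity[t]), length(nb))
  }
})

test_that("identical and anti-correlated profiles connect fully", {
  base <- c(0, 1, 2, 3, 3, 3, 3, 3)
  prof <- rbind(tr1 = base, g1 = 2 * base + 5, g2 = -base)
  net <- build_tr_coexpression_network(prof, rownames(prof), "tr1")
  expect_equal(unname(net$connectivity["tr1"]), 2)      # includes r = -1 edge
  expect_true(any(net$edges$r < 0))
  expect_warning(empty <- build_tr_coexpression_network(prof, c("g1", "g2"),
                                                        "tr9"), "no differentially")
  expect_equal(nrow(empty$edges), 0)
})

test_that("DE timing partitions TR genes by the day-1 rule", {
  cfg <- synthetic_config(
    n_genes = 90, rep_sigma = 0, seed = 3, tr_fraction = 1,
    module_spec = list(
      module_entry("immediate_persistent", 30, amp_meanlog = log(2), amp_sdlog = 0),
      module_entry("slow_persistent", 30, amp_meanlog = log(2), amp_sdlog = 0)))
  sim <- generate_timecourse(cfg)
  det <- de_analysis(sim$expr)
  timing <- tr_timing(det, sim$annotation$gene)
  imm <- names(sim$truth$module)[sim$truth$module == "M1"]
  slow <- names(sim$truth$module)[sim$truth$module == "M2"]
  flat <- names(sim$truth$module)[sim$truth$module == "background"]
  expect_setequal(timing$day1, imm)
  # slow ramp with amplitude 2: day-1 lfc = 0.8 < 1, crosses later
  expect_setequal(timing$later, slow)
  expect_false(any(flat %in% c(timing$day1, timing$later)))
})

test_that("footprint edges require footprint overlap inside the promoter", {
  tss <- data.frame(chrom = "chr1", start = 5000L, end = 5001L,
                    name = "geneA", score = 0L, strand = "+")
  fp <- data.frame(chrom = "chr1", start = 100L, end = 120L, name = "fp")
  motif_in <- data.frame(chrom = "chr1", start = 105L, end = 115L, name = "TFX")
  em <- footprint_edge_map(fp, motif_in, tss)
  expect_equal(em$tf, "TFX")
  expect_equal(em$gene, "geneA")
  # motif outside any footprint
  motif_nofp <- data.frame(chrom = "chr1", start = 300L, end = 310L, name = "TFX")
  expect_equal(nrow(footprint_edge_map(fp, motif_nofp, tss)), 0)
  # motif in a footprint but outside the promoter window
  fp_far <- data.frame(chrom = "chr1", start = 50000L, end = 50020L, name = "fp")
  motif_far <- data.frame(chrom = "chr1", start = 50005L, end = 50015L, name = "TFX")
  expect_equal(nrow(footprint_edge_map(rbind(fp, fp_far),
                                       rbind(motif_in, motif_far), tss)), 1)
  expect_error(footprint_edge_map(fp, motif_in,
                                  transform(tss, strand = "*")), "strand")
})

test_that("footprint mapping is invariant to record order and reads BED files", {
  genes <- sprintf("g%04d", 1:30)
  fx <- generate_footprint_fixtures(genes, paste0("TF", 1:4), n_edges = 15,
                                    seed = 4)
  em1 <- footprint_edge_map(fx$footprints, fx$motifs, fx$tss)
  shuf <- function(df) df[sample(nrow(df)), ]
  set.seed(2)
  em2 <- footprint_edge_map(shuf(fx$footprints), shuf(fx$motifs),
                            shuf(fx$tss))
  expect_equal(em1, em2)
  dir <- withr::local_tempdir()
  write_bed(fx$footprints, file.path(dir, "fp.bed"))
  write_bed(fx$motifs, file.path(dir, "mo.bed"))
  write_bed(transform(fx$tss, score = 0), file.path(dir, "tss.bed"))
  em3 <- footprint_edge_map(file.path(dir, "fp.bed"), file.path(dir, "mo.bed"),
                            file.path(dir, "tss.bed"))
  expect_equal(em1, em3)
})

test_that("correlation filtering is strict at the boundary", {
  prof <- rbind(TFX = c(0, 1, 2, 3, 4, 5, 6, 7),
                gene_same = c(0, 2, 4, 6, 8, 10, 12, 14),
                gene_mid = c(0, 1, 0, 2, 1, 3, 2, 4))
  edges <- data.frame(tf = c("TFX", "TFX", "TFZ"),
                      gene = c("gene_same", "gene_mid", "gene_same"))
  r_mid <- cor(prof["TFX", ], prof["gene_mid", ])
  filt_keep <- attach_correlations(edges, prof, min_abs_r = abs(r_mid) - 1e-9)
  expect_setequal(filt_keep$gene, c("gene_same", "gene_mid"))
  # an edge whose |r| equals the threshold exactly is dropped (strict >)
  filt_strict <- attach_correlations(edges, prof, min_abs_r = abs(r_mid))
  expect_equal(filt_strict$gene, "gene_same")
  expect_equal(filt_strict$r, 1)
  expect_equal(attr(filt_strict, "unmapped"), "TFZ")
})

test_that("coverage report arithmetic and flags", {
  pl <- sprintf("p%02d", 1:40)
  np <- sprintf("n%02d", 1:60)
  edges <- data.frame(
    tf = c(rep("TFA", 3), rep("TFB", 100)),
    gene = c(pl[1:2], np[1], c(pl, np)))
  cov <- module_coverage_report(edges, list(placental = pl, non_placental = np))
  a <- cov[cov$tf == "TFA", ]
  expect_equal(a$coverage_placental_pct, 5)
  expect_equal(a$coverage_nonplacental_pct, 100 / 60, tolerance = 1e-9)
  expect_false(a$both_ge_4)
  expect_true(a$placental_ge_5)
  b <- cov[cov$tf == "TFB", ]
  expect_equal(b$coverage_placental_pct, 100)
  expect_true(b$both_ge_4 && b$placental_ge_10 && b$nonplacental_ge_10)
  expect_error(module_coverage_report(edges, list(placental = pl,
                                                  non_placental = character(0))),
               "empty")
})

test_that("overlay classifies sign discordance and ignores absent genes", {
  det <- list(genes = c("t1", "t2", "t3"),
              is_de = setNames(c(TRUE, TRUE, TRUE), c("t1", "t2", "t3")),
              max_fc_signed = c(t1 = -2, t2 = 1.5, t3 = 2))
  dis <- data.frame(gene = c("t1", "t2"), log2fc = c(1, 1.2),
                    fdr = c(0.01, 0.01))
  ov <- disease_overlay(det, dis, c("t1", "t2", "t3"))
  expect_equal(ov$discordant, "t1")
  expect_false("t3" %in% ov$table$gene)       # absent from the disease table
  expect_equal(ov$table$concordance[ov$table$gene == "t2"], "concordant")
  expect_error(disease_overlay(det, dis[, c("gene", "log2fc")],
                               c("t1", "t2")), "fdr")
})

test_that("tightness permutation p behaves at its extremes and under the null", {
  set.seed(10)
  prof <- matrix(rnorm(400), 50, 8, dimnames = list(sprintf("g%02d", 1:50), NULL))
  clone <- prof[rep(1, 5), ]
  rownames(clone) <- paste0("c", 1:5)
  prof2 <- rbind(prof, clone)
  tight <- discordance_tightness(prof2, rownames(clone),
                                 pool = rownames(prof), B = 200, seed = 1)
  expect_equal(tight$statistic, 1)
  expect_lt(tight$p, 0.05)
  expect_gte(tight$p, 1 / 201)
  expect_error(discordance_tightness(prof2, "c1", rownames(prof)), "at least 2")
  expect_error(discordance_tightness(prof2, c("c1", "c2"), rownames(prof),
                                     B = 0), "positive")
  # null calibration: random sets give roughly uniform p-values
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    g <- sample(rownames(prof), 5)
    discordance_tightness(prof, g, rownames(prof), B = 200, seed = s)$p < 0.1
  }, TRUE)
  expect_true(sum(hits) >= 4 && sum(hits) <= 16)
})
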