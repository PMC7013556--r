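# Synthetic time-course generator with planted ground truth.
#
# The generator emulates the study design the pipeline targets: an 8-day
# (day 0..7) primary villous trophoblast differentiation culture measured on
# log2-scale expression arrays with 3 replicates per day, planted
# co-expression modules following distinct temporal archetypes, PPE
# (predominantly placenta-expressed) labels enriched in slowly-changing
# modules and on one designated chromosome, TR (transcription regulatory)
# labels, and a disease table in which a chosen TR subset flips fold-change
# sign.

.archetypes <- function(n_days) {
  d <- seq_len(n_days) - 1L
  tpl <- list(
    flat                 = rep(0, n_days),
    immediate_transient  = c(0, 1, 0.5, rep(0, max(0, n_days - 3)))[seq_len(n_days)],
    immediate_persistent = c(0, rep(1, n_days - 1L)),
    slow_persistent      = pmin(d / 5, 1),
    mid_transient        = c(0, 0, 0.5, 1, 0.5, rep(0, max(0, n_days - 5)))[seq_len(n_days)],
    late_transient       = c(0, 0, 0, 0, 0.5, 1, 0.5, rep(0, max(0, n_days - 7)))[seq_len(n_days)]
  )
  lapply(tpl, function(x) { x[is.na(x)] <- 0; x })
}

#' Names of the available temporal archetypes
#' @return character vector of archetype ids.
#' @export
archetype_names <- function() names(.archetypes(8L))

#' One planted-module specification entry
#'
#' @param archetype archetype id; see [archetype_names()].
#' @param n number of genes in the module.
#' @param amp_meanlog,amp_sdlog log-normal amplitude parameters (log2 units).
#' @param sign `"up"`, `"down"` or `"mixed"` direction of change.
#' @param ppe_fraction proportion of module genes flagged PPE.
#' @return a list usable inside `module_spec` of [synthetic_config()].
#' @export
module_entry <- function(archetype, n, amp_meanlog = log(2), amp_sdlog = 0.4,
                         sign = "up", ppe_fraction = 0.05) {
  if (!archetype %in% archetype_names()) stopf("unknown archetype id: %s", archetype)
  if (n <= 0) stopf("module gene count must be positive")
  if (!sign %in% c("up", "down", "mixed")) stopf("sign must be up/down/mixed")
  list(archetype = archetype, n = as.integer(n), amp_meanlog = amp_meanlog,
       amp_sdlog = amp_sdlog, sign = sign, ppe_fraction = ppe_fraction)
}

#' Configuration of the synthetic time-course generator
#'
#' Defaults are the study conditions the pipeline was designed around: 8
#' days x 3 replicates, five planted modules with distinct temporal
#' archetypes, PPE labels enriched in the slowly changing ("placental")
#' modules and on one designated chromosome, and PPE amplitudes drawn with
#' twice the background mean so that PPE genes carry larger fold changes.
#'
#' @param n_genes total genes; those not claimed by `module_spec` are flat
#'   background genes.
#' @param n_days days 0..`n_days`-1 (8 at most; the templates are defined on
#'   the 8-day grid and truncate downward for small tests).
#' @param n_reps replicates per day.
#' @param module_spec list of [module_entry()] items; `NULL` builds the
#'   default five shape-distinct modules scaled to `n_genes` (6%, 8%, 5%,
#'   7% and 4% of the genes; the slowly-changing modules PPE-rich).
#' @param background_ppe_fraction PPE proportion among background genes.
#' @param tr_fraction proportion of genes flagged TR (drawn uniformly).
#' @param n_chromosomes number of chromosome labels `chr1..chrN`.
#' @param ppe_chromosome designated PPE-enriched chromosome label.
#' @param ppe_chromosome_bias multiplicative oversampling of the designated
#'   chromosome when assigning chromosomes to PPE genes.
#' @param ppe_amp_boost multiplier on mean amplitude for PPE genes.
#' @param rep_sigma replicate noise SD (log2 units).
#' @param baseline_range range of uniform baseline log2 intensities.
#' @param disease_flip_set_size TR genes whose disease fold change flips sign.
#' @param seed integer seed; every draw is derived from it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_days = 8L,
                             n_reps = 3L,
                             module_spec = NULL,
                             background_ppe_fraction = 0.01,
                             tr_fraction = 0.10,
                             n_chromosomes = 23L,
                             ppe_chromosome = "chr19",
                             ppe_chromosome_bias = 4,
                             ppe_amp_boost = 2,
                             rep_sigma = 0.3,
                             baseline_range = c(6, 12),
                             disease_flip_set_size = 7L,
                             seed = 1L) {
  if (n_genes <= 0 || n_days <= 0 || n_reps <= 0) stopf("counts must be positive")
  if (is.null(module_spec)) {
    sz <- pmax(1L, round(n_genes * c(0.06, 0.08, 0.05, 0.07, 0.04)))
    module_spec <- list(
      module_entry("immediate_transient",  sz[1], ppe_fraction = 0.02),
      module_entry("immediate_persistent", sz[2], sign = "mixed", ppe_fraction = 0.02),
      module_entry("mid_transient",        sz[3], ppe_fraction = 0.02),
      module_entry("slow_persistent",      sz[4], sign = "mixed", ppe_fraction = 0.25),
      module_entry("late_transient",       sz[5], ppe_fraction = 0.25))
  }
  if (n_days > 8) stopf("the day grid is fixed at 0..7; n_days may only shrink")
  if (rep_sigma < 0) stopf("rep_sigma must be >= 0")
  fr <- c(background_ppe_fraction, tr_fraction,
          vapply(module_spec, `[[`, 0, "ppe_fraction"))
  if (any(fr < 0 | fr > 1)) stopf("all fractions must lie in [0, 1]")
  n_mod <- sum(vapply(module_spec, `[[`, 0L, "n"))
  if (n_mod > n_genes) stopf("module gene counts (%d) exceed n_genes (%d)", n_mod, n_genes)
  for (m in module_spec)
    if (!m$archetype %in% archetype_names()) stopf("unknown archetype id: %s", m$archetype)
  structure(list(
    n_genes = as.integer(n_genes), n_days = as.integer(n_days),
    n_reps = as.integer(n_reps), module_spec = module_spec,
    background_ppe_fraction = background_ppe_fraction,
    tr_fraction = tr_fraction, n_chromosomes = as.integer(n_chromosomes),
    ppe_chromosome = ppe_chromosome, ppe_chromosome_bias = ppe_chromosome_bias,
    ppe_amp_boost = ppe_amp_boost, rep_sigma = rep_sigma,
    baseline_range = baseline_range,
    disease_flip_set_size = as.integer(disease_flip_set_size),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic differentiation time course with known truth
#'
#' Each gene's log2 intensity is
#' `baseline_g + amplitude_g * sign_g * f_m(day) + N(0, rep_sigma)` per
#' replicate, where `f_m` is the module's temporal archetype template
#' (0..1). PPE genes draw amplitudes with `ppe_amp_boost` times the mean of
#' background draws, and their chromosome assignment oversamples the
#' designated chromosome by `ppe_chromosome_bias`.
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (genes x samples log2 matrix, columns
#'   `day<d>_rep<r>`), `annotation` (gene, chromosome, is_ppe, is_tr), and
#'   `truth` (module labels, archetypes, signs, amplitudes, config echo).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  tpl <- .archetypes(config$n_days)

  module <- rep("background", n)
  archetype <- rep("flat", n)
  sgn <- rep(1, n)
  amp <- rep(0, n)
  is_ppe <- logical(n)
  idx <- 0L
  mod_names <- sprintf("M%d", seq_along(config$module_spec))
  for (i in seq_along(config$module_spec)) {
    m <- config$module_spec[[i]]
    rows <- idx + seq_len(m$n)
    idx <- idx + m$n
    module[rows] <- mod_names[i]
    archetype[rows] <- m$archetype
    sgn[rows] <- switch(m$sign,
                        up = 1, down = -1,
                        mixed = sample(c(-1, 1), m$n, replace = TRUE))
    is_ppe[rows] <- stats::runif(m$n) < m$ppe_fraction
    boost <- ifelse(is_ppe[rows], log(config$ppe_amp_boost), 0)
    amp[rows] <- stats::rlnorm(m$n, meanlog = m$amp_meanlog + boost,
                               sdlog = m$amp_sdlog)
  }
  bg <- module == "background"
  is_ppe[bg] <- stats::runif(sum(bg)) < config$background_ppe_fraction
  is_tr <- stats::runif(n) < config$tr_fraction

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  if (!config$ppe_chromosome %in% chroms)
    chroms[length(chroms)] <- config$ppe_chromosome
  w <- rep(1, length(chroms))
  wp <- w; wp[chroms == config$ppe_chromosome] <- config$ppe_chromosome_bias
  chromosome <- character(n)
  chromosome[!is_ppe] <- sample(chroms, sum(!is_ppe), replace = TRUE, prob = w)
  chromosome[is_ppe] <- sample(chroms, sum(is_ppe), replace = TRUE, prob = wp)

  baseline <- stats::runif(n, config$baseline_range[1], config$baseline_range[2])
  days <- rep(seq_len(config$n_days) - 1L, each = config$n_reps)
  reps <- rep(seq_len(config$n_reps), times = config$n_days)
  shape <- t(vapply(archetype, function(a) tpl[[a]], numeric(config$n_days)))
  signal <- baseline + (amp * sgn) * shape[, days + 1L, drop = FALSE]
  noise <- matrix(stats::rnorm(n * length(days), sd = config$rep_sigma),
                  nrow = n)
  expr <- signal + noise
  dimnames(expr) <- list(genes, sprintf("day%d_rep%d", days, reps))

  annotation <- data.frame(gene = genes, chromosome = chromosome,
                           is_ppe = is_ppe, is_tr = is_tr,
                           stringsAsFactors = FALSE)
  truth <- list(
    module = stats::setNames(module, genes),
    archetype_by_module = stats::setNames(
      vapply(config$module_spec, `[[`, "", "archetype"), mod_names),
    archetype = stats::setNames(archetype, genes),
    sign = stats::setNames(sgn, genes),
    amplitude = stats::setNames(amp, genes),
    is_ppe = stats::setNames(is_ppe, genes),
    is_tr = stats::setNames(is_tr, genes),
    chromosome = stats::setNames(chromosome, genes),
    config = config
  )
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Generate a disease differential-expression table with a planted flip set
#'
#' Emulates an external disease (preterm preeclampsia style) DE table:
#' genes in the flip set — a subset of TR genes — receive a disease log2
#' fold change of sign opposite to their differentiation fold change at the
#' day of maximum |log2FC|, with small FDR; a set of concordant disease-DE
#' genes keeps the differentiation sign; all other genes are null.
#'
#' @param truth truth component of [generate_timecourse()].
#' @param de a `de_result` from [de_analysis()] on the same genes.
#' @param flip_set character vector of TR genes to flip; defaults to a
#'   seeded draw of `disease_flip_set_size` DE TR genes.
#' @param n_concordant number of additional concordant disease-DE genes.
#' @param fdr significant FDR value written for disease-DE genes.
#' @param effect absolute disease log2FC for disease-DE genes.
#' @return list with `table` (gene, log2fc, fdr) and `flip_set`.
#' @export
generate_disease_table <- function(truth, de, flip_set = NULL,
                                   n_concordant = 10L, fdr = 0.01,
                                   effect = 1.5) {
  genes <- names(truth$module)
  if (!setequal(genes, de$genes)) stopf("truth and de must share a gene universe")
  set.seed(.child_seed(truth$config$seed, 101L))
  de_tr <- de$genes[de$is_de & truth$is_tr[de$genes]]
  if (is.null(flip_set)) {
    k <- min(truth$config$disease_flip_set_size, length(de_tr))
    flip_set <- sort(sample(de_tr, k))
  }
  if (!all(truth$is_tr[flip_set])) stopf("flip set must be a subset of TR genes")
  sign_diff <- sign(de$max_fc_signed)
  sign_diff[sign_diff == 0] <- 1
  lfc <- stats::rnorm(length(genes), 0, 0.1)
  qv <- stats::runif(length(genes), 0.5, 1)
  names(lfc) <- names(qv) <- genes
  conc_pool <- setdiff(de_tr, flip_set)
  concordant <- sample(conc_pool, min(n_concordant, length(conc_pool)))
  lfc[concordant] <- sign_diff[concordant] * effect
  qv[concordant] <- fdr
  lfc[flip_set] <- -sign_diff[flip_set] * effect
  qv[flip_set] <- fdr
  list(table = data.frame(gene = genes, log2fc = unname(lfc),
                          fdr = unname(qv), stringsAsFactors = FALSE),
       flip_set = flip_set)
}

#' Generate toy-genome footprint, motif and TSS fixtures with planted edges
#'
#' For each planted TF->gene edge, emits a motif instance (named after the
#' TF) lying inside a DNaseI footprint and inside the gene's promoter
#' window; also emits decoy motifs outside footprints and decoy motifs in
#' footprints outside any promoter, which must not produce edges.
#'
#' @param genes character vector of target gene ids.
#' @param tfs character vector of TF names.
#' @param n_edges number of planted TF->gene edges.
#' @param n_decoys decoy motifs of each decoy class.
#' @param window promoter window (upstream, downstream) relative to TSS.
#' @param gene_spacing bp between consecutive TSSs on the toy chromosome.
#' @param seed integer seed.
#' @return list of data.frames `footprints`, `motifs`, `tss` (BED-style,
#'   0-based half-open) and `planted_edges` (tf, gene).
#' @export
generate_footprint_fixtures <- function(genes, tfs, n_edges = 20L,
                                        n_decoys = 10L,
                                        window = c(-5000L, 1000L),
                                        gene_spacing = 20000L, seed = 1L) {
  set.seed(seed)
  if (gene_spacing <= diff(window)) stopf("promoter window larger than gene spacing on toy chromosome")
  n <- length(genes)
  tss_pos <- 50000L + gene_spacing * (seq_len(n) - 1L)
  strand <- rep(c("+", "-"), length.out = n)
  tss <- data.frame(chrom = "chrT", start = tss_pos, end = tss_pos + 1L,
                    name = genes, score = 0L, strand = strand,
                    stringsAsFactors = FALSE)

  empty_bed <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          stringsAsFactors = FALSE)
  if (n_edges > 0) {
    pairs <- unique(data.frame(
      tf = sample(tfs, n_edges, replace = TRUE),
      gene = sample(genes, n_edges, replace = TRUE),
      stringsAsFactors = FALSE))
    # motif 10 bp inside footprint 30 bp, centred ~1 kb upstream of the TSS,
    # which falls inside the promoter window on either strand
    off <- ifelse(tss$strand[match(pairs$gene, tss$name)] == "+", -1000L, 1000L)
    centre <- tss_pos[match(pairs$gene, genes)] + off
    fp <- data.frame(chrom = "chrT", start = centre - 15L, end = centre + 15L,
                     name = "footprint", stringsAsFactors = FALSE)
    mo <- data.frame(chrom = "chrT", start = centre - 5L, end = centre + 5L,
                     name = pairs$tf, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(tf = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
    fp <- mo <- empty_bed
  }

  # decoys: motifs in promoters but with no footprint (shifted to a clean
  # spot), and motifs inside footprints placed between promoter windows
  if (n_decoys > 0) {
    d1_gene <- sample(genes, n_decoys, replace = TRUE)
    d1c <- tss_pos[match(d1_gene, genes)] +
      ifelse(tss$strand[match(d1_gene, tss$name)] == "+", -3000L, 3000L)
    d1 <- data.frame(chrom = "chrT", start = d1c - 5L, end = d1c + 5L,
                     name = sample(tfs, n_decoys, replace = TRUE),
                     stringsAsFactors = FALSE)
    d2c <- 50000L + gene_spacing * (sample(n, n_decoys, replace = TRUE) - 1L) +
      as.integer(gene_spacing / 2)
    d2 <- data.frame(chrom = "chrT", start = d2c - 5L, end = d2c + 5L,
                     name = sample(tfs, n_decoys, replace = TRUE),
                     stringsAsFactors = FALSE)
    fp2 <- data.frame(chrom = "chrT", start = d2c - 15L, end = d2c + 15L,
                      name = "footprint", stringsAsFactors = FALSE)
    mo <- rbind(mo, d1, d2)
    fp <- rbind(fp, fp2)
  }
  planted <- pairs[order(pairs$tf, pairs$gene), ]
  rownames(planted) <- rownames(fp) <- rownames(mo) <- NULL
  list(footprints = unique(fp), motifs = mo, tss = tss,
       planted_edges = planted)
}

#' Generate random signed pathway graphs
#'
#' Emits random signed DAGs (optionally with a single directed cycle) whose
#' node ids are drawn from a supplied gene universe.
#'
#' @param genes gene universe to draw node ids from.
#' @param n_pathways number of graphs.
#' @param n_nodes nodes per graph (>= 2).
#' @param p_edge edge probability between ordered node pairs.
#' @param dag if `TRUE` the graph is acyclic by construction; otherwise one
#'   back edge is added to close a cycle.
#' @param seed integer seed.
#' @return list of `pathway_graph` objects.
#' @export
generate_pathway_fixture <- function(genes, n_pathways = 5L, n_nodes = 8L,
                                     p_edge = 0.3, dag = TRUE, seed = 1L) {
  if (n_nodes < 2) stopf("node counts must be >= 2")
  set.seed(seed)
  lapply(seq_len(n_pathways), function(i) {
    nodes <- sample(genes, n_nodes)
    from <- integer(0); to <- integer(0)
    for (a in seq_len(n_nodes - 1L)) for (b in seq(a + 1L, n_nodes)) {
      if (stats::runif(1) < p_edge) { from <- c(from, a); to <- c(to, b) }
    }
    if (length(from) == 0) { from <- 1L; to <- 2L }
    if (!dag) {  # close a guaranteed 2-cycle on the first edge
      from <- c(from, to[1L]); to <- c(to, from[1L])
    }
    edges <- data.frame(source = nodes[from], target = nodes[to],
                        sign = sample(c(1, -1), length(from), replace = TRUE),
                        stringsAsFactors = FALSE)
    pathway_graph(sprintf("toy%02d", i), edges, nodes = nodes)
  })
}

#' Simulate per-gene maximum fold changes with a planted enrichment breakpoint
#'
#' Builds a gene population whose PPE odds ratio, as a function of the
#' log2 fold-change threshold, rises linearly below the planted breakpoint
#' and jumps steeply for a few grid steps just above it, so that threshold
#' selection has a recoverable answer. Non-PPE fold changes have linearly
#' decaying survival below the breakpoint and an exponentially decaying
#' tail above it (the fast non-PPE tail decay is what makes a jump in the
#' odds ratio attainable with a monotone PPE survival curve); PPE fold
#' changes are drawn by inverse transform from the survival curve implied
#' by the target odds-ratio curve.
#'
#' @param n_genes,n_ppe population sizes.
#' @param breakpoint planted breakpoint (log2 units).
#' @param base_or odds ratio at threshold 0.
#' @param rise linear OR increase per 0.1 grid step below the breakpoint.
#' @param jump OR increase per 0.1 step just above the breakpoint (4 steps).
#' @param tail_rate exponential decay rate of the non-PPE tail above the
#'   breakpoint.
#' @param seed integer seed.
#' @return list with `max_abs_fc` (named numeric) and `is_ppe` (named logical).
#' @export
simulate_fc_breakpoint <- function(n_genes = 20000L, n_ppe = 3000L,
                                   breakpoint = 2.5, base_or = 1.5,
                                   rise = 0.3, jump = 2.0, tail_rate = 5,
                                   seed = 1L) {
  set.seed(seed)
  grid <- seq(0, 4, by = 0.1)
  below <- grid <= breakpoint
  or_target <- numeric(length(grid))
  or_target[below] <- base_or + rise * (grid[below] / 0.1)
  peak_or <- base_or + rise * (breakpoint / 0.1)
  above <- which(!below)
  or_target[above] <- peak_or + jump * pmin(seq_along(above), 4)

  s_n <- ifelse(below, 1 - grid * (1 - 0.375) / breakpoint,
                0.375 * exp(-tail_rate * (grid - breakpoint)))
  odds_n <- ifelse(s_n < 1, s_n / (1 - s_n), Inf)
  odds_p <- or_target * odds_n
  s_p <- ifelse(is.finite(odds_p), odds_p / (1 + odds_p), 1)
  s_p <- rev(cummax(rev(pmin(s_p, 1))))  # enforce a valid survival curve

  draw <- function(surv, k) {
    surv[length(surv)] <- 0
    stats::approx(x = rev(surv), y = rev(grid), xout = stats::runif(k),
                  ties = "ordered")$y
  }
  n_bg <- n_genes - n_ppe
  fc <- c(draw(s_n, n_bg), draw(s_p, n_ppe))
  genes <- sprintf("g%05d", seq_len(n_genes))
  list(max_abs_fc = stats::setNames(fc, genes),
       is_ppe = stats::setNames(rep(c(FALSE, TRUE), c(n_bg, n_ppe)), genes))
}
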