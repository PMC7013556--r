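# Transcription-regulator networks: co-expression inference, DNaseI
# footprint-derived TF->target edges, module coverage, and the disease
# overlay that flags discordant regulators.

#' TR-target co-expression network
#'
#' Connects every differentially expressed TR gene to every DE gene whose
#' 8-day profile correlation satisfies `|r| >= r_min` (TR-TR pairs counted
#' once). Connectivity of a TR gene is its number of distinct neighbors.
#'
#' @param profiles genes x days matrix of day-mean expression (must cover
#'   all DE genes).
#' @param de_genes DE gene ids.
#' @param tr_flags TR gene ids or named logical vector.
#' @param r_min absolute-correlation threshold (inclusive).
#' @return list with `edges` (tr, gene, r), `connectivity` (named integer
#'   per DE TR gene) and `tr_genes`.
#' @export
build_tr_coexpression_network <- function(profiles, de_genes, tr_flags,
                                          r_min = 0.9) {
  if (!all(de_genes %in% rownames(profiles)))
    stopf("profiles must cover all DE genes")
  tr <- if (is.logical(tr_flags)) names(tr_flags)[tr_flags] else tr_flags
  tr_de <- intersect(tr, de_genes)
  if (length(tr_de) == 0) {
    warnf("no differentially expressed TR genes; empty network")
    return(list(edges = data.frame(tr = character(0), gene = character(0),
                                   r = numeric(0)),
                connectivity = stats::setNames(integer(0), character(0)),
                tr_genes = character(0)))
  }
  cc <- suppressWarnings(
    stats::cor(t(profiles[tr_de, , drop = FALSE]),
               t(profiles[de_genes, , drop = FALSE])))
  hit <- which(abs(cc) >= r_min & !is.na(cc), arr.ind = TRUE)
  edges <- data.frame(tr = tr_de[hit[, 1L]], gene = de_genes[hit[, 2L]],
                      r = cc[hit], stringsAsFactors = FALSE)
  edges <- edges[edges$tr != edges$gene, ]
  # collapse TR-TR duplicates to one undirected edge
  both_tr <- edges$gene %in% tr_de
  key <- ifelse(both_tr,
                paste(pmin(edges$tr, edges$gene), pmax(edges$tr, edges$gene)),
                paste(edges$tr, edges$gene))
  edges <- edges[!duplicated(key), ]
  rownames(edges) <- NULL
  neighbors <- rbind(data.frame(tr = edges$tr, other = edges$gene),
                     data.frame(tr = edges$gene, other = edges$tr))
  neighbors <- neighbors[neighbors$tr %in% tr_de, ]
  conn <- stats::setNames(integer(length(tr_de)), tr_de)
  if (nrow(neighbors)) {
    tab <- tapply(neighbors$other, neighbors$tr, function(x) length(unique(x)))
    conn[names(tab)] <- as.integer(tab)
  }
  list(edges = edges, connectivity = conn, tr_genes = tr_de)
}

#' Partition DE TR genes by first day of differential expression
#'
#' @param det a `de_result`.
#' @param tr_flags TR gene ids or named logical.
#' @return list with `day1` (TR genes meeting the DE rule on day 1) and
#'   `later` (DE TR genes whose rule first holds after day 1).
#' @export
tr_timing <- function(det, tr_flags) {
  tr <- if (is.logical(tr_flags)) names(tr_flags)[tr_flags] else tr_flags
  de_tr <- intersect(tr, det$genes[det$is_de])
  big <- abs(det$lfc_day0) >= log2(det$fc_threshold)
  sig <- if (all(is.na(det$q_day0))) big else big & det$q_day0 < det$q_threshold
  day1_col <- which(det$days == 1L)
  day1 <- de_tr[sig[de_tr, day1_col]]
  list(day1 = day1, later = setdiff(de_tr, day1))
}

# Coerce a BED-style input (path or data.frame chrom/start/end[/name/score/
# strand], 0-based half-open) to GRanges (1-based closed).
.as_granges <- function(x, what = "intervals") {
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    gr <- tryCatch(rtracklayer::import(x, format = "BED"),
                   error = function(e) stopf("malformed BED file %s: %s", x, conditionMessage(e)))
    return(gr)
  }
  if (is.data.frame(x)) {
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stopf("%s data.frame needs chrom/start/end columns", what)
    strand <- if ("strand" %in% names(x)) x$strand else "*"
    if (!all(strand %in% c("+", "-", "*"))) stopf("unknown strand in %s", what)
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = strand)
    if ("name" %in% names(x)) gr$name <- x$name
    return(gr)
  }
  stopf("cannot interpret %s input", what)
}

#' Map TF->gene edges from footprint, motif and TSS intervals
#'
#' An edge TF -> gene is created when a motif instance carrying the TF
#' name overlaps a DNaseI footprint by at least 1 bp and lies entirely
#' within the gene's strand-aware promoter window
#' `[TSS + window[1], TSS + window[2])` (coordinates reflected on the
#' minus strand). Duplicate edges collapse with an evidence count.
#'
#' @param footprints,motifs,tss BED file paths, BED-style data.frames
#'   (chrom, start, end, name, 0-based half-open) or `GRanges`. Motif
#'   names carry the TF; TSS names carry the gene and must have strand.
#' @param window promoter window relative to the TSS (upstream negative).
#' @return data.frame with tf, gene, n_support (motif instances).
#' @export
footprint_edge_map <- function(footprints, motifs, tss,
                               window = c(-5000L, 1000L)) {
  fp <- .as_granges(footprints, "footprint")
  mo <- .as_granges(motifs, "motif")
  ts <- .as_granges(tss, "TSS")
  if (is.null(mo$name)) stopf("motif records need a TF name field")
  if (is.null(ts$name)) stopf("TSS records need a gene name field")
  if (any(as.character(GenomicRanges::strand(ts)) == "*"))
    stopf("TSS records must carry strand (+/-)")
  if (length(mo) == 0 || length(fp) == 0 || length(ts) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      n_support = integer(0)))
  prom <- GenomicRanges::promoters(ts, upstream = -window[1L],
                                   downstream = window[2L])
  in_fp <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(mo, fp, ignore.strand = TRUE)))
  hits <- GenomicRanges::findOverlaps(mo, prom, type = "within",
                                      ignore.strand = TRUE)
  keep <- S4Vectors::queryHits(hits) %in% in_fp
  if (!any(keep))
    return(data.frame(tf = character(0), gene = character(0),
                      n_support = integer(0)))
  tf <- mo$name[S4Vectors::queryHits(hits)[keep]]
  gene <- ts$name[S4Vectors::subjectHits(hits)[keep]]
  agg <- stats::aggregate(list(n_support = rep(1L, length(tf))),
                          by = list(tf = tf, gene = gene), FUN = sum)
  agg <- agg[order(agg$tf, agg$gene), ]
  rownames(agg) <- NULL
  agg
}

#' Filter footprint edges by expression correlation
#'
#' Annotates each TF -> target edge with the correlation of the TF gene's
#' and the target's 8-day profiles and keeps edges with `|r| > min_abs_r`
#' (strict). TFs without a mappable gene id are dropped from the filtered
#' set and counted.
#'
#' @param edges data.frame from [footprint_edge_map()].
#' @param profiles genes x days day-mean matrix.
#' @param tf_map optional data.frame (tf, gene) mapping TF names to gene
#'   ids; by default TF names are used as gene ids directly.
#' @param min_abs_r correlation cut-off (strict >).
#' @return the filtered edge table with columns tf, tf_gene, gene, r;
#'   unmapped TF names in attribute `"unmapped"`.
#' @export
attach_correlations <- function(edges, profiles, tf_map = NULL,
                                min_abs_r = 0.6) {
  if (nrow(edges) == 0) {
    return(structure(cbind(edges[, c("tf", "gene"), drop = FALSE],
                           tf_gene = character(0), r = numeric(0)),
                     unmapped = character(0)))
  }
  tf_gene <- if (is.null(tf_map)) edges$tf
             else tf_map$gene[match(edges$tf, tf_map$tf)]
  mappable <- !is.na(tf_gene) & tf_gene %in% rownames(profiles) &
    edges$gene %in% rownames(profiles)
  unmapped <- sort(unique(edges$tf[!mappable]))
  out <- edges[mappable, , drop = FALSE]
  tfg <- tf_gene[mappable]
  r <- vapply(seq_len(nrow(out)), function(i)
    suppressWarnings(stats::cor(profiles[tfg[i], ], profiles[out$gene[i], ])),
    numeric(1))
  out$tf_gene <- tfg
  out$r <- r
  out <- out[!is.na(out$r) & abs(out$r) > min_abs_r, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, unmapped = unmapped)
}

#' Per-TF coverage of module-group genes
#'
#' For each TF, the fraction of placental-group and non-placental-group
#' genes among its targets, with the coverage flags used to rank
#' regulators (both groups >= 4%; per-group >= 5%; per-group >= 10%).
#'
#' @param edges edge table with columns `tf` and `gene`.
#' @param group_genes named list with `placental` and `non_placental`
#'   gene-id vectors.
#' @param thresholds coverage thresholds (fractions) for the three flags.
#' @return data.frame per TF with coverage percentages and flags.
#' @export
module_coverage_report <- function(edges, group_genes,
                                   thresholds = c(both = 0.04, five = 0.05,
                                                  ten = 0.10)) {
  pl <- group_genes$placental; np <- group_genes$non_placental
  if (length(pl) == 0 || length(np) == 0) stopf("empty module group")
  tfs <- sort(unique(edges$tf))
  rows <- lapply(tfs, function(tf) {
    tg <- unique(edges$gene[edges$tf == tf])
    cp <- length(intersect(tg, pl)) / length(pl)
    cn <- length(intersect(tg, np)) / length(np)
    data.frame(tf = tf, n_targets = length(tg),
               coverage_placental_pct = 100 * cp,
               coverage_nonplacental_pct = 100 * cn,
               both_ge_4 = cp >= thresholds[["both"]] & cn >= thresholds[["both"]],
               placental_ge_5 = cp >= thresholds[["five"]],
               nonplacental_ge_5 = cn >= thresholds[["five"]],
               placental_ge_10 = cp >= thresholds[["ten"]],
               nonplacental_ge_10 = cn >= thresholds[["ten"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlay a disease DE table on the differentiation results
#'
#' TR genes differentially expressed in both contexts are classified
#' concordant or discordant by the sign of their fold changes: the
#' differentiation fold change is the signed log2FC at the day of maximum
#' |log2FC|; the disease fold change comes from the supplied table.
#'
#' @param det a `de_result`.
#' @param disease_table data.frame with gene, log2fc and (unless
#'   `require_fdr = FALSE`) fdr.
#' @param tr_flags TR gene ids or named logical.
#' @param fc_threshold,q_threshold disease DE rule: `|log2fc| >=
#'   log2(fc_threshold)` and `fdr < q_threshold`.
#' @param require_fdr when `TRUE` (default) a missing fdr column is an
#'   error.
#' @param modules_diff,modules_disease optional named module labels per
#'   gene in each context, echoed in the output.
#' @return list with `table` (per TR gene DE in both contexts) and
#'   `discordant` (gene ids).
#' @export
disease_overlay <- function(det, disease_table, tr_flags,
                            fc_threshold = 2, q_threshold = 0.1,
                            require_fdr = TRUE,
                            modules_diff = NULL, modules_disease = NULL) {
  tr <- if (is.logical(tr_flags)) names(tr_flags)[tr_flags] else tr_flags
  if (!"fdr" %in% names(disease_table)) {
    if (require_fdr) stopf("disease table lacks the fdr column required by the DE rule")
    disease_table$fdr <- 0
  }
  de_tr <- intersect(tr, det$genes[det$is_de])
  idx <- match(de_tr, disease_table$gene)
  present <- !is.na(idx)
  de_tr <- de_tr[present]; idx <- idx[present]
  dlfc <- disease_table$log2fc[idx]
  dfdr <- disease_table$fdr[idx]
  de_dis <- abs(dlfc) >= log2(fc_threshold) & dfdr < q_threshold
  both <- de_tr[de_dis]
  fc_diff <- det$max_fc_signed[both]
  fc_dis <- dlfc[de_dis]
  disc <- sign(fc_diff) != sign(fc_dis)
  tab <- data.frame(gene = both,
                    log2fc_differentiation = unname(fc_diff),
                    log2fc_disease = fc_dis,
                    concordance = ifelse(disc, "discordant", "concordant"),
                    stringsAsFactors = FALSE)
  if (!is.null(modules_diff)) tab$module_differentiation <- unname(modules_diff[both])
  if (!is.null(modules_disease)) tab$module_disease <- unname(modules_disease[both])
  rownames(tab) <- NULL
  list(table = tab, discordant = both[disc])
}

#' Co-expression tightness of a gene set with a permutation p-value
#'
#' Statistic: mean pairwise |r| of the set's 8-day profiles. Null: `B`
#' random same-size subsets of the DE TR pool; `p = (#{null >= observed} +
#' 1) / (B + 1)`.
#'
#' @param profiles genes x days day-mean matrix.
#' @param gene_set genes whose tightness is tested (>= 2).
#' @param pool DE TR genes to draw null sets from.
#' @param B permutation rounds (> 0).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `null` (the null statistics).
#' @export
discordance_tightness <- function(profiles, gene_set, pool, B = 1000,
                                  seed = 1L) {
  if (length(gene_set) < 2) stopf("gene set must contain at least 2 genes")
  if (B <= 0) stopf("B must be positive")
  mean_abs_r <- function(g) {
    cc <- suppressWarnings(stats::cor(t(profiles[g, , drop = FALSE])))
    mean(abs(cc[upper.tri(cc)]), na.rm = TRUE)
  }
  obs <- mean_abs_r(gene_set)
  set.seed(seed)
  null <- vapply(seq_len(B), function(i)
    mean_abs_r(sample(pool, length(gene_set))), numeric(1))
  list(statistic = obs, p = (sum(null >= obs) + 1) / (B + 1), null = null)
}
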