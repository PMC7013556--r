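# 2x2 Fisher enrichment machinery: chromosome enrichment, module
# enrichment, generic gene-set (GMT) enrichment and coverage.
#
# Effect sizes are raw cross-product odds ratios OR = ad/bc (the form the
# field prints in module tables); a Haldane-Anscombe +0.5 correction is
# applied for display only when a cell is zero, and never enters the
# p-value. Exact p-values come from the hypergeometric distribution
# (stats::fisher.test), two-sided by the point-probability rule.

#' Fisher exact test on a 2x2 table with cross-product odds ratio
#'
#' Cell layout: `a` = in set & in group, `b` = in set & out of group,
#' `c` = out of set & in group, `d` = out & out, so that `OR = ad/bc`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"two.sided"` (point-probability rule), `"greater"`
#'   or `"less"`.
#' @return list with `odds_ratio` (cross-product; `NA` when a margin is
#'   empty), `p`, and `haldane` (`TRUE` when the displayed OR used the
#'   +0.5 correction).
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cells must be non-negative integers")
  margin_empty <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  haldane <- !margin_empty && any(cells == 0)
  or <- if (margin_empty) NA_real_
        else if (haldane) (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
        else a * d / (b * c)
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                          alternative = alternative)$p.value
  list(odds_ratio = or, p = min(p, 1), haldane = haldane)
}

# Enrichment record from group/flag counts within a universe.
.enrich_counts <- function(n_group, n_flag_in_group, n_universe, n_flag,
                           alternative = "two.sided") {
  a <- n_flag_in_group
  b <- n_group - a
  c <- n_flag - a
  d <- n_universe - n_group - c
  if (min(a, b, c, d) < 0) stopf("inconsistent counts for a 2x2 table")
  ft <- fisher_2x2(a, b, c, d, alternative)
  data.frame(a = a, b = b, c = c, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p, haldane = ft$haldane)
}

#' Enrichment of a flag within count-defined groups
#'
#' Direct counts interface used for module tables summarised as printed
#' counts (group size, flagged-in-group, universe size, flagged-in-universe).
#'
#' @param n_group,n_flag_in_group,n_universe,n_flag integer counts.
#' @param alternative passed to [fisher_2x2()].
#' @return data.frame with cells, `odds_ratio` and `p`.
#' @export
enrichment_from_counts <- function(n_group, n_flag_in_group, n_universe,
                                   n_flag, alternative = "two.sided") {
  out <- do.call(rbind, Map(function(g, f)
    .enrich_counts(g, f, n_universe, n_flag, alternative),
    n_group, n_flag_in_group))
  rownames(out) <- NULL
  out
}

#' Per-module enrichment of a gene flag (module-table statistics)
#'
#' For each module, a Fisher 2x2 of module membership against the flag
#' within the universe (the DE gene set for the canonical module table).
#'
#' @param modules named list of gene-id vectors, or a `module_set` from
#'   [detect_modules()] (unassigned genes excluded).
#' @param flags character vector of flagged genes, or named logical.
#' @param universe character vector of universe gene ids.
#' @param alternative passed to [fisher_2x2()].
#' @return data.frame with module, n, n_flagged, cells, odds_ratio, p and
#'   BH q across modules.
#' @export
module_enrichment <- function(modules, flags, universe,
                              alternative = "two.sided") {
  if (inherits(modules, "module_set")) modules <- module_gene_lists(modules)
  if (is.logical(flags)) flags <- names(flags)[flags]
  flags <- intersect(flags, universe)
  bad <- !vapply(modules, function(g) all(g %in% universe), TRUE)
  if (any(bad))
    stopf("module(s) not contained in universe: %s",
          paste(names(modules)[bad], collapse = ", "))
  rows <- lapply(names(modules), function(m) {
    g <- modules[[m]]
    rec <- .enrich_counts(length(g), sum(g %in% flags),
                          length(universe), length(flags), alternative)
    cbind(data.frame(module = m, n = length(g), n_flagged = sum(g %in% flags)),
          rec)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Per-chromosome enrichment of a gene set
#'
#' @param annotation data.frame with `gene` and `chromosome`.
#' @param gene_set character vector (must lie within the universe).
#' @param universe character vector of gene ids; defaults to all annotated.
#' @param alternative passed to [fisher_2x2()].
#' @return data.frame with chromosome, counts, odds_ratio, p, q.
#' @export
chromosome_enrichment <- function(annotation, gene_set,
                                  universe = annotation$gene,
                                  alternative = "two.sided") {
  if (!all(gene_set %in% universe)) stopf("gene_set must be a subset of the universe")
  ann <- annotation[annotation$gene %in% universe, ]
  chroms <- unique(ann$chromosome)
  rows <- lapply(chroms, function(ch) {
    on_ch <- ann$gene[ann$chromosome == ch]
    rec <- .enrich_counts(length(on_ch), sum(on_ch %in% gene_set),
                          nrow(ann), length(gene_set), alternative)
    cbind(data.frame(chromosome = ch, n = length(on_ch),
                     n_in_set = sum(on_ch %in% gene_set)), rec)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(-ifelse(is.na(out$odds_ratio), -Inf, out$odds_ratio)), ]
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: term, description, gene ids.
#'
#' @param path file path.
#' @return named list of gene-id vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) stopf("malformed GMT line(s): %s", paste(which(short), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), ""), path)
}

#' Gene-set (GMT) enrichment with coverage percentages
#'
#' Each term is intersected with the universe before testing; terms
#' disjoint from the universe are dropped with a warning. Enrichment
#' p-values are one-sided (over-representation); coverage is the
#' percentage of the query set inside the term.
#'
#' @param gene_set query gene ids.
#' @param universe universe gene ids.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param q_threshold significance threshold stored alongside the results.
#' @return data.frame with term, sizes, overlap, odds_ratio, p, q,
#'   coverage_pct and significant flag.
#' @export
gmt_enrichment <- function(gene_set, universe, collection, q_threshold = 0.2) {
  if (length(universe) == 0 || length(gene_set) == 0)
    stopf("gene_set and universe must be non-empty")
  gene_set <- intersect(gene_set, universe)
  terms <- lapply(collection, intersect, universe)
  empty <- vapply(terms, length, 1L) == 0L
  if (any(empty)) {
    warnf("dropping %d term(s) disjoint from the universe", sum(empty))
    terms <- terms[!empty]
  }
  if (length(terms) == 0) stopf("no terms overlap the universe")
  rows <- lapply(names(terms), function(tn) {
    tg <- terms[[tn]]
    rec <- .enrich_counts(length(tg), length(intersect(tg, gene_set)),
                          length(universe), length(gene_set),
                          alternative = "greater")
    cbind(data.frame(term = tn, term_size = length(tg),
                     overlap = length(intersect(tg, gene_set))), rec)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$coverage_pct <- 100 * out$overlap / length(gene_set)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out[order(out$p), ]
}
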