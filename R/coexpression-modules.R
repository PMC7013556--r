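# Weighted co-expression module detection on day-mean profiles.
#
# Adjacency is unsigned, a_ij = |cor_ij|^beta, with beta chosen for
# approximate scale-free topology; similarity is the topological overlap
# measure (TOM); modules come from average-linkage clustering of 1 - TOM
# with a static cut at a quantile of the merge heights. With only 8 day
# means per gene the correlations carry few degrees of freedom, so module
# claims rest on recovery benchmarks rather than inference.

.wgcna_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Day-mean expression profiles
#'
#' Per-gene mean over replicates for each day, optionally as log2FC
#' relative to day 0.
#'
#' @inheritParams sample_design
#' @param genes gene subset (default all).
#' @param type `"log2"` (day means) or `"lfc"` (minus the day-0 mean).
#' @return genes x days numeric matrix.
#' @export
day_mean_profiles <- function(expr, genes = rownames(expr),
                              type = c("log2", "lfc")) {
  type <- match.arg(type)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stopf("unknown gene(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  dm <- .day_means(expr)[genes, , drop = FALSE]
  if (type == "lfc") dm <- dm - dm[, 1L]
  dm
}

# |cor|^beta adjacency with zero diagonal; constant profiles dropped with a
# warning (their correlation is undefined).
.adjacency <- function(profiles, beta) {
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant profile(s) with undefined correlation", sum(sds == 0))
    profiles <- profiles[sds > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(profiles)))^beta
  diag(a) <- 0
  a
}

#' Choose the soft-thresholding power for scale-free topology
#'
#' For each candidate power, forms unsigned adjacency, computes per-gene
#' connectivity `k`, bins log10 k, and regresses log10 p(k) on the bin
#' means of log10 k; returns the smallest power whose R-squared reaches
#' `target_r2` (>= 5 occupied bins required), else falls back to
#' `fallback` with a warning.
#'
#' @param profiles genes x days matrix.
#' @param powers candidate integer powers.
#' @param target_r2 required scale-free fit R-squared.
#' @param n_bins degree-distribution bins.
#' @param fallback power returned when no candidate fits.
#' @return chosen power, with the scan table in attribute `"fit"`.
#' @export
pick_soft_power <- function(profiles, powers = 1:20, target_r2 = 0.8,
                            n_bins = 10, fallback = 9) {
  if (nrow(profiles) < 3) stopf("need at least 3 profiles")
  fit <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_)
  for (i in seq_along(powers)) {
    a <- .adjacency(profiles, powers[i])
    k <- rowSums(a)
    k <- k[k > 0]
    if (length(unique(k)) < 5) next
    bins <- cut(log10(k), breaks = n_bins)
    pk <- tapply(k, bins, length) / length(k)
    km <- tapply(log10(k), bins, mean)
    keep <- !is.na(pk) & pk > 0
    if (sum(keep) < 5) next
    m <- stats::lm(log10(pk[keep]) ~ km[keep])
    fit$r_squared[i] <- summary(m)$r.squared
    fit$slope[i] <- stats::coef(m)[2L]
  }
  ok <- which(!is.na(fit$r_squared) & fit$r_squared >= target_r2)
  if (length(ok) == 0) {
    warnf("no power reached scale-free R^2 >= %.2f; falling back to beta = %d",
          target_r2, fallback)
    beta <- fallback
  } else beta <- powers[ok[1L]]
  structure(beta, fit = fit)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` on
#' unsigned adjacency, with unit diagonal.
#'
#' @param profiles genes x days matrix (ignored when `adjacency` given).
#' @param beta soft power.
#' @param adjacency optional precomputed symmetric adjacency in \[0,1\]
#'   (diagonal ignored).
#' @return symmetric TOM matrix with entries in \[0, 1\].
#' @export
tom_matrix <- function(profiles = NULL, beta = 6, adjacency = NULL) {
  a <- if (is.null(adjacency)) .adjacency(profiles, beta) else {
    x <- as.matrix(adjacency); diag(x) <- 0; x
  }
  if (nrow(a) < 2) stopf("need at least 2 genes")
  k <- rowSums(a)
  shared <- crossprod(a)            # sum_u a_iu a_uj (diag(a) = 0)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' the `cut_quantile` of the merge heights; clusters smaller than
#' `min_size` become unassigned. Modules are labelled M1..Mk by decreasing
#' size and carry conventional module colors.
#'
#' @param tom TOM matrix from [tom_matrix()].
#' @param min_size minimum module size.
#' @param cut_quantile quantile of merge heights for the static cut.
#' @return object of class `module_set`: `labels` (named character;
#'   `"unassigned"` allowed), `colors`, `sizes`, `tree`, `cut_height`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_quantile = 0.99) {
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < min_size) {
    warnf("fewer genes (%d) than min_size (%d); all genes unassigned", nrow(tom), min_size)
    labels <- stats::setNames(rep("unassigned", nrow(tom)), genes)
    return(structure(list(labels = labels, colors = character(0),
                          sizes = integer(0), tree = NULL,
                          cut_height = NA_real_), class = "module_set"))
  }
  d <- 1 - tom
  d[d < 0] <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  # average linkage is monotone; repair floating-point tie inversions
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  cut_height <- stats::quantile(tree$height, cut_quantile, names = FALSE)
  # tolerance so merges exactly at the cut (floating-point ties) stay merged
  raw <- stats::cutree(tree, h = cut_height + 1e-8)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("unassigned", length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- sprintf("M%d", i)
  }
  names(labels) <- genes
  mods <- sprintf("M%d", seq_along(keep))
  colors <- stats::setNames(
    rep_len(.wgcna_colors, length(mods)), mods)
  structure(list(labels = labels,
                 colors = colors,
                 sizes = stats::setNames(as.integer(table(labels)[mods]), mods),
                 tree = tree, cut_height = cut_height),
            class = "module_set")
}

#' Genes of each module as a named list
#' @param modules a `module_set`.
#' @param include_unassigned include the unassigned set.
#' @return named list of gene-id vectors.
#' @export
module_gene_lists <- function(modules, include_unassigned = FALSE) {
  labs <- modules$labels
  keep <- sort(unique(labs))
  if (!include_unassigned) keep <- setdiff(keep, "unassigned")
  keep <- keep[order(nchar(keep), keep)]   # M1 < M2 < ... < M10
  stats::setNames(lapply(keep, function(m) names(labs)[labs == m]), keep)
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$labels), "genes,",
      length(x$sizes), "modules\n")
  if (length(x$sizes)) print(x$sizes)
  cat("unassigned:", sum(x$labels == "unassigned"), "\n")
  invisible(x)
}

#' Classify modules into placental / non-placental groups
#'
#' A module is "placental" when its PPE enrichment (one-sided Fisher, OR >
#' 1) is significant at `alpha`; all others are "non-placental".
#'
#' @param modules a `module_set` or named list of gene vectors.
#' @param ppe_flags PPE gene ids (or named logical vector).
#' @param universe gene universe (default: all genes carrying a module
#'   label, i.e. the DE set that entered clustering).
#' @param alpha significance level.
#' @return named character vector of group labels per module, with the
#'   enrichment table in attribute `"enrichment"`.
#' @export
classify_module_groups <- function(modules, ppe_flags, universe = NULL,
                                   alpha = 0.05) {
  lists <- if (inherits(modules, "module_set")) module_gene_lists(modules) else modules
  if (is.null(universe))
    universe <- if (inherits(modules, "module_set")) names(modules$labels)
                else unique(unlist(lists))
  if (is.logical(ppe_flags)) ppe_flags <- names(ppe_flags)[ppe_flags]
  if (length(intersect(ppe_flags, universe)) == 0) {
    warnf("no PPE genes in the universe; all modules non-placental")
    return(structure(stats::setNames(rep("non-placental", length(lists)),
                                     names(lists)),
                     enrichment = NULL))
  }
  enr <- module_enrichment(lists, ppe_flags, universe, alternative = "greater")
  grp <- ifelse(!is.na(enr$odds_ratio) & enr$odds_ratio > 1 & enr$p < alpha,
                "placental", "non-placental")
  structure(stats::setNames(grp, enr$module), enrichment = enr)
}

#' Module and group mean |log2FC| trajectories
#'
#' Per-module mean of |log2FC vs day 0| per day, plus group-level curves
#' (the gene-weighted mean over member modules).
#'
#' @param modules a `module_set` or named list of gene vectors.
#' @param det a `de_result` covering the module genes.
#' @param groups optional named group label per module (from
#'   [classify_module_groups()]).
#' @return list with `module_curves` and `group_curves` (matrices, rows =
#'   module/group, columns = days).
#' @export
module_trajectories <- function(modules, det, groups = NULL) {
  lists <- if (inherits(modules, "module_set")) module_gene_lists(modules) else modules
  if (any(vapply(lists, length, 1L) == 0)) stopf("empty module")
  abs_lfc <- abs(det$lfc_day0)
  curves <- t(vapply(lists, function(g)
    colMeans(abs_lfc[g, , drop = FALSE]), numeric(ncol(abs_lfc))))
  rownames(curves) <- names(lists)
  group_curves <- NULL
  if (!is.null(groups)) {
    gl <- split(names(lists), groups[names(lists)])
    group_curves <- t(vapply(gl, function(ms) {
      genes <- unlist(lists[ms], use.names = FALSE)
      colMeans(abs_lfc[genes, , drop = FALSE])
    }, numeric(ncol(abs_lfc))))
  }
  list(module_curves = curves, group_curves = group_curves)
}
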