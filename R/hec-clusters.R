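# High-expression-change (HEC) gene selection and temporal clustering.
#
# The HEC threshold is read off the curve of PPE-enrichment odds ratios
# as a function of the log2 fold-change threshold, at the point where the
# curve's slope turns sharply upward. The computable rule implemented
# here takes the smallest grid point whose forward difference exceeds
# slope_factor times the median positive forward difference; a manual
# override (default 2.5) wins when supplied, with the automatic choice
# logged.

#' PPE-enrichment odds-ratio curve over fold-change thresholds
#'
#' Per grid point t, a Fisher 2x2 of (max |log2FC| >= t) against the PPE
#' flag within the universe. Odds ratios with an empty margin are `NA`.
#'
#' @param max_abs_fc named numeric vector of per-gene max |log2FC|.
#' @param ppe_flags PPE gene ids or named logical vector.
#' @param universe gene universe (default: names of `max_abs_fc`).
#' @param grid threshold grid (log2 units).
#' @return data.frame with t, a, b, c, d, odds_ratio, p.
#' @export
ppe_enrichment_curve <- function(max_abs_fc, ppe_flags,
                                 universe = names(max_abs_fc),
                                 grid = seq(0.1, 4.0, by = 0.1)) {
  if (length(universe) == 0) stopf("empty universe")
  fc <- max_abs_fc[universe]
  ppe <- if (is.logical(ppe_flags)) names(ppe_flags)[ppe_flags] else ppe_flags
  is_ppe <- universe %in% ppe
  rows <- lapply(grid, function(t) {
    above <- fc >= t
    a <- sum(above & is_ppe); b <- sum(above & !is_ppe)
    c <- sum(!above & is_ppe); d <- sum(!above & !is_ppe)
    ft <- fisher_2x2(a, b, c, d)
    or <- if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
      NA_real_ else a * d / (b * c)
    data.frame(t = t, a = a, b = b, c = c, d = d,
               odds_ratio = or, p = ft$p)
  })
  do.call(rbind, rows)
}

#' Select the high-expression-change threshold from the enrichment curve
#'
#' Returns the smallest grid point whose forward difference in odds ratio
#' exceeds `slope_factor` times the median positive forward difference.
#' When `override` is supplied it wins and the automatic choice is logged
#' as a message and kept in attribute `"auto"`.
#'
#' @param curve data.frame from [ppe_enrichment_curve()].
#' @param slope_factor multiplier on the median positive forward difference.
#' @param override manual threshold that takes precedence (2.5 is the
#'   canonical choice for this assay).
#' @return the chosen threshold (log2 units).
#' @export
select_hec_threshold <- function(curve, slope_factor = 3, override = NULL) {
  ok <- which(!is.na(curve$odds_ratio))
  auto <- NA_real_
  if (length(ok) >= 5) {
    idx <- ok[which(diff(ok) == 1)]          # consecutive defined pairs
    dif <- curve$odds_ratio[idx + 1L] - curve$odds_ratio[idx]
    pos <- dif[dif > 0]
    if (length(pos) > 0) {
      thr <- slope_factor * stats::median(pos)
      hit <- which(dif > thr)
      if (length(hit)) auto <- curve$t[idx[hit[1L]]]
    }
  } else if (is.null(override)) {
    stopf("need at least 5 defined grid points")
  }
  if (!is.null(override)) {
    if (!is.na(auto))
      message(sprintf("HEC threshold override %.2f used (automatic choice: %.2f)",
                      override, auto))
    return(structure(override, auto = auto))
  }
  if (is.na(auto)) stopf("no slope breakpoint found in the enrichment curve")
  structure(auto, auto = auto)
}

#' Cluster HEC gene trajectories into temporal clusters
#'
#' Hierarchical clustering (correlation distance `1 - r`, average linkage)
#' of log2FC-vs-day0 trajectories, cut to `k` clusters. Clusters are
#' renumbered C1..Ck by the time-to-half-maximum of their mean |trajectory|
#' (earliest first), so cluster identity tracks trajectory shape, not
#' amplitude. With fewer distinct profiles than `k`, `k` is reduced with a
#' warning.
#'
#' @param traj genes x days matrix of log2FC vs day 0 (a day-0 column of
#'   zeros is allowed and used).
#' @param k number of clusters.
#' @return list with `cluster` (named character C1..Ck), `means` (cluster
#'   mean trajectories) and `k`.
#' @export
cluster_trajectories <- function(traj, k = 5) {
  keep <- apply(traj, 1L, function(x) stats::sd(x) > 0)
  if (sum(keep) < 1) stopf("no non-constant trajectories to cluster")
  traj <- traj[keep, , drop = FALSE]
  n_distinct <- nrow(unique(round(traj, 10)))
  if (n_distinct < k) {
    warnf("only %d distinct profiles; reducing k from %d", n_distinct, k)
    k <- n_distinct
  }
  if (nrow(traj) < k) k <- nrow(traj)
  cl <- if (k == 1L) stats::setNames(rep(1L, nrow(traj)), rownames(traj)) else {
    d <- stats::as.dist(1 - stats::cor(t(traj)))
    stats::cutree(stats::hclust(d, method = "average"), k = k)
  }
  means <- t(vapply(sort(unique(cl)), function(g)
    colMeans(traj[cl == g, , drop = FALSE]), numeric(ncol(traj))))
  # time to half maximum of |mean trajectory|, earliest = C1
  t_half <- apply(means, 1L, function(m) {
    am <- abs(m)
    which(am >= max(am) / 2)[1L]
  })
  ord <- order(t_half, seq_along(t_half))
  new_lab <- stats::setNames(sprintf("C%d", seq_along(ord)), sort(unique(cl))[ord])
  cluster <- stats::setNames(new_lab[as.character(cl)], names(cl))
  means <- means[ord, , drop = FALSE]
  rownames(means) <- sprintf("C%d", seq_len(k))
  colnames(means) <- colnames(traj)
  list(cluster = cluster, means = means, k = k)
}

#' Full HEC analysis
#'
#' Computes the enrichment curve, selects the threshold, derives the HEC
#' set, its enrichment record at the threshold, and the temporal clusters.
#'
#' @param det a `de_result`.
#' @param ppe_flags PPE gene ids or named logical.
#' @param universe enrichment universe; the default is every measured gene
#'   (the curve may alternatively be restricted to DE genes).
#' @param grid threshold grid.
#' @param slope_factor,override see [select_hec_threshold()].
#' @param k temporal cluster count.
#' @return object of class `hec_result`: curve, threshold, hec_genes,
#'   enrichment_at_threshold, clusters.
#' @export
hec_analysis <- function(det, ppe_flags, universe = det$genes,
                         grid = seq(0.1, 4.0, by = 0.1),
                         slope_factor = 3, override = 2.5, k = 5) {
  curve <- ppe_enrichment_curve(det$max_abs_lfc, ppe_flags, universe, grid)
  t_star <- select_hec_threshold(curve, slope_factor, override)
  hec <- names(det$max_abs_lfc)[det$max_abs_lfc >= t_star &
                                  names(det$max_abs_lfc) %in% universe]
  ppe <- if (is.logical(ppe_flags)) names(ppe_flags)[ppe_flags] else ppe_flags
  enr <- .enrich_counts(length(hec), length(intersect(hec, ppe)),
                        length(universe), length(intersect(ppe, universe)))
  traj <- cbind(`0` = 0, det$lfc_day0[hec, , drop = FALSE])
  clusters <- if (length(hec) >= 2) cluster_trajectories(traj, k) else NULL
  structure(list(curve = curve, threshold = as.numeric(t_star),
                 threshold_auto = attr(t_star, "auto"),
                 hec_genes = hec, enrichment_at_threshold = enr,
                 clusters = clusters), class = "hec_result")
}
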