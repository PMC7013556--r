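# Topology-based pathway impact analysis.
#
# Per-gene perturbation factors PF solve PF = dE + B PF, where B[g,u] =
# sign(u->g) / N_ds(u) normalizes each upstream gene's influence by its
# number of downstream edges. The pathway statistic tA accumulates
# Acc = PF - dE over genes. Over-representation (pORA, hypergeometric
# upper tail) and perturbation (pAcc, bootstrap with median-centred null)
# combine into the pathway p-value pG = c - c ln c with c = pORA * pAcc.

#' Construct a signed directed pathway graph
#'
#' @param id pathway identifier.
#' @param edges data.frame with source, target and sign (+1 activation,
#'   -1 inhibition).
#' @param nodes optional node set (defaults to the union of edge
#'   endpoints); extra isolated nodes are allowed.
#' @param name optional display name.
#' @return object of class `pathway_graph` with `N_ds` (downstream edge
#'   counts) precomputed.
#' @export
pathway_graph <- function(id, edges, nodes = NULL, name = id) {
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stopf("edges need source/target/sign columns")
  if (!all(edges$sign %in% c(-1, 1)))
    stopf("edge signs must be +1 (activation) or -1 (inhibition)")
  nodes <- union(nodes, union(edges$source, edges$target))
  n_ds <- table(factor(edges$source, levels = nodes))
  structure(list(id = id, name = name, nodes = nodes, edges = edges,
                 n_downstream = stats::setNames(as.integer(n_ds), nodes)),
            class = "pathway_graph")
}

# Influence matrix B[g,u] = sign(u->g) / N_ds(u).
.influence_matrix <- function(graph) {
  n <- length(graph$nodes)
  b <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  b[cbind(match(e$target, graph$nodes), match(e$source, graph$nodes))] <-
    e$sign / graph$n_downstream[e$source]
  b
}

#' Gene perturbation factors and accumulated perturbation
#'
#' Solves `PF = (I - B)^{-1} dE`; genes absent from `delta_e` contribute
#' 0. A singular system marks the pathway non-evaluable rather than
#' raising an error.
#'
#' @param graph a `pathway_graph`.
#' @param delta_e named numeric vector of log2 fold changes (0 for
#'   genes that are not differentially expressed).
#' @return list with `pf`, `acc` (`PF - dE`), `ta` (`sum(acc)`) and
#'   `status` (`"ok"` or `"non-evaluable"`).
#' @export
perturbation_factors <- function(graph, delta_e) {
  de <- stats::setNames(rep(0, length(graph$nodes)), graph$nodes)
  common <- intersect(names(delta_e), graph$nodes)
  de[common] <- delta_e[common]
  b <- .influence_matrix(graph)
  imb <- diag(length(de)) - b
  pf <- tryCatch(solve(imb, de), error = function(e) NULL)
  if (is.null(pf) || rcond(imb) < 1e-12) {
    return(list(pf = NULL, acc = NULL, ta = NA_real_, status = "non-evaluable"))
  }
  names(pf) <- graph$nodes
  acc <- pf - de
  list(pf = pf, acc = acc, ta = sum(acc), status = "ok")
}

#' Over-representation p-value for DE genes on a pathway
#'
#' Hypergeometric upper tail `P(X >= n_de_on_pathway)`.
#'
#' @param n_de_on_pathway DE genes on the pathway.
#' @param n_pathway measured pathway genes.
#' @param n_de_universe DE genes in the universe.
#' @param n_universe measured genes in the universe.
#' @return the p-value.
#' @export
p_ora <- function(n_de_on_pathway, n_pathway, n_de_universe, n_universe) {
  if (n_de_on_pathway > min(n_pathway, n_de_universe) ||
      n_pathway > n_universe || n_de_universe > n_universe)
    stopf("inconsistent over-representation counts")
  stats::phyper(n_de_on_pathway - 1, n_de_universe,
                n_universe - n_de_universe, n_pathway, lower.tail = FALSE)
}

# Linear weights: tA = sum(w * dE) with w = colSums((I - B)^{-1}) - 1.
.ta_weights <- function(graph) {
  b <- .influence_matrix(graph)
  imb <- diag(nrow(b)) - b
  inv <- tryCatch(solve(imb), error = function(e) NULL)
  if (is.null(inv) || rcond(imb) < 1e-12) return(NULL)
  stats::setNames(colSums(inv) - 1, graph$nodes)
}

#' Bootstrap perturbation p-value
#'
#' Draws `B` null rounds, each placing `n_de_on_pathway` fold changes
#' sampled from the observed DE pool onto uniformly chosen pathway genes,
#' recomputes tA (via its linearity in dE), median-centres the null, and
#' returns `(#{|tA_b - med| >= |tA_obs - med|} + 1) / (B + 1)`.
#'
#' @param graph a `pathway_graph`.
#' @param delta_pool observed DE log2 fold changes to resample.
#' @param n_de_on_pathway DE genes to place per round (0 gives pAcc = 1).
#' @param ta_obs observed tA.
#' @param B bootstrap rounds (> 0).
#' @param seed integer seed.
#' @return the pAcc value in `[1/(B+1), 1]`.
#' @export
p_acc <- function(graph, delta_pool, n_de_on_pathway, ta_obs, B = 2000,
                  seed = 1L) {
  if (B <= 0) stopf("B must be positive")
  if (n_de_on_pathway == 0) return(1)
  if (length(delta_pool) == 0) stopf("empty fold-change pool")
  w <- .ta_weights(graph)
  if (is.null(w)) return(NA_real_)
  set.seed(seed)
  n <- length(w)
  m <- min(n_de_on_pathway, n)
  pos <- vapply(seq_len(B), function(i) sample.int(n, m), integer(m))
  fc <- matrix(sample(delta_pool, B * m, replace = TRUE), nrow = m)
  ta_null <- colSums(matrix(w[pos], nrow = m) * fc)
  med <- stats::median(ta_null)
  (sum(abs(ta_null - med) >= abs(ta_obs - med)) + 1) / (B + 1)
}

#' Combine over-representation and perturbation p-values
#'
#' `pG = c - c ln(c)` with `c = pORA * pAcc` (the product-based
#' combination of two independent uniform p-values).
#'
#' @param p_ora,p_acc p-values in (0, 1].
#' @return the combined p-value.
#' @export
combine_p <- function(p_ora, p_acc) {
  if (any(c(p_ora, p_acc) <= 0) || any(c(p_ora, p_acc) > 1))
    stopf("p-values must lie in (0, 1]")
  cc <- p_ora * p_acc
  cc - cc * log(cc)
}

#' Impact analysis over a collection of pathway graphs
#'
#' Per pathway: measured and DE gene counts, perturbation factors and tA,
#' pORA, pAcc, pG, BH q across evaluable pathways, and bar-plot data of
#' genes ranked by |Acc|.
#'
#' @param graphs list of `pathway_graph` objects.
#' @param delta_e named log2FC vector for DE genes (non-DE genes omitted
#'   or 0).
#' @param universe measured gene universe.
#' @param B bootstrap rounds for pAcc.
#' @param seed integer seed; each pathway derives its own stream.
#' @return list with `results` (one row per pathway) and `details`
#'   (per-pathway PF/Acc tables).
#' @export
analyze_pathways <- function(graphs, delta_e, universe, B = 2000, seed = 1L) {
  if (length(graphs) == 0) stopf("no pathway graphs supplied")
  delta_e <- delta_e[delta_e != 0]
  de_genes <- intersect(names(delta_e), universe)
  details <- list()
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    measured <- intersect(g$nodes, universe)
    n_path <- length(measured)
    if (n_path == 0) {
      return(data.frame(pathway = g$id, n = 0L, n_de = 0L, ta = NA_real_,
                        p_ora = NA_real_, p_acc = NA_real_, p_g = NA_real_,
                        status = "non-evaluable"))
    }
    on_de <- intersect(measured, de_genes)
    pert <- perturbation_factors(g, delta_e)
    if (pert$status != "ok") {
      return(data.frame(pathway = g$id, n = n_path, n_de = length(on_de),
                        ta = NA_real_, p_ora = NA_real_, p_acc = NA_real_,
                        p_g = NA_real_, status = "non-evaluable"))
    }
    details[[g$id]] <<- data.frame(
      gene = g$nodes, pf = pert$pf, acc = pert$acc,
      row.names = NULL)[order(-abs(pert$acc)), ]
    pora <- p_ora(length(on_de), n_path, length(de_genes), length(universe))
    pacc <- p_acc(g, unname(delta_e[de_genes]), length(on_de), pert$ta,
                  B = B, seed = .child_seed(seed, i))
    data.frame(pathway = g$id, n = n_path, n_de = length(on_de),
               ta = pert$ta, p_ora = pora, p_acc = pacc,
               p_g = combine_p(pora, pacc), status = "ok")
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- res$status == "ok"
  res$q[ok] <- bh_adjust(res$p_g[ok])
  rownames(res) <- NULL
  list(results = res, details = details)
}
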