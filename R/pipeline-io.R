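# File formats, configuration and end-to-end orchestration.
#
# TSV everywhere, BED for intervals, GMT for gene sets, JSON for the run
# summary. Every run writes its fully resolved configuration next to the
# results so any number in the summary can be recomputed from the stage
# outputs.

#' Pipeline configuration with canonical defaults
#'
#' All stage parameters in one list; the defaults are the canonical
#' analysis choices (DE rule FC >= 2 with FDR < 0.1; co-expression network
#' |r| >= 0.9; footprint-edge correlation |r| > 0.6; HEC threshold
#' override 2.5; five temporal clusters; gene-set significance q < 0.2),
#' so running without arguments reproduces the canonical analysis path.
#'
#' @param ... overrides of the defaults listed below; unknown keys are
#'   rejected.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    fc_threshold = 2, q_threshold = 0.1,
    background_level = NULL, constitutive_ratio = 4,
    soft_powers = 1:20, target_r2 = 0.8, min_module_size = 30,
    cut_quantile = 0.99, module_alpha = 0.05,
    hec_grid = seq(0.1, 4.0, by = 0.1), hec_override = 2.5,
    slope_factor = 3, k_clusters = 5,
    r_min = 0.9, min_abs_r = 0.6,
    footprint_window = c(-5000L, 1000L),
    coverage_thresholds = c(both = 0.04, five = 0.05, ten = 0.10),
    gmt_q = 0.2, impact_B = 2000, tightness_B = 1000,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Write / read an expression matrix as TSV
#'
#' Layout: first column `gene`, then one column per sample named
#' `day<d>_rep<r>`.
#'
#' @param expr genes x samples log2 matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv` returns the validated matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stopf("%s: missing 'gene' column", path)
  if (anyDuplicated(df$gene)) stopf("%s: duplicate gene ids", path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  validate_expression(m)
  m
}

#' Read a gene annotation TSV
#'
#' Columns: gene, chromosome, is_ppe, is_tr; optional tss_chrom, tss_pos
#' (0-based), tss_strand.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "is_ppe", "is_tr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stopf("%s: duplicate gene ids", path)
  df$is_ppe <- as.logical(df$is_ppe); df$is_tr <- as.logical(df$is_tr)
  if ("tss_strand" %in% names(df) &&
      !all(df$tss_strand %in% c("+", "-", NA)))
    stopf("%s: tss_strand must be + or -", path)
  df
}

#' Read a disease differential-expression TSV (gene, log2fc, fdr)
#' @param path file path.
#' @return data.frame.
#' @export
read_disease_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "log2fc"), names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df
}

#' Read pathway graphs from an edge-list TSV
#'
#' Columns: pathway_id, source, target, sign.
#'
#' @param path file path.
#' @return named list of `pathway_graph` objects.
#' @export
read_pathways_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("pathway_id", "source", "target", "sign"), names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  by_id <- split(df, df$pathway_id)
  lapply(by_id, function(e) pathway_graph(e$pathway_id[1L],
                                          e[, c("source", "target", "sign")]))
}

#' Write pathway graphs to an edge-list TSV
#' @param graphs list of `pathway_graph` objects.
#' @param path file path.
#' @export
write_pathways_tsv <- function(graphs, path) {
  df <- do.call(rbind, lapply(graphs, function(g)
    cbind(pathway_id = g$id, g$edges)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a BED-style data.frame (0-based half-open) to a BED file
#' @param df data.frame with chrom, start, end and optional name, score,
#'   strand.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Load and cross-validate the pipeline input bundle
#'
#' @param expression_path expression TSV (required).
#' @param annotation_path annotation TSV (required).
#' @param disease_path,gmt_path,pathways_path optional inputs.
#' @return list with `expr`, `annotation`, and any optional tables; genes
#'   present in the expression matrix but absent from the annotation are
#'   kept with a warning and treated as unflagged.
#' @export
load_inputs <- function(expression_path, annotation_path,
                        disease_path = NULL, gmt_path = NULL,
                        pathways_path = NULL) {
  expr <- read_expression_tsv(expression_path)
  ann <- read_annotation_tsv(annotation_path)
  missing <- setdiff(rownames(expr), ann$gene)
  if (length(missing)) {
    warnf("%d gene(s) missing from the annotation; treated as unflagged",
          length(missing))
    ann <- rbind(ann[, c("gene", "chromosome", "is_ppe", "is_tr")],
                 data.frame(gene = missing, chromosome = NA_character_,
                            is_ppe = FALSE, is_tr = FALSE))
  }
  ann <- ann[match(rownames(expr), ann$gene), ]
  out <- list(expr = expr, annotation = ann)
  if (!is.null(disease_path)) out$disease <- read_disease_tsv(disease_path)
  if (!is.null(gmt_path)) out$gmt <- read_gmt(gmt_path)
  if (!is.null(pathways_path)) out$pathways <- read_pathways_tsv(pathways_path)
  message(sprintf("loaded %d genes x %d samples; %d PPE, %d TR",
                  nrow(expr), ncol(expr), sum(ann$is_ppe), sum(ann$is_tr)))
  out
}

#' Run the full differentiation analysis pipeline
#'
#' Chains differential expression -> chromosome/module enrichment ->
#' co-expression modules -> HEC threshold and temporal clusters -> TR
#' networks -> pathway impact -> disease overlay, and writes all stage
#' outputs plus a machine-readable summary under `out_dir`.
#'
#' @param expr genes x samples log2 matrix.
#' @param annotation annotation data.frame (gene, chromosome, is_ppe,
#'   is_tr).
#' @param config a [pipeline_config()].
#' @param disease_table optional disease DE table for the overlay.
#' @param gmt optional gene-set collection for GMT enrichment of DE genes.
#' @param pathways optional list of `pathway_graph` objects.
#' @param footprints,motifs,tss optional interval inputs for the
#'   footprint network.
#' @param out_dir output directory (created); `NULL` skips writing.
#' @return results list (invisibly when writing).
#' @export
run_pipeline <- function(expr, annotation, config = pipeline_config(),
                         disease_table = NULL, gmt = NULL, pathways = NULL,
                         footprints = NULL, motifs = NULL, tss = NULL,
                         out_dir = NULL) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  validate_expression(expr)
  ann <- annotation[match(rownames(expr), annotation$gene), ]
  ppe <- ann$gene[ann$is_ppe %in% TRUE]
  tr <- ann$gene[ann$is_tr %in% TRUE]

  det <- stage("differential_expression",
               de_analysis(expr, config$fc_threshold, config$q_threshold,
                           config$background_level, config$constitutive_ratio))
  de_genes <- det$genes[det$is_de]
  counts <- summarize_time_course(det)

  chrom_enr <- stage("chromosome_enrichment",
                     chromosome_enrichment(ann, intersect(ppe, ann$gene)))

  modules <- NULL; groups <- NULL; mod_enr <- NULL; traj <- NULL
  profiles <- day_mean_profiles(expr)
  if (length(de_genes) >= 3) {
    modules <- stage("coexpression_modules", {
      prof_de <- profiles[de_genes, , drop = FALSE]
      beta <- pick_soft_power(prof_de, config$soft_powers, config$target_r2)
      tom <- tom_matrix(prof_de, beta = as.numeric(beta))
      ms <- detect_modules(tom, config$min_module_size, config$cut_quantile)
      ms$beta <- as.numeric(beta)
      ms
    })
    lists <- module_gene_lists(modules)
    if (length(lists)) {
      groups <- classify_module_groups(modules, ppe, alpha = config$module_alpha)
      mod_enr <- stage("module_enrichment", {
        enr_ppe <- module_enrichment(lists, ppe, de_genes)
        enr_tr <- module_enrichment(lists, tr, de_genes)
        up <- vapply(lists, function(g)
          mean(det$max_fc_signed[g] > 0) * 100, numeric(1))
        data.frame(module = enr_ppe$module, n = enr_ppe$n,
                   n_ppe = enr_ppe$n_flagged, or_ppe = enr_ppe$odds_ratio,
                   p_ppe = enr_ppe$p, n_tr = enr_tr$n_flagged,
                   or_tr = enr_tr$odds_ratio, p_tr = enr_tr$p,
                   pct_up = up[enr_ppe$module],
                   group = groups[enr_ppe$module])
      })
      traj <- module_trajectories(modules, det, groups)
    }
  }

  hec <- stage("hec", hec_analysis(det, ppe, universe = det$genes,
                                   grid = config$hec_grid,
                                   slope_factor = config$slope_factor,
                                   override = config$hec_override,
                                   k = config$k_clusters))

  network <- stage("tr_network",
                   build_tr_coexpression_network(profiles, de_genes, tr,
                                                 r_min = config$r_min))
  timing <- tr_timing(det, tr)

  gmt_enr <- if (!is.null(gmt) && length(de_genes))
    stage("gmt_enrichment",
          gmt_enrichment(de_genes, det$genes, gmt, config$gmt_q)) else NULL

  fp_edges <- NULL; fp_filtered <- NULL; coverage <- NULL
  if (!is.null(footprints) && !is.null(motifs) && !is.null(tss)) {
    fp_edges <- stage("footprint_network",
                      footprint_edge_map(footprints, motifs, tss,
                                         window = config$footprint_window))
    fp_filtered <- attach_correlations(fp_edges, profiles,
                                       min_abs_r = config$min_abs_r)
    if (!is.null(groups) && nrow(fp_filtered)) {
      gl <- module_gene_lists(modules)
      pl <- unlist(gl[names(groups)[groups == "placental"]], use.names = FALSE)
      np <- unlist(gl[names(groups)[groups == "non-placental"]], use.names = FALSE)
      if (length(pl) && length(np))
        coverage <- module_coverage_report(
          fp_filtered, list(placental = pl, non_placental = np),
          config$coverage_thresholds)
    }
  }

  impact <- if (!is.null(pathways))
    stage("pathway_impact", {
      delta <- det$max_fc_signed[de_genes]
      analyze_pathways(pathways, delta, det$genes, B = config$impact_B,
                       seed = .child_seed(config$seed, 7L))
    }) else NULL

  overlay <- NULL; tightness <- NULL
  if (!is.null(disease_table)) {
    overlay <- stage("disease_overlay",
                     disease_overlay(det, disease_table, tr,
                                     fc_threshold = config$fc_threshold,
                                     q_threshold = config$q_threshold,
                                     modules_diff = if (!is.null(modules)) modules$labels))
    if (length(overlay$discordant) >= 2 && length(network$tr_genes) >= 2)
      tightness <- discordance_tightness(profiles, overlay$discordant,
                                         network$tr_genes,
                                         B = config$tightness_B,
                                         seed = .child_seed(config$seed, 9L))
  }

  results <- list(
    config = config, det = det, counts = counts, chrom_enr = chrom_enr,
    modules = modules, groups = groups, module_table = mod_enr,
    trajectories = traj, hec = hec, network = network, timing = timing,
    gmt_enr = gmt_enr, fp_edges = fp_edges, fp_filtered = fp_filtered,
    coverage = coverage, impact = impact, overlay = overlay,
    tightness = tightness
  )
  if (!is.null(out_dir)) {
    write_report(results, out_dir)
    return(invisible(results))
  }
  results
}

# Flatten a de_result into the writable per-gene table.
.de_table_df <- function(det) {
  days <- det$days
  df <- data.frame(gene = det$genes)
  for (d in seq_along(days)) {
    df[[sprintf("lfc_day0_d%d", days[d])]] <- det$lfc_day0[, d]
    df[[sprintf("lfc_prev_d%d", days[d])]] <- det$lfc_prev[, d]
    df[[sprintf("p_d%d", days[d])]] <- det$p_day0[, d]
    df[[sprintf("q_d%d", days[d])]] <- det$q_day0[, d]
  }
  df$max_abs_lfc <- det$max_abs_lfc
  df$max_fc_day <- det$max_fc_day
  df$is_de <- det$is_de
  df$is_constitutive <- det$is_constitutive
  df
}

#' Write all stage outputs, summary JSON and optional figures
#'
#' @param results list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param plots write diagnostic figures (requires ggplot2 device access).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(.de_table_df(results$det), "de_table.tsv")
  w(results$counts, "timecourse_counts.tsv")
  w(results$chrom_enr, "chromosome_enrichment.tsv")
  if (!is.null(results$modules))
    w(data.frame(gene = names(results$modules$labels),
                 module = results$modules$labels,
                 color = ifelse(results$modules$labels == "unassigned", "grey",
                                results$modules$colors[results$modules$labels]),
                 group = ifelse(results$modules$labels == "unassigned", NA,
                                results$groups[results$modules$labels])),
      "modules.tsv")
  if (!is.null(results$module_table)) {
    mt <- results$module_table
    sigma <- data.frame(module = "Sum", n = sum(mt$n), n_ppe = sum(mt$n_ppe),
                        or_ppe = NA, p_ppe = NA, n_tr = sum(mt$n_tr),
                        or_tr = NA, p_tr = NA,
                        pct_up = 100 * sum(mt$n * mt$pct_up / 100) / sum(mt$n),
                        group = NA)
    w(rbind(mt, sigma), "module_table.tsv")
  }
  if (!is.null(results$hec)) {
    w(results$hec$curve, "hec_curve.tsv")
    hg <- results$hec$hec_genes
    hec_df <- data.frame(gene = hg,
                         max_abs_lfc = results$det$max_abs_lfc[hg],
                         cluster = if (!is.null(results$hec$clusters))
                           results$hec$clusters$cluster[hg] else NA)
    w(hec_df, "hec_genes.tsv")
  }
  w(results$network$edges, "network_edges.tsv")
  if (length(results$network$connectivity))
    w(data.frame(tr = names(results$network$connectivity),
                 connectivity = results$network$connectivity,
                 de_day1 = names(results$network$connectivity) %in%
                   results$timing$day1),
      "tr_connectivity.tsv")
  w(results$gmt_enr, "gmt_enrichment.tsv")
  w(results$fp_edges, "footprint_edges.tsv")
  w(results$fp_filtered, "footprint_edges_filtered.tsv")
  w(results$coverage, "tf_coverage.tsv")
  if (!is.null(results$impact)) w(results$impact$results, "pathway_impact.tsv")
  if (!is.null(results$overlay)) w(results$overlay$table, "disease_overlay.tsv")

  summary <- list(
    n_genes = length(results$det$genes),
    n_de = sum(results$det$is_de),
    n_up = sum(results$det$is_de & results$det$max_fc_signed > 0),
    n_down = sum(results$det$is_de & results$det$max_fc_signed < 0),
    n_constitutive = if (all(is.na(results$det$is_constitutive))) NA
                     else sum(results$det$is_constitutive),
    n_modules = length(results$modules$sizes),
    module_sizes = as.list(results$modules$sizes),
    n_placental_modules = sum(results$groups == "placental"),
    hec_threshold = results$hec$threshold,
    n_hec = length(results$hec$hec_genes),
    hec_or = results$hec$enrichment_at_threshold$odds_ratio,
    n_de_tr = length(results$network$tr_genes),
    n_network_edges = nrow(results$network$edges),
    n_discordant = if (!is.null(results$overlay))
      length(results$overlay$discordant) else NA,
    discordant = if (!is.null(results$overlay)) results$overlay$discordant else NULL,
    tightness = if (!is.null(results$tightness))
      results$tightness[c("statistic", "p")] else NULL,
    seed = results$config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  cfg <- unclass(results$config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  if (plots) .write_plots(results, out_dir)
  invisible(out_dir)
}

# Diagnostic figures: enrichment curve, module trajectories, cluster means.
.write_plots <- function(results, out_dir) {
  curve <- results$hec$curve
  curve <- curve[!is.na(curve$odds_ratio), ]
  p1 <- ggplot2::ggplot(curve, ggplot2::aes(x = t, y = odds_ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = results$hec$threshold, linetype = 2) +
    ggplot2::labs(x = "log2 fold-change threshold", y = "PPE odds ratio",
                  title = "PPE enrichment vs fold-change threshold")
  ggplot2::ggsave(file.path(out_dir, "hec_curve.pdf"), p1, width = 5, height = 4)
  if (!is.null(results$trajectories$group_curves)) {
    gc <- results$trajectories$group_curves
    df <- data.frame(group = rep(rownames(gc), ncol(gc)),
                     day = rep(as.integer(colnames(gc)), each = nrow(gc)),
                     mean_abs_lfc = as.vector(gc))
    p2 <- ggplot2::ggplot(df, ggplot2::aes(day, mean_abs_lfc, colour = group)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "mean |log2FC| vs day 0",
                    title = "Module-group expression-change time course")
    ggplot2::ggsave(file.path(out_dir, "group_trajectories.pdf"), p2,
                    width = 5, height = 4)
  }
  if (!is.null(results$hec$clusters)) {
    mm <- results$hec$clusters$means
    df <- data.frame(cluster = rep(rownames(mm), ncol(mm)),
                     day = rep(as.integer(colnames(mm)), each = nrow(mm)),
                     mean_lfc = as.vector(mm))
    p3 <- ggplot2::ggplot(df, ggplot2::aes(day, mean_lfc, colour = cluster)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "mean log2FC vs day 0",
                    title = "HEC temporal cluster mean trajectories")
    ggplot2::ggsave(file.path(out_dir, "hec_clusters.pdf"), p3,
                    width = 5, height = 4)
  }
  invisible(NULL)
}
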