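# Differential expression over the differentiation time course.
#
# Fold changes are differences of day-mean log2 intensities, taken against
# two baselines (day 0 and the previous day). Per-day significance uses an
# empirical-Bayes moderated t: per-gene pooled variances are shrunk toward
# a prior variance s0^2 with prior degrees of freedom d0, both estimated by
# method of moments on log s^2 (the classic moderated-t derivation). A gene
# is differentially expressed (DE) when, on some day, |log2FC vs day 0| >=
# log2(fc_threshold) and the BH-adjusted p on that same day is below
# q_threshold.

# -- moderation hyperparameters ---------------------------------------------

# Newton solve of trigamma(y) = x, vectorized, for the method-of-moments fit.
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of (d0, s0^2) from per-gene variances s2 on df
# degrees of freedom. If the spread of log s2 is no larger than its
# expected sampling spread, d0 is infinite (full shrinkage).
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_sq = NA_real_))
  e <- log(s2[ok])
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_sq <- exp(emean - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# -- core operations --------------------------------------------------------

#' Per-day log2 fold changes against both baselines
#'
#' `log2FC` on day d is the difference of day-mean log2 intensities, versus
#' day 0 or versus day d-1.
#'
#' @inheritParams sample_design
#' @return list with `lfc_day0` and `lfc_prev` (genes x days matrices for
#'   days 1..max) and `day_means` (genes x all days).
#' @export
fold_change_table <- function(expr) {
  validate_expression(expr)
  dm <- .day_means(expr)
  days <- as.integer(colnames(dm))
  later <- which(days > 0L)
  lfc0 <- dm[, later, drop = FALSE] - dm[, 1L]
  lfcp <- dm[, later, drop = FALSE] - dm[, later - 1L, drop = FALSE]
  dimnames(lfc0) <- dimnames(lfcp) <- list(rownames(expr), days[later])
  list(lfc_day0 = lfc0, lfc_prev = lfcp, day_means = dm)
}

#' Empirical-Bayes moderated t-test for one day-vs-baseline comparison
#'
#' Pools per-gene residual variance across the two groups, shrinks it
#' toward a method-of-moments prior, and refers the moderated t to a t
#' distribution with `d0 + df` degrees of freedom (normal when `d0` is
#' infinite). With fewer than 2 replicates in either group the statistics
#' are reported as `NA` with a warning, and DE calling falls back to fold
#' change only.
#'
#' @inheritParams sample_design
#' @param day day being tested (>= 1).
#' @param baseline `"day0"` or `"prev"`.
#' @param d0,s0_sq optional forced hyperparameters; `d0 = 0` gives the
#'   ordinary pooled two-sample t, `d0 = Inf` a z-test against `s0_sq`.
#' @return list with `t`, `p` (named per gene) and `params`
#'   (`d0`, `s0_sq`, `df`).
#' @export
moderated_t_test <- function(expr, day, baseline = c("day0", "prev"),
                             d0 = NULL, s0_sq = NULL) {
  baseline <- match.arg(baseline)
  des <- sample_design(expr)
  ref_day <- if (baseline == "day0") 0L else as.integer(day) - 1L
  ga <- expr[, des$sample[des$day == as.integer(day)], drop = FALSE]
  gb <- expr[, des$sample[des$day == ref_day], drop = FALSE]
  if (ncol(ga) == 0 || ncol(gb) == 0) stopf("day %d or its baseline absent", day)
  na <- ncol(ga); nb <- ncol(gb)
  delta <- rowMeans(ga) - rowMeans(gb)
  if (na < 2 || nb < 2) {
    warnf("fewer than 2 replicates in a group on day %d; moderated statistics unavailable", day)
    nv <- stats::setNames(rep(NA_real_, nrow(expr)), rownames(expr))
    return(list(t = nv, p = nv, delta = delta,
                params = list(d0 = NA_real_, s0_sq = NA_real_, df = NA_real_)))
  }
  df <- na + nb - 2
  ss <- rowSums((ga - rowMeans(ga))^2) + rowSums((gb - rowMeans(gb))^2)
  s2 <- ss / df
  if (is.null(d0) || is.null(s0_sq)) {
    prior <- .fit_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    if (d0 == 0 || !is.finite(s0_sq)) s2_post <- s2
    df_total <- d0 + df
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, delta / se,
                  ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- if (is.finite(df_total)) 2 * stats::pt(abs(tstat), df_total, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(tstat), lower.tail = FALSE)
  p[is.infinite(tstat)] <- 0
  names(tstat) <- names(p) <- rownames(expr)
  list(t = tstat, p = p, delta = delta,
       params = list(d0 = d0, s0_sq = s0_sq, df = df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment within one comparison family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full per-day differential-expression analysis
#'
#' Runs [fold_change_table()] and per-day [moderated_t_test()] for both
#' baselines, BH-adjusts each day's p-values within that day's family, and
#' applies the DE rule via [call_de()] and the constitutive-expression rule
#' via [detect_constitutive()].
#'
#' @inheritParams sample_design
#' @param fc_threshold linear fold-change threshold for the DE rule.
#' @param q_threshold FDR threshold for the DE rule.
#' @param background_level linear-scale background intensity for the
#'   constitutive rule (`NULL` skips it).
#' @param constitutive_ratio required ratio over background.
#' @return object of class `de_result`: gene vector, per-day matrices
#'   (`lfc_day0`, `lfc_prev`, `t_day0`, `p_day0`, `q_day0`, `t_prev`,
#'   `p_prev`, `q_prev`), `max_abs_lfc`, `max_fc_day`, `max_fc_signed`,
#'   `is_de`, `is_constitutive`, moderation params per day, thresholds.
#' @export
de_analysis <- function(expr, fc_threshold = 2, q_threshold = 0.1,
                        background_level = NULL, constitutive_ratio = 4) {
  fc <- fold_change_table(expr)
  days <- as.integer(colnames(fc$lfc_day0))
  run <- function(baseline) {
    res <- lapply(days, function(d) moderated_t_test(expr, d, baseline))
    t <- do.call(cbind, lapply(res, `[[`, "t"))
    p <- do.call(cbind, lapply(res, `[[`, "p"))
    q <- apply(p, 2L, bh_adjust)
    dimnames(t) <- dimnames(p) <- dimnames(q) <- dimnames(fc$lfc_day0)
    list(t = t, p = p, q = q, params = lapply(res, `[[`, "params"))
  }
  b0 <- run("day0"); bp <- run("prev")
  max_idx <- max.col(abs(fc$lfc_day0), ties.method = "first")
  max_abs <- abs(fc$lfc_day0)[cbind(seq_len(nrow(expr)), max_idx)]
  max_signed <- fc$lfc_day0[cbind(seq_len(nrow(expr)), max_idx)]
  out <- structure(list(
    genes = rownames(expr), days = days,
    lfc_day0 = fc$lfc_day0, lfc_prev = fc$lfc_prev, day_means = fc$day_means,
    t_day0 = b0$t, p_day0 = b0$p, q_day0 = b0$q,
    t_prev = bp$t, p_prev = bp$p, q_prev = bp$q,
    params_day0 = b0$params, params_prev = bp$params,
    max_abs_lfc = stats::setNames(max_abs, rownames(expr)),
    max_fc_day = stats::setNames(days[max_idx], rownames(expr)),
    max_fc_signed = stats::setNames(max_signed, rownames(expr)),
    fc_threshold = fc_threshold, q_threshold = q_threshold
  ), class = "de_result")
  out$is_de <- call_de(out, fc_threshold, q_threshold)
  out$is_constitutive <- if (is.null(background_level))
    stats::setNames(rep(NA, nrow(expr)), rownames(expr))
  else detect_constitutive(expr, background_level, constitutive_ratio)
  out
}

#' Apply the differential-expression rule
#'
#' A gene is DE when some day d has `|log2FC vs day 0| >=
#' log2(fc_threshold)` and `q < q_threshold`, both on that same day. When
#' q-values are unavailable (single-replicate designs) the rule degrades to
#' fold change only.
#'
#' @param det a `de_result`.
#' @param fc_threshold,q_threshold rule parameters (linear FC; FDR).
#' @return named logical vector per gene.
#' @export
call_de <- function(det, fc_threshold = 2, q_threshold = 0.1) {
  big <- abs(det$lfc_day0) >= log2(fc_threshold)
  if (all(is.na(det$q_day0))) {
    return(stats::setNames(rowSums(big, na.rm = TRUE) > 0, det$genes))
  }
  hit <- big & det$q_day0 < q_threshold
  stats::setNames(rowSums(hit, na.rm = TRUE) > 0, det$genes)
}

#' Constitutively high expression relative to background
#'
#' Flags genes whose day-mean intensity stays at least `ratio` times above
#' the background level on every day. Day means are taken on the log2 scale
#' (geometric means on the linear scale), consistent with the fold-change
#' definitions.
#'
#' @inheritParams sample_design
#' @param background_level linear-scale background intensity (> 0).
#' @param ratio required fold over background (boundary inclusive).
#' @return named logical vector per gene.
#' @export
detect_constitutive <- function(expr, background_level, ratio = 4) {
  if (background_level <= 0) stopf("background_level must be > 0")
  dm <- .day_means(expr)
  min_linear <- 2^apply(dm, 1L, min)
  stats::setNames(min_linear >= ratio * background_level, rownames(expr))
}

#' Per-day up/down-regulated gene counts for both baselines
#'
#' A gene counts as up (down) on day d for a baseline when that single
#' comparison meets the DE rule: |log2FC| >= log2(fc_threshold) and q <
#' q_threshold in that comparison.
#'
#' @param det a `de_result`.
#' @inheritParams call_de
#' @return data.frame with day, baseline, n_up, n_down.
#' @export
summarize_time_course <- function(det, fc_threshold = det$fc_threshold,
                                  q_threshold = det$q_threshold) {
  one <- function(lfc, q, baseline) {
    sig <- abs(lfc) >= log2(fc_threshold) &
      (if (all(is.na(q))) TRUE else q < q_threshold)
    data.frame(day = as.integer(colnames(lfc)), baseline = baseline,
               n_up = colSums(sig & lfc > 0, na.rm = TRUE),
               n_down = colSums(sig & lfc < 0, na.rm = TRUE),
               row.names = NULL)
  }
  rbind(one(det$lfc_day0, det$q_day0, "day0"),
        one(det$lfc_prev, det$q_prev, "prev"))
}

#' Compare maximum fold changes between a gene group and its complement
#'
#' Reports the mean linear fold change (`2^max_abs_lfc`) inside and outside
#' the group and a two-sided Welch t-test on the log2 values.
#'
#' @param det a `de_result`.
#' @param group_flags named logical vector (or character vector of gene
#'   ids) defining the group; the comparison set is the complement within
#'   `det$genes`.
#' @return list with `mean_fc_in`, `mean_fc_out`, `ratio`, `p`.
#' @export
group_fc_comparison <- function(det, group_flags) {
  if (is.character(group_flags))
    group_flags <- stats::setNames(det$genes %in% group_flags, det$genes)
  flags <- group_flags[det$genes]
  x <- det$max_abs_lfc[which(flags)]
  y <- det$max_abs_lfc[which(!flags)]
  if (length(x) < 2 || length(y) < 2)
    stopf("need at least 2 genes on each side of the comparison")
  list(mean_fc_in = mean(2^x), mean_fc_out = mean(2^y),
       ratio = mean(2^x) / mean(2^y),
       p = stats::t.test(x, y)$p.value)
}
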