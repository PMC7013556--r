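# Internal helpers shared across the pipeline.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Parse the sample design from expression matrix column names
#'
#' Columns must be named `day<d>_rep<r>`, e.g. `day0_rep1`.
#'
#' @param expr numeric matrix, genes x samples, log2 scale.
#' @return data.frame with columns `sample`, `day` (integer) and `rep`.
#' @export
sample_design <- function(expr) {
  cn <- colnames(expr)
  if (is.null(cn)) stopf("expression matrix must have 'day<d>_rep<r>' column names")
  m <- regmatches(cn, regexec("^day([0-9]+)_rep([0-9]+)$", cn))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("malformed sample name(s): %s", paste(cn[bad], collapse = ", "))
  data.frame(
    sample = cn,
    day = as.integer(vapply(m, `[`, "", 2L)),
    rep = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Validate a log2 expression matrix
#'
#' Checks finiteness, unique gene ids, presence of day 0 and at least one
#' replicate per present day.
#'
#' @inheritParams sample_design
#' @return the matrix, invisibly.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stopf("expr must be a numeric matrix")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stopf("expr must have unique gene-id rownames")
  if (!all(is.finite(expr))) stopf("expr contains non-finite values")
  des <- sample_design(expr)
  if (!0L %in% des$day) stopf("day 0 is required but absent from the design")
  invisible(expr)
}

# Per-day means of a genes x samples matrix; returns genes x days matrix
# with columns named by day, in increasing day order.
.day_means <- function(expr, design = sample_design(expr)) {
  days <- sort(unique(design$day))
  out <- vapply(days, function(d) {
    cols <- design$sample[design$day == d]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), as.character(days)))
  out
}

# Deterministic child seed for a stage, derived from a master seed.
# Kept below 2^31 - 1.
.child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2017L + as.integer(offset)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted module structure.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("labelings differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxim <- (sum_a + sum_b) / 2
  if (maxim == expected) return(1)
  (sum_ij - expected) / (maxim - expected)
}
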