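## Scoring: criterion sums, biological risk gene selection and the
## nearest-gene association check.

#' Score evidence rows
#'
#' The gene score is the plain sum of the seven criterion indicators
#' (0-7). The nearest-gene flag never contributes. Adds `score` and
#' `biological` (score at or above the threshold) columns.
#'
#' @param matrix Evidence matrix from [buildEvidenceMatrix()].
#' @param threshold Biological-risk-gene score threshold (default 2: the
#'   selection rule is score >= 2).
#' @return The matrix with `score` and `biological` columns appended.
#' @export
scoreRows <- function(matrix, threshold = 2L) {
  matrix$score <- as.integer(rowSums(matrix[, .criterionCols, drop = FALSE]))
  matrix$biological <- matrix$score >= threshold
  matrix
}

#' Select biological risk gene rows
#'
#' Rows with score at or above the threshold, in their original order.
#' Idempotent.
#'
#' @param records Scored matrix from [scoreRows()].
#' @param threshold Minimum score (inclusive).
#' @return The selected rows.
#' @export
selectBiological <- function(records, threshold = 2L) {
  out <- records[records$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct genes among selected rows
#'
#' A gene listed under several risk SNPs counts once.
#'
#' @param records Scored (typically selected) evidence rows.
#' @return Character vector of unique symbols, in order of first
#'   appearance.
#' @export
distinctGenes <- function(records) {
  unique(normSymbol(records$gene))
}

#' Are high-scoring genes more often the nearest gene?
#'
#' Contingency of (score >= threshold) against the nearest-gene flag,
#' with per-class nearest proportions and a one-sided Fisher exact p for
#' the high-score class being nearest more often. When one score class
#' is absent the proportions are still reported and the p-value is
#' `NA`-flagged.
#'
#' @param records Scored matrix from [scoreRows()].
#' @param threshold Score threshold splitting the classes.
#' @return List with `table` (2x2 counts), `proportions` (named numeric,
#'   nearest fraction per class), and `p` (one-sided Fisher, or NA).
#' @export
nearestGeneAssociation <- function(records, threshold = 2L) {
  hi <- records$score >= threshold
  near <- as.logical(records$nearest)
  tab <- matrix(c(sum(hi & near), sum(hi & !near),
                  sum(!hi & near), sum(!hi & !near)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(score = c(sprintf(">=%d", threshold),
                                          sprintf("<%d", threshold)),
                                nearest = c("yes", "no")))
  props <- c(high = if (sum(hi)) mean(near[hi]) else NA_real_,
             low = if (sum(!hi)) mean(near[!hi]) else NA_real_)
  p <- if (all(rowSums(tab) > 0))
    stats::fisher.test(tab, alternative = "greater")$p.value
  else NA_real_
  list(table = tab, proportions = props, p = p)
}

#' Score histogram summary
#'
#' Counts of rows per score value 0..7 plus selection totals, for the
#' JSON run report.
#'
#' @param records Scored matrix.
#' @param threshold Selection threshold.
#' @return List: histogram (named counts), selected rows, distinct
#'   selected genes.
#' @export
scoreSummary <- function(records, threshold = 2L) {
  hist <- vapply(0:7, function(s) sum(records$score == s), integer(1))
  names(hist) <- as.character(0:7)
  sel <- selectBiological(records, threshold)
  list(histogram = as.list(hist),
       n_rows = nrow(records),
       n_selected_rows = nrow(sel),
       n_distinct_biological_genes = length(distinctGenes(sel)))
}
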