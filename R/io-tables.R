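## Readers and writers for the tabular inputs. All tables are
## tab-separated with a header; positions are 1-based in files.

.gwasCol <- function(nm, candidates) {
  hit <- which(tolower(nm) %in% candidates)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read a GWAS risk-SNP table
#'
#' Expects a tab-separated file whose header names at least the rsid,
#' chromosome, position, association p-value and odds-ratio columns
#' (`rsid`, `chrom`, `pos`, `p`/`assoc_p`, `or`/`odds_ratio`; a cytoband
#' `region` column and `ci_low`/`ci_high` are optional). Malformed or
#' absent confidence-interval fields become `NA`, never errors; an
#' unparsable p or OR is a row-level error naming the line.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns rsid, chrom, pos, region, assoc_p,
#'   odds_ratio, ci_low, ci_high (one row per input row).
#' @seealso [dedupRiskSnps()]
#' @export
readGwasTable <- function(path) {
  df <- readTsv(path, "GWAS table")
  nm <- names(df)
  idx <- c(rsid = .gwasCol(nm, "rsid"),
           chrom = .gwasCol(nm, c("chrom", "chr", "chromosome")),
           pos = .gwasCol(nm, c("pos", "position", "bp")),
           assoc_p = .gwasCol(nm, c("p", "assoc_p", "pvalue", "p_value")),
           odds_ratio = .gwasCol(nm, c("or", "odds_ratio")))
  miss <- names(idx)[is.na(idx)]
  if (length(miss))
    stopf("missing mandatory column(s) %s in %s",
          paste(miss, collapse = ", "), path)
  out <- data.frame(
    rsid = trimws(as.character(df[[idx["rsid"]]])),
    chrom = as.character(df[[idx["chrom"]]]),
    pos = suppressWarnings(as.integer(df[[idx["pos"]]])),
    region = if (!is.na(i <- .gwasCol(nm, "region")))
      as.character(df[[i]]) else rep(NA_character_, nrow(df)),
    assoc_p = asNum(df[[idx["assoc_p"]]], "p", path),
    odds_ratio = asNum(df[[idx["odds_ratio"]]], "OR", path),
    stringsAsFactors = FALSE)
  ## CI columns are best-effort: malformed entries silently become NA
  for (cc in c("ci_low", "ci_high")) {
    i <- .gwasCol(nm, cc)
    out[[cc]] <- if (!is.na(i)) suppressWarnings(as.numeric(df[[i]]))
                 else rep(NA_real_, nrow(df))
  }
  if (any(!nzchar(out$rsid)))
    stopf("empty rsid at row %d of %s", which(!nzchar(out$rsid))[1L], path)
  if (any(!is.na(out$pos) & out$pos < 1L))
    stopf("position below 1 at row %d of %s",
          which(!is.na(out$pos) & out$pos < 1L)[1L], path)
  bad <- !is.na(out$ci_low) & !is.na(out$ci_high) & out$ci_low > out$ci_high
  out$ci_low[bad] <- NA_real_; out$ci_high[bad] <- NA_real_
  out
}

#' @rdname readGwasTable
#' @param snps data.frame as returned by `readGwasTable()`.
#' @export
writeGwasTable <- function(snps, path) {
  writeTsv(snps[, c("rsid", "chrom", "pos", "region", "assoc_p",
                    "odds_ratio", "ci_low", "ci_high")], path)
}

#' Collapse repeated risk-SNP rows to one record per rsid
#'
#' GWAS catalogue exports list one row per study, so the same rsid can
#' recur with different association statistics. Keeps, per rsid, the row
#' with the smallest association p-value, in order of first appearance.
#' Idempotent; never lengthens the list.
#'
#' @param snps data.frame of risk SNPs ([readGwasTable()] layout).
#' @return data.frame with one row per distinct rsid.
#' @examples
#' tab <- data.frame(rsid = c("rs1", "rs1"), chrom = "1", pos = 1:2,
#'                   region = NA, assoc_p = c(1e-8, 1e-12),
#'                   odds_ratio = c(1.1, 1.2), ci_low = NA, ci_high = NA)
#' dedupRiskSnps(tab)$assoc_p
#' @export
dedupRiskSnps <- function(snps) {
  if (!nrow(snps)) return(snps)
  ## per rsid keep the min-p row, listed in order of first appearance
  kept <- vapply(unique(snps$rsid), function(r) {
    i <- which(snps$rsid == r)
    i[which.min(snps$assoc_p[i])]
  }, integer(1))
  out <- snps[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an LD proxy table
#'
#' Columns: lead_rsid, proxy_rsid, r2, proxy_chrom, proxy_pos (1-based).
#' A lead SNP counts as its own proxy at r2 = 1 whether or not a self row
#' is present; downstream code adds the lead implicitly.
#'
#' @param path TSV path.
#' @return data.frame with the five columns above.
#' @export
readLdTable <- function(path) {
  df <- readTsv(path, "LD table")
  requireCols(df, c("lead_rsid", "proxy_rsid", "r2", "proxy_chrom",
                    "proxy_pos"), path)
  df$r2 <- asNum(df$r2, "r2", path)
  if (any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE))
    stopf("r2 outside [0,1] at row %d of %s",
          which(df$r2 < 0 | df$r2 > 1)[1L], path)
  df$proxy_pos <- as.integer(df$proxy_pos)
  df$proxy_chrom <- as.character(df$proxy_chrom)
  df
}

#' @rdname readLdTable
#' @param ld data.frame in the `readLdTable()` layout.
#' @export
writeLdTable <- function(ld, path) {
  writeTsv(ld[, c("lead_rsid", "proxy_rsid", "r2", "proxy_chrom",
                  "proxy_pos")], path)
}

#' Read / write a variant-consequence table
#'
#' Annotation-tool output reduced to three columns: rsid, gene,
#' consequence (a free-text class; `missense` is the one the pipeline
#' inspects). Symbols are upper-cased.
#'
#' @param path TSV path.
#' @return data.frame rsid, gene, consequence.
#' @export
readConsequenceTable <- function(path) {
  df <- readTsv(path, "consequence table")
  requireCols(df, c("rsid", "gene", "consequence"), path)
  df$gene <- normSymbol(df$gene)
  df$consequence <- tolower(trimws(df$consequence))
  df
}

#' @rdname readConsequenceTable
#' @param consequences data.frame in the reader's layout.
#' @export
writeConsequenceTable <- function(consequences, path) {
  writeTsv(consequences[, c("rsid", "gene", "consequence")], path)
}

#' Read / write a cis-eQTL association table
#'
#' Columns: rsid, gene, p, fdr, distance (bp between SNP and probe
#' midpoint). Symbols are upper-cased.
#'
#' @param path TSV path.
#' @return data.frame rsid, gene, p, fdr, distance.
#' @export
readEqtlTable <- function(path) {
  df <- readTsv(path, "eQTL table")
  requireCols(df, c("rsid", "gene", "p", "fdr", "distance"), path)
  df$gene <- normSymbol(df$gene)
  df$p <- asNum(df$p, "p", path)
  df$fdr <- asNum(df$fdr, "fdr", path)
  df$distance <- asNum(df$distance, "distance", path)
  df
}

#' @rdname readEqtlTable
#' @param eqtl data.frame in the reader's layout.
#' @export
writeEqtlTable <- function(eqtl, path) {
  writeTsv(eqtl[, c("rsid", "gene", "p", "fdr", "distance")], path)
}

#' Read / write a per-gene p-value table
#'
#' Two columns (gene, p); used for the text-mining and PPI-seed criteria,
#' whose upstream tools are consumed as score tables.
#'
#' @param path TSV path.
#' @return Named numeric vector, gene symbol -> p.
#' @export
readGenePvalues <- function(path) {
  df <- readTsv(path, "gene p-value table")
  requireCols(df, c("gene", "p"), path)
  p <- asNum(df$p, "p", path)
  setNames(p, normSymbol(df$gene))
}

#' @rdname readGenePvalues
#' @param p Named numeric vector (gene -> p).
#' @export
writeGenePvalues <- function(p, path) {
  writeTsv(data.frame(gene = names(p), p = unname(p)), path)
}

#' Read / write the SNP universe for permutation sampling
#'
#' Two columns: chrom, pos (1-based).
#'
#' @param path TSV path.
#' @return data.frame chrom, pos.
#' @export
readSnpUniverse <- function(path) {
  df <- readTsv(path, "SNP universe")
  requireCols(df, c("chrom", "pos"), path)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos) | df$pos < 1L))
    stopf("invalid position at row %d of %s",
          which(is.na(df$pos) | df$pos < 1L)[1L], path)
  df
}

#' @rdname readSnpUniverse
#' @param universe data.frame chrom, pos.
#' @export
writeSnpUniverse <- function(universe, path) {
  writeTsv(universe[, c("chrom", "pos")], path)
}

#' Read / write an undirected PPI edge list
#'
#' Two tab-separated symbol columns (extra columns are ignored). Edges
#' are undirected: self-loops are dropped and duplicates in either
#' orientation collapsed; the canonical form has `from` < `to`
#' lexicographically. Node and edge counts are attached as attributes
#' `nodes` and `edges`.
#'
#' @param path TSV path with header (first two columns are the symbols).
#' @return data.frame from, to.
#' @export
readEdgeList <- function(path) {
  df <- readTsv(path, "edge list")
  if (ncol(df) < 2L) stopf("edge list %s needs two columns", path)
  a <- normSymbol(df[[1L]]); b <- normSymbol(df[[2L]])
  blank <- which(!nzchar(a) | !nzchar(b))
  if (length(blank)) stopf("blank symbol at row %d of %s", blank[1L], path)
  canonicalizeEdges(data.frame(from = a, to = b, stringsAsFactors = FALSE))
}

canonicalizeEdges <- function(edges) {
  a <- normSymbol(edges$from); b <- normSymbol(edges$to)
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  out <- unique(data.frame(from = a2, to = b2, stringsAsFactors = FALSE))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes") <- length(unique(c(out$from, out$to)))
  attr(out, "edges") <- nrow(out)
  out
}

#' @rdname readEdgeList
#' @param edges data.frame from, to.
#' @export
writeEdgeList <- function(edges, path) {
  writeTsv(as.data.frame(edges)[, c("from", "to")], path)
}

#' Read / write a drug-target table
#'
#' Columns: drug, target, status (one of `approved`, `clinical`,
#' `experimental`), indication, crc_approved (0/1 or TRUE/FALSE flag for
#' targets of disease-approved first-line drugs). One gene may be hit by
#' several drugs; distinct target-gene counts per status and for the
#' crc_approved subset are attached as attribute `target_counts`.
#'
#' @param path TSV path.
#' @return data.frame drug, target, status, indication, crc_approved.
#' @export
readDrugTable <- function(path) {
  df <- readTsv(path, "drug table")
  requireCols(df, c("drug", "target", "status", "indication",
                    "crc_approved"), path)
  df$target <- normSymbol(df$target)
  df$status <- tolower(trimws(df$status))
  bad <- which(!df$status %in% c("approved", "clinical", "experimental"))
  if (length(bad))
    stopf("unknown status '%s' at row %d of %s", df$status[bad[1L]],
          bad[1L], path)
  df$crc_approved <- as.logical(as.integer(as.logical(df$crc_approved) |
                                           df$crc_approved %in% c(1, "1")))
  attr(df, "target_counts") <- c(
    total = length(unique(df$target)),
    vapply(c("approved", "clinical", "experimental"), function(s)
      length(unique(df$target[df$status == s])), integer(1)),
    crc_approved = length(unique(df$target[df$crc_approved])))
  df
}

#' @rdname readDrugTable
#' @param drugs data.frame in the reader's layout.
#' @export
writeDrugTable <- function(drugs, path) {
  out <- as.data.frame(drugs)[, c("drug", "target", "status", "indication",
                                  "crc_approved")]
  out$crc_approved <- as.integer(out$crc_approved)
  writeTsv(out, path)
}
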