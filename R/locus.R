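## Locus mapping: assign candidate genes to each risk SNP from LD extent
## and proximity, and flag the nearest gene.

#' LD interval of a risk SNP
#'
#' The locus interval spans the lead SNP plus all proxies on the lead's
#' chromosome with r2 strictly above `r2Threshold` (a proxy at exactly
#' the threshold is excluded), extended by `flankBp` on each side and
#' clipped at the chromosome origin. Proxies on other chromosomes are
#' skipped with a warning.
#'
#' @param lead One-row risk-SNP data.frame (rsid, chrom, pos).
#' @param proxies LD proxy data.frame ([readLdTable()] layout); may
#'   contain rows for other leads, which are ignored.
#' @param r2Threshold,flankBp numeric threshold and integer flank (bp).
#' @return Length-1 `GRanges` with metadata `lead_rsid` and `n_proxies`
#'   (count of qualifying proxies, lead excluded).
#' @export
ldInterval <- function(lead, proxies, r2Threshold = 0.80, flankBp = 0L) {
  stopifnot(nrow(lead) == 1L)
  px <- proxies[proxies$lead_rsid == lead$rsid &
                proxies$r2 > r2Threshold &
                proxies$proxy_rsid != lead$rsid, , drop = FALSE]
  off <- px$proxy_chrom != lead$chrom
  if (any(off)) {
    warnf("%d proxy row(s) of %s on a different chromosome skipped",
          sum(off), lead$rsid)
    px <- px[!off, , drop = FALSE]
  }
  pos <- c(lead$pos, px$proxy_pos)
  gr <- GenomicRanges::GRanges(
    lead$chrom,
    IRanges::IRanges(start = max(1L, min(pos) - flankBp),
                     end = max(pos) + flankBp))
  S4Vectors::mcols(gr)$lead_rsid <- lead$rsid
  S4Vectors::mcols(gr)$n_proxies <- nrow(px)
  gr
}

#' Nearest gene to a risk SNP
#'
#' Distance is zero when the position falls inside the gene body,
#' otherwise basepairs to the nearer body edge; strand is ignored. Ties
#' break to the gene with the smaller start, then the lexicographically
#' smaller symbol.
#'
#' @param snp One-row risk-SNP data.frame (rsid, chrom, pos).
#' @param genes `GRanges` with a `symbol` column.
#' @return Length-1 `GRanges` (the winning gene) with a `distance`
#'   metadata column; errors if no gene shares the SNP's chromosome.
#' @export
nearestGene <- function(snp, genes) {
  stopifnot(nrow(snp) == 1L)
  onChrom <- genes[as.character(GenomicRanges::seqnames(genes)) == snp$chrom]
  if (!length(onChrom))
    stopf("no gene on chromosome %s for SNP %s", snp$chrom, snp$rsid)
  s <- GenomicRanges::start(onChrom); e <- GenomicRanges::end(onChrom)
  d <- pmax(0L, pmax(s - snp$pos, snp$pos - e))
  ord <- order(d, s, S4Vectors::mcols(onChrom)$symbol)
  win <- onChrom[ord[1L]]
  S4Vectors::mcols(win)$distance <- d[ord[1L]]
  win
}

#' Candidate genes of one risk locus
#'
#' Candidates are the genes whose bodies intersect the lead SNP's LD
#' interval, always unioned with the nearest gene (so a locus overlapping
#' no gene still yields one candidate). Exactly one returned pair has
#' `nearest = TRUE`.
#'
#' @param lead One-row risk-SNP data.frame.
#' @param bundle A [ResourceBundle-class] with gene models and LD table.
#' @param cfg A [PipelineConfig-class].
#' @return data.frame: rsid, gene, nearest, locus_start, locus_end
#'   (1-based closed span of the LD interval).
#' @export
mapLocusGenes <- function(lead, bundle, cfg = pipelineConfig()) {
  iv <- ldInterval(lead, bundle@ld, cfg@r2Threshold, cfg@locusFlankBp)
  near <- nearestGene(lead, bundle@genes)  # errors early on a bare chromosome
  hits <- bundle@genes[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(bundle@genes, iv, ignore.strand = TRUE))]
  sym <- unique(c(S4Vectors::mcols(near)$symbol,
                  S4Vectors::mcols(hits)$symbol))
  ## keep deterministic ordering: nearest first, then by position
  rest <- setdiff(S4Vectors::mcols(hits)$symbol[
    order(GenomicRanges::start(hits))], S4Vectors::mcols(near)$symbol)
  sym <- c(S4Vectors::mcols(near)$symbol, rest)
  data.frame(rsid = lead$rsid, gene = sym,
             nearest = sym == S4Vectors::mcols(near)$symbol,
             locus_start = GenomicRanges::start(iv),
             locus_end = GenomicRanges::end(iv),
             stringsAsFactors = FALSE)
}

#' Candidate SNP-gene pairs for every risk locus
#'
#' Runs [mapLocusGenes()] over the (de-duplicated) risk-SNP table. Loci
#' whose chromosome carries no gene model are reported in the `errors`
#' attribute and skipped rather than aborting the run. Multi-SNP loci
#' sharing a gene contribute separate SNP-gene pairs.
#'
#' @param bundle A [ResourceBundle-class].
#' @param cfg A [PipelineConfig-class].
#' @return data.frame of pairs, with attribute `errors` (character).
#' @export
mapAllLoci <- function(bundle, cfg = pipelineConfig()) {
  snps <- dedupRiskSnps(bundle@riskSnps)
  out <- vector("list", nrow(snps))
  errs <- character()
  for (i in seq_len(nrow(snps))) {
    res <- tryCatch(mapLocusGenes(snps[i, , drop = FALSE], bundle, cfg),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) errs <- c(errs, res) else out[[i]] <- res
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(rsid = character(), gene = character(),
                        nearest = logical(), locus_start = integer(),
                        locus_end = integer())
  rownames(pairs) <- NULL
  attr(pairs, "errors") <- errs
  pairs
}
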