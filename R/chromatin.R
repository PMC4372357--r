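## Chromatin-mark enrichment: do risk loci (lead SNPs plus LD proxies)
## fall inside peaks more often than random SNPs from a universe?
## Assessed per cell type by permutation.

#' Member SNP positions of every risk locus
#'
#' One element per (de-duplicated) risk SNP: the lead position plus all
#' proxy positions at r2 strictly above the threshold, as a data.frame
#' of chrom/pos. Leads without a position are skipped.
#'
#' @param bundle A [ResourceBundle-class].
#' @param cfg A [PipelineConfig-class].
#' @return Named list of data.frames (chrom, pos), one per locus.
#' @export
lociPositions <- function(bundle, cfg = pipelineConfig()) {
  snps <- dedupRiskSnps(bundle@riskSnps)
  snps <- snps[!is.na(snps$pos), , drop = FALSE]
  out <- lapply(seq_len(nrow(snps)), function(i) {
    px <- bundle@ld[bundle@ld$lead_rsid == snps$rsid[i] &
                    bundle@ld$r2 > cfg@r2Threshold &
                    bundle@ld$proxy_rsid != snps$rsid[i], , drop = FALSE]
    data.frame(chrom = c(snps$chrom[i], px$proxy_chrom),
               pos = c(snps$pos[i], px$proxy_pos),
               stringsAsFactors = FALSE)
  })
  setNames(out, snps$rsid)
}

.posGRanges <- function(chrom, pos)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))

#' Count loci overlapping a peak set
#'
#' A locus counts (at most once) when at least one member SNP position
#' falls inside at least one peak.
#'
#' @param loci List of data.frames (chrom, pos), see [lociPositions()].
#' @param peaks `GRanges` of peak intervals.
#' @return Integer count of overlapping loci.
#' @export
locusOverlapCount <- function(loci, peaks) {
  if (!length(loci) || !length(peaks)) return(0L)
  memb <- do.call(rbind, loci)
  idx <- rep(seq_along(loci), vapply(loci, nrow, integer(1)))
  hit <- IRanges::overlapsAny(.posGRanges(memb$chrom, memb$pos), peaks,
                              ignore.strand = TRUE)
  length(unique(idx[hit]))
}

#' Permutation p-value for locus-peak overlap
#'
#' Each iteration samples positions uniformly without replacement from
#' the SNP universe and recomputes the overlap statistic on the sampled
#' null loci. By default each null locus is a single position
#' (|loci| draws); with `matchLocusSize` the null mimics the observed
#' locus sizes, drawing as many member positions per null locus as the
#' corresponding observed locus has. The estimator uses the add-one
#' pseudo-count, p = (1 + #{null >= observed}) / (1 + iterations), so p
#' is never exactly 0 and always in (0, 1].
#'
#' @param observed Observed overlap count; computed from `loci` and
#'   `peaks` via [locusOverlapCount()] when `NULL`.
#' @param loci List of member-position data.frames.
#' @param universe data.frame (chrom, pos) of candidate SNP positions;
#'   must hold at least as many positions as are drawn per iteration.
#' @param peaks `GRanges` of peaks.
#' @param iterations Number of permutations (>= 1).
#' @param seed Integer seed; same seed gives a bit-identical result.
#' @param matchLocusSize Match null locus sizes to observed ones.
#' @return One-row data.frame: observed, iterations, n_ge, p.
#' @export
permutationPvalue <- function(observed = NULL, loci, universe, peaks,
                              iterations = 100000L, seed = 1L,
                              matchLocusSize = FALSE) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stopf("iterations must be >= 1")
  if (is.null(observed)) observed <- locusOverlapCount(loci, peaks)
  sizes <- if (matchLocusSize) vapply(loci, nrow, integer(1))
           else rep(1L, length(loci))
  nDraw <- sum(sizes)
  if (nrow(universe) < nDraw)
    stopf("SNP universe (%d) smaller than positions drawn per iteration (%d)",
          nrow(universe), nDraw)
  inPeak <- if (length(peaks))
    IRanges::overlapsAny(.posGRanges(universe$chrom, universe$pos), peaks,
                         ignore.strand = TRUE)
  else rep(FALSE, nrow(universe))
  grp <- rep.int(seq_along(sizes), sizes)
  nGe <- 0L
  set.seed(seed)
  for (it in seq_len(iterations)) {
    hits <- inPeak[sample.int(nrow(universe), nDraw)]
    stat <- if (matchLocusSize)
      sum(vapply(split(hits, grp), any, logical(1)))
    else sum(hits)
    if (stat >= observed) nGe <- nGe + 1L
  }
  data.frame(observed = as.integer(observed), iterations = iterations,
             n_ge = nGe, p = (nGe + 1) / (iterations + 1))
}

#' Scan all cell types for locus-peak enrichment
#'
#' Runs [permutationPvalue()] once per peak set. Reproducibility is per
#' cell type: each test's seed derives from the global seed and the
#' cell-type name ([deriveSeed()]), so results do not depend on scan
#' order or on which other cell types are present.
#'
#' @param loci List of member-position data.frames.
#' @param universe data.frame (chrom, pos).
#' @param peakSets Named list of `GRanges`, one per cell type.
#' @param cfg A [PipelineConfig-class] (iterations, seed, null matching).
#' @return data.frame sorted by ascending p (ties by cell type):
#'   cell_type, observed, iterations, n_ge, p.
#' @export
multiCelltypeScan <- function(loci, universe, peakSets,
                              cfg = pipelineConfig()) {
  if (!length(peakSets))
    return(data.frame(cell_type = character(), observed = integer(),
                      iterations = integer(), n_ge = integer(),
                      p = numeric()))
  rows <- lapply(names(peakSets), function(ct) {
    res <- permutationPvalue(NULL, loci, universe, peakSets[[ct]],
                             iterations = cfg@permutationIters,
                             seed = deriveSeed(cfg@rngSeed, ct),
                             matchLocusSize = cfg@matchLocusSize)
    cbind(cell_type = ct, res)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
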