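## Exact hypergeometric machinery shared by the category-enrichment and
## drug-target stages. Computed in log space from log-binomials so that
## tails of order 1e-5 at N ~ 1e4 come out exact, never via a normal or
## binomial approximation.

#' Exact hypergeometric upper tail
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a uniform
#' draw of `n` genes from a universe of `N` containing `K` category
#' members hits the category at least `k` times. Each pmf term is
#' evaluated as exp(lchoose(K,i) + lchoose(N-K,n-i) - lchoose(N,n)) and
#' the tail accumulated by log-sum-exp. `k = 0` returns exactly 1.
#' Vectorized over `k`.
#'
#' @param N,K,n,k universe size, category size, draw size, observed
#'   overlap; must satisfy `K, n <= N` and `0 <= k <= min(K, n)`.
#' @return Numeric in (0, 1], same length as `k`.
#' @examples
#' hypergeomUpperTail(11303, 8, 584, 5)   # 1.78e-5
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L)
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n)
  k <- as.integer(k)
  if (K > N || n > N || K < 0L || n < 0L)
    stopf("invalid hypergeometric bounds: need 0 <= K, n <= N")
  if (any(k < 0L | k > pmin(K, n)))
    stopf("overlap k must satisfy 0 <= k <= min(K, n)")
  kmax <- min(K, n)
  i <- 0:kmax
  logpmf <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  vapply(k, function(kk) {
    if (kk == 0L) return(1)
    lp <- logpmf[(kk + 1L):(kmax + 1L)]
    m <- max(lp)
    min(1, exp(m) * sum(exp(lp - m)))
  }, numeric(1))
}

#' Build an overlap test from raw counts
#'
#' @param N,K,n,k see [hypergeomUpperTail()].
#' @param ease Use the conservative EASE-style tail: the observed overlap
#'   is reduced by one (floored at 0) before computing the upper tail,
#'   while the reported counts and fold keep the true `k`.
#' @return An [OverlapTest-class].
#' @export
overlapTestCounts <- function(N, K, n, k, ease = FALSE) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  expected <- as.numeric(K) * n / N
  kTail <- if (ease) max(k - 1L, 0L) else k
  new("OverlapTest", universeN = N, categoryK = K, drawN = n,
      overlapK = k, expected = expected,
      fold = if (expected > 0) k / expected else NaN,
      pUpper = hypergeomUpperTail(N, K, n, kTail))
}

#' Overlap test between two gene sets
#'
#' Intersects the draw with the category on normalized (upper-cased)
#' symbols and runs the exact test against a universe of `universeN`
#' genes.
#'
#' @param universeN Universe size N (must be at least each set's size).
#' @param category,draw Character symbol sets.
#' @param ease See [overlapTestCounts()].
#' @return An [OverlapTest-class].
#' @examples
#' overlapTest(11303, paste0("y", 1:8),
#'             c(paste0("y", 1:5), paste0("g", 1:579)))
#' @export
overlapTest <- function(universeN, category, draw, ease = FALSE) {
  category <- unique(normSymbol(category))
  draw <- unique(normSymbol(draw))
  if (length(category) > universeN || length(draw) > universeN)
    stopf("universe (N = %d) smaller than a set (K = %d, n = %d)",
          universeN, length(category), length(draw))
  overlapTestCounts(universeN, length(category), length(draw),
                    length(intersect(draw, category)), ease = ease)
}

#' Relative fold enrichment of two overlap tests
#'
#' (k_y/K_y) / (k_z/K_z): how much more densely the draw covers category
#' y than category z. `NA` (flagged via attribute `undefined`) when the
#' z overlap is zero.
#'
#' @param testY,testZ [OverlapTest-class] objects over the same draw.
#' @return Numeric scalar; attribute `undefined` is TRUE when the
#'   denominator vanishes.
#' @export
relativeFold <- function(testY, testZ) {
  if (testZ@overlapK == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (testY@overlapK / testY@categoryK) /
    (testZ@overlapK / testZ@categoryK)
}

#' Compare hit rates of two drug-target sets
#'
#' One-sided Fisher exact test on the 2x2 table
#' `[[k_y, K_y - k_y], [k_z, K_z - k_z]]` — is category y hit at a higher
#' rate than category z? With `excludeY = TRUE` the z row uses z minus y
#' (counts `k_z - k_y`, `K_z - K_y`), for when y is a subset of z.
#'
#' @param testY,testZ [OverlapTest-class] objects.
#' @param excludeY logical, see above.
#' @return Fisher one-sided p-value.
#' @export
compareTargetSets <- function(testY, testZ, excludeY = FALSE) {
  ky <- testY@overlapK; Ky <- testY@categoryK
  kz <- testZ@overlapK; Kz <- testZ@categoryK
  if (excludeY) { kz <- kz - ky; Kz <- Kz - Ky }
  tab <- matrix(c(ky, Ky - ky, kz, Kz - kz), nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stopf("negative cell in target-set comparison table")
  stats::fisher.test(tab, alternative = "greater")$p.value
}
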