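#' @import methods
#' @importFrom stats cor fisher.test ks.test rbinom rpois runif setNames
#' @importFrom utils read.table write.table
NULL

## Gene identity is the upper-cased symbol string throughout the package.
normSymbol <- function(x) toupper(trimws(as.character(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage- or label-specific seed from a global seed
#'
#' A single global seed drives every stochastic stage; per-stage seeds are
#' derived deterministically from the global seed and a string label (e.g. a
#' cell-type name), so that adding or reordering stages never perturbs the
#' random stream of another stage. The derived seed stays below 2^31.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the consumer.
#' @return A single integer seed.
#' @examples
#' deriveSeed(1L, "rectal_mucosa")
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  codes <- utf8ToInt(as.character(label))
  ## small multiplicative rolling hash, kept in double precision below 2^31
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009)
}

readTsv <- function(path, what = "table") {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  read.table(path, header = TRUE, sep = "\t", quote = "",
             comment.char = "", stringsAsFactors = FALSE,
             check.names = FALSE)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("missing mandatory column%s %s in %s",
          if (length(miss) > 1L) "s" else "", paste(miss, collapse = ", "),
          path)
  invisible(df)
}

asNum <- function(x, field, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(out))
  if (length(bad))
    stopf("unparsable %s value '%s' in %s (row %d)",
          field, x[bad[1L]], path, bad[1L])
  out
}
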