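#' Read / write BED intervals as GRanges
#'
#' BED coordinates are 0-based half-open; in memory the intervals live in
#' a [GenomicRanges::GRanges] (1-based closed), converted at this
#' boundary: BED `[start, end)` becomes `start+1 .. end`. Column 4, when
#' present, is stored as the `name` metadata column (and as `symbol` by
#' [readGeneBed()]). Rows are returned sorted by chromosome then start;
#' overlapping intervals are retained, never merged.
#'
#' @param path BED3/BED4/BED6 file, whitespace-separated, no header.
#' @return `GRanges`, sorted, with optional `name` column.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tgeneA", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "", quote = "",
               comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame(V1 = character(), V2 = character(), V3 = character())
      else stop(e)
    })
  if (!nrow(df)) return(GenomicRanges::GRanges())
  if (ncol(df) < 3L) stopf("BED file %s needs at least 3 columns", path)
  s <- suppressWarnings(as.numeric(df[[2L]]))
  e <- suppressWarnings(as.numeric(df[[3L]]))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stopf("non-integer coordinates at row %d of %s", bad[1L], path)
  bad <- which(s >= e)
  if (length(bad))
    stopf("start >= end at row %d of %s", bad[1L], path)
  strand <- if (ncol(df) >= 6L && all(df[[6L]] %in% c("+", "-", ".")))
    df[[6L]] else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = s + 1, end = e),
    strand = strand)
  if (ncol(df) >= 4L) S4Vectors::mcols(gr)$name <- df[[4L]]
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname readBed
#' @param gr A `GRanges`; a `name` (or `symbol`) metadata column becomes
#'   BED column 4.
#' @export
writeBed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) mc$name
          else if ("symbol" %in% names(mc)) mc$symbol else NULL
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED4
#'
#' As [readBed()] but requires the name column, upper-cases it into a
#' `symbol` metadata column and enforces symbol uniqueness.
#'
#' @inheritParams readBed
#' @return `GRanges` with a `symbol` column.
#' @export
readGeneBed <- function(path) {
  gr <- readBed(path)
  mc <- S4Vectors::mcols(gr)
  if (!length(gr)) {
    S4Vectors::mcols(gr)$symbol <- character()
    return(gr)
  }
  if (!"name" %in% names(mc))
    stopf("gene BED %s needs a 4th (symbol) column", path)
  sym <- normSymbol(mc$name)
  if (anyDuplicated(sym))
    stopf("duplicate gene symbol '%s' in %s", sym[duplicated(sym)][1L], path)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(symbol = sym)
  gr
}

#' Read / write gene-set collections (GMT dialect)
#'
#' Each line: set name, description, then member symbols, tab-separated.
#' Members are upper-cased and de-duplicated. Duplicate set names are an
#' error, as is a line with fewer than 3 fields (i.e. an empty member
#' list).
#'
#' @param path GMT file.
#' @return Named list of character vectors (symbol sets).
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stopf("GMT line %d of %s has fewer than 3 fields (empty member list?)",
          short[1L], path)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stopf("duplicate set name '%s' in %s", nm[duplicated(nm)][1L], path)
  sets <- lapply(fields, function(f) unique(normSymbol(f[-(1:2)])))
  setNames(sets, nm)
}

#' @rdname readGeneSets
#' @param sets Named list of symbol vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
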