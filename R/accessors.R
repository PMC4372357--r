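## Accessors. Slot access from user code should go through these.

#' @name snp2drug-accessors
#' @title Accessors for the package's S4 containers
#' @description Extract slots of [ResourceBundle-class],
#'   [OverlapTest-class] and [DrugOverlapReport-class] objects without
#'   touching `@`.
#' @param x An object of the documented class.
#' @return The slot value.
#' @examples
#' ot <- overlapTestCounts(100, 10, 20, 5)
#' foldEnrichment(ot)
#' pUpper(ot)
NULL

#' @rdname snp2drug-accessors
#' @export
setGeneric("riskSnps", function(x) standardGeneric("riskSnps"))
#' @rdname snp2drug-accessors
#' @export
setMethod("riskSnps", "ResourceBundle", function(x) x@riskSnps)

#' @rdname snp2drug-accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname snp2drug-accessors
#' @export
setMethod("geneModels", "ResourceBundle", function(x) x@genes)

#' @rdname snp2drug-accessors
#' @export
setGeneric("ldTable", function(x) standardGeneric("ldTable"))
#' @rdname snp2drug-accessors
#' @export
setMethod("ldTable", "ResourceBundle", function(x) x@ld)

#' @rdname snp2drug-accessors
#' @export
setGeneric("ppiNetwork", function(x) standardGeneric("ppiNetwork"))
#' @rdname snp2drug-accessors
#' @export
setMethod("ppiNetwork", "ResourceBundle", function(x) x@network)

#' @rdname snp2drug-accessors
#' @export
setGeneric("drugTable", function(x) standardGeneric("drugTable"))
#' @rdname snp2drug-accessors
#' @export
setMethod("drugTable", "ResourceBundle", function(x) x@drugs)

#' @rdname snp2drug-accessors
#' @export
setGeneric("peakSets", function(x) standardGeneric("peakSets"))
#' @rdname snp2drug-accessors
#' @export
setMethod("peakSets", "ResourceBundle", function(x) x@peaks)

#' @rdname snp2drug-accessors
#' @export
setGeneric("geneUniverseN", function(x) standardGeneric("geneUniverseN"))
#' @rdname snp2drug-accessors
#' @export
setMethod("geneUniverseN", "ResourceBundle", function(x) x@geneUniverseN)

#' @rdname snp2drug-accessors
#' @export
setGeneric("foldEnrichment", function(x) standardGeneric("foldEnrichment"))
#' @rdname snp2drug-accessors
#' @export
setMethod("foldEnrichment", "OverlapTest", function(x) x@fold)

#' @rdname snp2drug-accessors
#' @export
setGeneric("pUpper", function(x) standardGeneric("pUpper"))
#' @rdname snp2drug-accessors
#' @export
setMethod("pUpper", "OverlapTest", function(x) x@pUpper)

#' @rdname snp2drug-accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))
#' @rdname snp2drug-accessors
#' @export
setMethod("overlapCounts", "OverlapTest", function(x)
  c(N = x@universeN, K = x@categoryK, n = x@drawN, k = x@overlapK))

#' @rdname snp2drug-accessors
#' @export
setGeneric("expectedOverlap", function(x) standardGeneric("expectedOverlap"))
#' @rdname snp2drug-accessors
#' @export
setMethod("expectedOverlap", "OverlapTest", function(x) x@expected)

#' @rdname snp2drug-accessors
#' @export
setGeneric("xSet", function(x) standardGeneric("xSet"))
#' @rdname snp2drug-accessors
#' @export
setMethod("xSet", "DrugOverlapReport", function(x) x@xSet)

#' @rdname snp2drug-accessors
#' @export
setGeneric("crcTest", function(x) standardGeneric("crcTest"))
#' @rdname snp2drug-accessors
#' @export
setMethod("crcTest", "DrugOverlapReport", function(x) x@crcTest)

#' @rdname snp2drug-accessors
#' @export
setGeneric("allTest", function(x) standardGeneric("allTest"))
#' @rdname snp2drug-accessors
#' @export
setMethod("allTest", "DrugOverlapReport", function(x) x@allTest)

#' @rdname snp2drug-accessors
#' @export
setGeneric("relativeFoldEnrichment",
           function(x) standardGeneric("relativeFoldEnrichment"))
#' @rdname snp2drug-accessors
#' @export
setMethod("relativeFoldEnrichment", "DrugOverlapReport",
          function(x) x@relativeFold)

#' @rdname snp2drug-accessors
#' @export
setGeneric("connectionPaths", function(x) standardGeneric("connectionPaths"))
#' @rdname snp2drug-accessors
#' @export
setMethod("connectionPaths", "DrugOverlapReport", function(x) x@connections)
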