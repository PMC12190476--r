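#' @rdname RepertoireTable-class
#' @param object,x a \linkS4class{RepertoireTable}
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))

#' @rdname RepertoireTable-class
#' @export
setGeneric("cloneKeyMode", function(x) standardGeneric("cloneKeyMode"))

#' @rdname RepertoireTable-class
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @rdname RepertoireTable-class
#' @export
setGeneric("nClonotypes", function(x) standardGeneric("nClonotypes"))

#' @describeIn RepertoireTable-class clonotype records as a data.frame
#' @export
setMethod("clonotypes", "RepertoireTable", function(x) x@clonotypes)

#' @describeIn RepertoireTable-class clone-identity convention
#' @export
setMethod("cloneKeyMode", "RepertoireTable", function(x) x@cloneKeyMode)

#' @describeIn RepertoireTable-class provenance / parse report
#' @export
setMethod("parseReport", "RepertoireTable", function(x) x@provenance)

#' @describeIn RepertoireTable-class number of clonotype records
#' @export
setMethod("nClonotypes", "RepertoireTable", function(x) nrow(x@clonotypes))

setMethod("show", "RepertoireTable", function(object) {
  df <- object@clonotypes
  cat("RepertoireTable with", nrow(df), "clonotype records\n")
  cat("  clone key mode:", object@cloneKeyMode, "\n")
  if (nrow(df) > 0) {
    cat("  chains:", paste(names(table(df$chain)), table(df$chain),
                           sep = ":", collapse = " "), "\n")
    for (k in intersect(c("cluster", "treatment", "tissue"), names(df)))
      cat("  ", k, ": ", paste(unique(df[[k]]), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(object@provenance$n_dropped))
    cat("  parse report:", object@provenance$n_dropped, "row(s) dropped\n")
})

#' @rdname SpotLattice-class
#' @param x a \linkS4class{SpotLattice}
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname SpotLattice-class
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))

#' @rdname SpotLattice-class
#' @export
setGeneric("spotExpression", function(x) standardGeneric("spotExpression"))

#' @describeIn SpotLattice-class spot coordinates (barcode, x, y, in_tissue)
#' @export
setMethod("spotCoords", "SpotLattice", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(barcode = rownames(cd), x = cd$x, y = cd$y,
             in_tissue = cd$in_tissue, stringsAsFactors = FALSE)
})

#' @describeIn SpotLattice-class logical in-tissue mask
#' @export
setMethod("inTissue", "SpotLattice", function(x)
  SummarizedExperiment::colData(x)$in_tissue)

#' @describeIn SpotLattice-class genes x spots expression matrix
#' @export
setMethod("spotExpression", "SpotLattice", function(x)
  SummarizedExperiment::assay(x, "expression"))

setMethod("show", "SpotLattice", function(object) {
  cat("SpotLattice:", ncol(object), "spots x", nrow(object), "genes;",
      sum(SummarizedExperiment::colData(object)$in_tissue), "in tissue\n")
})

#' @rdname CoincidenceMap-class
#' @param x a \linkS4class{CoincidenceMap}
#' @export
setGeneric("coincidenceValues", function(x) standardGeneric("coincidenceValues"))

#' @rdname CoincidenceMap-class
#' @export
setGeneric("validSpots", function(x) standardGeneric("validSpots"))

#' @describeIn CoincidenceMap-class per-spot local correlations (NA invalid)
#' @export
setMethod("coincidenceValues", "CoincidenceMap", function(x)
  stats::setNames(x@values, x@barcode))

#' @describeIn CoincidenceMap-class logical validity mask
#' @export
setMethod("validSpots", "CoincidenceMap", function(x)
  stats::setNames(x@valid, x@barcode))

setMethod("show", "CoincidenceMap", function(object) {
  cat("CoincidenceMap", paste(object@genes, collapse = " ~ "), "\n")
  cat("  ", sum(object@valid), "valid /", length(object@valid), "spots;",
      "area >", object@params$threshold, "=",
      format(object@areaFraction, digits = 4), "\n")
})

#' @rdname CloneSetComparison-class
#' @param x a \linkS4class{CloneSetComparison}
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname CloneSetComparison-class
#' @export
setGeneric("sharedKeys", function(x) standardGeneric("sharedKeys"))

#' @rdname CloneSetComparison-class
#' @param group group label
#' @export
setGeneric("uniqueKeys", function(x, group) standardGeneric("uniqueKeys"))

#' @rdname CloneSetComparison-class
#' @param groupA,groupB a pair of group labels
#' @export
setGeneric("pairwiseShared", function(x, groupA, groupB)
  standardGeneric("pairwiseShared"))

#' @describeIn CloneSetComparison-class keys x groups 0/1 membership matrix
#' @export
setMethod("membershipMatrix", "CloneSetComparison", function(x) x@membership)

#' @describeIn CloneSetComparison-class keys present in every group
#' @export
setMethod("sharedKeys", "CloneSetComparison", function(x)
  rownames(x@membership)[rowSums(x@membership) == ncol(x@membership)])

#' @describeIn CloneSetComparison-class keys present in exactly this group
#' @export
setMethod("uniqueKeys", "CloneSetComparison", function(x, group) {
  stopifnot(group %in% colnames(x@membership))
  rownames(x@membership)[x@membership[, group] & rowSums(x@membership) == 1]
})

#' @describeIn CloneSetComparison-class keys present in both named groups
#' @export
setMethod("pairwiseShared", "CloneSetComparison", function(x, groupA, groupB) {
  stopifnot(all(c(groupA, groupB) %in% colnames(x@membership)))
  rownames(x@membership)[x@membership[, groupA] & x@membership[, groupB]]
})

setMethod("show", "CloneSetComparison", function(object) {
  g <- colnames(object@membership)
  cat("CloneSetComparison over", length(g), "groups:",
      paste(g, collapse = ", "), "\n")
  cat("  ", nrow(object@membership), "distinct keys;",
      length(sharedKeys(object)), "shared by all groups\n")
})

setMethod("show", "SRIConfig", function(object) {
  cat("SRIConfig: combine =", object@combine,
      "| required length =", object@requiredLength, "\n")
  if (object@combine == "sum")
    cat("  threshold >=", object@threshold, "(inclusive)\n")
  else
    cat("  promoting set: {", paste(object@promotingSet, collapse = ", "), "}\n")
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat("PositionFrequencyMatrix: length", nrow(object@freqs),
      "| support", object@support, paste0("(", object@weighting, "-weighted)"),
      "|", object@nExcluded, "clone(s) with 'X' excluded\n")
})
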