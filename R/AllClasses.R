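#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetically ordered residue alphabet used throughout the package.
#' CDR3 junctions may additionally contain \code{"X"} (undetermined residue);
#' positional analyses exclude such clones rather than impute them.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Recognised receptor chain loci
#' @export
CHAIN_LOCI <- c("TRB", "TRA", "IGH", "IGK", "IGL")

.valid_junction <- function(x) {
  nzchar(x) & !is.na(x) &
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) all(ch %in% c(AA_ALPHABET, "X")), logical(1))
}

#' RepertoireTable: a collection of clonotype records
#'
#' One row per receptor-chain clonotype record. Mandatory columns are
#' \code{sequence_id}, \code{chain}, \code{v_call}, \code{junction_aa} and
#' \code{count}; optional annotation columns include \code{barcode},
#' \code{j_call}, \code{c_call} (BCR isotype), \code{cluster},
#' \code{treatment} and \code{tissue}. The junction amino-acid string uses
#' 1-based indexing and includes both conserved anchors (position 1 is the
#' conserved cysteine), so positions 6/7 of a 13-mer are its central residues.
#'
#' @slot clonotypes data.frame of clonotype records
#' @slot cloneKeyMode clone-identity convention, one of \code{"cdr3_aa"},
#'   \code{"cdr3_aa+v"}
#' @slot provenance list describing the source file, parser dialect and
#'   parse report (rows dropped, notes)
#' @export
setClass("RepertoireTable",
  slots = c(clonotypes = "data.frame",
            cloneKeyMode = "character",
            provenance = "list"))

setValidity("RepertoireTable", function(object) {
  df <- object@clonotypes
  need <- c("sequence_id", "chain", "v_call", "junction_aa", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!object@cloneKeyMode %in% c("cdr3_aa", "cdr3_aa+v", "cdr3_nt"))
    return("cloneKeyMode must be one of cdr3_aa, cdr3_aa+v, cdr3_nt")
  if (nrow(df) > 0) {
    if (!all(.valid_junction(df$junction_aa)))
      return("junction_aa must be non-empty strings over the 20 residues + X")
    if (any(is.na(df$count)) || any(df$count < 0))
      return("count must be >= 0")
    if (!all(df$chain %in% CHAIN_LOCI))
      return(paste("unrecognised chain locus:",
                   paste(unique(setdiff(df$chain, CHAIN_LOCI)), collapse = ", ")))
  }
  TRUE
})

#' Construct a RepertoireTable
#'
#' @param clonotypes data.frame with at least \code{junction_aa}; missing
#'   bookkeeping columns (\code{sequence_id}, \code{chain}, \code{v_call},
#'   \code{count}) are filled with defaults
#' @param cloneKeyMode clone-identity convention (default \code{"cdr3_aa"}:
#'   chain + junction amino acids)
#' @param provenance list recording source and parse report
#' @return a \linkS4class{RepertoireTable}
#' @examples
#' rt <- RepertoireTable(data.frame(junction_aa = c("CASSF", "CAF")))
#' nClonotypes(rt)
#' @export
RepertoireTable <- function(clonotypes, cloneKeyMode = "cdr3_aa",
                            provenance = list()) {
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (is.null(df$sequence_id)) df$sequence_id <- sprintf("seq%06d", seq_len(n))
  if (is.null(df$chain)) df$chain <- rep("TRB", n)
  if (is.null(df$v_call)) df$v_call <- rep("TRBV1", n)
  if (is.null(df$count)) df$count <- rep(1L, n)
  rownames(df) <- NULL
  new("RepertoireTable", clonotypes = df, cloneKeyMode = cloneKeyMode,
      provenance = provenance)
}

#' ChemistryScheme: residue chemistry classification
#'
#' Partition of the 20 residues into mutually exclusive primary classes, plus
#' an aromatic overlay set (tyrosine is both aromatic and polar-uncharged, so
#' aromaticity is kept separate from the partition).
#'
#' @slot primaryClass named character vector mapping each residue to one of
#'   \code{hydrophobic}, \code{polar_uncharged}, \code{positively_charged},
#'   \code{negatively_charged}, \code{special}
#' @slot aromaticSet character vector of aromatic residues
#' @export
setClass("ChemistryScheme",
  slots = c(primaryClass = "character", aromaticSet = "character"))

setValidity("ChemistryScheme", function(object) {
  pc <- object@primaryClass
  if (!setequal(names(pc), AA_ALPHABET))
    return("primaryClass must name all 20 standard residues exactly once")
  ok <- c("hydrophobic", "polar_uncharged", "positively_charged",
          "negatively_charged", "special")
  if (!all(pc %in% ok))
    return(paste("unknown class:", paste(setdiff(pc, ok), collapse = ", ")))
  if (!all(object@aromaticSet %in% AA_ALPHABET))
    return("aromaticSet must be standard residues")
  TRUE
})

#' Default residue chemistry scheme
#'
#' hydrophobic \{A,V,L,I,M,F,W\}; polar uncharged \{S,T,N,Q,Y\}; positively
#' charged \{K,R,H\}; negatively charged \{D,E\}; special \{C,G,P\}.
#' Aromatic overlay defaults to \{F,W,Y\}.
#'
#' @param aromaticSet aromatic residue overlay
#' @return a \linkS4class{ChemistryScheme}
#' @export
defaultChemistryScheme <- function(aromaticSet = c("F", "W", "Y")) {
  cls <- c(hydrophobic = "AVLIMFW", polar_uncharged = "STNQY",
           positively_charged = "KRH", negatively_charged = "DE",
           special = "CGP")
  pc <- character(0)
  for (k in names(cls)) {
    res <- strsplit(cls[[k]], "")[[1]]
    pc[res] <- k
  }
  new("ChemistryScheme", primaryClass = pc[AA_ALPHABET],
      aromaticSet = aromaticSet)
}

#' PositionFrequencyMatrix: per-position residue frequencies of length-L CDR3s
#'
#' @slot freqs L x 20 matrix; rows are junction positions (1-based, anchors
#'   included), columns the residue alphabet; each row sums to 1 when
#'   \code{support > 0}
#' @slot support number of clones (or total count weight) tallied
#' @slot weighting \code{"clonotype"} (each clone once) or \code{"count"}
#' @slot nExcluded clones excluded for containing 'X'
#' @export
setClass("PositionFrequencyMatrix",
  slots = c(freqs = "matrix", support = "numeric", weighting = "character",
            nExcluded = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
  f <- object@freqs
  if (ncol(f) != 20L || !identical(colnames(f), AA_ALPHABET))
    return("freqs must have the 20-residue alphabet as columns")
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    return("frequencies must lie in [0, 1]")
  if (object@support > 0 && any(abs(rowSums(f) - 1) > 1e-9))
    return("each position's frequencies must sum to 1")
  TRUE
})

#' SRIConfig: self-reactivity index configuration
#'
#' Per-residue weights at junction positions 6 and 7, the required CDR3
#' length, and the classification rule. \code{combine = "sum"} scores a clone
#' as \code{weights["6", aa6] + weights["7", aa7]} and classifies it
#' self-reactive when the score is >= \code{threshold} (inclusive boundary).
#' The set-based modes classify on membership of P6/P7 in
#' \code{promotingSet}: \code{"both_promoting"} requires both positions in
#' the set, \code{"either_promoting"} at least one.
#'
#' @slot weights 2 x 20 numeric matrix, rownames \code{c("6","7")}, colnames
#'   the residue alphabet (required complete for \code{combine = "sum"})
#' @slot requiredLength junction length scored (default 13; others excluded)
#' @slot combine one of \code{"sum"}, \code{"both_promoting"},
#'   \code{"either_promoting"}
#' @slot threshold classification cutoff for \code{combine = "sum"}
#' @slot promotingSet residues treated as self-reactivity-promoting by the
#'   set-based modes
#' @export
setClass("SRIConfig",
  slots = c(weights = "matrix", requiredLength = "integer",
            combine = "character", threshold = "numeric",
            promotingSet = "character"))

setValidity("SRIConfig", function(object) {
  if (!object@combine %in% c("sum", "both_promoting", "either_promoting"))
    return("combine must be sum, both_promoting or either_promoting")
  if (object@requiredLength < 7L)
    return("requiredLength must be >= 7")
  if (object@combine == "sum") {
    w <- object@weights
    if (!identical(rownames(w), c("6", "7")) ||
        !identical(colnames(w), AA_ALPHABET))
      return("weights must be a 2 x 20 matrix with rownames '6','7' and the residue alphabet as columns")
    if (any(is.na(w)))
      return("weights must be defined for all residues at both positions")
  } else {
    if (!all(object@promotingSet %in% AA_ALPHABET))
      return("promotingSet must be standard residues")
  }
  TRUE
})

#' Construct an SRIConfig
#'
#' @param weights 2 x 20 matrix (rows positions 6 and 7), or a named list
#'   \code{list(`6` = c(Y = 1, ...), `7` = ...)} of sparse weights expanded
#'   over the alphabet with fill 0
#' @param requiredLength junction length scored (default 13)
#' @param combine scoring/classification mode (see \linkS4class{SRIConfig})
#' @param threshold classification cutoff for \code{combine = "sum"}
#' @param promotingSet residues for the set-based modes
#' @return an \linkS4class{SRIConfig}
#' @examples
#' cfg <- SRIConfig(list(`6` = c(Y = 1), `7` = c(W = 1)), threshold = 1.5)
#' sriScore("CASSLYWNTEVFF", cfg)
#' @export
SRIConfig <- function(weights = NULL, requiredLength = 13L,
                      combine = c("sum", "both_promoting", "either_promoting"),
                      threshold = 0, promotingSet = character(0)) {
  combine <- match.arg(combine)
  if (is.list(weights)) {
    w <- matrix(0, 2, 20, dimnames = list(c("6", "7"), AA_ALPHABET))
    for (p in c("6", "7")) {
      v <- weights[[p]]
      if (!is.null(v)) w[p, names(v)] <- v
    }
    weights <- w
  }
  if (is.null(weights))
    weights <- matrix(NA_real_, 2, 20, dimnames = list(c("6", "7"), AA_ALPHABET))
  new("SRIConfig", weights = weights, requiredLength = as.integer(requiredLength),
      combine = combine, threshold = threshold, promotingSet = promotingSet)
}

#' SpotLattice: spatial transcriptomics spots with expression
#'
#' A \linkS4class{SummarizedExperiment} (genes in rows, spots in columns)
#' whose \code{colData} carries the spot array coordinates \code{x}, \code{y}
#' (spot-pitch units) and the \code{in_tissue} flag. The single assay
#' \code{"expression"} holds non-negative values.
#'
#' @export
setClass("SpotLattice", contains = "SummarizedExperiment")

setValidity("SpotLattice", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("x", "y", "in_tissue")
  miss <- setdiff(need, names(cd))
  if (length(miss) > 0)
    return(paste("colData must contain:", paste(miss, collapse = ", ")))
  if (!"expression" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expression' required")
  if (ncol(object) > 0 && min(SummarizedExperiment::assay(object, "expression")) < 0)
    return("expression values must be non-negative")
  TRUE
})

#' Construct a SpotLattice
#'
#' @param expression genes x spots matrix (dense or sparse) with dimnames
#' @param coords data.frame with columns \code{barcode}, \code{x}, \code{y}
#'   and logical \code{in_tissue}; rows matched to the expression columns
#' @return a \linkS4class{SpotLattice}
#' @export
SpotLattice <- function(expression, coords) {
  coords <- as.data.frame(coords)
  if (is.null(colnames(expression)))
    stop("expression must carry spot barcodes as column names")
  m <- match(colnames(expression), coords$barcode)
  if (anyNA(m))
    stop("alignment error: barcodes absent from positions table: ",
         paste(utils::head(colnames(expression)[is.na(m)], 5), collapse = ", "))
  coords <- coords[m, , drop = FALSE]
  cd <- S4Vectors::DataFrame(x = as.numeric(coords$x), y = as.numeric(coords$y),
                             in_tissue = as.logical(coords$in_tissue),
                             row.names = coords$barcode)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = expression), colData = cd)
  new("SpotLattice", se)
}

#' CoincidenceMap: local gene-pair correlation over a spot lattice
#'
#' Per-spot kernel-weighted Pearson correlation of two genes, with a validity
#' mask (spots with too little effective neighbourhood weight or zero local
#' variance are invalid) and the area fraction above the positive-coincidence
#' threshold.
#'
#' @slot barcode spot identifiers (in-tissue spots only)
#' @slot x,y spot coordinates
#' @slot values local correlation per spot (\code{NA} where invalid)
#' @slot valid logical validity mask
#' @slot genes the gene pair
#' @slot params the \code{coincidenceParams()} used
#' @slot areaFraction fraction of valid spots with value > threshold
#' @export
setClass("CoincidenceMap",
  slots = c(barcode = "character", x = "numeric", y = "numeric",
            values = "numeric", valid = "logical", genes = "character",
            params = "list", areaFraction = "numeric"))

setValidity("CoincidenceMap", function(object) {
  n <- length(object@barcode)
  if (length(object@values) != n || length(object@valid) != n ||
      length(object@x) != n || length(object@y) != n)
    return("per-spot slots must have equal length")
  v <- object@values[object@valid]
  if (length(v) > 0 && (any(is.na(v)) || any(v < -1 - 1e-9) || any(v > 1 + 1e-9)))
    return("valid values must lie in [-1, 1]")
  TRUE
})

#' CloneSetComparison: presence/absence lattice of clone keys across groups
#'
#' @slot membership logical keys x groups matrix (key present in group)
#' @slot counts numeric keys x groups matrix of aggregated clone counts
#' @export
setClass("CloneSetComparison",
  slots = c(membership = "matrix", counts = "matrix"))

setValidity("CloneSetComparison", function(object) {
  if (!is.logical(object@membership)) return("membership must be logical")
  if (!identical(dim(object@membership), dim(object@counts)))
    return("membership and counts must share dimensions")
  if (is.null(colnames(object@membership)) || is.null(rownames(object@membership)))
    return("membership needs key rownames and group colnames")
  if (anyDuplicated(colnames(object@membership)))
    return("duplicate group labels")
  if (!all(rowSums(object@membership) >= 1))
    return("every key must be present in at least one group")
  TRUE
})
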