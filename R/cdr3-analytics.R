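#' CDR3 junction length
#'
#' Number of residues of the junction amino-acid string, anchors included
#' (position 1 is the conserved cysteine). The printed top shared BCR clone
#' \code{"CALWYSNHWVF"} is an 11-mer, the modal BCR CDR3 length in this
#' system.
#'
#' @param junction_aa character vector of junction sequences
#' @return integer vector of lengths
#' @examples
#' cdr3Length("CALWYSNHWVF")  # 11
#' @export
cdr3Length <- function(junction_aa) {
  if (length(junction_aa) == 0) return(integer(0))
  ok <- !is.na(junction_aa) & .valid_junction(junction_aa)
  if (!all(ok))
    stop("validation error: empty or illegal junction sequence(s): ",
         paste(utils::head(junction_aa[!ok], 3), collapse = ", "))
  nchar(junction_aa)
}

.empty_group_warn <- function(labels) {
  if (length(labels) > 0)
    warning("empty group(s) omitted: ", paste(labels, collapse = ", "))
}

#' CDR3 length distribution per group
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param group_by annotation columns to stratify by (e.g.
#'   \code{c("cluster")}); empty means one pooled group
#' @param weighting \code{"clonotype"} (each record once) or \code{"count"}
#' @return data.frame with columns \code{group}, \code{length}, \code{n},
#'   \code{frequency}; frequencies sum to 1 within each group
#' @export
lengthDistribution <- function(x, group_by = character(0),
                               weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  groups <- .group_rows(df, group_by)
  w_all <- .record_weights(df, weighting)
  len <- nchar(df$junction_aa)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    w <- w_all[i]
    if (sum(w) == 0) return(NULL)
    tab <- tapply(w, len[i], sum)
    data.frame(group = g, length = as.integer(names(tab)),
               n = as.numeric(tab), frequency = as.numeric(tab) / sum(w),
               stringsAsFactors = FALSE)
  })
  .empty_group_warn(names(groups)[vapply(out, is.null, logical(1))])
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' V-segment usage per group
#'
#' @inheritParams lengthDistribution
#' @param top_k how many top segments to report per group; ties broken by
#'   (frequency descending, gene name ascending)
#' @return list with \code{usage} (data.frame group, v_call, n, frequency)
#'   and \code{top} (data.frame group, rank, v_call, frequency)
#' @export
vGeneUsage <- function(x, group_by = character(0), top_k = 5,
                       weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  groups <- .group_rows(df, group_by)
  w_all <- .record_weights(df, weighting)
  usage <- list(); top <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    w <- w_all[i]
    if (sum(w) == 0) next
    tab <- tapply(w, df$v_call[i], sum)
    freq <- as.numeric(tab) / sum(tab)
    u <- data.frame(group = g, v_call = names(tab), n = as.numeric(tab),
                    frequency = freq, stringsAsFactors = FALSE)
    u <- u[order(-u$frequency, u$v_call), , drop = FALSE]
    usage[[g]] <- u
    k <- min(top_k, nrow(u))
    top[[g]] <- data.frame(group = g, rank = seq_len(k),
                           v_call = u$v_call[seq_len(k)],
                           frequency = u$frequency[seq_len(k)],
                           stringsAsFactors = FALSE)
  }
  usage <- do.call(rbind, usage); rownames(usage) <- NULL
  top <- do.call(rbind, top); rownames(top) <- NULL
  list(usage = usage, top = top)
}

#' Position frequency matrix of length-L junctions
#'
#' Tallies residue frequencies at every position of all length-\code{L}
#' junctions. Clones containing \code{'X'} are excluded (reported in the
#' \code{nExcluded} slot), not imputed.
#'
#' @inheritParams lengthDistribution
#' @param L junction length selected (e.g. 13 for TCRbeta 13-mers)
#' @return a \linkS4class{PositionFrequencyMatrix}; when no length-L clones
#'   exist the result has \code{support} 0 and an all-zero matrix
#' @export
positionFrequencyMatrix <- function(x, L, weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  len <- nchar(df$junction_aa)
  sel <- len == L
  hasX <- grepl("X", df$junction_aa, fixed = TRUE)
  use <- which(sel & !hasX)
  nEx <- sum(sel & hasX)
  f <- matrix(0, L, 20, dimnames = list(seq_len(L), AA_ALPHABET))
  if (length(use) == 0) {
    warning("no usable length-", L, " clones; empty-support result")
    return(new("PositionFrequencyMatrix", freqs = f, support = 0,
               weighting = weighting, nExcluded = as.integer(nEx)))
  }
  w <- .record_weights(df, weighting)[use]
  chars <- .junction_chars(df$junction_aa[use])
  for (k in seq_along(use)) {
    cc <- chars[[k]]
    for (p in seq_len(L)) f[p, cc[p]] <- f[p, cc[p]] + w[k]
  }
  support <- sum(w)
  new("PositionFrequencyMatrix", freqs = f / support, support = support,
      weighting = weighting, nExcluded = as.integer(nEx))
}

#' Aggregate a position frequency matrix into chemistry-class fractions
#'
#' @param pfm a \linkS4class{PositionFrequencyMatrix}
#' @param scheme a \linkS4class{ChemistryScheme} (default
#'   \code{defaultChemistryScheme()})
#' @return data.frame with columns \code{position}, \code{class},
#'   \code{fraction}; fractions sum to 1 at each position
#' @export
classifyPositionChemistry <- function(pfm, scheme = defaultChemistryScheme()) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"), is(scheme, "ChemistryScheme"))
  cls <- scheme@primaryClass[colnames(pfm@freqs)]
  agg <- t(apply(pfm@freqs, 1, function(row) tapply(row, cls, sum)))
  classes <- colnames(agg)
  out <- data.frame(
    position = rep(seq_len(nrow(agg)), times = length(classes)),
    class = rep(classes, each = nrow(agg)),
    fraction = as.numeric(agg), stringsAsFactors = FALSE)
  out[order(out$position, out$class), , drop = FALSE]
}

# Compile the motif grammar to an anchored regular expression.
# Grammar: literal residues; '?' exactly one arbitrary residue; '(n)'
# exactly n arbitrary residues; '*' zero or more; 'X' any residue.
.compile_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern))
    stop("pattern error at position 1: empty pattern")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1
      digits <- character(0)
      while (j <= length(chars) && chars[j] != ")") {
        digits <- c(digits, chars[j]); j <- j + 1
      }
      if (j > length(chars))
        stop("pattern error at position ", i, ": unclosed '('")
      bad <- which(!grepl("[0-9]", digits))
      if (length(bad) > 0)
        stop("pattern error at position ", i + bad[1],
             ": expected digit in (n)")
      if (length(digits) == 0)
        stop("pattern error at position ", i + 1, ": empty (n)")
      out <- c(out, sprintf(".{%s}", paste(digits, collapse = "")))
      i <- j + 1
    } else if (ch == "?") {
      out <- c(out, "."); i <- i + 1
    } else if (ch == "*") {
      out <- c(out, ".*"); i <- i + 1
    } else if (ch == "X") {
      out <- c(out, "."); i <- i + 1
    } else if (ch %in% AA_ALPHABET) {
      out <- c(out, ch); i <- i + 1
    } else {
      stop("pattern error at position ", i, ": illegal character '", ch, "'")
    }
  }
  paste0("^", paste(out, collapse = ""), "$")
}

#' Match junctions against a CDR3 motif pattern
#'
#' Pattern grammar: literal residues match themselves; \code{'?'} matches
#' exactly one arbitrary residue; \code{'(n)'} exactly \code{n} arbitrary
#' residues; \code{'*'} zero or more; \code{'X'} any single residue. The
#' shared BCR motif \code{"CQQ(4)PXTF"} and the unique-clone motif
#' \code{"CA(7)YW"} are 11-mer instances of this grammar.
#'
#' @param junction_aa character vector of junction sequences
#' @param pattern motif string
#' @return logical vector
#' @examples
#' motifMatch("CQQSNEDPLTF", "CQQ(4)PXTF")   # TRUE
#' motifMatch("CASSLGAYEQYF", "CA*F")        # TRUE
#' @export
motifMatch <- function(junction_aa, pattern) {
  rx <- .compile_motif(pattern)
  grepl(rx, junction_aa)
}

#' Fraction of clonotypes conforming to a motif
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param pattern motif string (see \code{\link{motifMatch}})
#' @param weighting record weighting mode
#' @return fraction of evaluated clonotypes matching the pattern
#' @export
motifConformity <- function(x, pattern, weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  if (nrow(df) == 0) return(NA_real_)
  w <- .record_weights(df, weighting)
  hit <- motifMatch(df$junction_aa, pattern)
  sum(w[hit]) / sum(w)
}

#' Isotype (constant-region call) usage per group
#'
#' @inheritParams lengthDistribution
#' @return list with \code{usage} (data.frame group, c_call, n, frequency
#'   over records carrying a c_call) and \code{unassigned} (data.frame
#'   group, n without c_call)
#' @export
isotypeUsage <- function(x, group_by = character(0),
                         weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  has_c <- if (is.null(df$c_call)) rep(FALSE, nrow(df)) else
    (!is.na(df$c_call) & nzchar(df$c_call))
  w_all <- .record_weights(df, weighting)
  groups <- .group_rows(df, group_by)
  usage <- list(); unassigned <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    i_c <- i[has_c[i]]
    unassigned[[g]] <- data.frame(group = g, n = sum(w_all[setdiff(i, i_c)]),
                                  stringsAsFactors = FALSE)
    if (length(i_c) == 0) next
    tab <- tapply(w_all[i_c], df$c_call[i_c], sum)
    usage[[g]] <- data.frame(group = g, c_call = names(tab),
                             n = as.numeric(tab),
                             frequency = as.numeric(tab) / sum(tab),
                             stringsAsFactors = FALSE)
  }
  usage <- do.call(rbind, usage); rownames(usage) <- NULL
  unassigned <- do.call(rbind, unassigned); rownames(unassigned) <- NULL
  list(usage = usage, unassigned = unassigned)
}

#' Write a position frequency matrix in plain PWM text layout
#'
#' One row per position, tab-separated residue columns, consumable by
#' sequence-logo renderers.
#'
#' @param pfm a \linkS4class{PositionFrequencyMatrix}
#' @param path output path
#' @return invisibly, the path
#' @export
writePFM <- function(pfm, path) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"))
  out <- data.frame(position = seq_len(nrow(pfm@freqs)), pfm@freqs,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
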