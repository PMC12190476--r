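#' Load a self-reactivity weight table
#'
#' Reads a TSV with columns \code{position} (6 or 7), \code{residue} and
#' \code{weight} into an \linkS4class{SRIConfig}. For \code{combine = "sum"}
#' the table must cover all 20 residues at both positions; gaps are rejected
#' with a message listing them. For the set-based modes the table's residues
#' (any position) define the promoting set and weights are ignored.
#'
#' The per-residue index values are configuration data, not package
#' constants: \code{inst/extdata/sri_toy.tsv} is a toy table used by the
#' examples and tests, and \code{inst/extdata/sri_template.tsv} is a blank
#' template to be populated from the thymic-selection literature the index
#' derives from.
#'
#' @param path TSV path
#' @param requiredLength junction length scored (default 13)
#' @param combine scoring mode
#' @param threshold classification cutoff (combine = "sum")
#' @return an \linkS4class{SRIConfig}
#' @export
loadSRITable <- function(path, requiredLength = 13L,
                         combine = c("sum", "both_promoting",
                                     "either_promoting"),
                         threshold = 0) {
  combine <- match.arg(combine)
  if (!file.exists(path)) stop("cannot read SRI table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("position", "residue"))
    if (!col %in% names(df))
      stop("format error: SRI table missing column: ", col)
  if (combine != "sum") {
    return(SRIConfig(requiredLength = requiredLength, combine = combine,
                     threshold = threshold,
                     promotingSet = sort(unique(df$residue))))
  }
  if (!"weight" %in% names(df))
    stop("format error: SRI table missing column: weight")
  w <- matrix(NA_real_, 2, 20, dimnames = list(c("6", "7"), AA_ALPHABET))
  for (k in seq_len(nrow(df))) {
    p <- as.character(df$position[k])
    if (!p %in% c("6", "7"))
      stop("config error: position must be 6 or 7, got ", p)
    w[p, df$residue[k]] <- as.numeric(df$weight[k])
  }
  gaps <- which(is.na(w), arr.ind = TRUE)
  if (nrow(gaps) > 0)
    stop("config error: missing weight(s): ",
         paste(sprintf("P%s:%s", rownames(w)[gaps[, 1]],
                       colnames(w)[gaps[, 2]]), collapse = ", "))
  SRIConfig(weights = w, requiredLength = requiredLength, combine = "sum",
            threshold = threshold)
}

#' Write an SRIConfig weight table
#'
#' Round-trips with \code{\link{loadSRITable}}.
#'
#' @param config an \linkS4class{SRIConfig}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeSRITable <- function(config, path) {
  stopifnot(is(config, "SRIConfig"))
  if (config@combine == "sum") {
    w <- config@weights
    out <- data.frame(position = rep(c(6L, 7L), each = 20),
                      residue = rep(AA_ALPHABET, 2),
                      weight = c(w["6", ], w["7", ]))
  } else {
    out <- data.frame(position = NA_integer_, residue = config@promotingSet,
                      weight = NA_real_)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Residues at positions 6 and 7, or NULL when the clone is not scoreable
# (wrong length, or 'X' at either position).
.p67 <- function(junction_aa, requiredLength) {
  if (nchar(junction_aa) != requiredLength) return(NULL)
  aa <- substring(junction_aa, 6:7, 6:7)
  if (any(aa == "X")) return(NULL)
  aa
}

#' Per-clone self-reactivity index
#'
#' Scores the residues at junction positions 6 and 7 (1-based, anchors
#' included; the central residues of a 13-mer). Clones whose length differs
#' from \code{requiredLength}, or with \code{'X'} at P6/P7, are undefined
#' (\code{NA}) and excluded from downstream fractions. For
#' \code{combine = "sum"} the score is the sum of the two positional
#' weights; the set-based modes return a 0/1 indicator of promoting-set
#' membership (both positions, or either).
#'
#' @param junction_aa character vector of junctions
#' @param config an \linkS4class{SRIConfig}
#' @return numeric vector of scores (\code{NA} = undefined/excluded)
#' @examples
#' cfg <- SRIConfig(list(`6` = c(Y = 1), `7` = c(W = 1)), threshold = 1.5)
#' sriScore("CASSLYWNTEVFF", cfg)  # 2
#' sriScore("CALWYSNHWVF", cfg)    # NA: 11-mer under requiredLength 13
#' @export
sriScore <- function(junction_aa, config) {
  stopifnot(is(config, "SRIConfig"))
  vapply(junction_aa, function(s) {
    aa <- .p67(s, config@requiredLength)
    if (is.null(aa)) return(NA_real_)
    switch(config@combine,
      sum = config@weights["6", aa[1]] + config@weights["7", aa[2]],
      both_promoting = as.numeric(all(aa %in% config@promotingSet)),
      either_promoting = as.numeric(any(aa %in% config@promotingSet)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify scores as predicted self-reactive
#'
#' \code{combine = "sum"}: self-reactive iff score >= threshold (inclusive
#' boundary, fixed for determinism). Set-based modes: their 0/1 indicator.
#' Undefined scores stay \code{NA} and are never counted in either class.
#'
#' @param score numeric scores from \code{\link{sriScore}}
#' @param config the \linkS4class{SRIConfig} used
#' @return logical vector (\code{NA} for undefined scores)
#' @export
classifySelfReactive <- function(score, config) {
  stopifnot(is(config, "SRIConfig"))
  if (config@combine == "sum") score >= config@threshold else score > 0
}

#' Per-group self-reactive clone fractions
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param config an \linkS4class{SRIConfig}
#' @param group_by annotation columns (e.g. \code{c("cluster")})
#' @param weighting record weighting mode
#' @return data.frame with per group: \code{n_total}, \code{n_scored},
#'   \code{n_excluded}, \code{n_self_reactive}, \code{fraction}
#'   (\code{NA} when no clone in the group is scoreable)
#' @export
clusterSelfReactivity <- function(x, config, group_by = character(0),
                                  weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  sc <- sriScore(df$junction_aa, config)
  sr <- classifySelfReactive(sc, config)
  w <- .record_weights(df, weighting)
  groups <- .group_rows(df, group_by)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    scored <- i[!is.na(sc[i])]
    n_scored <- sum(w[scored])
    data.frame(group = g, n_total = sum(w[i]), n_scored = n_scored,
               n_excluded = sum(w[i]) - n_scored,
               n_self_reactive = sum(w[scored][sr[scored]]),
               fraction = if (n_scored > 0)
                 sum(w[scored][sr[scored]]) / n_scored else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-group aromatic P6/P7 fractions
#'
#' Fraction of scoreable clones (length filter and 'X' exclusion as in
#' \code{\link{sriScore}}) carrying an aromatic residue at junction position
#' 6 or 7 (\code{mode = "or"}, the default) or at both (\code{mode = "and"}).
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param aromaticSet aromatic residues (default \{F, W, Y\})
#' @param group_by annotation columns
#' @param requiredLength junction length scored (default 13)
#' @param mode \code{"or"} (either position) or \code{"and"} (both)
#' @param weighting record weighting mode
#' @return data.frame with per group: \code{n_scored}, \code{n_aromatic},
#'   \code{fraction}
#' @export
aromaticP67Fraction <- function(x, aromaticSet = c("F", "W", "Y"),
                                group_by = character(0), requiredLength = 13L,
                                mode = c("or", "and"),
                                weighting = c("clonotype", "count")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  df <- clonotypes(x)
  w <- .record_weights(df, weighting)
  hit <- vapply(df$junction_aa, function(s) {
    aa <- .p67(s, requiredLength)
    if (is.null(aa)) return(NA)
    if (mode == "or") any(aa %in% aromaticSet) else all(aa %in% aromaticSet)
  }, logical(1), USE.NAMES = FALSE)
  groups <- .group_rows(df, group_by)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    scored <- i[!is.na(hit[i])]
    n_scored <- sum(w[scored])
    data.frame(group = g, n_scored = n_scored,
               n_aromatic = sum(w[scored][hit[scored]]),
               fraction = if (n_scored > 0)
                 sum(w[scored][hit[scored]]) / n_scored else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
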