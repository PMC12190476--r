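#' Clone identity keys
#'
#' Builds the clone key for each record under the table's (or an explicit)
#' key convention: \code{"cdr3_aa"} = chain + junction amino acids;
#' \code{"cdr3_aa+v"} additionally includes the V call. The chain is always
#' part of the key, so an IGH and a TRB clone with the same CDR3 never
#' collide.
#'
#' @param x a \linkS4class{RepertoireTable} or a clonotype data.frame
#' @param mode key convention; defaults to the table's \code{cloneKeyMode}
#' @return character vector of keys
#' @export
cloneKey <- function(x, mode = NULL) {
  if (is(x, "RepertoireTable")) {
    if (is.null(mode)) mode <- cloneKeyMode(x)
    df <- clonotypes(x)
  } else {
    df <- x
    if (is.null(mode)) mode <- "cdr3_aa"
  }
  switch(mode,
    cdr3_aa = paste(df$chain, df$junction_aa, sep = "|"),
    `cdr3_aa+v` = paste(df$chain, df$junction_aa, df$v_call, sep = "|"),
    stop("unsupported clone key mode: ", mode))
}

# Aggregated count per clone key for a subset of rows.
.key_counts <- function(df, rows, keys) {
  tab <- tapply(as.numeric(df$count[rows]), keys[rows], sum)
  tab[sort(names(tab))]
}

#' Clonal expansion profile per group
#'
#' Aggregates counts per clone key within each group, bins clonotypes into
#' frequency classes, and computes a clonality index
#' \code{1 - H / log(R)} where \code{H} is the Shannon entropy (natural log)
#' of the clone frequency distribution and \code{R} the number of distinct
#' clonotypes. A single-clonotype group has index 1 by convention; an
#' all-singleton group has index 0. The index is invariant under uniform
#' rescaling of counts.
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param group_by annotation columns
#' @param breaks lower edges of the frequency classes (default
#'   \code{c(1, 2, 4, 10)} giving classes 1, 2-3, 4-9, >=10)
#' @return data.frame with per group: one column per frequency class,
#'   \code{n_clonotypes}, \code{n_cells}, \code{clonality_index}
#' @export
expansionProfile <- function(x, group_by = character(0),
                             breaks = c(1, 2, 4, 10)) {
  df <- clonotypes(x)
  keys <- cloneKey(x)
  groups <- .group_rows(df, group_by)
  labs <- vapply(seq_along(breaks), function(i) {
    if (i == length(breaks)) paste0(">=", breaks[i])
    else if (breaks[i + 1] - breaks[i] == 1) as.character(breaks[i])
    else paste0(breaks[i], "-", breaks[i + 1] - 1)
  }, character(1))
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    if (length(i) == 0) return(NULL)
    cnt <- .key_counts(df, i, keys)
    R <- length(cnt)
    p <- cnt / sum(cnt)
    H <- -sum(p * log(p))
    ci <- if (R == 1) 1 else 1 - H / log(R)
    cls <- table(factor(findInterval(cnt, breaks), levels = seq_along(breaks)))
    row <- data.frame(group = g, stringsAsFactors = FALSE)
    for (k in seq_along(labs)) row[[labs[k]]] <- as.integer(cls[k])
    row$n_clonotypes <- R
    row$n_cells <- sum(cnt)
    row$clonality_index <- ci
    row
  })
  drop <- vapply(out, is.null, logical(1))
  if (any(drop)) warning("empty group(s) omitted: ",
                         paste(names(groups)[drop], collapse = ", "))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Shared / unique clone partition across groups
#'
#' Builds the presence/absence lattice of clone keys over the groups defined
#' by \code{group_by} (or over a list of tables). The resulting
#' \linkS4class{CloneSetComparison} exposes the fully-shared key set, the
#' per-group unique sets and pairwise intersections; the partition cells of
#' the presence/absence lattice are disjoint and cover the key universe.
#'
#' @param x a \linkS4class{RepertoireTable}, or a named list of them (one
#'   per group)
#' @param group_by annotation column(s) defining the groups when \code{x} is
#'   a single table (e.g. \code{"treatment"})
#' @return a \linkS4class{CloneSetComparison}
#' @export
overlapPartition <- function(x, group_by = "treatment") {
  if (is.list(x) && !is(x, "RepertoireTable")) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("list groups must carry unique names")
    modes <- unique(vapply(x, cloneKeyMode, character(1)))
    if (length(modes) > 1) stop("groups disagree on cloneKeyMode")
    dfs <- lapply(x, clonotypes)
    glab <- rep(names(x), vapply(dfs, nrow, integer(1)))
    df <- do.call(rbind, lapply(dfs, function(d)
      d[c("chain", "junction_aa", "v_call", "count")]))
    keys <- cloneKey(df, modes)
  } else {
    df <- clonotypes(x)
    if (!all(group_by %in% names(df)))
      stop("grouping column(s) absent: ",
           paste(setdiff(group_by, names(df)), collapse = ", "))
    glab <- do.call(paste, c(df[group_by], sep = "/"))
    keys <- cloneKey(x)
  }
  if (length(keys) < 1 || length(unique(glab)) < 2)
    stop("overlapPartition needs at least two groups")
  groups <- unique(glab)
  allk <- sort(unique(keys))
  mem <- matrix(FALSE, length(allk), length(groups),
                dimnames = list(allk, groups))
  cnt <- matrix(0, length(allk), length(groups),
                dimnames = list(allk, groups))
  for (g in groups) {
    rows <- which(glab == g)
    tab <- tapply(as.numeric(df$count[rows]), keys[rows], sum)
    mem[names(tab), g] <- TRUE
    cnt[names(tab), g] <- as.numeric(tab)
  }
  new("CloneSetComparison", membership = mem, counts = cnt)
}

#' Track clones across tissues
#'
#' Presence and aggregated counts of every clone key per tissue, with a
#' dual-tissue flag for clones observed in more than one tissue (e.g. both
#' injured muscle and the draining inguinal lymph node). Matching follows
#' the table's clone key convention (amino-acid sequence matching by
#' default).
#'
#' @param x a \linkS4class{RepertoireTable} with a \code{tissue} column, or
#'   a named list of tables keyed by tissue
#' @param group_by tissue column name when \code{x} is one table
#' @return data.frame: \code{key}, one count column per tissue,
#'   \code{n_tissues}, \code{dual_tissue}
#' @export
trackClones <- function(x, group_by = "tissue") {
  cmp <- overlapPartition(x, group_by = group_by)
  cnt <- cmp@counts
  out <- data.frame(key = rownames(cnt), stringsAsFactors = FALSE)
  for (g in colnames(cnt)) out[[paste0("count_", g)]] <- cnt[, g]
  out$n_tissues <- rowSums(cmp@membership)
  out$dual_tissue <- out$n_tissues >= 2
  rownames(out) <- NULL
  out
}

#' Abundance of one clone per group
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param key clone key as produced by \code{\link{cloneKey}}, or a bare
#'   junction string (matched as chain-agnostic junction)
#' @param group_by annotation columns
#' @return data.frame per group: \code{proportion} (of the group's total
#'   count) and \code{count}; (0, 0) where absent
#' @export
cloneAbundance <- function(x, key, group_by = character(0)) {
  df <- clonotypes(x)
  keys <- cloneKey(x)
  hit <- if (grepl("|", key, fixed = TRUE)) keys == key else
    df$junction_aa == key
  groups <- .group_rows(df, group_by)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    tot <- sum(as.numeric(df$count[i]))
    n <- sum(as.numeric(df$count[i][hit[i]]))
    data.frame(group = g, proportion = if (tot > 0) n / tot else 0,
               count = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top clones per group
#'
#' Ranks clone keys by aggregated count (descending), ties broken by key
#' (ascending).
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param group_by annotation columns
#' @param k clones per group (truncated to the number of distinct keys)
#' @return data.frame: \code{group}, \code{rank}, \code{key},
#'   \code{count}, \code{proportion}
#' @export
topClones <- function(x, group_by = character(0), k = 10) {
  stopifnot(k >= 1)
  df <- clonotypes(x)
  keys <- cloneKey(x)
  groups <- .group_rows(df, group_by)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    if (length(i) == 0) return(NULL)
    tab <- tapply(as.numeric(df$count[i]), keys[i], sum)
    ord <- order(-as.numeric(tab), names(tab))
    kk <- min(k, length(tab))
    sel <- ord[seq_len(kk)]
    data.frame(group = g, rank = seq_len(kk), key = names(tab)[sel],
               count = as.numeric(tab)[sel],
               proportion = as.numeric(tab)[sel] / sum(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-unique expanded clones
#'
#' Composes \code{\link{overlapPartition}} with a count cutoff: clone keys
#' present in exactly one group with aggregated count >= \code{min_count}
#' (default 2, i.e. any expansion). This is the "unique and expanded"
#' read-out used to flag treatment-specific, potentially autoreactive
#' clones.
#'
#' @param x a \linkS4class{RepertoireTable} or named list of tables
#' @param group_by grouping column(s) when \code{x} is one table
#' @param group the group whose unique expanded clones are wanted
#' @param min_count expansion cutoff (aggregated count, inclusive)
#' @return data.frame: \code{key}, \code{count}
#' @export
uniqueExpandedClones <- function(x, group_by = "treatment", group,
                                 min_count = 2) {
  cmp <- overlapPartition(x, group_by = group_by)
  uk <- uniqueKeys(cmp, group)
  cnt <- cmp@counts[uk, group]
  sel <- cnt >= min_count
  out <- data.frame(key = uk[sel], count = as.numeric(cnt[sel]),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$key), , drop = FALSE]
}
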