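#' Read an AIRR Rearrangement TSV into a RepertoireTable
#'
#' Expects a tab-separated file with a header containing at least
#' \code{junction_aa} and \code{v_call}; \code{duplicate_count} (or
#' \code{count}) supplies clone counts, defaulting to 1 when absent. Extra
#' columns (e.g. \code{cluster}, \code{treatment}, \code{tissue}) are
#' preserved as annotations. Rows with an empty \code{junction_aa} are
#' dropped and tallied in the parse report.
#'
#' @param path path to the TSV
#' @param cloneKeyMode clone-identity convention for downstream set algebra
#' @return a \linkS4class{RepertoireTable}; \code{parseReport()} records the
#'   source, dialect and number of dropped rows
#' @export
readAIRR <- function(path, cloneKeyMode = "cdr3_aa") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  for (col in c("junction_aa", "v_call"))
    if (!col %in% names(df))
      stop("format error: mandatory column missing: ", col)
  n_in <- nrow(df)
  keep <- !is.na(df$junction_aa) & nzchar(df$junction_aa)
  df <- df[keep, , drop = FALSE]
  notes <- character(0)
  if ("duplicate_count" %in% names(df)) {
    df$count <- as.integer(df$duplicate_count)
    df$duplicate_count <- NULL
  } else if ("count" %in% names(df)) {
    df$count <- as.integer(df$count)
  } else {
    df$count <- 1L
    notes <- c(notes, "no duplicate_count column; counts set to 1")
  }
  if (!"sequence_id" %in% names(df))
    df$sequence_id <- sprintf("row%06d", which(keep))
  if (!"chain" %in% names(df)) {
    df$chain <- ifelse(grepl("^IGH", df$v_call), "IGH",
                ifelse(grepl("^IGK", df$v_call), "IGK",
                ifelse(grepl("^IGL", df$v_call), "IGL",
                ifelse(grepl("^TRA", df$v_call), "TRA", "TRB"))))
    notes <- c(notes, "chain inferred from v_call prefix")
  }
  RepertoireTable(df, cloneKeyMode = cloneKeyMode,
                  provenance = list(source = path, dialect = "airr",
                                    n_input = n_in, n_dropped = n_in - nrow(df),
                                    notes = notes))
}

#' Read a 10x-style filtered contig annotation CSV
#'
#' Maps \code{cdr3} to \code{junction_aa} and \code{v_gene}/\code{j_gene}/
#' \code{c_gene} to the AIRR-style calls. Counts come from \code{umis},
#' falling back to \code{reads} (noted in provenance). Rows whose
#' \code{cdr3} is the dialect's missing token (\code{"None"}, \code{""},
#' \code{NA}) are dropped and reported. When several contigs share a
#' (barcode, chain) pair only the highest-count row is kept, so each cell
#' contributes one record per chain.
#'
#' @inheritParams readAIRR
#' @return a \linkS4class{RepertoireTable}
#' @export
readTenxContigs <- function(path, cloneKeyMode = "cdr3_aa") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("barcode", "chain", "v_gene", "cdr3"))
    if (!col %in% names(df))
      stop("format error: mandatory column missing: ", col)
  n_in <- nrow(df)
  notes <- character(0)
  if ("umis" %in% names(df)) {
    df$count <- as.integer(df$umis)
  } else if ("reads" %in% names(df)) {
    df$count <- as.integer(df$reads)
    notes <- c(notes, "umis column absent; counts taken from reads")
  } else stop("format error: mandatory column missing: umis (or reads)")
  missing_tok <- is.na(df$cdr3) | df$cdr3 %in% c("", "None", "NA")
  df <- df[!missing_tok, , drop = FALSE]
  names(df)[names(df) == "cdr3"] <- "junction_aa"
  names(df)[names(df) == "v_gene"] <- "v_call"
  if ("j_gene" %in% names(df)) names(df)[names(df) == "j_gene"] <- "j_call"
  if ("c_gene" %in% names(df)) names(df)[names(df) == "c_gene"] <- "c_call"
  # one record per (barcode, chain): keep the best-supported contig
  if (nrow(df) > 0) {
    ord <- order(df$barcode, df$chain, -df$count)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df[c("barcode", "chain")]), , drop = FALSE]
  }
  if (!"sequence_id" %in% names(df)) {
    cid <- if ("contig_id" %in% names(df)) df$contig_id else
      paste(df$barcode, df$chain, sep = "_")
    df$sequence_id <- cid
  }
  rownames(df) <- NULL
  RepertoireTable(df, cloneKeyMode = cloneKeyMode,
                  provenance = list(source = path, dialect = "tenx",
                                    n_input = n_in,
                                    n_dropped = n_in - nrow(df),
                                    notes = notes))
}

#' Write a RepertoireTable as AIRR Rearrangement TSV
#'
#' Field order is fixed (\code{sequence_id}, \code{v_call}, \code{j_call},
#' \code{junction_aa}, \code{duplicate_count}, then remaining annotation
#' columns alphabetically), so output is byte-stable and
#' \code{readAIRR(writeAIRR(x))} reproduces junctions, calls, counts and
#' annotations exactly.
#'
#' @param x a \linkS4class{RepertoireTable}
#' @param path output path
#' @return invisibly, the path
#' @export
writeAIRR <- function(x, path) {
  stopifnot(is(x, "RepertoireTable"))
  df <- clonotypes(x)
  out <- data.frame(sequence_id = df$sequence_id, v_call = df$v_call,
                    stringsAsFactors = FALSE)
  out$j_call <- if (!is.null(df$j_call)) df$j_call else
    rep("", nrow(df))
  out$junction_aa <- df$junction_aa
  out$duplicate_count <- df$count
  rest <- setdiff(names(df), c(names(out), "count", "duplicate_count"))
  for (col in sort(rest)) out[[col]] <- df[[col]]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a spot lattice from MTX triplet (or dense CSV) plus positions table
#'
#' @param matrix_path MatrixMarket file (genes x spots) or a dense CSV whose
#'   first column is the gene name and whose header names the spot barcodes
#' @param features_path one feature name per line (ignored for dense CSV)
#' @param barcodes_path one spot barcode per line (ignored for dense CSV)
#' @param positions_path CSV with columns \code{barcode}, \code{in_tissue}
#'   (0/1 or logical), \code{x}, \code{y}
#' @return a \linkS4class{SpotLattice}; every matrix barcode must appear in
#'   the positions table, otherwise an alignment error names the offenders
#' @export
readSpatial <- function(matrix_path, features_path = NULL,
                        barcodes_path = NULL, positions_path) {
  if (grepl("\\.csv$", matrix_path)) {
    dense <- utils::read.csv(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- dense[[1]]
    m <- as.matrix(dense[, -1, drop = FALSE])
    rownames(m) <- genes
    mat <- Matrix::Matrix(m, sparse = TRUE)
  } else {
    mat <- Matrix::readMM(matrix_path)
    genes <- readLines(features_path)
    bcs <- readLines(barcodes_path)
    if (nrow(mat) != length(genes) || ncol(mat) != length(bcs))
      stop("alignment error: matrix dimensions do not match feature/barcode lists")
    dimnames(mat) <- list(genes, bcs)
  }
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  for (col in c("barcode", "in_tissue", "x", "y"))
    if (!col %in% names(pos))
      stop("format error: positions table missing column: ", col)
  absent <- setdiff(colnames(mat), pos$barcode)
  if (length(absent) > 0)
    stop("alignment error: spot(s) absent from positions table: ",
         paste(absent, collapse = ", "))
  pos$in_tissue <- as.logical(as.integer(as.logical(pos$in_tissue)) |
                              (pos$in_tissue %in% c("1", "TRUE", "true")))
  SpotLattice(mat, pos)
}

#' Write a SpotLattice to MTX triplet plus positions CSV
#'
#' Emits the same formats \code{readSpatial()} consumes, so generated data
#' can be run through the full file-based pipeline.
#'
#' @param x a \linkS4class{SpotLattice}
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the four file paths
#' @export
writeSpatial <- function(x, dir, prefix = "lattice") {
  stopifnot(is(x, "SpotLattice"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c("_matrix.mtx", "_features.tsv",
                                       "_barcodes.tsv", "_positions.csv")))
  Matrix::writeMM(methods::as(Matrix::Matrix(spotExpression(x), sparse = TRUE),
                              "generalMatrix"), p[1])
  writeLines(rownames(x), p[2])
  writeLines(colnames(x), p[3])
  co <- spotCoords(x)
  co$in_tissue <- as.integer(co$in_tissue)
  utils::write.csv(co[c("barcode", "in_tissue", "x", "y")], p[4],
                   row.names = FALSE, quote = FALSE)
  invisible(p)
}
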