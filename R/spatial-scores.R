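#' Module score parameters
#'
#' @param n_bins number of equal-frequency expression bins the genes are cut
#'   into by mean expression (default 24)
#' @param n_ctrl control genes drawn per signature gene from its bin
#'   (default 100; drawn without replacement, with replacement only when the
#'   bin is smaller than \code{n_ctrl}, which is reported)
#' @param seed RNG seed for the control draw
#' @return list of class parameters for \code{\link{moduleScore}}
#' @export
moduleScoreParams <- function(n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(n_bins >= 2, n_ctrl >= 1)
  list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
       seed = as.integer(seed))
}

#' Coincidence parameters
#'
#' @param bandwidth Gaussian kernel scale in spot-pitch units (default 2)
#' @param min_effective_neighbors validity cutoff on the effective
#'   neighbourhood weight (sum of kernel weights, self included; default 8)
#' @param threshold positive-coincidence cutoff on the local correlation
#'   (default 0.2, exceeded strictly)
#' @return parameter list for \code{\link{localCoincidence}}
#' @export
coincidenceParams <- function(bandwidth = 2, min_effective_neighbors = 8,
                              threshold = 0.2) {
  stopifnot(bandwidth > 0, threshold >= -1, threshold <= 1)
  list(bandwidth = bandwidth,
       min_effective_neighbors = min_effective_neighbors,
       threshold = threshold)
}

#' Gene-signature module score with binned control genes
#'
#' Re-implementation of the standard binned-control signature score: genes
#' are ranked by mean expression across observations and cut into
#' \code{n_bins} equal-frequency bins; for every signature gene,
#' \code{n_ctrl} control genes are drawn from its bin; the score of an
#' observation is the mean expression of the signature genes minus the mean
#' expression of the pooled (deduplicated) control genes. Input is assumed
#' log-normalised. The draw is seeded and reproducible, and invariant to
#' the order of genes in the matrix.
#'
#' @param x genes x observations matrix (dense or sparse, rownames
#'   required), or a \linkS4class{SpotLattice} /
#'   \code{SummarizedExperiment}
#' @param gene_set character vector of signature genes; genes absent from
#'   the matrix are dropped with a warning
#' @param params \code{\link{moduleScoreParams}()}
#' @return named numeric vector of per-observation scores, with attributes
#'   \code{control_genes} (the pooled control set) and
#'   \code{small_bin_replacement} (whether any bin was smaller than
#'   \code{n_ctrl})
#' @export
moduleScore <- function(x, gene_set, params = moduleScoreParams()) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, 1)
  if (is.null(rownames(x))) stop("expression matrix needs gene rownames")
  present <- intersect(gene_set, rownames(x))
  if (length(present) < length(gene_set))
    warning("dropping ", length(gene_set) - length(present),
            " signature gene(s) absent from the matrix")
  if (length(present) == 0) stop("empty gene set after dropping absent genes")
  means <- if (is(x, "sparseMatrix")) Matrix::rowMeans(x) else rowMeans(x)
  # order-invariant equal-frequency binning: rank genes by (mean, name)
  ord <- order(means, rownames(x))
  bin <- integer(length(means))
  bin[ord] <- ceiling(seq_along(ord) * params$n_bins / length(ord))
  names(bin) <- rownames(x)
  small_bin <- FALSE
  ctrl <- with_seed(params$seed, {
    unlist(lapply(sort(present), function(g) {
      mates <- sort(names(bin)[bin == bin[g]])
      if (length(mates) < params$n_ctrl) {
        small_bin <<- TRUE
        sample(mates, params$n_ctrl, replace = TRUE)
      } else sample(mates, params$n_ctrl, replace = FALSE)
    }))
  })
  ctrl <- unique(ctrl)
  cm <- if (is(x, "sparseMatrix")) Matrix::colMeans else colMeans
  score <- cm(x[present, , drop = FALSE]) - cm(x[ctrl, , drop = FALSE])
  score <- stats::setNames(as.numeric(score), colnames(x))
  attr(score, "control_genes") <- ctrl
  attr(score, "small_bin_replacement") <- small_bin
  score
}

#' Map per-spot scores onto a lattice and summarise the section
#'
#' @param scores named numeric vector (names = spot barcodes), e.g. from
#'   \code{\link{moduleScore}}
#' @param lattice a \linkS4class{SpotLattice}
#' @return list with \code{map} (data.frame barcode, x, y, in_tissue,
#'   score) and \code{summary} (mean / median / quartiles over in-tissue
#'   spots only)
#' @export
mapScoresToSpots <- function(scores, lattice) {
  stopifnot(is(lattice, "SpotLattice"))
  co <- spotCoords(lattice)
  if (is.null(names(scores)))
    stop("alignment error: scores must be named by spot barcode")
  m <- match(co$barcode, names(scores))
  if (all(is.na(m)))
    stop("alignment error: no score barcode matches the lattice")
  co$score <- as.numeric(scores)[m]
  s <- co$score[co$in_tissue & !is.na(co$score)]
  list(map = co,
       summary = data.frame(n = length(s), mean = mean(s),
                            median = stats::median(s),
                            q25 = as.numeric(stats::quantile(s, 0.25)),
                            q75 = as.numeric(stats::quantile(s, 0.75))))
}

#' Local spatial coincidence of a gene pair
#'
#' For each in-tissue focal spot, computes the Pearson correlation of the
#' two genes over neighbouring in-tissue spots under Gaussian kernel
#' weights \eqn{w_i = \exp(-d_i^2 / (2 b^2))} (self included, weight 1):
#' weighted means, variances and covariance, then
#' \eqn{r = cov / \sqrt{var_A var_B}}. A spot is invalid when its effective
#' neighbourhood weight \eqn{\sum w_i} falls below
#' \code{min_effective_neighbors} or either weighted variance is zero. The
#' map records the fraction of valid spots whose correlation strictly
#' exceeds the positive-coincidence threshold.
#'
#' @param lattice a \linkS4class{SpotLattice}
#' @param geneA,geneB gene names (order-symmetric)
#' @param params \code{\link{coincidenceParams}()}
#' @return a \linkS4class{CoincidenceMap} over the in-tissue spots
#' @export
localCoincidence <- function(lattice, geneA, geneB,
                             params = coincidenceParams()) {
  stopifnot(is(lattice, "SpotLattice"))
  for (g in c(geneA, geneB))
    if (!g %in% rownames(lattice)) stop("gene absent from lattice: ", g)
  keep <- which(inTissue(lattice))
  if (length(keep) < 2) stop("need at least 2 in-tissue spots")
  co <- spotCoords(lattice)[keep, , drop = FALSE]
  a <- as.numeric(spotExpression(lattice)[geneA, keep])
  b <- as.numeric(spotExpression(lattice)[geneB, keep])
  d2 <- outer(co$x, co$x, "-")^2 + outer(co$y, co$y, "-")^2
  W <- exp(-d2 / (2 * params$bandwidth^2))
  sw <- rowSums(W)
  ma <- as.numeric(W %*% a) / sw
  mb <- as.numeric(W %*% b) / sw
  va <- as.numeric(W %*% (a * a)) / sw - ma^2
  vb <- as.numeric(W %*% (b * b)) / sw - mb^2
  cv <- as.numeric(W %*% (a * b)) / sw - ma * mb
  eps <- 1e-12
  valid <- sw >= params$min_effective_neighbors & va > eps & vb > eps
  r <- rep(NA_real_, length(keep))
  r[valid] <- pmin(1, pmax(-1, cv[valid] / sqrt(va[valid] * vb[valid])))
  area <- if (any(valid)) mean(r[valid] > params$threshold) else NA_real_
  new("CoincidenceMap", barcode = co$barcode, x = co$x, y = co$y,
      values = r, valid = valid, genes = c(geneA, geneB), params = params,
      areaFraction = area)
}

#' Coincidence area above a threshold
#'
#' Fraction of valid spots whose local correlation strictly exceeds
#' \code{threshold}; monotone non-increasing in the threshold.
#'
#' @param map a \linkS4class{CoincidenceMap}
#' @param threshold correlation cutoff (default the map's own, 0.2 by
#'   default)
#' @return a fraction in [0, 1]; \code{NA} (with a warning) when the map
#'   has no valid spot
#' @export
coincidenceArea <- function(map, threshold = NULL) {
  stopifnot(is(map, "CoincidenceMap"))
  if (is.null(threshold)) threshold <- map@params$threshold
  v <- map@values[map@valid]
  if (length(v) == 0) {
    warning("no valid spots; coincidence area undefined")
    return(NA_real_)
  }
  mean(v > threshold)
}

#' Export a coincidence map as a tidy table
#'
#' @param map a \linkS4class{CoincidenceMap}
#' @return data.frame: \code{barcode}, \code{x}, \code{y}, \code{value},
#'   \code{valid}
#' @export
coincidenceTable <- function(map) {
  stopifnot(is(map, "CoincidenceMap"))
  data.frame(barcode = map@barcode, x = map@x, y = map@y,
             value = map@values, valid = map@valid, stringsAsFactors = FALSE)
}
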