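#' Repertoire simulation configuration
#'
#' Seeded generator settings for multi-cluster receptor repertoires with
#' known ground truth: cluster-specific clonal expansion, planted P6/P7
#' self-reactive enrichment, a globally dominant V segment, fully-shared and
#' treatment-unique clones, cross-tissue clones, and optional motif-template
#' clones.
#'
#' Defaults emulate the structure of a TCRbeta repertoire from injured
#' muscle: CDR3 lengths concentrated on 13-15 residues, a killer-Treg-like
#' first cluster that is self-reactive-enriched (planted fraction 0.3 vs 0.1
#' elsewhere) but not clonally expanded (singleton counts), power-law
#' expansion (exponent 2.5) in the remaining clusters, and a dominant V
#' segment present in every cluster.
#'
#' @param n_clusters number of cell clusters
#' @param clones_per_cluster clonotype records per cluster
#' @param chain receptor chain for all records (\code{"TRB"} or \code{"IGH"})
#' @param length_distribution named probability vector over junction lengths
#' @param expansion either a single spec or a list of per-cluster specs;
#'   a spec is \code{list(type = "singleton")} or
#'   \code{list(type = "powerlaw", exponent = 2.5, max = 100)}
#' @param self_reactive_fraction per-cluster probability that a 13-mer clone
#'   is planted self-reactive (P6 and P7 drawn from \code{promoting_set});
#'   recycled over clusters
#' @param promoting_set residues planted at P6/P7 of self-reactive clones;
#'   non-planted clones are rejection-sampled so that P6 and P7 are never
#'   both in this set, making the planted label exact ground truth for the
#'   \code{both_promoting} classifier
#' @param aromatic_p67_prob optional probability that a non-self-reactive
#'   13-mer carries an aromatic residue at P6 or P7 (exact planting: the
#'   complement carries none); \code{NULL} leaves the background untouched
#' @param aromatic_set aromatic residues for the planting above
#' @param vgene_segments V segment universe
#' @param dominant_segment segment up-weighted in every cluster
#' @param dominant_weight sampling weight of the dominant segment (others 1)
#' @param treatments treatment-group labels
#' @param tissues tissue labels (first = local tissue, second = draining
#'   lymph node)
#' @param n_shared clones planted in every treatment (first tissue)
#' @param n_treatment_unique clones planted per treatment, guaranteed unique
#'   to it and expanded (count >= 2)
#' @param n_cross_tissue clones planted in both tissues of the second
#'   treatment
#' @param motif_templates optional list of \code{list(pattern =, n =)};
#'   each plants \code{n} clones realised from the motif pattern, and all
#'   other junctions are rejection-sampled to not match any template
#' @param isotype_probs named probability vector of constant-region calls
#'   (used when \code{chain = "IGH"}; default IGHM/IGHD-dominated)
#' @param seed RNG seed
#' @return validated configuration list
#' @export
repertoireSimConfig <- function(n_clusters = 6, clones_per_cluster = 200,
    chain = "TRB",
    length_distribution = c(`12` = 0.10, `13` = 0.40, `14` = 0.30, `15` = 0.20),
    expansion = NULL,
    self_reactive_fraction = c(0.30, rep(0.10, n_clusters - 1)),
    promoting_set = c("F", "W", "Y"),
    aromatic_p67_prob = NULL, aromatic_set = c("F", "W", "Y"),
    vgene_segments = paste0("TRBV", 1:20), dominant_segment = "TRBV3",
    dominant_weight = 4,
    treatments = c("control", "ECM", "PE"), tissues = c("muscle", "ILN"),
    n_shared = 5, n_treatment_unique = 10, n_cross_tissue = 8,
    motif_templates = NULL, isotype_probs = NULL, seed = 1L) {
  if (abs(sum(length_distribution) - 1) > 1e-9)
    stop("config error: length_distribution must sum to 1")
  if (is.null(expansion)) {
    expansion <- c(list(list(type = "singleton")),
                   rep(list(list(type = "powerlaw", exponent = 2.5,
                                 max = 100)), n_clusters - 1))
  } else if (!is.null(expansion$type)) {
    expansion <- rep(list(expansion), n_clusters)
  }
  if (length(expansion) != n_clusters)
    stop("config error: need one expansion spec per cluster")
  self_reactive_fraction <- rep_len(self_reactive_fraction, n_clusters)
  if (any(self_reactive_fraction < 0 | self_reactive_fraction > 1))
    stop("config error: self_reactive_fraction must lie in [0, 1]")
  n_planted <- n_shared * length(treatments) +
    n_treatment_unique * length(treatments) + n_cross_tissue
  if (chain == "IGH" && is.null(isotype_probs))
    isotype_probs <- c(IGHM = 0.5, IGHD = 0.2, IGHG1 = 0.15, IGHA = 0.15)
  cfg <- list(n_clusters = n_clusters,
              clones_per_cluster = clones_per_cluster, chain = chain,
              length_distribution = length_distribution,
              expansion = expansion,
              self_reactive_fraction = self_reactive_fraction,
              promoting_set = promoting_set,
              aromatic_p67_prob = aromatic_p67_prob,
              aromatic_set = aromatic_set,
              vgene_segments = vgene_segments,
              dominant_segment = dominant_segment,
              dominant_weight = dominant_weight,
              treatments = treatments, tissues = tissues,
              n_shared = n_shared, n_treatment_unique = n_treatment_unique,
              n_cross_tissue = n_cross_tissue,
              motif_templates = motif_templates,
              isotype_probs = isotype_probs, seed = as.integer(seed))
  total_bg <- n_clusters * clones_per_cluster
  n_motif <- sum(vapply(motif_templates, function(t) t$n, numeric(1)))
  if (length(motif_templates) > 0 && n_motif > total_bg)
    stop("config error: planted motif clones exceed total clones")
  cfg
}

.draw_count <- function(spec, n) {
  if (spec$type == "singleton") return(rep(1L, n))
  if (spec$type != "powerlaw") stop("config error: unknown expansion type")
  k <- seq_len(spec$max %||% 100)
  p <- k^(-spec$exponent)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random junction: conserved C + i.i.d. interior + F/W terminal anchor.
.draw_junction <- function(len, p_termF = 0.9) {
  interior <- sample(AA_ALPHABET, len - 2, replace = TRUE)
  term <- if (stats::runif(1) < p_termF) "F" else "W"
  paste0("C", paste(interior, collapse = ""), term)
}

.realise_motif <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- character(0); i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1; digits <- character(0)
      while (chars[j] != ")") { digits <- c(digits, chars[j]); j <- j + 1 }
      n <- as.integer(paste(digits, collapse = ""))
      out <- c(out, sample(AA_ALPHABET, n, replace = TRUE))
      i <- j + 1
    } else if (ch %in% c("?", "X")) {
      out <- c(out, sample(AA_ALPHABET, 1)); i <- i + 1
    } else if (ch == "*") {
      out <- c(out, sample(AA_ALPHABET, sample(0:3, 1), replace = TRUE))
      i <- i + 1
    } else { out <- c(out, ch); i <- i + 1 }
  }
  paste(out, collapse = "")
}

#' Simulate a repertoire with ground truth
#'
#' Pure function of its configuration (seed included): identical configs
#' give byte-identical tables. Background junctions are rejection-sampled to
#' be globally unique, so the planted shared / treatment-unique /
#' cross-tissue key sets are exact ground truth for the set-algebra stages.
#'
#' @param config from \code{\link{repertoireSimConfig}}
#' @return list with \code{table} (a \linkS4class{RepertoireTable}) and
#'   \code{truth}: per-clone data.frame (planted self-reactive and
#'   aromatic-P6/P7 labels, planting type) plus \code{shared_keys},
#'   \code{unique_keys} (per treatment), \code{cross_tissue_keys},
#'   \code{motif_sequence_ids} and the per-cluster expansion specs
#' @export
simulateRepertoire <- function(config = repertoireSimConfig()) {
  with_seed(config$seed, .simulate_repertoire_impl(config))
}

.simulate_repertoire_impl <- function(cfg) {
  lens <- as.integer(names(cfg$length_distribution))
  seen <- new.env(hash = TRUE)
  templates <- cfg$motif_templates
  matches_template <- function(s) {
    for (t in templates) if (motifMatch(s, t$pattern)) return(TRUE)
    FALSE
  }
  fresh_junction <- function(len) {
    repeat {
      s <- .draw_junction(len)
      if (!is.null(seen[[s]])) next
      if (length(templates) > 0 && matches_template(s)) next
      seen[[s]] <- TRUE
      return(s)
    }
  }
  set_p67 <- function(s, res6, res7) {
    paste0(substr(s, 1, 5), res6, res7, substr(s, 8, nchar(s)))
  }
  rows <- list()
  truth_rows <- list()
  idx <- 0
  add_row <- function(junction, cluster, treatment, tissue, count, planted,
                      self_reactive = NA, aromatic = NA) {
    idx <<- idx + 1
    vw <- ifelse(cfg$vgene_segments == cfg$dominant_segment,
                 cfg$dominant_weight, 1)
    v <- sample(cfg$vgene_segments, 1, prob = vw / sum(vw))
    cc <- if (!is.null(cfg$isotype_probs))
      sample(names(cfg$isotype_probs), 1, prob = cfg$isotype_probs) else NA
    rows[[idx]] <<- data.frame(
      sequence_id = sprintf("sim%05d", idx), barcode = NA_character_,
      chain = cfg$chain, v_call = v, j_call = paste0(cfg$chain, "J1"),
      junction_aa = junction, c_call = cc, count = as.integer(count),
      cluster = cluster, treatment = treatment, tissue = tissue,
      stringsAsFactors = FALSE)
    truth_rows[[idx]] <<- data.frame(
      sequence_id = sprintf("sim%05d", idx), junction_aa = junction,
      cluster = cluster, treatment = treatment, tissue = tissue,
      count = as.integer(count), length = nchar(junction),
      self_reactive = self_reactive, aromatic_p67 = aromatic,
      planted = planted, stringsAsFactors = FALSE)
  }
  # background clones, cluster by cluster
  for (c in seq_len(cfg$n_clusters)) {
    clab <- paste0("cluster", c)
    counts <- .draw_count(cfg$expansion[[c]], cfg$clones_per_cluster)
    for (k in seq_len(cfg$clones_per_cluster)) {
      len <- lens[sample.int(length(lens), 1, prob = cfg$length_distribution)]
      sr <- NA; ar <- NA
      if (len == 13L) {
        sr <- stats::runif(1) < cfg$self_reactive_fraction[c]
        if (!sr && !is.null(cfg$aromatic_p67_prob))
          ar <- stats::runif(1) < cfg$aromatic_p67_prob
        repeat {
          s <- .draw_junction(len)
          if (sr) {
            r6 <- sample(cfg$promoting_set, 1)
            r7 <- sample(cfg$promoting_set, 1)
          } else {
            repeat {
              r6 <- sample(AA_ALPHABET, 1); r7 <- sample(AA_ALPHABET, 1)
              both_prom <- r6 %in% cfg$promoting_set &&
                r7 %in% cfg$promoting_set
              if (both_prom) next
              if (is.na(ar)) break
              hasar <- r6 %in% cfg$aromatic_set || r7 %in% cfg$aromatic_set
              if (hasar == ar) break
            }
          }
          s <- set_p67(s, r6, r7)
          if (is.null(seen[[s]]) &&
              !(length(templates) > 0 && matches_template(s))) break
        }
        seen[[s]] <- TRUE
        if (is.na(ar)) ar <- any(c(r6, r7) %in% cfg$aromatic_set)
      } else {
        s <- fresh_junction(len)
      }
      add_row(s, clab, sample(cfg$treatments, 1), cfg$tissues[1], counts[k],
              planted = "background", self_reactive = sr, aromatic = ar)
    }
  }
  # motif-template clones replace the junctions of the first planted rows
  motif_ids <- character(0)
  if (length(templates) > 0) {
    bg_idx <- seq_along(rows)
    take <- 0
    for (t in templates) {
      for (j in seq_len(t$n)) {
        take <- take + 1
        repeat {
          s <- .realise_motif(t$pattern)
          if (is.null(seen[[s]])) break
        }
        seen[[s]] <- TRUE
        rows[[take]]$junction_aa <- s
        truth_rows[[take]]$junction_aa <- s
        truth_rows[[take]]$planted <- paste0("motif:", t$pattern)
        truth_rows[[take]]$self_reactive <- NA
        truth_rows[[take]]$aromatic_p67 <- NA
        truth_rows[[take]]$length <- nchar(s)
        motif_ids <- c(motif_ids, rows[[take]]$sequence_id)
      }
    }
  }
  pl_count <- function() 1L + .draw_count(list(type = "powerlaw",
                                               exponent = 2.5, max = 50), 1)
  shared_keys <- character(0)
  for (k in seq_len(cfg$n_shared)) {
    len <- lens[sample.int(length(lens), 1, prob = cfg$length_distribution)]
    s <- fresh_junction(len)
    shared_keys <- c(shared_keys, paste(cfg$chain, s, sep = "|"))
    for (tr in cfg$treatments)
      add_row(s, paste0("cluster", sample(cfg$n_clusters, 1)), tr,
              cfg$tissues[1], pl_count(), planted = "shared")
  }
  unique_keys <- stats::setNames(vector("list", length(cfg$treatments)),
                                 cfg$treatments)
  for (tr in cfg$treatments) {
    for (k in seq_len(cfg$n_treatment_unique)) {
      len <- lens[sample.int(length(lens), 1, prob = cfg$length_distribution)]
      s <- fresh_junction(len)
      unique_keys[[tr]] <- c(unique_keys[[tr]], paste(cfg$chain, s, sep = "|"))
      add_row(s, paste0("cluster", sample(cfg$n_clusters, 1)), tr,
              cfg$tissues[1], pl_count(), planted = "treatment_unique")
    }
  }
  cross_keys <- character(0)
  if (cfg$n_cross_tissue > 0 && length(cfg$tissues) >= 2) {
    tr <- cfg$treatments[min(2, length(cfg$treatments))]
    for (k in seq_len(cfg$n_cross_tissue)) {
      len <- lens[sample.int(length(lens), 1, prob = cfg$length_distribution)]
      s <- fresh_junction(len)
      cross_keys <- c(cross_keys, paste(cfg$chain, s, sep = "|"))
      cl <- paste0("cluster", sample(cfg$n_clusters, 1))
      add_row(s, cl, tr, cfg$tissues[1], pl_count(), planted = "cross_tissue")
      add_row(s, cl, tr, cfg$tissues[2], pl_count(), planted = "cross_tissue")
    }
  }
  df <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  tab <- RepertoireTable(df, cloneKeyMode = "cdr3_aa",
                         provenance = list(source = "simulateRepertoire",
                                           dialect = "synthetic",
                                           seed = cfg$seed, n_dropped = 0))
  list(table = tab,
       truth = list(clones = truth, shared_keys = shared_keys,
                    unique_keys = unique_keys, cross_tissue_keys = cross_keys,
                    motif_sequence_ids = motif_ids,
                    expansion = cfg$expansion, config = cfg))
}

#' Spatial simulation configuration
#'
#' A rectangular spot lattice (pitch 1) containing a disc-shaped "injury
#' region" of stated area fraction. Inside the region, designated gene pairs
#' share a latent spatial factor (local co-expression) and signature genes
#' are up-shifted by \code{delta}; everywhere else expression is independent
#' noise around gene-specific baselines. Values are generated directly in a
#' log-normalised-like space and floored at zero (baselines are chosen so
#' truncation is negligible).
#'
#' @param nrow,ncol lattice dimensions (default 48 x 48)
#' @param region_fraction planted disc area as a fraction of spots
#' @param n_genes total genes
#' @param n_signature signature genes (named \code{sig001} ...)
#' @param delta expression shift of signature genes inside the region
#' @param n_pairs co-expressed gene pairs (named \code{coexA1}/\code{coexB1}
#'   ...)
#' @param pair_latent_sd latent factor strength shared by a pair inside the
#'   region
#' @param pair_noise_sd independent noise of the pair genes; the in-region
#'   local correlation is
#'   \code{pair_latent_sd^2 / (pair_latent_sd^2 + pair_noise_sd^2)}
#' @param noise_sd independent noise of all other genes
#' @param base_range gene baseline expression range (uniform)
#' @param pair_base baseline of the pair genes (kept high so the unit-scale
#'   noise never truncates at zero)
#' @param seed RNG seed
#' @return validated configuration list
#' @export
spatialSimConfig <- function(nrow = 48, ncol = 48, region_fraction = 0.2,
                             n_genes = 1000, n_signature = 30, delta = 0.5,
                             n_pairs = 1, pair_latent_sd = 0.8,
                             pair_noise_sd = 1.0, noise_sd = 0.25,
                             base_range = c(1, 3), pair_base = 5,
                             seed = 1L) {
  stopifnot(region_fraction > 0, region_fraction < 1, delta >= 0,
            n_genes >= n_signature + 2 * n_pairs)
  list(nrow = as.integer(nrow), ncol = as.integer(ncol),
       region_fraction = region_fraction, n_genes = as.integer(n_genes),
       n_signature = as.integer(n_signature), delta = delta,
       n_pairs = as.integer(n_pairs), pair_latent_sd = pair_latent_sd,
       pair_noise_sd = pair_noise_sd, noise_sd = noise_sd,
       base_range = base_range, pair_base = pair_base,
       seed = as.integer(seed))
}

#' Simulate a spot lattice with a planted injury region
#'
#' @param config from \code{\link{spatialSimConfig}}
#' @return list with \code{lattice} (a \linkS4class{SpotLattice}),
#'   \code{truth}: \code{injury_mask} (named logical per barcode),
#'   \code{signature_genes}, \code{pairs} (data.frame geneA, geneB),
#'   \code{delta} and the config
#' @export
simulateSpatial <- function(config = spatialSimConfig()) {
  with_seed(config$seed, .simulate_spatial_impl(config))
}

.simulate_spatial_impl <- function(cfg) {
  gx <- rep(seq_len(cfg$ncol), times = cfg$nrow)
  gy <- rep(seq_len(cfg$nrow), each = cfg$ncol)
  n <- length(gx)
  bc <- sprintf("spot%04d", seq_len(n))
  cx <- (1 + cfg$ncol) / 2; cy <- (1 + cfg$nrow) / 2
  d2 <- (gx - cx)^2 + (gy - cy)^2
  n_region <- round(cfg$region_fraction * n)
  # exactly n_region spots: take the n_region closest to the centre
  mask <- rank(d2, ties.method = "first") <= n_region
  sig <- sprintf("sig%03d", seq_len(cfg$n_signature))
  pairA <- if (cfg$n_pairs > 0) sprintf("coexA%d", seq_len(cfg$n_pairs)) else character(0)
  pairB <- if (cfg$n_pairs > 0) sprintf("coexB%d", seq_len(cfg$n_pairs)) else character(0)
  n_bg <- cfg$n_genes - cfg$n_signature - 2 * cfg$n_pairs
  bg <- sprintf("gene%04d", seq_len(n_bg))
  genes <- c(sig, pairA, pairB, bg)
  base <- stats::runif(cfg$n_genes, cfg$base_range[1], cfg$base_range[2])
  names(base) <- genes
  base[c(pairA, pairB)] <- cfg$pair_base
  expr <- matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                 cfg$n_genes, n, dimnames = list(genes, bc))
  expr <- expr + base
  expr[sig, mask] <- expr[sig, mask] + cfg$delta
  for (p in seq_len(cfg$n_pairs)) {
    z <- stats::rnorm(n)
    for (g in c(pairA[p], pairB[p])) {
      e <- cfg$pair_base + stats::rnorm(n, sd = cfg$pair_noise_sd)
      e[mask] <- e[mask] + cfg$pair_latent_sd * z[mask]
      expr[g, ] <- e
    }
  }
  expr <- pmax(expr, 0)
  lattice <- SpotLattice(expr,
    data.frame(barcode = bc, x = gx, y = gy, in_tissue = TRUE,
               stringsAsFactors = FALSE))
  list(lattice = lattice,
       truth = list(injury_mask = stats::setNames(mask, bc),
                    signature_genes = sig,
                    pairs = data.frame(geneA = pairA, geneB = pairB,
                                       stringsAsFactors = FALSE),
                    delta = cfg$delta, config = cfg))
}
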