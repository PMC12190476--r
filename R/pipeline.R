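#' Pipeline configuration
#'
#' Single structured configuration for the file-based pipeline stages; all
#' randomness flows from the one \code{seed}. A persisted copy of the
#' effective configuration accompanies every output set (the run manifest).
#'
#' @param out_dir output directory
#' @param seed root RNG seed
#' @param repertoire_path AIRR TSV input (stages repertoire/sri/clonality);
#'   when \code{NULL} the simulate stage's output inside \code{out_dir} is
#'   used
#' @param sri_table_path SRI weight TSV (stage sri, \code{combine = "sum"})
#' @param sri_combine scoring mode; the set-based modes take the promoting
#'   set from the table's residues
#' @param sri_threshold classification cutoff for \code{combine = "sum"}
#' @param group_by annotation keys used by the repertoire stages
#' @param repertoire_sim \code{\link{repertoireSimConfig}()} for the
#'   simulate stage
#' @param spatial_sim \code{\link{spatialSimConfig}()} for the simulate /
#'   spatial stages
#' @param module_params \code{\link{moduleScoreParams}()}
#' @param coincidence_params \code{\link{coincidenceParams}()}
#' @return configuration list of class \code{pipeline_config}
#' @export
pipelineConfig <- function(out_dir, seed = 1L, repertoire_path = NULL,
                           sri_table_path = NULL,
                           sri_combine = "both_promoting",
                           sri_threshold = 0,
                           group_by = c("cluster", "treatment"),
                           repertoire_sim = NULL, spatial_sim = NULL,
                           module_params = NULL,
                           coincidence_params = NULL) {
  seed <- as.integer(seed)
  if (is.null(repertoire_sim)) repertoire_sim <- repertoireSimConfig(seed = seed)
  if (is.null(spatial_sim)) spatial_sim <- spatialSimConfig(seed = seed)
  if (is.null(module_params)) module_params <- moduleScoreParams(seed = seed)
  if (is.null(coincidence_params)) coincidence_params <- coincidenceParams()
  structure(list(out_dir = out_dir, seed = seed,
                 repertoire_path = repertoire_path,
                 sri_table_path = sri_table_path,
                 sri_combine = sri_combine, sri_threshold = sri_threshold,
                 group_by = group_by, repertoire_sim = repertoire_sim,
                 spatial_sim = spatial_sim, module_params = module_params,
                 coincidence_params = coincidence_params),
            class = "pipeline_config")
}

.write_stage <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  invisible(names(tables))
}

.resolve_repertoire <- function(config) {
  p <- config$repertoire_path %||%
    file.path(config$out_dir, "simulate", "repertoire.tsv")
  if (!file.exists(p))
    stop("configuration error: repertoire input not found: ", p,
         " (run the simulate stage or set repertoire_path)")
  readAIRR(p)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} writes a synthetic repertoire (AIRR TSV) and
#' spot lattice (MTX triplet + positions CSV); \code{repertoire} computes
#' length distributions, V usage and isotype usage; \code{sri} the
#' self-reactivity tables; \code{clonality} expansion profiles, overlap
#' partition, clone tracking and top clones; \code{spatial} module scores
#' and the gene-pair coincidence maps of the simulated co-expressed pair;
#' \code{report} collates every stage summary into one CSV. Each stage
#' writes tidy CSVs under \code{out_dir/<stage>/} plus a JSON run manifest
#' recording the package version, seed, inputs and excluded-record counts.
#' Outputs are deterministic given config + seed.
#'
#' @param stage one of \code{"simulate"}, \code{"repertoire"},
#'   \code{"sri"}, \code{"clonality"}, \code{"spatial"}, \code{"report"},
#'   or \code{"all"}
#' @param config a \code{\link{pipelineConfig}}
#' @return invisibly, a list of the stage's principal tables
#' @export
runPipeline <- function(stage = c("all", "simulate", "repertoire", "sri",
                                  "clonality", "spatial", "report"),
                        config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  if (stage == "all") {
    for (s in c("simulate", "repertoire", "sri", "clonality", "spatial",
                "report"))
      runPipeline(s, config)
    return(invisible(NULL))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    simulate = .stage_simulate(config),
    repertoire = .stage_repertoire(config),
    sri = .stage_sri(config),
    clonality = .stage_clonality(config),
    spatial = .stage_spatial(config),
    report = .stage_report(config))
  manifest <- list(stage = stage, package = "clonoSpat",
                   version = as.character(utils::packageVersion("clonoSpat")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   tables = names(out))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(out)
}

.stage_simulate <- function(config) {
  dir <- file.path(config$out_dir, "simulate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateRepertoire(config$repertoire_sim)
  writeAIRR(sim$table, file.path(dir, "repertoire.tsv"))
  utils::write.csv(sim$truth$clones, file.path(dir, "repertoire_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  sp <- simulateSpatial(config$spatial_sim)
  writeSpatial(sp$lattice, dir, prefix = "spatial")
  utils::write.csv(data.frame(barcode = names(sp$truth$injury_mask),
                              injury = as.integer(sp$truth$injury_mask)),
                   file.path(dir, "spatial_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(repertoire_truth = sim$truth$clones))
}

.stage_repertoire <- function(config) {
  rep <- .resolve_repertoire(config)
  gb <- intersect(config$group_by, names(clonotypes(rep)))
  iso <- isotypeUsage(rep, gb)
  tabs <- list(length_distribution = lengthDistribution(rep, gb),
               vgene_usage = vGeneUsage(rep, gb)$usage,
               vgene_top = vGeneUsage(rep, gb)$top)
  if (!is.null(iso$usage)) tabs$isotype_usage <- iso$usage
  .write_stage(tabs, file.path(config$out_dir, "repertoire"))
  invisible(tabs)
}

.stage_sri <- function(config) {
  rep <- .resolve_repertoire(config)
  if (is.null(config$sri_table_path))
    stop("configuration error: sri stage requires sri_table_path")
  cfg <- loadSRITable(config$sri_table_path, combine = config$sri_combine,
                      threshold = config$sri_threshold)
  gb <- intersect(config$group_by, names(clonotypes(rep)))
  tabs <- list(self_reactivity = clusterSelfReactivity(rep, cfg, gb),
               aromatic_p67 = aromaticP67Fraction(rep, group_by = gb))
  .write_stage(tabs, file.path(config$out_dir, "sri"))
  invisible(tabs)
}

.stage_clonality <- function(config) {
  rep <- .resolve_repertoire(config)
  df <- clonotypes(rep)
  gb <- intersect(config$group_by, names(df))
  tabs <- list(expansion = expansionProfile(rep, gb),
               top_clones = topClones(rep, gb, k = 10))
  if ("treatment" %in% names(df) && length(unique(df$treatment)) >= 2) {
    cmp <- overlapPartition(rep, "treatment")
    mm <- membershipMatrix(cmp)
    tabs$clone_membership <- data.frame(key = rownames(mm),
                                        mm * 1L, check.names = FALSE)
  }
  if ("tissue" %in% names(df) && length(unique(df$tissue)) >= 2)
    tabs$clone_tracking <- trackClones(rep, "tissue")
  .write_stage(tabs, file.path(config$out_dir, "clonality"))
  invisible(tabs)
}

.stage_spatial <- function(config) {
  dir <- file.path(config$out_dir, "simulate")
  p <- file.path(dir, paste0("spatial", c("_matrix.mtx", "_features.tsv",
                                          "_barcodes.tsv", "_positions.csv")))
  if (!all(file.exists(p)))
    stop("configuration error: spatial inputs not found under ", dir)
  lattice <- readSpatial(p[1], p[2], p[3], p[4])
  sig <- grep("^sig", rownames(lattice), value = TRUE)
  tabs <- list()
  if (length(sig) > 0) {
    sc <- moduleScore(lattice, sig, config$module_params)
    ms <- mapScoresToSpots(sc, lattice)
    tabs$module_score_map <- ms$map
    tabs$module_score_summary <- ms$summary
  }
  pA <- grep("^coexA", rownames(lattice), value = TRUE)
  for (a in pA) {
    b <- sub("^coexA", "coexB", a)
    if (!b %in% rownames(lattice)) next
    map <- localCoincidence(lattice, a, b, config$coincidence_params)
    tabs[[paste0("coincidence_", a, "_", b)]] <- coincidenceTable(map)
    tabs$coincidence_area <- rbind(tabs$coincidence_area,
      data.frame(geneA = a, geneB = b,
                 threshold = config$coincidence_params$threshold,
                 area_fraction = map@areaFraction))
  }
  .write_stage(tabs, file.path(config$out_dir, "spatial"))
  invisible(tabs)
}

.stage_report <- function(config) {
  rows <- list()
  add <- function(stage, file) {
    p <- file.path(config$out_dir, stage, file)
    if (file.exists(p)) {
      d <- utils::read.csv(p, check.names = FALSE)
      d2 <- data.frame(stage = stage, table = sub("\\.csv$", "", file),
                       d, check.names = FALSE)
      rows[[length(rows) + 1]] <<- d2
    }
  }
  for (st in c("repertoire", "sri", "clonality", "spatial")) {
    dir <- file.path(config$out_dir, st)
    if (!dir.exists(dir)) next
    for (f in sort(list.files(dir, pattern = "\\.csv$")))
      add(st, f)
  }
  dir.create(file.path(config$out_dir, "report"), showWarnings = FALSE)
  summary_rows <- do.call(rbind, lapply(rows, function(d) {
    data.frame(stage = d$stage[1], table = d$table[1], n_rows = nrow(d))
  }))
  if (is.null(summary_rows))
    summary_rows <- data.frame(stage = character(0), table = character(0),
                               n_rows = integer(0))
  utils::write.csv(summary_rows,
                   file.path(config$out_dir, "report", "report_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(report_summary = summary_rows))
}
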