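# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Split the clonotype data.frame by annotation keys; empty group_by means a
# single group labelled "all". Returns a named list of row-index vectors with
# deterministic (first-appearance) group order.
.group_rows <- function(df, group_by) {
  if (length(group_by) == 0)
    return(list(all = seq_len(nrow(df))))
  miss <- setdiff(group_by, names(df))
  if (length(miss) > 0)
    stop("grouping column(s) absent: ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(df[group_by], sep = "/"))
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  idx
}

# Per-record weights under the given weighting mode.
.record_weights <- function(df, weighting = c("clonotype", "count")) {
  weighting <- match.arg(weighting)
  if (weighting == "clonotype") rep(1, nrow(df)) else as.numeric(df$count)
}

.junction_chars <- function(x) strsplit(x, "", fixed = TRUE)
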