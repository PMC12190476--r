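# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, recursion) so they cannot share a defect with
# the vectorised implementation paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_junction <- function(len) {
  paste0("C", paste(sample(AA, len - 2, replace = TRUE), collapse = ""), "F")
}

make_rep <- function(junctions, ...) {
  RepertoireTable(data.frame(junction_aa = junctions, ...,
                             stringsAsFactors = FALSE))
}

# position-by-position tally, one clone at a time
oracle_pfm <- function(junctions, weights = NULL) {
  keep <- !grepl("X", junctions, fixed = TRUE)
  junctions <- junctions[keep]
  if (is.null(weights)) weights <- rep(1, length(junctions)) else
    weights <- weights[keep]
  L <- nchar(junctions[1])
  f <- matrix(0, L, 20, dimnames = list(seq_len(L), AA))
  for (i in seq_along(junctions)) {
    for (p in seq_len(L)) {
      r <- substr(junctions[i], p, p)
      f[p, r] <- f[p, r] + weights[i]
    }
  }
  f / sum(weights)
}

# recursive motif matcher, independent of regex
oracle_motif_tokens <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  toks <- list(); i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1; d <- ""
      while (chars[j] != ")") { d <- paste0(d, chars[j]); j <- j + 1 }
      toks[[length(toks) + 1]] <- list(type = "n", n = as.integer(d))
      i <- j + 1
    } else if (ch %in% c("?", "X")) {
      toks[[length(toks) + 1]] <- list(type = "n", n = 1L); i <- i + 1
    } else if (ch == "*") {
      toks[[length(toks) + 1]] <- list(type = "star"); i <- i + 1
    } else {
      toks[[length(toks) + 1]] <- list(type = "lit", ch = ch); i <- i + 1
    }
  }
  toks
}

oracle_motif_match <- function(s, pattern) {
  toks <- oracle_motif_tokens(pattern)
  n <- nchar(s)
  rec <- function(ti, si) {
    if (ti > length(toks)) return(si == n + 1)
    t <- toks[[ti]]
    if (t$type == "lit")
      return(si <= n && substr(s, si, si) == t$ch && rec(ti + 1, si + 1))
    if (t$type == "n")
      return(si + t$n - 1 <= n && rec(ti + 1, si + t$n))
    for (k in si:(n + 1)) if (rec(ti + 1, k)) return(TRUE)
    FALSE
  }
  rec(1, 1)
}

oracle_clonality <- function(counts) {
  p <- counts / sum(counts)
  H <- 0
  for (pi in p) H <- H - pi * log(pi)
  R <- length(counts)
  if (R == 1) 1 else 1 - H / log(R)
}

# brute-force presence/absence partition over groups
oracle_partition <- function(keys, groups) {
  gl <- unique(groups)
  universe <- sort(unique(keys))
  mem <- sapply(gl, function(g) universe %in% keys[groups == g])
  if (is.null(dim(mem))) mem <- matrix(mem, nrow = length(universe))
  dimnames(mem) <- list(universe, gl)
  list(shared = universe[apply(mem, 1, all)],
       unique = lapply(stats::setNames(gl, gl), function(g)
         universe[mem[, g] & rowSums(mem) == 1]),
       membership = mem)
}

# per-spot weighted Pearson, plain loops
oracle_local_coincidence <- function(x, y, a, b, bandwidth, min_w) {
  n <- length(x)
  vals <- rep(NA_real_, n); valid <- logical(n)
  for (i in seq_len(n)) {
    sw <- swa <- swb <- swaa <- swbb <- swab <- 0
    for (j in seq_len(n)) {
      d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
      w <- exp(-d2 / (2 * bandwidth^2))
      sw <- sw + w
      swa <- swa + w * a[j]; swb <- swb + w * b[j]
      swaa <- swaa + w * a[j]^2; swbb <- swbb + w * b[j]^2
      swab <- swab + w * a[j] * b[j]
    }
    ma <- swa / sw; mb <- swb / sw
    va <- swaa / sw - ma^2; vb <- swbb / sw - mb^2
    cv <- swab / sw - ma * mb
    if (sw >= min_w && va > 1e-12 && vb > 1e-12) {
      valid[i] <- TRUE
      vals[i] <- max(-1, min(1, cv / sqrt(va * vb)))
    }
  }
  list(values = vals, valid = valid)
}

# a small lattice with explicit expression rows
make_lattice <- function(nrow_g, ncol_g, genes) {
  gx <- rep(seq_len(ncol_g), times = nrow_g)
  gy <- rep(seq_len(nrow_g), each = ncol_g)
  bc <- sprintf("s%03d", seq_along(gx))
  m <- do.call(rbind, genes)
  dimnames(m) <- list(names(genes), bc)
  SpotLattice(m, data.frame(barcode = bc, x = gx, y = gy, in_tissue = TRUE))
}

toy_sri <- function(threshold = 1.5) {
  SRIConfig(list(`6` = c(Y = 1), `7` = c(W = 1)), threshold = threshold)
}

sri_toy_path <- function() system.file("extdata", "sri_toy.tsv",
                                       package = "clonoSpat")
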