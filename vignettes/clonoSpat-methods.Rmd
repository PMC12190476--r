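---
title: "Methods: repertoire analytics and spatial coincidence in clonoSpat"
author: "clonoSpat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire analytics and spatial coincidence in clonoSpat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoSpat)
```

# Scope and data model

`clonoSpat` analyses two kinds of objects. A `RepertoireTable` holds one row
per receptor-chain clonotype record: the CDR3 junction amino-acid sequence
(1-based, both conserved anchors included, position 1 = the conserved
cysteine), V/J/C gene calls, a non-negative count (cells or duplicate
reads), and categorical annotations (cell cluster, treatment group, tissue).
A `SpotLattice` is a `SummarizedExperiment` of non-negative expression
values (genes × spots) whose `colData` carries spot coordinates in
spot-pitch units and an in-tissue mask, as produced by array-based spatial
transcriptomics.

The junction convention matters for everything downstream: with anchors
included, a 13-mer TCRβ CDR3 follows a C-A-(x₃…x₁₂)-F layout, positions
2, 3 and 13 are peripheral, and positions 6 and 7 are the central residues.
All positional analyses use this indexing.

# CDR3 composition analytics

Length distributions, V-segment usage and isotype usage are frequency
tables computed per group; each is simplex-valued (frequencies sum to 1
within each group). Two weighting modes exist everywhere: `clonotype`
(each distinct record counts once; the default, matching
repertoire-diversity convention) and `count` (records weighted by their
cell/read counts, for read-outs that report both proportions and absolute
counts). With all counts equal to 1 the two modes coincide, which the test
suite asserts as an invariant.

Position frequency matrices are computed over junctions of a single stated
length `L`: mixing lengths would smear positional signal, and
centre-alignment of unequal lengths would require a gap model we do not
want to invent. Clones containing the undetermined residue `X` are excluded
and counted, never imputed. Chemistry-class profiles aggregate a PFM
through a residue partition; the shipped default is hydrophobic
{A,V,L,I,M,F,W}, polar-uncharged {S,T,N,Q,Y}, positively charged {K,R,H},
negatively charged {D,E}, special {C,G,P}, with an aromatic overlay {F,W,Y}
kept separate because tyrosine is both aromatic and polar. The partition is
a standard one, and it is fully configurable because no single partition is
canonical.

The motif grammar (literals, `?` = one arbitrary residue, `(n)` = exactly
`n`, `*` = zero or more, `X` = any residue) mirrors the way shared- and
unique-clone patterns such as `CQQ(4)PXTF` or `CA(7)YW` are written in the
field. Patterns compile to anchored regular expressions; the test suite
checks the compiler against an independent recursive matcher on thousands
of random (sequence, pattern) pairs.

# Self-reactivity scoring at P6/P7

The self-reactivity index scores the two central residues of 13-mer CDR3β
junctions. Literature on thymic selection associates specific (notably
hydrophobic and aromatic) doublets at these positions with self-reactive T
cell fates; the index operationalises this as either

* `combine = "sum"`: `score = w6[aa6] + w7[aa7]`, self-reactive when
  `score ≥ threshold`, with the boundary inclusive (a tie must classify
  deterministically; we document and test the `≥` convention); or
* set-based modes: indicator that both (`both_promoting`) or at least one
  (`either_promoting`) of P6/P7 lies in a promoting residue set.

The two routes are mutually consistent: `both_promoting` equals the sum
mode with 0/1 weights on the promoting set and threshold 2 (asserted in the
tests). The numeric per-residue weights are deliberately *data*, not code:
the package ships a toy table for examples/tests and a blank template
(`inst/extdata/sri_template.tsv`) to be filled from the primary literature,
because no complete weight table is printed in the sources this package is
modelled on, and inventing one would masquerade as science.

Only 13-mers are scored by default (`requiredLength = 13`); other lengths
are "undefined", excluded from both numerator and denominator, and
book-kept so that `n_scored + n_excluded = group size` always holds. An
optional any-length mode (score absolute positions 6/7 of any junction of
length ≥ 7) can be configured via `requiredLength`, but is not the default
because the aromatic-P6/P7 analyses this supports are defined on 13-mers.

# Clonality and clone set algebra

Clone identity is `(chain, junction_aa)` by default, optionally including
the V call; matching on amino-acid sequence alone is the default because
cross-sample clone tracking in this setting is defined by CDR3 amino-acid
identity. The expansion profile bins aggregated clone counts into classes
{1, 2–3, 4–9, ≥10} (a fixed, configurable default; determinism requires
fixed bins) and reports a clonality index

`clonality = 1 − H / ln(R)`

with `H` the Shannon entropy (natural log) of clone frequencies and `R` the
number of distinct clonotypes — one minus Pielou evenness. It is 0 for an
all-singleton repertoire, 1 for a single clonotype (the `R = 1` case is
defined as 1 by convention), lies in [0, 1], and is invariant under uniform
count rescaling. "Not clonally expanded" has no universal metric; this
index is the package's explicit operationalisation.

Shared/unique partitions are plain set algebra on the presence/absence
lattice of clone keys over groups: fully-shared = present in all groups,
group-unique = present in exactly one, with pairwise intersections
available. "Unique and expanded" composes the partition with a count cutoff
(default ≥ 2 — the weakest sensible meaning of "expanded", configurable).
Cross-tissue tracking is the same partition keyed by tissue, with a
dual-tissue flag.

# Module scores with binned controls

The module score of a gene set re-implements the standard binned-control
algorithm: rank all genes by mean expression across observations, cut the
ranking into `n_bins = 24` equal-frequency bins, draw `n_ctrl = 100`
control genes per signature gene from the signature gene's bin (without
replacement; with replacement only when the bin is smaller than `n_ctrl`,
which is flagged), and score each observation as mean(signature) −
mean(pooled, deduplicated controls). The defaults are the conventional ones
for this algorithm. Inputs are assumed log-normalised. Two numerical
choices make the implementation deterministic and order-invariant: ranking
ties are broken by gene name, and the control draw iterates over the
signature genes in sorted order under a caller-supplied seed, so permuting
matrix rows cannot change the result.

Scores are shift-equivariant up to binning: adding a constant to every
gene's expression leaves ranks, bins and scores unchanged; unequal shifts
can move genes across bin boundaries and perturb the control pool, which is
inherent to the binning idea.

# Local spatial coincidence

For a gene pair (A, B) on a spot lattice, each in-tissue focal spot `i`
receives a kernel-weighted Pearson correlation computed over all in-tissue
spots `j` with Gaussian weights `w_j = exp(−d_ij² / (2b²))` (the focal spot
included with weight 1): weighted means, variances and covariance, then
`r_i = cov_w / sqrt(var_w(A) · var_w(B))`. A spot is *invalid* when its
effective neighbourhood weight `Σw` falls below
`min_effective_neighbors` (default 8) — e.g. isolated or edge spots — or
when either weighted variance is zero; invalid spots are excluded from all
summaries. The headline summary is the *coincidence area*: the fraction of
valid spots with `r` strictly above a threshold, 0.2 by default, chosen to
match the convention of reporting the "area of positive (> 0.2) correlated
gene coincidence". Strict inequality and the in-tissue restriction are
fixed conventions; the map is symmetric in gene order and values are
clipped to [−1, 1] against floating-point drift.

The default bandwidth is 2.0 spot-pitch units. Bandwidth controls a
bias–variance trade-off that can be reasoned about analytically: on a unit
lattice the effective degrees of freedom of the weighted correlation are
approximately `(Σw)²/Σw² ≈ 4πb²`, so the null standard deviation of `r`
under spatial independence is ≈ `1/sqrt(4πb²)` — about 0.14 at `b = 2` and
0.09 at `b = 3`. At threshold 0.2 this implies a null exceedance
(false-positive area) of roughly 8% at `b = 2` but only ~2% at `b = 3`. The
recovery studies in the acceptance suite therefore analyse the planted
co-expression disc at `b = 3`, trading a slightly wider boundary ring for a
much smaller background tail; the package default stays at 2.0, which
favours spatial resolution for hotspot mapping. Users quantifying areas on
their own data should pick the bandwidth with this trade-off in mind.

# Synthetic data: what is emulated, and what is not

`simulateRepertoire()` emulates the *structure* the analyses assume, not
receptor biology: junctions are a conserved C, i.i.d. interior residues and
an F/W terminal anchor; CDR3 lengths follow a stated distribution
(default mass on 12–15 with the mode at 13, TCRβ-like; BCR simulations use
an 11-mer mode); clone counts are singleton or discrete-power-law
(default exponent 2.5, the standard heavy-tail assumption for clone sizes);
each cluster has a V-segment profile with one globally dominant segment;
and the planted structure — self-reactive P6/P7 enrichment per cluster
(default 0.30 in the killer-Treg-like first cluster vs 0.10 elsewhere,
mirroring the reported contrast), fully-shared, treatment-unique and
cross-tissue clones, and motif-template clones — is recorded as exact
ground truth. Two generator choices make truth exact rather than
approximate: background junctions are rejection-sampled to be globally
unique (so planted sharing is the only sharing), and non-planted 13-mers
are rejection-sampled so P6 and P7 are never both in the promoting set (so
the planted label coincides exactly with the `both_promoting` classifier).
Real repertoires violate both (public clones arise by convergence;
self-reactivity is graded, not binary), so passing recovery tests
demonstrates estimator correctness, not biological realism.

`simulateSpatial()` plants a central disc covering a stated fraction
(default 0.20) of a 48×48 lattice. Inside the disc, each co-expressed pair
shares a latent spatial factor (strength 0.8 against unit independent
noise, giving an in-region pair correlation of 0.8²/(0.8²+1) ≈ 0.39 —
strong enough to exceed 0.2 reliably, weak enough that the ring of
kernel spill-over beyond the disc boundary stays narrow), and signature
genes gain `delta = 0.5`. All other genes are independent Gaussian noise
(sd 0.25) around uniform baselines in [1, 3]; values are floored at zero,
with baselines chosen so truncation is negligible. The generator does not
emulate count noise, spot deconvolution mixtures, tissue morphology or
spatially varying capture efficiency.

Problem sizes used by the validation studies (20 seeded replicates each:
two clusters of 400 scoreable 13-mers for self-reactive recovery, 1,000 for
the aromatic fraction, 48×48 lattices for area and module-score recovery)
were chosen so that binomial/Monte-Carlo error is well inside the stated
tolerances.

# Degenerate inputs and tie-breaks

Empty groups are omitted with a warning; groups with no scoreable clone
report an undefined (`NA`) fraction rather than 0. A PFM with no length-L
clones is returned with support 0 and flagged. Top-k rankings break ties by
(frequency descending, key/gene ascending). The coincidence area of a map
with no valid spots is `NA` with a warning. Readers treat `"None"`, `""`
and `NA` as missing CDR3 tokens (10x dialect), keep the highest-count
contig per (barcode, chain), and fall back from `umis` to `reads` with a
provenance note.

# Known limitations

* The SRI ships without real weight values; quantitative self-reactivity
  calls require the user to populate the template from primary sources.
* The coincidence estimator assumes an approximately stationary local
  relationship at the kernel scale; area estimates carry the
  boundary-ring and null-tail biases quantified above.
* Module scores inherit the binning artefacts of the control-gene
  algorithm they re-implement.
* The clonality index is one of many; comparisons across repertoires of
  very different richness `R` should be made with care.
* Statistical testing of group differences, lineage reconstruction, and
  upstream alignment/assembly are out of scope by design.
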