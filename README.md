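# clonoSpat

Immune-repertoire analytics and spatial gene-pair coincidence for injured
tissue.

After traumatic tissue injury, normally hidden self-antigens become exposed,
and the balance between regulatory and naïve lymphocytes decides whether the
outcome is regeneration or autoimmune-like pathology. Studies of volumetric
muscle loss treated with a pro-healing extracellular-matrix (ECM) implant or
a pro-inflammatory polyethylene (PE) particle implant read this balance out
in three data modalities: single-cell TCR/BCR repertoires from muscle and
the draining inguinal lymph node, cell×gene expression with cluster labels,
and Visium-style spatial transcriptomics of the injury site. `clonoSpat`
implements the analysis layer those read-outs need, as a Bioconductor-style
S4 package, and ships seeded synthetic-data generators with known ground
truth so every estimator can be validated end to end.

## What it computes

**CDR3 analytics** — junction length distributions, Vβ-segment usage with
tie-stable top-k, position frequency matrices of length-L junctions
(`PositionFrequencyMatrix`), chemistry-class profiles per position, and
motif conformity under a small pattern grammar (`CQQ(4)PXTF`, `CA*F`, ...).

**Self-reactivity scoring** — a per-clone self-reactivity index (SRI) over
junction positions 6 and 7 of 13-mer CDR3s (1-based, anchors included, so
P6/P7 are the central residues). Scores are either the sum of two
position-specific residue weights (`score = w6[aa6] + w7[aa7]`, classified
self-reactive when `score ≥ threshold`) or set-based indicators of a
promoting residue set; per-cluster self-reactive fractions and aromatic
P6/P7 proportions follow. Weight values are configuration data loaded from
TSV, not package constants.

**Clonality** — clone keys (chain + CDR3 amino acids, optionally + V gene),
expansion profiles with frequency classes {1, 2–3, 4–9, ≥10} and a
normalized-entropy clonality index `1 − H/ln(R)`, shared/unique clone
partitions across treatments, cross-tissue clone tracking, per-clone
abundance, top clones, and "unique and expanded" clone calls.

**Spatial scores** — gene-signature module scores with expression-binned
control genes (mean of signature genes minus mean of bin-matched controls),
and local gene-pair coincidence: a per-spot Gaussian-kernel-weighted Pearson
correlation `w_i = exp(−d_i²/(2b²))` with an effective-neighbourhood
validity cutoff, summarised as the fraction of valid spots with correlation
strictly above a threshold (0.2 by default).

**Synthetic data** — `simulateRepertoire()` and `simulateSpatial()` generate
AIRR-style repertoires (planted self-reactive enrichment, dominant V
segment, shared/unique/cross-tissue clones, motif templates, power-law
expansion) and spot lattices (planted injury disc with co-expressed gene
pairs and signature offsets), each returning exact ground truth.

## Worked example

```r
library(clonoSpat)

cdr3Length("CALWYSNHWVF")        # the top shared BCR clone is an 11-mer
#> [1] 11

sim <- simulateRepertoire(repertoireSimConfig(seed = 42))
sim$table
#> RepertoireTable with 1261 clonotype records
#>   clone key mode: cdr3_aa
#>   chains: TRB:1261
#>   cluster: cluster1, cluster2, cluster3, cluster4, cluster5, cluster6
#>   treatment: ECM, PE, control
#>   tissue: muscle, ILN

cfg <- SRIConfig(combine = "both_promoting", promotingSet = c("F", "W", "Y"))
clusterSelfReactivity(sim$table, cfg, "cluster")
#>      group n_scored n_self_reactive fraction
#> 1 cluster1       78              22   0.2821   <- planted 0.30
#> 2 cluster2       81              10   0.1235   <- planted 0.10
#> ...

expansionProfile(sim$table, "cluster")
#>      group   1 2-3 4-9 >=10 clonality_index
#> 1 cluster1 200   7   2    2           0.047   <- singleton cluster
#> 2 cluster2 147  42  12    6           0.088   <- power-law expanded
#> ...

sp  <- simulateSpatial(spatialSimConfig(seed = 42))
map <- localCoincidence(sp$lattice, "coexA1", "coexB1",
                        coincidenceParams(bandwidth = 3))
map
#> CoincidenceMap coexA1 ~ coexB1
#>    2304 valid / 2304 spots; area > 0.2 = 0.2396   <- planted disc = 0.20
```

The first cluster is generated killer-Treg-like: enriched for predicted
self-reactive clones (fraction ~0.3 of scoreable 13-mers, both P6 and P7 in
the promoting set) yet essentially unexpanded (clonality index near 0),
while the remaining clusters carry power-law clone sizes. The coincidence
area slightly exceeds the planted 0.20 disc because the kernel smooths over
the region boundary and the null distribution of the weighted correlation
has a small positive tail; the methods vignette quantifies both effects.

A file-based pipeline (`pipelineConfig()` + `runPipeline()`, stages
simulate / repertoire / sri / clonality / spatial / report, with a thin
Rscript wrapper at `inst/scripts/run_pipeline.R`) writes tidy CSVs plus a
JSON run manifest and is deterministic under a fixed seed.

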