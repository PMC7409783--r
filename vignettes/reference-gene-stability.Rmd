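---
title: "Choosing and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR divides a target gene's signal by that
of one or more reference genes. The division only removes technical
variation (RNA input, reverse-transcription yield, loading) if the
references are themselves unaffected by the experimental conditions. In
practice references are often inherited from earlier studies — other
tissues, other conditions, even other species — and a reference that
responds to the condition biases every downstream fold change. `refstab`
implements the three standard stability algorithms, a consensus ranking, a
rule for how many references to use, and the downstream ΔΔCq
quantification, so the whole selection-and-validation loop is reproducible
from a raw Cq table.

The motivating experimental design — which the synthetic generator
emulates and the bundled published tables reflect — is a panel of 8
candidate genes measured in 2 condition groups (isolated- vs
crowded-reared insects) × 5 biological replicates, in two tissues and
several closely related grasshopper species, with each reaction run in
duplicate or triplicate. Nothing in the data model hard-codes these
counts.

## Data model and conversions

A `cq_dataset` stores one row per well (sample, gene, technical replicate,
Cq, group). Cq values outside a plausibility window (default 5–40 cycles;
published panels span ~17.5–28.5) are rejected or flagged, never silently
used. Technical replicates collapse by arithmetic mean (the qbase+ and
BestKeeper convention; median available). Missing wells are data: any
statistic skips them and reports effective n; nothing is imputed.

Relative quantities anchor each gene at its minimum observed Cq:
`q = E^(Cq_min − Cq)`, with the amplification factor `E = 2` under the
100%-efficiency assumption used throughout stability analysis (measured
efficiencies can be supplied per gene). The anchor is arbitrary by
construction — every stability statistic below is invariant to per-gene
additive Cq shifts — and the package tests that property rather than
assuming it.

## The three algorithms

**geNorm.** `V_jk` is the sample standard deviation (n−1) across samples
of `log2(q_j/q_k)`; `M_j` is the mean of `V_jk` over all partners. Taking
ratios within a sample cancels loading exactly, which is also geNorm's
blind spot: a block of genes that respond to the condition *together* have
stable ratios and look good. Two ranking modes exist: the default ranks
the full-panel M in a single pass — on the published 8 panels the printed
M values are strictly monotone with the printed ranks, which identifies
the single-pass statistic — while classic stepwise exclusion (recompute
after dropping the worst gene; final two inseparable) is kept as a
secondary mode. The pairwise-variation series
`V_{n/n+1} = sd log2(NF_n/NF_{n+1})` compares normalization factors built
from the top n and n+1 genes; the smallest n with `V < 0.15` (threshold
configurable) is the recommended number of references, falling back to
all genes when nothing passes.

**NormFinder.** Per condition group, log2 expression is double-centered
(removing sample and gene effects); the residual variance yields a
moment-based intra-group variance estimate
`σ̂²_gj = max(0, k/(k−2)·(s_gj − s̄_g/(k−1)))` (k genes, truncated at 0 as
required at small n), and the group-mean deviations give the gene×group
bias `d_gj` (size-weighted across groups, summing to zero within each
group). The between-gene variance of those biases,
`γ̂² = max(0, Σd²/((G−1)(k−1)) − mean(σ̂²/n))`, shrinks each bias by
`γ̂²/(γ̂² + σ̂²/n)`, and the stability value averages
`|d̃| + sqrt(γ̂²·(σ̂²/n)/(γ̂² + σ̂²/n))` over groups. Log base 2 is used;
the base cancels in ranks but not values. With a single group the
inter-group terms vanish and the value degrades to the intra-group
standard error (reported with a warning). The implementation is verified
against an independently written step-by-step oracle to 1e−10 and by
parameter recovery on synthetic panels.

**BestKeeper.** Purely descriptive, computed on Cq (not quantities):
per-gene dispersion and Pearson correlation with the BestKeeper index,
the per-sample geometric mean Cq over all candidates. The default
dispersion is the mean absolute deviation from the arithmetic mean Cq
(the tool's documented "SD (± CP)"); the sample sd is an option. The
bundled published tables cannot arbitrate the variant (they ship only the
printed dispersions, not the raw Cq), so the tool's documented default is
kept. Ranking is by descending r — an ordering that exactly reproduces
the published BestKeeper ranks from the published r columns in all 8
panels, which is asserted as a test. Genes above 1 cycle of dispersion
are flagged inconsistent but kept; a constant gene has undefined r and
ranks last with a diagnostic, never a silent 0.

## Consensus and recommendation

The comprehensive rank is the geometric mean of the per-method *ranks*
(not values — the three value scales are incommensurable), re-ranked
ascending; ties break by arithmetic mean rank, then gene name, and are
reported. Aggregating the published per-method ranks reproduces the
published comprehensive ranks exactly for all 64 gene×panel entries
(an acceptance test).

`recommend_references()` fills the required number of genes (from the V
series) off the consensus in order. Two published recommendations are
*not* derivable from the consensus alone — in the swarming species most
candidates respond to rearing density, and the authors overrode the
ranking (most strikingly keeping a gene the algorithms ranked 8/8 because
its raw Cq showed no group difference). The package therefore treats
exclusions and forced inclusions as explicit, logged inputs with an
optional per-gene ΔCq/t-test diagnostic as evidence, rather than trying
to reverse-engineer a heuristic.

## Quantification

Primer efficiency is ordinary least squares of replicate-mean Cq on log10
relative template amount across a dilution series (≥3 levels; 2 levels
run as a flagged diagnostic); `E% = (10^(−1/slope) − 1)·100`, so slope
−3.32 is 100%. ΔΔCq quantification subtracts the arithmetic-mean Cq of
the references (= geometric mean of their quantities, the standard
multi-reference extension) from the target Cq, centers on the
control-group mean ΔCq, and exponentiates. The group fold change defaults
to the ratio of group means of the exponentialized per-sample values
(matching practice of plotting exponentialized values with SEM computed
on them); `2^(−mean ΔΔCq)` is available as a method option — the raw data
that could arbitrate the two against the published fold changes is not
available, so the exponentialized-mean reading of the published figure
legend is the default. The group test is a two-tailed t test on the
non-transformed ΔCq values, classic Student by default (the published
wording names a Student t test; R's Welch default is available via
`var_equal = FALSE` — the published p values cannot be re-derived without
the raw data, so the wording wins). No multiple-testing correction is
applied across targets, matching the validated design; apply one
externally if needed.

## The synthetic world

`simulate_cq()` draws
`Cq = baseline_j + δ_j·1[treated] + L_i + ε_ij + τ_ijr` with loading
`L ~ N(0, 0.5)`, per-gene biological noise `ε ~ N(0, 0.3)`, technical
noise `τ ~ N(0, 0.15)` over 2 technical replicates, 8 genes with
baselines spread over 17–29 cycles, and 2×5 samples — the defaults state
the emulated design and are not tuned to test outcomes. Noise is drawn as
standard normals and scaled, so two configs differing only in an sd share
draws at a fixed seed; this makes the loading-invariance property of
geNorm exact rather than Monte-Carlo. Presets: `ideal`, `one-bad-gene`
(δ = 1 cycle on one gene), `piceifrons-like` (a correlated block of seven
responsive genes, δ ≈ 0.8–1.2, around one stable gene — the regime where
correlation-based methods mis-rank the stable gene, reproduced as a
majority-of-seeds property), and `americana-like` (all stable, realistic
noise). Missingness is completely at random; aberrant-melt-curve removal
is not modeled mechanistically. What a green synthetic test establishes
is algorithmic correctness and qualitative behaviour under the stated
noise model — not agreement with any particular wet-lab dataset.

## Numerical choices and edge cases

* Standard deviations use n−1 throughout (geNorm convention).
* Variance estimates in NormFinder truncate at 0; 0/0 shrinkage is
  defined as 0.
* Rank ties break deterministically (input order for single methods;
  mean rank then name for the consensus) and are always flagged.
* Pairwise statistics drop missing samples pairwise; matrix-wide
  statistics (NormFinder, BestKeeper index, V series) drop them listwise
  with a warning/report, since they need complete rows.
* Efficiencies must lie in (1, 2.2]; dilution series with non-negative
  slope are rejected.

## Known limitations

* The published stability values themselves (M, NormFinder values,
  BestKeeper SD/r) are certified only against independent oracles and
  synthetic truth, not against the original raw Cq tables, which are not
  redistributable here; the corresponding acceptance tests are left
  failing by construction to keep that gap visible.
* No amplification-curve or melt-curve processing, no inter-plate
  calibration, no absolute quantification.
* NormFinder's "best pair of genes" combined output is not implemented.
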