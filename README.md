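# refstab — reference-gene stability analysis for RT-qPCR

RT-qPCR quantifies a target gene's expression *relative to* reference
("housekeeping") genes that are assumed stable across the experimental
conditions. When that assumption silently fails — common when the same
primers and references are reused across tissues, conditions or closely
related species — target-gene fold changes and p values can flip sign or
significance. `refstab` implements, in one tested package, the standard
workflow for choosing and validating reference genes from raw
quantification-cycle (Cq) tables:

* **geNorm** — gene *j*'s stability `M_j` is the mean over partners *k* of
  `V_jk = sd_i( log2 q_ij − log2 q_ik )` (sample sd, n−1), with relative
  quantities `q = E^(Cq_min − Cq)` (amplification factor `E = 2` at 100%
  efficiency). Lower M = more stable; M < 1.5 is the conventional "stable"
  flag. The pairwise-variation series `V_{n/n+1} = sd_i log2(NF_n/NF_{n+1})`
  between normalization factors (`NF_n` = geometric mean of the top-*n*
  genes' quantities) decides how many references to use: the smallest *n*
  with `V < 0.15`.
* **NormFinder** — a two-way model per condition group decomposes log2
  expression into sample and gene effects, a gene×group deviation `d_gj`
  and intra-group variance `σ²_gj`; the stability value averages
  `|d̃_gj| + sqrt(γ² σ²_gj/n_g / (γ² + σ²_gj/n_g))` over groups, where
  `d̃` is the deviation shrunk by `γ²/(γ² + σ²/n)` and `γ²` is the
  between-gene variance of the deviations. Unlike correlation-based
  methods it explicitly penalizes condition-responsive genes.
* **BestKeeper** — descriptive: per-gene Cq dispersion (mean absolute
  deviation by default, sample sd optional) and the Pearson correlation
  *r* of each gene's Cq with the BestKeeper index (per-sample geometric
  mean Cq of all candidates); rank 1 = highest *r*.
* **Consensus** — geometric mean of the three per-method ranks, re-ranked
  ascending, plus an audited recommendation step (exclusions and forced
  inclusions are explicit and logged, never heuristic).
* **Quantification** — primer efficiency from dilution series
  (`E% = (10^(−1/slope) − 1)·100`) and ΔΔCq relative quantification of
  target genes under configurable reference sets, with a two-tailed t test
  on the non-transformed ΔCq values.
* **Synthetic data** — a generator with known ground truth
  (`Cq = baseline + δ·1[treated] + loading + gene noise + technical noise`)
  so every stage is testable without external data, including the
  cautionary regime where a correlated block of condition-responsive genes
  fools correlation-based rankings.

## Worked example

A simulated panel in the hard regime — seven genes share a correlated
1-cycle condition response, only `G01` is truly stable:

```r
library(refstab)
synth <- simulate_cq(sim_preset("piceifrons-like", seed = 42))
ds <- collapse_replicates(synth$dataset)
qm <- to_quantities(ds)
gn <- genorm_m(qm)
cons <- comprehensive_rank(list(gn, normfinder_stability(ds),
                                bestkeeper_rank(bestkeeper_summary(ds))))
cons
#> <consensus_ranking> 8 genes, 3 methods
#>  gene genorm normfinder bestkeeper geo_mean_rank comprehensive_rank
#>   G08      2          4          1         2.000                  1
#>   G04      1          3          4         2.289                  2
#>   G03      3          2          5         3.107                  3
#>   G05      5          1          6         3.107                  4
#>   G06      4          6          2         3.634                  5
#>   G07      6          7          3         5.013                  6
#>   G02      7          5          7         6.257                  7
#>   G01      8          8          8         8.000                  8
```

The only gene with *no* planted condition effect (`G01`) is ranked *last*
by every method: the responsive majority agrees with itself, so
correlation-based stability mistakes agreement for stability. This is why
stability values must be read alongside the raw Cq — and why
`recommend_references()` supports evidence-backed exclusions:

```r
vs <- v_series(qm, gn)
vs$recommended_n            # 2 (all V_{n/n+1} < 0.15 here)
recommend_references(cons, vs)
#> <ref_gene_recommendation> n = 2: G08, G04
#>   include G08: consensus rank 1
#>   include G04: consensus rank 2
```

Primer efficiency and target-gene quantification:

```r
fit_efficiency(dilution_series(10^(0:4), c(19.9, 23.3, 26.6, 29.9, 33.2),
                               gene = "Act5C"))
#> <efficiency_result> Act5C: slope -3.3200, E = 100.08% (R2 = 1.0000, 5 levels)

# ds2: a collapsed cq_dataset holding the target "ast" plus the three
# references in 5 isolated- and 5 crowded-reared samples (see ?cq_dataset)
delta_delta_cq(ds2, "ast", c("RIBL5", "GAPDH", "Hsp70"), control_group = "isolated")
#> <expression_result> ast vs refs {RIBL5, GAPDH, Hsp70}: fold change 0.394 (crowded/isolated), p = 4.6e-06
```

A fold change of 0.394 means `ast` expression in crowded-reared animals is
~2.5× lower than in isolated-reared ones after normalization; the p value
comes from a two-tailed Student t test on the per-sample ΔCq.

Command-line use (the `inst/cli/refstab` wrapper, or `refstab_cli()`):

```sh
refstab simulate --preset one-bad-gene --seed 2 --out cq.csv
refstab stability --method genorm --input cq.csv --output genorm.tsv
refstab full-panel --input cq.csv --output report.tsv
```

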