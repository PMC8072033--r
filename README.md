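# DoseDHS

Early T cell development is confined to the thymus because it requires high
levels of Notch signaling. One proposed mechanism is chromatin-level: the
promoters of genes essential for T-lineage commitment (*Il2ra*, *Cd3ε*,
*Rag1*, ...) are DNA-inaccessible in hematopoietic stem/progenitor (LSK)
cells and have low CpG content, so they open and fire only under a high
Notch dose, while low-dose-responsive genes open already at the LSK→DN1
transition. `DoseDHS` implements the computational chain needed to test this
idea on stage-resolved DNase-seq and RNA-seq data:

1. **Spatial differential accessibility.** For each fixed 4-kb DHS window,
   binned cut-count profiles (20-bp bins, reads-per-million normalized) are
   compared between two stages with a nonparametric score
   — a Welch-standardized integrated squared difference of the per-bin
   condition means,

   `TS = (1/B) Σ_b ( ȳ_A(b) − ȳ_B(b) )² / ( s²_A(b)/n_A + s²_B(b)/n_B + ε )`,

   either unsmoothed (`tsDnun`, robust to heteroscedastic error variance)
   or with Nadaraya–Watson Gaussian kernel smoothing of the mean and
   variance curves (`tsKn`, bandwidth 150 bp). The score responds to
   peak/no-peak differences, peak-height changes and peak-position shifts.
   Null calibration is by replicate-label permutation with a
   moment-matched Gamma tail pooled across regions, followed by Bonferroni
   adjustment on the *effective* number of tests (overlapping windows are
   merged into clusters).
2. **Expression gates.** Genes are filtered at ≥1 CPM in ≥2 samples; the
   low-dose gate requires log2FC(DN1, ctrl) ≥ 2, the high-dose gate requires
   log2FC(DN2b, ctrl) ≥ 2 *and* log2FC(DN2b, DN1) ≥ 2 (mean CPM with a 0.5
   pseudocount).
3. **Dose-response classification.** DHS windows are assigned to promoters
   when their midpoint lies within ±1 kb of a TSS; each (region, gene) pair
   becomes **low_I** (opens de novo in DN1), **low_II** (open in LSK,
   significantly increased in DN1) or **high** (closed in LSK/DN1, opens in
   DN2b) when the accessibility flags, the adjusted p-value (< 0.05) and the
   expression gate all agree.
4. **Promoter CpG content.** Per 2-kb promoter, observed CpG = count of CG
   dinucleotides, expected CpG = n_C × n_G / length; the class groups are
   compared with a Mann–Whitney test (exact for small tie-free groups).

A synthetic-data generator (`simConfig`, `plantedTruth`,
`simulateDataset`) produces Poisson cut-count profiles, negative-binomial
expression and Markov-chain promoter sequences with known ground truth, so
the whole pipeline is testable end to end without external data. It is aimed
at computational biologists who want a tested, reusable reference
implementation of this analysis style rather than a genome-scale production
peak caller.

## Worked example

```r
library(DoseDHS)

cfg <- simConfig(seed = 42)                       # study-condition defaults
ds  <- simulateDataset(cfg, c(low_I = 3, high = 3, null = 4))
x   <- normalizeRPM(ds$profiles)
x
#> DHSProfileSet with 10 regions, 15 samples, 200 bins of 20 bp
#> stages: ctrl(3), DN1(3), DN2a(3), DN2b(3), LSK(3)
#> assays: counts, rpm

res <- diffAccessTest(x, "LSK", "DN1")            # spatial test, 3v3
res <- adjustEffectiveBonferroni(res, rowRanges(x))
head(as.data.frame(res)[, c("region_id", "ts_dnun", "p_value", "p_adjusted",
                            "delta_mean_rpm")], 4)
#>    region_id  ts_dnun      p_value   p_adjusted delta_mean_rpm
#> 1 region0001 4.099911 6.036029e-46 6.036029e-45     -0.5783333
#> 2 region0002 3.350333 1.622946e-32 1.622946e-31     -0.6766667
#> 3 region0003 5.900207 1.338765e-80 1.338765e-79     -0.6550000
#> 4 region0004 1.014847 1.486765e-01 1.000000e+00      0.0200000
```

The first three regions carry planted low-dose peaks that appear in DN1
(negative LSK − DN1 effect, vanishing adjusted p); region 4 is a null.
Promoter CpG ratios come straight off the simulated 2-kb sequences:

```r
head(as.data.frame(oeCpG(ds$promoters$sequences)), 3)
#>    gene_id observed_cpg n_c n_g length expected_cpg  oe_ratio
#> 1 gene0001           74 521 465   2000     121.1325 0.6109013
#> 2 gene0002           76 493 512   2000     126.2080 0.6021805
#> 3 gene0003           76 486 495   2000     120.2850 0.6318327

mannWhitneyCpG(c(1, 2, 3), c(4, 5, 6))[c("U", "p", "exact")]
#> $U      [1] 0
#> $p      [1] 0.1
#> $exact  [1] TRUE
```

`runPipeline(pipelineConfig(...))` chains all stages (simulation,
accessibility calls, both stage-pair tests, gates, classification, CpG
comparison) and, given `out_dir`, writes every intermediate as TSV plus a
JSON report and manifest; `makeReport()` summarizes class sizes and the
high- versus low-dose CpG contrast.

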