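# stressgwas

Linking stress-resistance phenotypes of *Saccharomyces cerevisiae* strain
collections to their genetic variants.

Industrial strain selection needs to know not only *how well* a strain grows
under a stress (performance) but *how well it holds up* as the stress
intensifies (robustness). This package implements the full analysis chain
for a strain-collection screen of that design — dozens of strains grown
under many stress conditions at 4–7 increasing inhibitory levels — and its
downstream genetics:

* **Growth phenomics** — five parameters per growth curve: lag time
  λ (Zwietering tangent construction), maximum specific growth rate μmax
  (sliding-window log-linear regression), amplitude A, half-maximum time
  t½, and area under the curve.
* **Resistance scoring** — per level, parameters are oriented (time-like
  ones inverted) and min–max normalized across strains; *performance* is
  the weighted cross-sectional score, integrated over levels; *robustness*
  is the weighted mean retention of a strain's own parameters relative to
  the least inhibitory level, clamped to [0, 1]. Strains are ranked per
  condition (average-rank ties, decile "ranking values" 1–10), with rank
  variability analysis (Dirichlet-sampled weights) and parameter-influence
  (PI) scores normalized to [−1, 1].
* **Mixed-model GWAS** — strain rankings as phenotypes (rank-based
  inverse-normal transform by default), an EMMA-style spectral REML fit of
  `y = Xb + g + e`, `g ~ N(0, σg²K)` with a VanRaden kinship, and a
  P3D/EMMAX-style generalized-least-squares scan. Two marker branches:
  core-genome SNPs/indels (MAF > 5%) chained into LD blocks tested via
  representatives, and CNV gain/loss interval markers built from the
  overlap relationships of per-strain copy-number segments. Significance
  cutoffs come from the departure of observed from expected P-value
  quantiles on the −log10 scale; gene-level P values take the minimum over
  units overlapping the gene span plus an 800 bp strand-aware upstream
  window.
* **Variant-source contributions** — per gene category, the 75% quantile of
  each source's −log10 P (SNP / gain / loss) normalized to barycentric
  coordinates.
* **Network modules** — maximal-clique enumeration on a STRING-style
  interaction network, hypergeometric foreground enrichment with BH
  correction, union of significant cliques into connected modules,
  modularity statistics, and a random-gene-list null compared by paired
  Wilcoxon signed-rank tests.
* **Cohort statistics** — Wilcoxon rank-sum and Kruskal–Wallis group
  comparisons with related-strain binning (e.g. Brazilian bioethanol
  strains as one pseudo-observation), BH FDR, Bonferroni-adjusted Spearman
  matrices, and metabolome pathway/class group scores and rankings.
* **Synthetic data** — seeded generators for every input (dose-response
  growth curves, Balding–Nichols structured genotypes with planted causal
  markers, subtelomere-biased CNV segments, planted network cliques,
  coupled two-compartment metabolomes) returning the ground truth they
  used, so the whole pipeline runs and is tested offline.

## Worked example

Score and rank a small synthetic collection:

```r
library(stressgwas)

strains  <- gen_strains(12, seed = 1)
gc       <- gen_growth_curves(strains, n_conditions = 3,
                              levels_per_condition = 5, n_replicates = 3,
                              noise_sd = 0.01, seed = 2, dt = 0.5)
params   <- extract_params_table(gc$curves, blank = gc$truth$blank,
                                 smooth_window = 3)
rankings <- rank_all(params)
head(subset(rankings, condition == "C01" & score_type == "performance"), 5)
#>    condition  score_type strain     score rank ranking_value
#> 5        C01 performance   S005 0.8028786    1             1
#> 10       C01 performance   S010 0.7840461    2             2
#> 9        C01 performance   S009 0.7122849    3             3
#> 11       C01 performance   S011 0.5830313    4             4
#> 3        C01 performance   S003 0.5348458    5             5
```

Each row is one strain in one per-condition ranking: `score` is the
integrated performance in [0, 1], `rank` 1 is the best strain, and
`ranking_value` is the decile (values > 6 flag poorly resistant strains).

Run a mixed-model scan against structured genotypes with one planted
causal marker:

```r
gt   <- gen_genotypes(strains36 <- gen_strains(36, seed = 1),
                      n_markers = 800,
                      causal = data.frame(marker = 400, effect = 2),
                      seed = 3)
fit  <- reml_null(gt$phenotype, gt$kinship)
fit
#> reml_fit: delta = 1e+05 (sigma_g2 = 4.379e-05, sigma_e2 = 4.379),
#>           REML logLik = -75.5092
scan <- assoc_scan(gt$phenotype, gt$genotypes$G, fit, source = "snp")
qq_cutoff(scan$p, "snp")
#> threshold 6.47e-12; 1 significant of 763 markers
scan$unit[which.min(scan$p)]   # the planted marker, m00166
```

`run_all(default_config(seed = 1), outdir)` executes every stage end to end
(curves → parameters → rankings → both GWAS branches → cutoffs → gene P →
contributions → modules → cohort tests) and writes plain-text TSV/JSON
artifacts plus a run log with the config hash. A thin CLI wrapper lives at
`inst/cli/stressgwas.R`.

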