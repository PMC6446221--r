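---
title: "Methods: from growth curves to genotype associations"
author: "stressgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from growth curves to genotype associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, their assumptions, the tunable parameters and their defaults,
and the design decisions taken where several constructions were defensible.

## 1. The screening design

The analysis targets a strain-collection screen: a few dozen yeast strains
grown under many stress conditions, each condition applied at 4–7
increasing inhibitory levels (compound concentration, pH, temperature),
with replicate growth curves monitored for about 66 hours. Two scores
summarize resistance: *performance* compares a strain against the other
strains at a condition (cross-sectional), *robustness* measures how well a
strain maintains its own growth parameters as the level increases
(longitudinal retention). Rankings derived from these scores become the
phenotypes of two GWAS branches (SNP/indel and CNV markers), whose
gene-level results feed a variant-source decomposition and
protein-interaction module discovery.

## 2. Growth-parameter extraction

Five parameters are extracted per curve (`extract_params()`): lag λ, maximum
specific growth rate μmax, amplitude A, half-maximum time t½, and the area
under the curve. The scoring layer is parameter-agnostic — it operates on
any five-vector — so substituting a different parameter set is a
configuration change, not a code change.

* μmax is the maximum slope of `log(signal − blank)` over a sliding
  regression window (default `reg_window = 5` points; robust on a
  15–30-minute sampling grid). Windows containing non-positive
  blank-subtracted values are skipped.
* A is the maximum smoothed blank-subtracted signal; t½ the first
  linearly-interpolated crossing of A/2.
* λ uses the Zwietering tangent construction: the tangent through the
  half-amplitude point with the logistic inflection slope `μmax·A/4`
  intersects the baseline at `t½ − 2/μmax` (clamped at 0). For an exact
  logistic trajectory this recovers the generative lag exactly.
* Curves whose amplitude stays below `min_amplitude` (default 0.05 signal
  units) are scored "no growth" and receive defined worst-case sentinels
  (λ = t½ = end of observation, μmax = A = AUC = 0) so that every
  downstream ranking is total, rather than propagating missing values.

**Validity regime.** The log-slope of a logistic saturates to μ only while
the population is far below capacity: the initial signal fraction is
`1/(1 + exp(μλ + 2))`, so recovery to within 2% requires roughly
`μλ ≥ 2.5`. The recovery checks therefore use lag values in that regime
(λ = 12 h on the test grid); for curves started close to capacity the
extracted μmax is a downward-biased but monotone summary, which ranking
preserves. Replicates are aggregated by per-field medians, majority-vote
`grew` (ties count as growth), and MAD dispersions.

Smoothing is a centered moving median (`smooth_signal()`), which removes
single-point spikes without displacing monotone stretches; window 1 (the
default in `extract_params_table()`) disables it, and noisy data benefit
from window 3–5.

## 3. Scoring, ranking, and sensitivity

Per condition and level, parameters are *oriented* (λ and t½ negated so
larger is always better) and min–max scaled across the growing strains
(`orient_and_normalize()`). Min–max rather than z-scoring keeps scores in
[0, 1] and is robust at the small per-level n; a degenerate range maps to
0.5 (the parameter carries no information at that level), a single grower
maps to 1, and non-growers are pinned to 0.

*Performance* at a level is the weighted sum of oriented parameters
(weights normalized to the 4-simplex; equal weights by default), and levels
are integrated by an unweighted mean over usable levels (configurable
weights are provided because alternative integration rules — worst-case,
dose-area — are equally defensible). *Robustness* is computed against the
least inhibitory level as reference: per parameter, the retention ratio
(inverted for time-like parameters) clamped to [0, 1], averaged over
higher levels with non-growing levels contributing 0, then weighted across
parameters. This directly operationalizes "maintains its growth parameters
as levels increase": a level-invariant strain scores exactly 1 and a
reference-only grower exactly 0. Strains absent or non-growing at the
reference level have undefined robustness and are ranked last.

Rankings use descending scores with average-rank ties and NA-last; the
decile `ranking_value = ceiling(10·rank/n)` reproduces the ">6 = poorly
resistant" and "top 10" reading at a 36-strain scale while raw ranks are
always reported alongside.

*Rank variability analysis* re-scores under weights drawn uniformly from
the simplex (Dirichlet(1,…,1)) and reports rank quantiles and decile-bin
probabilities. *Parameter influence* compares the equal-weight baseline
ranking with the ranking after adding `bump` (default 0.2) to one weight
and renormalizing; raw PI = baseline rank − bumped rank (positive = the
strain moves up), normalized by the global maximum absolute raw PI over all
parameters and conditions so the matrix lies in [−1, 1] with at least one
entry at ±1. PI profiles of two strains are compared by Spearman
correlation over the flattened parameter × condition vector.

## 4. Genotypes, LD blocks, kinship, CNV markers

Coordinates are 0-based half-open internally; VCF positions are converted
on read (`read_vcf()`, via vcfR; biallelic records only, multiallelics
skipped with a warning). Indels are genotyped exactly like SNPs. The
SNP-branch filter keeps markers inside the core-genome mask with MAF
strictly above 5% (`filter_core_maf()`).

**LD blocks** (`ld_blocks()`) use greedy left-to-right chaining: a block
extends while the next marker is within `max_gap_bp` (default 20 kb) of
the last member and has r² ≥ `r2_min` (default 0.8) with the block's
current representative, the highest-MAF member so far (ties leftmost).
This exact rule is the package's own choice among the many published
blocking heuristics; both thresholds are exposed. Scans test only the
representatives and assign the block P to all members.

**Kinship** (`kinship()`) is the VanRaden genomic relationship matrix —
centered, frequency-scaled cross-product over polymorphic markers —
normalized to unit *mean* diagonal and made PSD by clipping tiny negative
eigenvalues; an IBS allele-sharing variant is available. Note that sample
centering biases off-diagonals by about −1/(n−1), visible at small n.

**CNV markers** (`cnv_markers()`) implement the overlap-relationship
construction: pool all strains' intervals of one event type (gain, or
loss + deletion), cut at the union of breakpoints, attach to each atomic
segment the presence vector of covering strains (any overlap of an atomic
segment is full cover by construction), merge adjacent atomic segments
with identical presence, and drop constant markers and markers whose minor
presence class is rarer than `min_class_frac` (default 5%). Marker
genotypes are binary presence indicators, not copy numbers, because gain
and loss are tested separately. A per-base brute-force oracle verifies the
construction in the tests.

**Gene-event assignment** (`gene_cnv_events()`): full coverage by a gain
region labels the gene `gain`; partial gain overlap assigns nothing (the
extra copy is incomplete); loss and deletion label on any overlap (at
least one copy is truncated); deletion (copy 0) takes precedence over
loss, which takes precedence over gain.

## 5. The mixed model

Rankings are used as phenotypes. Because rank numbers violate LMM
normality, the default applies a rank-based inverse-normal transform
(`transform_phenotype()`, quantiles `(r − ½)/n`); raw-rank mode is retained
for fidelity to designs that regress ranks directly.

`reml_null()` fits `y = X0 b + g + e`, `g ~ N(0, σg²K)`,
`e ~ N(0, σe²I)` by the spectral REML reduction: one eigendecomposition of
the projected kinship turns the restricted likelihood into a 1-D function
of `δ = σe²/σg²`, maximized over a 100-point grid on `log10 δ ∈ [−5, 5]`
with local refinement. A grid-boundary maximum (e.g. `K = I`, where only
`σg² + σe²` is identifiable) triggers a warning and returns the boundary
estimate. The tests verify the spectral objective against explicit-inverse
linear algebra to 1e−6.

`assoc_scan()` tests each marker by GLS of the whitened phenotype on
`[X0, x]` with a Wald t-test. The default reuses the null variance
components for every marker (P3D/EMMAX); `mode = "exact"` re-estimates δ
per marker, which is affordable at strain-collection scale and agrees
closely with P3D in practice. Constant markers are skipped and counted.
When `K = I` the scan reduces exactly to OLS.

**Significance cutoffs** (`qq_cutoff()`) walk from the most significant
P value and accept points while the observed −log10 P exceeds the expected
uniform quantile by at least `eps_log10` (default 0.5). The expected value
at each step is the rank-1 quantile of the *remaining* points,
`1/(m − j + 1)`: once a point is accepted it no longer counts toward the
null distribution the rest are compared with. This peeling makes the rule
self-consistent — with a fixed expected sequence `i/(m+1)`, any block of s
accepted points forces a structural departure of `log10(s+1)` on the next
null point, so a spike set would always drag trailing null points past any
reasonable band. The threshold is the largest accepted P; an empty prefix
yields the 0 sentinel (no significant calls). Separate cutoffs are
computed per source (SNP, gain, loss).

**Gene-level P** (`gene_pvalues()`) is the minimum over units overlapping
the gene span plus a strand-aware 800 bp upstream window, per source and
ranking, without multiplicity correction — contiguous genes in a
significant block deliberately share P values ("passengers"), and module
discovery is the designated de-noiser. `genomic_windows()` counts
significant units in non-overlapping 50 kb windows for hot-spot tables.

## 6. Variant-source contributions

For a gene category and ranking, `category_contribution()` takes the
q-quantile (default 0.75) of each source's −log10 P over the category's
genes and normalizes the three quantiles to sum to one. The
quantile-then-normalize construction is this package's definition of the
contribution coordinates; it is permutation-equivariant in the sources,
invariant to rescaling all evidence, and monotone in each source.
Normalization happens after category selection; `q` is exposed.

## 7. Network modules

`find_modules()` enumerates maximal cliques of at least `clique_min_size`
(default 3) exactly via igraph — exhaustive enumeration is feasible at
interaction-network scale on a desktop, and is declared the reference
behaviour rather than randomized clique sampling. Each clique is tested
for foreground enrichment with a hypergeometric test whose background is
**all network nodes after score filtering** (not the genome — this choice
changes the P values and is therefore stated explicitly), BH-adjusted
across cliques; the union of significant cliques decomposes into connected
components, the modules.

`null_comparison()` contrasts the modularity statistics (nodes in modules,
nodes in cliques, internal edges, foreground proportion, edges to
reference nodes, overlap rates) against random node lists. The default
pairing draws, per replicate, a random 90% subsample of the foreground and
an independent random list of the same length and compares the paired runs
with one-sided Wilcoxon signed-rank tests. Under a random foreground the
two lists are exchangeable, so the reported P values are calibrated
(conservatively so when sparse graphs yield zero-module runs, whose zero
differences are dropped or collapse to P = 1); under a planted foreground
all differences are positive and P ≈ 2^−n_random. The alternative
`"vs_real"` pairing (full real list vs each null) is available but its P
values are descriptive only, because all pairs share the single real
value. `shared_modules()` reports cross-phenotype module overlap by
Jaccard similarity of node sets (threshold 0.5 by default).

## 8. Cohort statistics

Group tests are rank-based throughout: Wilcoxon rank-sum for two groups
(exact null for small untied samples), Kruskal–Wallis for several, both
invariant to monotone transforms. Related strains sharing a `bin_group`
are collapsed to one pseudo-observation (median by default, mean as
option) before testing, to avoid pseudo-replication. BH FDR is used for
test families; correlation matrices use Spearman with Bonferroni
adjustment over the tested pairs — the stricter of the two conventions for
correlation screens, with both raw and adjusted values retained in the
outputs. Metabolome group scores center and scale each metabolite's log
abundance across strains and average z-scores within pathway/compound
groups; a sign option lets extracellular groups rank production above
consumption.

## 9. The synthetic-data generators

The generators emulate the statistical *structure* of the study inputs, at
the stated study conditions, with fixed seeds:

* **Strains**: four categories in 17/13/4/2-of-36 proportions with
  consistent subcategories, ploidies 1–4, and a binned group of related
  bioethanol strains (≥ 2 members once n ≥ 10).
* **Curves**: logistic trajectories (Gompertz as option)
  `blank + A/(1 + exp(−μ(t − t_mid)))`, `t_mid = λ + 2/μ`, on a ~66 h
  grid; per strain and condition a Hill dose-response with strain-specific
  IC50 scales μ and A down and λ up with the level index; dosed amplitudes
  below `blank_threshold` give flat no-growth curves, reproducing the
  varying number of growing strains per setting. The Hill construction is
  test scaffolding: the extraction module makes no use of it, and the
  extraction layer never assumes the generator's curve family.
* **Genotypes**: Balding–Nichols population frequencies
  (`Beta(p(1−F)/F, (1−p)(1−F)/F)`) and binomial dosages give a real
  kinship; phenotypes add planted standardized marker effects, a polygenic
  term drawn with covariance proportional to the realized kinship, and
  noise; the true kinship and allele frequencies are returned.
* **CNV segments**: subtelomere-biased placement (U-shaped Beta positions),
  copy numbers drawn relative to ploidy, and shared events across strain
  subsets to create marker overlap structure.
* **Network**: Erdős–Rényi background plus fully connected planted cliques
  with a controllable foreground fraction; **metabolome**: log-normal
  abundances with a configurable intra/extra coupling and group shifts for
  chosen subcategories.

What passing tests on these inputs show — and what they do not: parameter
recovery, ranking correctness against planted orderings, GWAS calibration
and power, and module recovery are demonstrated under clean logistic
kinetics, ideal Balding–Nichols structure, and planted cliques. Real
screens add plate effects, calibration nonlinearity between optical signal
and biomass, diauxic shifts, LD decay profiles and CNV breakpoints far
messier than these generators produce; results on synthetic data bound
correctness of the *computations*, not the biology.

## 10. Problem sizes and numerical choices

The default pipeline configuration (12 strains × 3 conditions × 4 levels ×
2 replicates, 300 markers, 60-node network) exercises every stage in a few
seconds and is the size used in the end-to-end tests; the acceptance
script scales the statistical checks up to 100 strains × ~5,000 marker
tests for the null-calibration estimate and 100 simulation seeds for the
power estimate, sizes chosen to give stable Monte-Carlo estimates on a
single CPU. Tolerances: REML spectral-vs-direct agreement 1e−6; recovery
bands 2% (μmax, A) and 5% (λ, t½) on the noise-free grid; type-I error in
[0.03, 0.07] at nominal 0.05. Ties are handled by average ranks
everywhere; degenerate min–max ranges map to 0.5; grid-boundary REML
maxima warn rather than fail; P = 0 inputs to the contribution layer are
capped at the smallest representable double with a warning.

## 11. Known limitations

* The five-parameter identities and the level-integration rule follow the
  standard growth-phenomics set; designs that integrate levels by
  worst-case or dose-area should switch the exposed configuration.
* The LD-block chaining rule and the QQ-departure band are this package's
  constructions; both are parameterized and should be recalibrated against
  a reference implementation when one is available.
* Gene-level P values are deliberately uncorrected minima; interpret gene
  lists through the module layer.
* The signed-rank module comparison is conservative on sparse networks
  where random lists rarely form modules.
* `exact` scan mode re-estimates δ per marker but still uses a t reference
  distribution; at very small n permutation P values would be preferable.
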