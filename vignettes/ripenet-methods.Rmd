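---
title: "ripenet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ripenet: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripenet)
```

# Scope

`ripenet` integrates replicate-level metabolite and transcript abundance
tables from a panel of metabolic-pathway mutants sampled at several
developmental stages. Its four analysis products are wild-type-normalized
differential tables, stage-specific hierarchical clustering of genotypes,
stage-specific Pearson correlation matrices over the joint feature space,
and hub-centered thresholded correlation networks around each mutated gene.
A synthetic-data generator reproduces the statistical structure the analysis
assumes, so every stage is testable offline.

The pipeline starts from quantified abundance tables. It does not parse raw
LC-MS, qRT-PCR or microarray files, does not render graphics, and performs
no network inference beyond marginal Pearson correlation (no partial
correlations, no Gaussian graphical models, no community detection).

# Data model

The single input currency is the `abundance_table`: a features × samples
matrix of nonnegative abundances with a parallel logical `detected` mask.
**Not-detected (ND) is a first-class flag, not a zero and not a plain
missing value**: a measured zero is a detected value of 0, while an ND cell
is a censored observation below the limit of detection (LOD). ND survives
I/O (sentinel token `"ND"` in the TSV dialect), is excluded from every group
mean and every correlation pair, and renders as an explicit status in the
differential export. Feature and sample metadata live in sidecar TSVs so the
matrix file stays a plain table; tables are features-in-rows,
samples-in-columns, and the reader rejects (never guesses) the transpose.

The genotype and stage vocabularies are open. The defaults ship the
motivating panel: mutants *at*, *r*, *t*, *B* normalized against AC and
*Del* against M82, stages MG < Br < FR, at least three biological
replicates per genotype × stage. Technical-replicate averaging, if any, is
the caller's responsibility upstream.

# Differential statistics

For mutant *m*, matched wild type *w*, stage *s*, feature *f*:

* `log2fc = log2(mean(detected mutant reps)) − log2(mean(detected WT reps))`.
  The difference-of-logs form (rather than `log2` of the ratio) makes
  antisymmetry under group swap exact in floating point.
* Replicate means are arithmetic on the raw scale; the *t*-test runs on
  log2-transformed values by default because the noise model is
  multiplicative (a raw-scale option exists since either convention is
  defensible).
* The test is the classical pooled-variance two-tailed Student's *t*
  (a Welch option sits behind `var_equal = FALSE`). Stars are a pure
  function of p with inclusive boundaries: `***` p ≤ 0.001, `**` p ≤ 0.01,
  `*` p ≤ 0.05.
* No multiple-testing correction drives the stars (matching the per-feature
  star convention of the source analyses); users who need FDR control can
  apply it to the exported p-values.
* ND rules: a group with zero detected replicates makes the cell ND with
  status `nd_both` / `nd_mutant_only` / `nd_wildtype_only`. One detected
  replicate is `insufficient_replicates` (no fold change or p is reported —
  a deliberate, conservative contract: a 1-replicate "mean" invites
  overinterpretation). One-sided detection with a zero wild-type mean is
  reported as a `±Inf` sentinel with `status = ok`, flagged in the export as
  the strings `+Inf`/`-Inf` — appearing/disappearing compounds are real
  biology and must not be silently imputed.
* One-way ANOVA + Tukey HSD across genotypes is provided alongside
  (classical sum-of-squares decomposition; Tukey adjusted p from the
  studentized range distribution). Both test families coexist because panel
  studies commonly star metabolite maps by mutant-vs-WT *t*-tests while
  comparing expression across all genotypes by ANOVA/Tukey; in `ripenet`
  the *t*-test drives the heatmap stars. Degenerate inputs are guarded:
  all-identical observations give status `no_variance`; zero within-group
  variance with distinct means gives F = ∞, p = 0.

# Hierarchical clustering of genotypes

Profiles are built per stage either as log2fc vectors (one per mutant;
masked where ND or one-sided) or z-scored abundance means (one per genotype
including wild types). Whether the original analyses clustered mutants only
or mutants + wild types, and on which transformation, is not stated in the
sources this design follows; both modes are exposed, `log2fc` is the
default, and the choice is recorded in output provenance rather than
asserted as canonical.

Distances are 1 − Pearson on mutually unmasked entries (Euclidean as an
option); pairs sharing fewer than 3 entries are an error, not a guess.
The default distance/linkage pair (correlation distance, average linkage)
was chosen because the rest of the analysis is correlation-centric.
The agglomerator is the textbook O(n³) Lance–Williams loop — n is the
number of genotypes, so efficiency is irrelevant — with a deterministic
tie-break: leaves are pre-sorted lexicographically and the first minimal
pair in scan order wins, so the tree is reproducible and independent of
input order. Heights are non-decreasing for the supported linkages
(average, complete, ward.D2). `cut_clusters(k)` removes the k − 1 last
merges. Dendrograms export as Newick (via an `hclust` bridge and ape) plus
a raw merge table.

# Correlation matrices and hub networks

Pearson r is computed per stage over replicate-level samples by default:
that maximizes n, and the original sample unit is ambiguous in the sources —
a `genotype_mean` mode is provided. Pairs are **pairwise-complete**: each
r(i, j) uses only samples where both features are detected (and positive,
on the default log2 scale). A cell is undefined (`NA`, with the per-pair n
recorded) when fewer than `min_pairs = 4` samples remain or a variable is
constant on the shared samples — below 4 points a Pearson r is noise, and
reporting a number there would be worse than reporting nothing.
Implementation note: the matrix is computed from masked moment sums after
per-feature centering, which keeps it within 1e-12 of a per-pair two-pass
computation while staying vectorized.

Hub networks are **star graphs by default**: edges are exactly the hub row
of the matrix filtered at |r| ≥ τ (τ = 0.88, the threshold of the
motivating study). Partner–partner edges at the same threshold are opt-in
(`include_neighbor_edges = TRUE`), never silently added. Node strength is
the weighted degree, ns(v) = Σ|r| over incident retained edges — the
sources name "node strength" without a formula, so the standard definition
is adopted and documented. Edges are thresholded on |r| only; a correlation
p-value column can be derived downstream but never filters edges. ρ and r
refer to the same Pearson coefficient; the code uses `r`.

Trajectory labels across stages (expanding / contracting / stable /
rewired) are descriptive delta-sign rules, not inference.

# The synthetic generator: what it emulates

The generator's stated world mirrors the motivating panel: 7 genotypes ×
3 stages × 3 replicates, a carotenoid pathway DAG of 15 core metabolites
plus 29 satellite isomers/derivatives (44 carotenoids total), ABA/CHL/TOC/
QUI metabolite panels, 22 carotenoid transcripts plus accessory transcript
panels, and mutant presets *at*/*r*/*t* = loss-of-function on
IDI1/PSY1/CrtISO1 (λ = 0, 0, 0.05) and *B*/*Del* = gain-of-function on
CYC-b/LCY-e (g = 5). No quantitative allele strengths exist for these
mutants; the preset values are illustrative defaults chosen to reproduce
the qualitative signatures (downstream depletion for full blocks, substrate
backlog with partial leak-through for *t*, branch redirection for the
cyclase gains) and are documented as such.

**Flux model.** Steady-state multiplicative propagation on the DAG — not
ODE kinetics. The analysis only needs realistic cross-feature covariance
and mutant contrasts; a steady-state model is the simplest thing that
produces them. Entry nodes receive `base_input × stage_activity[stage]`
(defaults 100 × {MG 1, Br 2.5, FR 4}: abundances in arbitrary LC-MS-like
units rising through ripening). Loss-of-function transmission λ ∈ [0, 1],
backlog factor 1 + (1 − λ)κ on the immediate substrate (κ = 1 by default;
the backlog does not feed forward, so conservation holds at unmutated
branch nodes to 1e-9). Gain-of-function multiplies the target edges' branch
fractions by g ≥ 1 before per-node renormalization (0.5/0.5 at g = 3
becomes 0.25/0.75).

**Transcript response.** Each transcript's mean is a class-specific stage
trend times a deterministic gene level, times a genotype modifier. The
mutated gene's own transcript scales by λ (lof) or g (gof). A
loss-of-function genotype additionally triggers a shared compensation
pattern over the other carotenoid genes — early genes induced, late genes
repressed, scaled by severity 1 − λ. This is a package design choice: the
motivating biology reports compensatory transcriptional reprogramming only
qualitatively, and *some* heterogeneous shared response is required for
mutants blocking neighboring steps to resemble each other in profile space
(a flat response carries no correlation signal). The pattern's exact shape
is not asserted as biological truth.

**Noise, modules, censoring.** Replicate = mean × exp(σ·z), σ = 0.25 by
default (log-normal multiplicative noise — positive, heteroscedastic, the
standard MS-like model). Planted modules share a per-sample latent factor
with loading √ρ: z = √ρ·F + √(1 − ρ)·ε, which makes the expected pairwise
log-scale correlation within a module exactly ρ (the loading-based
construction with loading ρ would give ρ², contradicting the intended
"planted correlation = ρ" semantics; the square-root loading is the
consistent choice). LOD censoring (default 1 unit) is applied after noise,
per replicate, so a feature can be ND in only some replicates — exactly the
case the differential ND rules must handle. Ground truth records the
noiseless means, the planted modules, and the genotype pairs implied by
same-effect mutations on chain-adjacent steps (for the default presets:
*at*–*r*; the two gain-of-function mutants push flux into opposite branches
and are deliberately not recorded as a pair).

**What the generator does not emulate** — and hence what a green test does
not establish: enzyme kinetics and saturation, allosteric/feedback
regulation, chromoplast sequestration effects, apocarotenoid volatiles,
batch effects, missingness mechanisms other than a sharp LOD, heavy-tailed
or correlated measurement error, and any coupling between transcripts and
metabolites beyond planted latent factors and shared flux means. Recovery
tests certify the pipeline's statistical machinery on data satisfying its
assumptions, not performance on real LC-MS/qRT-PCR data.

# Numerical choices and degenerate inputs

* Branch fractions must sum to 1 within 1e-9 at load time; flux
  conservation is asserted to the same tolerance.
* Pearson cells are clamped to [−1, 1] after the moment computation; the
  diagonal is exactly 1 where defined and `NA` for constant features.
* t and F statistics with zero denominators are guarded explicitly
  (identical groups → t = 0, p = 1; zero variance with distinct means →
  p = 0; all-identical ANOVA → `no_variance`).
* Dendrogram ties break on lexicographic leaf order after pre-sorting, so
  permuting the input cannot change the tree.
* On the log2 scale, nonpositive detected values (possible only in
  user-supplied tables, e.g. measured zeros) are treated as unusable for
  log-scale statistics and drop out pairwise, like ND.
* All generator randomness flows through one `set.seed(config$seed)`; the
  caller's RNG state is saved and restored, and identical config + seed
  gives bit-identical tables.

# Acceptance

Acceptance for this package is property-based: the motivating study's
headline numbers were measured on a wet-lab dataset that is not distributed
in machine-readable form, so there are no numeric point targets to
reproduce. The nine criteria (oracle equivalence for Pearson/t/ANOVA/HCL,
type-I calibration, flux-model exactness, hub-module recovery at τ = 0.88,
threshold monotonicity, differential exactness, end-to-end determinism)
live in `tests/testthat/test-acceptance.R` with their tolerances stated
inline; `scripts/acceptance.R` runs a seeded end-to-end execution and
reports an empty target set.

# Known limitations

* The flux model cannot represent accumulation at internal nodes other than
  via the backlog factor, nor negative regulation.
* `insufficient_replicates` suppresses the fold change even though a
  point estimate exists (see the differential contract above).
* Hub recovery guarantees hold for the planted-module world; correlated
  decoys (e.g. co-regulated but biologically unrelated features) will
  inflate false partners at any threshold.
* The CLI reads the default design for `diff`/`hcl` subcommands; panels
  with other wild-type structures should use `run-all` with a config or
  the R API directly.
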