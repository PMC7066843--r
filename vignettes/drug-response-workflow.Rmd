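---
title: "Methods: metaproteomic drug-response screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaproteomic drug-response screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpscreen)
```

## The observation model

`mpscreen` analyzes screens in which individual gut microbiomes are
cultured in multi-well plates with one compound per well (plus a DMSO
vehicle control per individual) and read out by label-free quantitative
metaproteomics. The central assumption is the **equal-volume contract**:
because every well is digested and injected at the same volume, measured
peptide intensity is proportional to the absolute amount of protein in the
well. Nothing in the workflow renormalizes samples to a common total
before biomass estimation — that proportionality *is* the measurement of
absolute biomass, and the package treats any per-sample rescaling of raw
peptide intensities as a modelling error.

Three quantities follow directly:

* **Total biomass** of a sample: the sum of its peptide intensities.
* **Taxon biomass**: each peptide is assigned to the lowest common
  ancestor (LCA) of its candidate taxa on the fixed ladder superkingdom,
  phylum, class, order, family, genus, species; a taxon's biomass at rank
  *r* is the summed intensity of peptides whose LCA sits at or below it.
* **Functional activity**: protein-group LFQ intensities, aggregated by
  COG category, COG, KO, or EC.

### LCA contribution rule

A peptide contributes its *full* intensity to every ancestor of its LCA
and to nothing below the LCA. We deliberately do not split shared-peptide
intensity among candidate taxa: splitting requires an estimate of the
candidates' relative abundance (circular, since that is what is being
measured), whereas the full-intensity rule keeps two exact invariants that
the test suite checks on every simulated table — per-sample conservation
(taxon sums plus the unassigned remainder equal total intensity at every
rank) and rank nesting (a genus never outweighs its family, order, or
phylum). Peptides whose LCA lies above the reporting rank are pooled into
an explicit `unassigned` row rather than dropped. Missing observations
are absent rows and enter all sums as zero; this is a summation semantics,
not an imputation.

## Statistical procedures

**Abundance contrasts.** Per-individual log2 fold changes use
`log2((x_drug + c)/(x_ctrl + c))`. The default pseudocount *c* is half the
smallest nonzero entry of the matrix — small enough not to distort
quantified features, large enough to keep ratios defined under
left-censored missingness; it is configurable, and `c = 0` flags 0/0
cells instead of guessing. Because LFQ-derived quantities are heavily
non-normal, significance uses the Wilcoxon rank-sum test: exact by
enumeration when both groups have ≤ 8 untied observations, otherwise the
normal approximation with tie and continuity correction. A fully tied
input (no evidence of separation) reports p = 1. Multiplicity is
controlled by Benjamini–Hochberg step-up FDR. COG-level summaries use a
raw p < 0.05 cutoff while genus/species and replicate analyses use
BH q < 0.05, both exposed in the configuration.

**Community shifts.** For each compound we compute the Bray–Curtis
dissimilarity between each individual's drug-treated and own-control
relative-abundance profile, then compare the compound's distance set
against a reference distribution by a two-sided rank-sum test with BH
adjustment across compounds. The reference is an open design point (the
comparison baseline is not fixed by convention): we use control
replicate-pair distances when the design has replicate controls, and
otherwise, for each compound, the pooled distances of all *other*
compounds — a compound then stands out only against the panel's baseline
variability. Both choices are explicit in `drug_shift_test()`.

**Functional profiling.** Protein groups are kept when quantified in
strictly more than 80% of individuals ("quantified" meaning nonzero in at
least one of that individual's samples — the most literal reading of
"appears in"; with 5 individuals, 4/5 = 80% is removed). Intensities are
log2-transformed and quotient-normalized per sample (`v/mean(v)`, so each
sample's mean is exactly 1), then batch-corrected across individuals with
parametric empirical-Bayes location/scale adjustment (ComBat, via the
`sva` package). The EB standardization needs a complete matrix, and the
literature gives no imputation rule here, so cells still missing after
filtering are mean-imputed per (feature, individual) and flagged. Two
numerical guards matter: a single batch returns the input unchanged, and
features whose residual variance after batch-mean removal is numerically
zero (< 1e-10) are adjusted by exact batch-mean centering — the EB
standardization would otherwise divide by zero; this also makes the
pure-location case exactly idempotent.

**Multivariate analysis.** PLS-DA is fitted by NIPALS on column-centered
data with a centered 0/1 class vector, deflating X after each component;
weights are unit-norm and scores orthogonal by construction. Variable
importance is `VIP_j = sqrt(p · Σ_a ssy_a w_ja² / Σ_a ssy_a)`, which
satisfies `Σ VIP² = p` for every fit (asserted to 1e-9 in the tests);
VIP > 1 marks differential features. Model quality is R² on the training
fit and Q² = 1 − PRESS/TSS from cross-validation; leave-one-out is the
default because per-compound contrasts have ~10 samples, where k-fold
splits degenerate. PerMANOVA uses Anderson's pseudo-F on squared
distances with seeded label permutations; p = (1 + #{F* ≥ F})/(1 + n_perm),
so 999 permutations give a floor of 0.001, and an exhaustive mode
enumerates all n! permutations for small n. Note that the floor is only
attainable when the probability of a random permutation reproducing the
observed partition is negligible — with two groups of five it is ~0.8%,
so well-separated multi-group designs (e.g. five individuals) are needed
to reach 0.001.

**Compound classes.** A compound is called class I (consistent
cross-individual metaproteomic shift) iff cross-validated Q² ≥ 0.4 or the
protein-level shift test has q < 0.05, class II otherwise. The outcome of
such calls is reported in screens, but no published decision rule exists;
0.4 is a conventional chemometrics threshold and the boundary counts as
class I (≥). Both thresholds and the component count (default 2) are
configuration values.

## The synthetic data generator

The generator exists to give every analytical claim a ground truth. It
emulates, with one seeded RNG stream per operation call and no global
state:

* log-normal baseline taxon abundances (sdlog 1.5 — community members
  spread over orders of magnitude), lineages drawn from a fixed table of
  ~45 real gut genera so congeneric species, shared families, and
  single-member phyla occur naturally;
* protein catalogs with COG/KO/EC annotations drawn from a shared
  ortholog pool and Dirichlet expression fractions summing to 1 per
  taxon;
* peptides with log-normal ionization factors, a controllable fraction
  shared between taxa that have a genus or phylum in common;
* drug effects in three modes: global scale *g*, per-taxon survival
  *s_t ∈ [0, 1]*, and per-(taxon, COG category) regulation *r*.
  Regulation does **not** renormalize the taxon's other proteins, so a
  regulated taxon's biomass drifts by the regulated expression share:
  the ground truth stays exactly computable, at the cost of a small,
  quantified biomass leak (a category with expression share *f* regulated
  by *r* scales biomass by 1 + f(r−1));
* observation noise: multiplicative log-normal peptide noise (log2 sd,
  default 0.3), per-(protein, individual) batch offsets (log2 sd 0.5),
  per-(taxon, individual) compositional offsets (log2 sd 1.0 — different
  people carry the same taxa at very different levels; this is what makes
  samples cluster by individual and buries small biomass drifts in
  between-individual variability, as in real screens), and logistic
  left-censoring missingness on log2 intensity (50% point at 14, slope
  −1, ~3–8% missing at baseline intensities; slope 0 disables it).
  Published screens do not quantify LFQ noise magnitudes, so these
  defaults are stated choices, not empirical estimates.

What the generator does *not* emulate: spectra (no m/z, retention time,
peak shapes), peptide sequences, database-search errors, razor-peptide
assignment ambiguity beyond the candidate-taxon sets, growth kinetics of
the 24-h culture, and drug chemistry. Passing tests therefore demonstrate
that the *analytics* recover known effects under realistic intensity
statistics — not that any particular real compound behaves a given way.

## Validation study sizes

The acceptance checks run at desk scale, chosen to exercise each property
with comfortable margins: LCA oracle agreement on 1,000 random peptides
against a prefix-intersection reference; dilution series of 6 gradients ×
3 replicates at log2 noise 0.1; global-kill recovery (g = 0.3) over 20
screens of 5 individuals; selective 4-fold depletion of one random genus
over 50 screens of 5 individuals with triplicate wells and ~39 genus
features; function-only regulation (r = 4 on a category with ~10%
expression share) over 25 screens. Exact rank-sum tests are discrete:
with single wells the smallest attainable 5-vs-5 one-sided p is 1/252, so
BH-adjusted detection of a *single* responding genus among ~40 at
q < 0.05 is impossible by arithmetic — the depletion power study
therefore uses triplicate wells (15 vs 15 per genus), the same technical
replication used to establish assay reproducibility. In real panels many
features respond at once, which lowers BH thresholds and restores
single-well sensitivity.

## Known limitations

* Two-class PLS-DA only; no multiclass or sparse/orthogonal variants.
* The rank-sum contrast treats all wells as exchangeable within arm;
  a paired signed-rank alternative across individuals is a reasonable
  variant we note but do not implement.
* No phylogeny-aware distances (UniFrac) and no compositional (CLR)
  transforms — the workflow's premise is precisely the absolute-abundance
  view.
* Absolute biomass is relative-to-control in arbitrary intensity units;
  no conversion to cells or protein mass is attempted.
* t-SNE visualization of class I compounds is delegated to standard
  implementations (perplexity 10, 1200 iterations recorded in
  configuration); the package computes the corrected matrices it would
  consume but draws no embeddings.
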