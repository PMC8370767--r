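---
title: "Master regulator discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master regulator discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`regmra` turns a heterogeneous collection of gene-by-sample expression
matrices into a ranked list of candidate master regulators of a two-state
transcriptional phenotype (mesenchymal vs non-mesenchymal in the glioma
stem-cell setting the package was built for), and provides the companion
survival-stratification and limiting-dilution analyses used to validate
candidates. This vignette explains each model, the parameters that matter,
the numerical conventions, and the choices made where the design was
genuinely open. Every empirical claim below is one the package's own test
suite or acceptance script computes.

## Harmonization

**Model.** Platforms differ in per-gene location and scale. We assume these
effects are affine per gene within a dataset, so z-scoring each gene across
a dataset's samples (mean 0, SD 1) makes blocks from different platforms
comparable; downstream stages are rank-based (mutual information, ssGSEA) or
include batch indicators (differential expression), so any residual
distributional mismatch must act through ranks to matter.

- *Probe collapse*: the per-sample **median** over a gene's probes; an even
  probe count uses the mean of the two middle values. Probes without a
  mapping, or mapping to several genes, are dropped. Collapse commutes
  exactly with sample subsetting.
- *Scaling axis*: per **gene** within dataset, not per sample. Per-sample
  scaling would erase between-sample differences — the very signal the
  subtype and network stages need — whereas per-gene scaling removes exactly
  the platform effects the assumption names.
- *SD convention*: population SD (divisor *n*). The choice is immaterial to
  every rank-based consumer and differs from divisor *n − 1* only by a
  constant per-gene factor; fixing it makes the standardization exactly
  idempotent and the tests exact (tolerance 1e-9).
- *Degenerate genes*: a gene constant within any dataset has no defined
  z-score and would produce degenerate dependence estimates, so it is
  removed from **all** datasets and reported in the removal list rather than
  imputed as 0.
- *Missing values*: rejected by default; per-row median imputation within a
  dataset is available behind `impute = TRUE` and off by default, because
  silent imputation changes ranks.

## Subtype scoring and classification

**Score.** For one sample, genes are ranked by decreasing expression (ties
broken lexicographically by gene id, for determinism). A signature's score
is the running-sum integral
\[
\mathrm{ES} = \sum_{i=1}^{N} \left[ P_{\text{in}}(i) - P_{\text{out}}(i) \right],
\]
where \(P_{\text{in}}\) accumulates in-set weights
\((N - \text{rank} + 1)^{w}\) normalized to sum 1 and \(P_{\text{out}}\)
accumulates uniform steps over out-of-set genes. Using the *descending rank*
as the weight statistic (not the raw value) keeps the score invariant to any
strictly monotone transform of the profile — essential when profiles come
from different platforms.

- `weight_exponent` *w*: default **0.25**, the canonical single-sample GSEA
  choice; 0 gives unweighted steps. The score is exactly mean-zero over
  uniformly random signatures only at *w* = 0 (by rank-reversal symmetry);
  weighted scores carry a positive offset, which is irrelevant to
  classification because p-values come from a size-matched null.
- *Null model*: `n_perm` (default **1000**) gene sets drawn uniformly
  without replacement from the profile's genes, size-matched to the
  signature — our reading of "equivalent distribution resampling". The
  empirical p is \((1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}}+1)\),
  so the smallest attainable p is \(1/(n_{\mathrm{perm}}+1)\).
- *Shared nulls*: null sets are drawn per signature **size** (seed derived
  from the size), so equal-size signatures — including duplicates — face the
  identical null and the tie-break (smaller p, then larger score, then
  signature order) is well defined.
- *Concordance filtering*: with two classification schemes (e.g. a
  three-subtype scheme and a two-state scheme), samples are retained only if
  their labels agree under a user-supplied mapping (mesenchymal ↔
  injury-response; proneural/classical ↔ developmental) — the selection
  rule used to assemble concordant stem-cell line collections.

## Differential expression

Per-gene OLS on `~ group + batch` (intercept, one two-level group indicator,
batch indicators). Rank-deficient designs — e.g. a batch perfectly
confounded with the group — are rejected with the aliased columns named.
Additive batch shifts are absorbed exactly (tested at 1e-8).

**Empirical-Bayes moderation.** Residual variances are modeled as
\(s^2 \sim s_0^2 F(d, d_0)\). The prior \((d_0, s_0^2)\) is estimated by
method of moments on \(\log s^2\): the excess of \(\mathrm{Var}(\log s^2)\)
over \(\psi'(d/2)\) determines \(d_0\) through a trigamma inversion (Newton,
relative tolerance 1e-10), and the mean determines \(s_0^2\). Non-positive
excess dispersion means the variances are exchangeable: \(d_0 = \infty\) and
the posterior collapses to the pooled mean variance. Moment matching was
chosen over marginal maximum likelihood because it is closed-form,
deterministic and directly testable (prior recovery from simulated
scaled-F variances is part of the acceptance suite); it also reproduces
limma's estimates to 1e-6 on shared inputs, which the test suite checks as
an independent cross-validation. The moderated statistic
\(t = \hat\beta / \sqrt{\tilde s^2 v}\) is referred to a t distribution with
\(d + d_0\) df (normal when infinite).

- `q_threshold` (default **0.05**) defines the signature gene lists (up =
  q below threshold and positive effect; down likewise). 0.05 is a declared
  default, not an inferred one, and is configurable.
- `top_n` (default **100**) is only a display list (the heatmap convention),
  ranked by q with ties by |t| then gene id.

## Regulon network inference

**Estimator.** Dependence between a TF and a candidate target is measured by
Gaussian-copula mutual information: both vectors are transformed to normal
scores (\(\Phi^{-1}(r_i/(n+1))\), average ranks on ties) and
\(\mathrm{MI} = -\tfrac12 \log(1 - r^2)\) for their Pearson correlation *r*.
This estimator is symmetric, nonnegative, closed-form, deterministic and
invariant to strictly monotone transforms of either input — properties an
adaptive-binning estimator only approximates. \(r^2\) is clipped at
\(1 - 10^{-12}\) so deterministic relationships give a large finite value.
A fixed-grid histogram estimator (`mutual_information_binned`) is provided
for comparison only.

**Null and filtering.** For each TF, the sample order of its normal-score
vector is permuted `n_perm` = **1000** times and MI recomputed against all
of that TF's targets; all null values across all TFs are pooled into a
single distribution (pool size = n_perm × targets × TFs), and each edge's
p-value is its pooled upper-tail rank. This pooled design is the convention in pooled-null network tools and, with no ties in the data, is statistically equivalent
to per-pair nulls while being far cheaper per effective null sample. Edges
are kept at BH **q < 0.05** (`alpha`). Under a fully independent matrix the
edge p-values are uniform (KS < 0.05) and the post-BH false-edge fraction
stays at or below 0.05 — both checked in the acceptance suite.

**DPI pruning.** In every fully connected triangle of two TFs and a target,
the weakest edge is removed if its MI is below
\((1 - \text{tolerance}) \times\) the smaller of the other two
(`dpi_tolerance` default **0**; exact ties are left alone). All removals are
marked against the pre-pruning table and applied simultaneously, making the
result independent of enumeration order and the operation idempotent. Any
of the three edges may be removed, including the TF–TF edge — the rule
names "the weakest interaction", not a type; `protect_tf_tf = TRUE`
implements the alternative reading. Regulons are the surviving TF→target
edges to non-TF targets, with the normal-score correlation sign attached.

## Master-regulator ranking

Each regulon (intersected with the analysis universe — the harmonized
matrix's genes, *not* the genome, because both regulons and signature were
derived there) is tested two ways:

1. **Hypergeometric overlap** with the signature genes (up ∪ down by
   default; per-direction lists are also available):
   \(p = P(X \ge \text{overlap})\) with population = universe, successes =
   signature, draws = regulon size; BH across TFs. The ranking key is
   q ascending, ties by p, then |NES| descending, then TF id; the reported
   top slice uses `mra_alpha` = **1e-4** (the "BH p < 0.0001" convention).
2. **One-tail GSEA** of the regulon (as an unsigned set) against the
   moderated-t ranking, the classical weighted KS running sum (`weight` =
   1): hits advance by \(|t|^{w}\) normalized, misses by \(1/(N - k)\); ES =
   signed maximum deviation (a positive deviation wins an exact magnitude
   tie). NES = ES / mean |null ES| over size-matched random sets;
   regulons with fewer than 3 ranked genes are skipped with a warning.
   Signed two-tail variants are deliberately not the default; the one-tail
   form is the reporting convention this package follows.

## Survival stratification

Samples are sorted by marker expression (ties by sample id); the top
\(\lfloor 0.30 n \rfloor\) form the high group and the bottom
\(\lfloor 0.30 n \rfloor\) the low group (`high_fraction`, `low_fraction`;
floor, not rounding, so group sizes never exceed the nominal fraction). Cuts
are computed on the pooled cohort. Kaplan–Meier estimation and the log-rank
test are delegated to the `survival` package (events precede censorings at
tied times; classical variance, no continuity correction); the test suite
validates the statistic against an independent O−E−V tabulation at 1e-10.
The 1-df chi-square reference for the log-rank statistic is asymptotic; its
null p-values meet the KS < 0.07 uniformity band at cohort sizes around 200
(the TCGA/CGGA-like regime this module targets), while cohorts of a few
dozen show visible finite-sample conservatism.

## Limiting-dilution analysis

Single-hit model: \(P(\text{well negative} \mid \text{dose } d) =
e^{-f d}\). The MLE of *f* is the intercept of a binomial GLM for
positive-well counts with complementary-log-log link and offset \(\log d\)
— the standard ELDA formulation — and the single-dose case reduces to the
closed form \(\hat f = -\log(\text{neg}/\text{tested})/d\) exactly.
Frequencies are reported as "1 in N" (N = 1/f). The 95% CI is Wald on
\(\log f\) (the standard ELDA choice; profile likelihood behind
`profile = TRUE`). Wald coverage at a 96-well, three-dose design with true
N = 30 sits inside 93–97% over 500 simulated replicates (acceptance suite).
Boundary cases: all wells negative returns f = 0, N = ∞ with a `boundary`
flag; all wells positive at every dose is an error (f unbounded). Group
comparison is the likelihood-ratio chi-square between pooled and per-group
fits with (groups − 1) df. Dose rows may be split or merged freely — the
fit depends only on per-dose totals.

## Synthetic data: what it emulates and what it does not

`gen_expression()` plants the statistical structure the analysis assumes:
two latent states (half the samples, balanced within every batch so state
and batch are never confounded), MES-driving TF genes carrying an additive
effect *a* in MES samples, disjoint regulons whose targets are
sign·TF + Gaussian noise, i.i.d. background genes, and per-batch per-gene
affine distortions (shift SD = `batch_shift`, log-normal scale SD 0.25) that
per-batch standardization removes *exactly* — which makes the harmonization
stage's contribution testable by ablation. A heavy-tailed noise option
(t with 3 df) exercises the rank-based MI estimator's robustness.

Planted regulons are attached to the first `n_reg_tfs` TFs (default: the
MES drivers); the remaining TFs are decoys with no targets. Giving *every*
TF a regulon of the default size would need more genes than a realistic
common-gene intersection contains, and decoy TFs are the relevant negative
control for the ranking stage. Default study-scale conditions: 2000 genes,
150 samples, 3 batches, 100 TFs, 5 MES drivers with regulons of 40, effect
1.0, noise SD 1 — chosen to mirror the scale of real multi-platform
stem-cell collections (about ten thousand common genes and ~900 TFs,
scaled down ~5× for desk-scale runtimes) while keeping per-edge signal (correlation ≈ 0.7 at effect 1,
noise 1) in the regime where recovery is expected but not trivial.

What the generator does **not** emulate: count-distribution artifacts of
RNA-seq, probe saturation, correlated background modules, overlapping
regulons, feedback loops, or dropout. Passing tests therefore demonstrate
correctness of the inferential machinery under the stated model, not
robustness to every failure mode of real cross-platform data.

`gen_survival()` ties an exponential event-time model (baseline hazard
1/500 per day, hazard ratio applied to marker-high samples, independent
exponential censoring) to a Gaussian marker; `gen_lda()` draws well counts
binomially from the single-hit model.

## Reproducibility conventions

Every stochastic operation takes a seed and restores the caller's RNG state;
a single pipeline seed derives per-stage seeds by hashing the stage name
(`stage_seed()`), so stages can be rerun in isolation and full reruns are
byte-identical (verified via output checksums in the test suite). All
tie-breaks (rank ties, classification ties, ranking ties, percentile cuts)
are deterministic and documented above. Validation problem sizes: ten
study-scale end-to-end runs for regulator recovery; 500-replicate null
simulations for edge-p uniformity, log-rank calibration and CI coverage;
200 random graphs for the DPI oracle; 5000 genes for prior recovery.

## Known limitations

- The pooled permutation null assumes exchangeable samples; strong residual
  batch structure after standardization would inflate edge significance.
- BH across all TF–target pairs controls FDR edge-wise, not per regulon.
- The hypergeometric MRA treats signature membership as binary; a TF whose
  regulon sits just below the q threshold contributes nothing.
- Wald CIs on log f degrade near the f = 0 boundary; use the profile option
  for very rare frequencies.
- The survival module implements two-group comparison only (no Cox
  adjustment), matching its role of validating a single marker.
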