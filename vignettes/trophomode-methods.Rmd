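---
title: "Inferring protist trophic mode from gene-family expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protist trophic mode from gene-family expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophomode)
```

## The problem

Marine protists span a nutritional continuum from strict phototrophy
(photosynthesis) through mixotrophy (simultaneous photosynthesis and
phagocytic feeding) to strict heterotrophy (prey ingestion). Which strategy a
population is actually using *in situ* is hard to observe: incubation-based
feeding assays are laborious and perturb the community. `trophomode`
implements a machine-guided alternative: train tree-ensemble classifiers on
gene-family (Pfam) expression profiles of cultured protists whose trophic
mode is known from growth conditions, distill the feature space down to the
gene families that actually carry trophic signal, and deploy the fitted
models onto species-level taxonomic bins extracted from environmental
metatranscriptomes.

The package starts at annotated gene-family abundance tables (features ×
samples, TPM); upstream read QC, assembly, annotation, and taxonomic binning
are the province of established pipelines and out of scope.

## Data model

An expression matrix (`trophic_matrix`) is a non-negative features × samples
matrix with a units flag. Under the `"tpm"` flag each sample column must sum
to $10^6$ within a relative tolerance of $10^{-6}$ — the tolerance exists to
absorb decimal round-tripping through text files, nothing more. Per-sample
metadata ride along as a tibble, and everything downstream that is naturally
tabular (label assignments, prediction records, bin summaries, trend fits)
is a tibble, so the pipeline composes with dplyr verbs and the pipe.

Labels live in a closed vocabulary: heterotrophy, mixotrophy, phototrophy,
with `"unlabeled"` allowed only in metadata. The ordering
heterotrophy < mixotrophy < phototrophy is fixed and used wherever a
deterministic tie-break is needed (argmax ties in prediction are
measure-zero but must not depend on memory layout).

## Labeling by growth conditions

Training labels are assigned per *transcriptome*, not per species: a known
mixotroph grown in the light with bacteria present is labeled mixotrophic,
while the same organism grown in the light without bacteria is labeled
phototrophic; curated literature labels pass through for everything the
condition rules do not cover. The rules are data, not code — an ordered
first-match-wins table (`default_label_rules()`, extensible via YAML) —
because the full label rule set used in any given study is usually longer
than what its text states, and users must be able to extend it without
touching the package. Samples matching no rule are reported unlabeled with a
reason code; when several matching rules disagree the first still wins but a
warning is raised, and a strict mode converts such conflicts to unlabeled,
mirroring the exclusion of conflicting literature classifications.

## Class balancing

Culture compendia are dominated by phototrophs (at compendium scale:
275 phototrophic, 93 mixotrophic, 78 heterotrophic labeled transcriptomes).
`undersample()` draws a uniform without-replacement subset of the dominant
class under a recorded seed; `mda_multi()` repeats feature selection over
several under-sample sizes (80, 100, 120, 140 at compendium scale) and
merges the results. The merge rule defaults to the union — selection is a
screening step, and a family that carries signal at any class balance is
worth keeping — but intersection and majority policies are available because
the right merge is genuinely a judgment call.

## Permutation feature selection (mean decrease in accuracy)

The selection core is a train–test permutation importance loop:

1. Fix a stratified $k$-fold partition (default $k = 5$) under `fold_seed`.
2. Compute the baseline mean held-out accuracy over the folds.
3. For each gene family $j$, shuffle its values across *all* samples (one
   draw, seeded by `bitwXor(perm_seed, j)`), recompute the cross-validated
   accuracy **with the same partition**, and retain $j$ iff the permuted
   accuracy is *strictly* lower than the baseline.

Three choices deserve justification:

* **The fold partition is frozen** across the baseline and every permuted
  run. If folds were re-drawn per feature, fold noise rather than the
  feature's contribution would drive retention.
* **Strict inequality, ties dropped.** "Any decrease in accuracy" is read
  literally. A feature the ensemble never uses leaves predictions unchanged
  under permutation, produces an exact tie, and is discarded. This is the
  aggressive pruning that keeps a ~9,000-family feature space from
  overwhelming a few-hundred-sample training set; it also means the
  false-positive rate of the rule is governed by how often permuting an
  irrelevant column happens to perturb the ensemble into a strictly worse
  configuration.
* **One permutation per feature** is the default (a `permutations` argument
  averages several, with replicate $r$ seeded by
  `bitwXor(perm_seed, j) + r - 1`). The single-pass variant is the described
  behavior of the procedure this package implements; averaging is offered
  for users who want a less noisy importance estimate at proportional cost.

Permutation is applied before fold splitting (shuffling "across samples"),
not within folds. Per-feature seeds derive deterministically from
`(perm_seed, j)`, so reruns are bit-identical and features can be
re-examined in isolation.

Two learner families are supported behind one `classifier_spec` surface: a
bagged tree ensemble (random forest, via ranger) and a gradient-boosted tree
ensemble (via xgboost, histogram splits). Both are seeded and fitted
single-threaded, making every accuracy in the package a pure function of
(data, spec, seeds).

The forest used *inside* the selection loop is deliberately small (the
examples and the acceptance script use 32 trees). This is partly a runtime
concession — the loop fits $k$ ensembles per feature, and a full pass over
2,000 families runs in minutes on one core at this size — and partly a
sensitivity requirement of the strict-decrease rule. Because the model is
*retrained* on each permuted matrix, it simply routes around a permuted
family whenever correlated block-mates carry the same signal: held-out
predictions do not change, the accuracy ties the baseline exactly, and the
family is dropped. Whatever per-family recall the rule has therefore comes
from finite-sample fragility, and a large, stable forest suppresses it. A
small forest keeps the single-feature perturbations visible while leaving
the false-retention rate low. Per-family retention under the single-pass
rule is nonetheless intrinsically noisy (reruns under different
learner/fold seeds retain overlapping but different sets) — which is why
the deployed workflow unions selections across several under-sampled
datasets rather than trusting one pass, and why retained *sets* (strongly
enriched for signal) are more meaningful than any single family's
in-or-out status. Final models, where stability rather than sensitivity is
wanted, use larger ensembles (200 trees / 50 boosting rounds).

Selection outputs are `feature_set` objects carrying full provenance
(learner, seeds, baseline and per-feature permuted accuracies).
`combine_feature_sets()` implements the common (intersection) and combined
(union) set algebra used when two learners' selections are reconciled; sizes
obey inclusion–exclusion exactly.

## Classification and evaluation

`train_classifier()` fits the final model on the complete labeled set
reduced to a feature set. The study this package operationalizes
under-sampled only for *selection*; for the final fit the package keeps all
labeled transcriptomes and addresses imbalance with inverse-frequency class
weights by default (`weights = "none"` disables this). Feature-set members
absent from the training matrix are zero-filled and logged — environmental
profiles routinely lack a handful of selected families, and rejecting them
would discard usable bins.

Predictions are tibbles with three class scores summing to one. A profile in
which *every* model feature is zero carries no usable signal; it is flagged
`no_signal`, given an `NA` label, and excluded from downstream proportions.

`cross_validate()` aggregates held-out predictions into a single confusion
matrix and reports per-class precision/recall, macro-averaged precision
(reported alongside the per-class values, since "precision" unqualified is
ambiguous), and Cohen's κ computed from the aggregated matrix as
$\kappa = (p_o - p_e)/(1 - p_e)$. `compare_runs()` wires together the
standard non-parametric battery for comparing metric distributions across
model families: Kruskal–Wallis omnibus, pairwise Wilcoxon rank-sum
(exact enumeration when both groups have ≤ 10 values and no ties, normal
approximation with tie correction otherwise), Benjamini–Hochberg adjustment.
These call the stats implementations; the package adds only the exact/approx
switch and the degenerate all-tied guard ($H = 0$).

`consensus()` (two models agree or the call is `"none"`) and
`majority_vote()` (strict > ½ majority, or plurality with ties unresolved)
implement the replicate-aggregation rules used when interpreting predictions
over replicated transcriptomes.

## Environmental deployment

Field bins pass through three gates before aggregation (`filter_bins()`):

* **Completeness**: a profile needs at least 800 gene families with nonzero
  abundance. The boundary is compared as ≥ — a profile with exactly 800
  passes — because the criterion is phrased as *meeting* a cutoff of 800;
  the comparison is configurable for users who read it exclusively.
* **Replication**: within a grouping unit (station by default) a bin needs
  at least 4 surviving profiles; prediction proportions from fewer
  replicates are too noisy to interpret.
* **Relatedness**: bins not closely related to a training-set species are
  dropped. This is a user-supplied metadata flag; the package does no
  phylogenetics.

Every dropped profile appears in exactly one exclusion-report row with a
machine-readable reason.

`bin_proportions()` sums per-transcriptome predictions into per-bin,
per-group counts and proportions. `conflict_exclusion()` then flags bins
whose classified profiles split into > 25% phototrophy *and* > 25%
heterotrophy while essentially lacking mixotrophy — such bins sit on the
model's decision boundary and their trophic mode cannot be called. "Lacking
mixotrophic predictions" is not a number in the source description; the
package defaults the mixotrophy floor to 0.05 (a bin with a token
mixotrophic call or two is still conflicted) and a strict `mix_floor = 0`
reading is one argument away. The thresholds are strict inequalities at the
boundary.

**Model choice at deployment.** Environmental bin profiles are sparser
than culture profiles: extra zeros remove mass that TPM renormalization
redistributes over the detected families, inflating their values by a
roughly constant per-sample factor. Boosted ensembles, which carve sharp
absolute-abundance thresholds, are more sensitive to that compositional
shift than bagged forests, whose bootstrap-averaged thresholds blur over
it. The synthetic end-to-end recovery check therefore deploys the bagged
forest; for real data the choice between the two learners should weigh
in-distribution accuracy (where boosting tends to win) against robustness
to sparsity (where the forest does).

`latitude_trend()` fits, per trophic mode, an ordinary least-squares
polynomial (degree 2 by default) of prediction proportion against station
latitude with a pointwise 95% confidence band. The overall trend p-value is
the F-test of the polynomial against the intercept-only model — the source
reports a strongly significant latitudinal decline without naming a test,
and the model-comparison F-test is the natural frequentist choice for a
nested polynomial fit. Latitudes are used per station as given; size
fractions are kept separate by the caller's grouping. `diel_aggregate()`
groups by hour-of-day across days or by a day/night split (06:00–18:00
local by default, configurable).

## Diagnostics

`tsne_embed()` reproduces the standard latent-space diagnostic: reduce to a
feature set, log10-transform, standardize each feature, and embed with
t-SNE at high perplexity (default 100, reduced with a warning when the
sample count cannot support it) to emphasize global structure. "Scaling" is
read as per-feature standardization after the log transform; min–max and
no-op scaling are available since the choice is not canonical. Only
neighborhood structure in the embedding is meaningful, and tests assert
separation (silhouette), never coordinates.

`median_cluster_heatmap()` computes per-mode median TPM for each selected
family, removes families with zero median in every mode, log10-transforms,
and orders rows by agglomerative clustering — average linkage on
correlation distance by default, both configurable, because neither metric
nor linkage is canonical for this view. Zero-variance rows are assigned
maximal distance to everything else rather than propagating NaN
correlations.

## The synthetic-data generator

Every stage is testable without downloads via `synthetic_spec()` /
`generate_training()` / `generate_env_bins()`. The generator draws
gene-family counts from a negative binomial (variance
$\mu + \phi\mu^2$), applies Bernoulli dropout, draws library sizes
uniformly, and TPM-normalizes — a count layer gives realistic
overdispersion and a natural dropout mechanism even though the consumed
data are TPM. The trophic signal is block-structured: a
heterotroph+mixotroph block, a phototroph+mixotroph block, and a
mixotroph-specific block, each elevated by `effect` (log2 fold-change) in
the classes where it is active. Mixotrophs thus share signal with both
specialist classes plus a private block — encoding the empirical
observation that mixotroph profiles overlap both specialist clusters
rather than forming a third isolated cluster.

Default conditions: 2,000 features with 20/20/20 informative blocks, effect
2 (4-fold), dispersion 0.5, dropout 0.2, classes 75/45/30
(phototrophy/mixotrophy/heterotrophy — preserving the compendium's
dominance ordering at a size where a full permutation-selection pass runs
in minutes). An `"mmetsp"` preset exposes the compendium-scale shape
(9,000 features, 275/93/78). Environmental bins get extra Bernoulli
thinning calibrated so the median nonzero-family count per profile
approaches a target (default 900, comfortably above the 800 cutoff so the
completeness gate is exercised from both sides); the calibration is a
simple expected-value scaling, chosen to exercise the deployment rules
rather than to mimic any measured field sparsity distribution, which the
source describes only qualitatively.

What passing tests on this generator do **not** show: robustness to
taxonomic mis-binning, compositional artifacts of assembly and annotation,
diel expression oscillation, or covariance between gene families beyond
block membership. The generator is a statistical caricature sufficient to
verify the machinery, not a simulator of ocean metatranscriptomes.

## Numerical and reproducibility choices

* All randomness flows through named integer seeds (`withr::with_seed`), so
  no call disturbs the caller's RNG state; per-feature permutation seeds
  are `bitwXor(perm_seed, j)`, kept in 32-bit range.
* Both learners run single-threaded with explicit seeds; identical inputs
  and seeds give bit-identical selections and predictions.
* The log transform is $\log_{10}(x + 1)$ by default — base and
  pseudocount are stated nowhere canonical, so both are explicit arguments.
* Model directories persist a manifest (class counts, seeds,
  hyperparameters, a hash of the feature list, engine versions); loading
  verifies the feature-list hash and refuses silently tampered models.
* Problem sizes used by the test-suite and the acceptance script — 2,000
  features / 150 training samples / 20 bins × 6 profiles — are the
  generator defaults described above; cross-validation depth is the
  standard 5 folds throughout.

## Known limitations

* The MDA retention rule is binary and single-pass; it reports no effect
  size per family beyond the permuted-accuracy drop stored in provenance.
* Because the rule retrains on every permuted matrix, its per-family
  recall against redundant co-expressed blocks is modest by construction
  (see the selection section); it is a screening enrichment device, not a
  complete catalogue of informative families.
* Validation-scale claims (external culture transcriptomes, real field
  campaigns) require the original public datasets and are outside what the
  synthetic generator can certify.
* The latitude trend is a descriptive polynomial fit, not a causal or
  spatially autocorrelation-aware model.
* `training_related` is an input, so a mislabeled relatedness flag silently
  admits a bin the training set cannot speak for.
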