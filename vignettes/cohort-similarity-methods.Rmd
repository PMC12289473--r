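---
title: "Quantifying a shared facial gestalt: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a shared facial gestalt: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegestalt)
```

## The question the package answers

Ultra-rare syndromes often lack enough diagnosed patients for their facial
phenotype to be represented in reference databases. Given a handful of
patient photographs encoded as learned facial embeddings, do these patients
look more like *each other* than random faces do — i.e., is there a shared
facial gestalt? `facegestalt` answers this with three complementary
analyses in embedding space:

1. **Cohort-level**: compare the cohort's resampled mean pairwise distance
   distribution against two null distributions from a labelled reference
   gallery, and classify it with a threshold fitted by ROC analysis.
2. **Individual-level**: leave-one-out rank retrieval — when one patient
   image is the query, at what rank do the other cohort images appear in
   the distance-sorted gallery?
3. **Neighborhood-level**: which syndromes dominate each patient's top-k
   nearest gallery images?

## Distance model

Each image is an ensemble of `E` unit-norm embedding vectors of dimension
`d` (defaults `E = 12`, `d = 512`, the shape produced by model ensembles
with test-time augmentation). Similarity between images `A` and `B` is
the ensemble-averaged cosine distance

$$ D(A,B) \;=\; \frac{1}{E}\sum_{k=1}^{E}\bigl(1 - \langle a_k, b_k\rangle\bigr) \in [0,2]. $$

Member `k` of `A` is paired with member `k` of `B`: each ensemble member
comes from one model/augmentation, so index-aligned pairing yields one
distance per model. Averaging over all `E × E` member pairs is also
implemented (`mode = "all_pairs"`) but is not the default, because it
mixes distances across models and (for `A = B`) no longer vanishes.
Embeddings are L2-normalized once at load time; rows already unit to
within `1e-12` are left bit-identical, so loading is idempotent and
archives round-trip exactly.

## Resampled distance distributions

For a cohort with `m` subjects, one draw picks exactly one image per
subject (uniformly among that subject's photos) and records the mean
pairwise distance over all pairs. Two images of the same person are never
sampled together — within-person similarity would otherwise masquerade as
cohort similarity. The draw is repeated `n = 100` times.

Two null distributions come from the gallery, using sub-cohorts of the
same size `m` (the size is configurable; the choice of "same size as the
test cohort" keeps the statistic comparable, since mean pairwise distance
concentrates differently with sub-cohort size):

* **same-syndrome**: pick an eligible syndrome uniformly (any syndrome
  with at least two labelled subjects), then `min(m, available)` distinct
  subjects of it, one image each. Small syndromes contribute smaller
  sub-cohorts (minimum 2) rather than being excluded — real galleries are
  dominated by small cohorts, and dropping them would bias the null
  toward well-sampled syndromes.
* **random**: the same, ignoring syndrome labels entirely.

Syndrome selection is uniform over eligible syndromes, not image-weighted:
the syndrome is the sampling unit of the "same" null. Draws are
independent across the `n` repetitions (identical sub-cohorts may recur).
Any cohort image also present in the gallery is removed from the gallery
first, keeping test and reference disjoint.

## Threshold selection and the fraction-below statistic

The "same" and "random" samples are separated by a cutoff `c`: a distance
`<= c` is called "same disorder". Candidate cutoffs are midpoints between
consecutive distinct pooled values, plus sentinels below the minimum and
above the maximum, which makes the inclusive rule unambiguous (no
candidate ever equals an observed value). `c` maximizes the Youden index
`J = sensitivity + specificity − 1`; ties go to the smallest candidate,
with a `1e-12` tolerance so equal count ratios computed along different
floating-point paths still count as ties. AUC uses the Mann–Whitney rank
statistic (ties counted half), which equals the trapezoidal area under
the step ROC exactly.

The deployable threshold is fitted on all pooled samples; stratified
k-fold cross-validation (default `k = 5`, fold unit = one resampled draw)
supplies out-of-fold sensitivity/specificity as a generalization
estimate. The headline statistic is the fraction of the *test* cohort's
resampled distribution at or below `c`: near 1 means the cohort is
tighter than random same-syndrome cohorts; near `1 − specificity` is what
an unrelated cohort would produce.

## Rank retrieval

For query image `t`, the pool is the gallery plus the remaining cohort
images; the pool is sorted by distance to `t` (ties broken by image id,
so ranks are deterministic across platforms) and the 1-based rank of
every other cohort image is recorded. Same-subject probes stay in the
pool — that mirrors the realistic search scenario — but are flagged so
summaries can exclude them. Rank asymmetry (`rank(i→j) ≠ rank(j→i)`) is
expected and permitted. Top-k syndrome tallies count gallery images only:
cohort probes are excluded from the neighborhood, so the tally reflects
which *database* syndromes the patient resembles. Per-image tallies are
summed per subject; the modal syndrome breaks ties lexicographically.

## The synthetic gallery generator

Real reference galleries of patient facial embeddings are not
redistributable, so the package ships a generator that reproduces the
statistical structure the analysis relies on — nothing more. It is a
hierarchical model on the unit `(d−1)`-sphere:

* syndrome centers: uniform on the sphere (independent Gaussians,
  normalized);
* subject center: syndrome center + `sigma_subject`·Gaussian, normalized;
* image: subject center + `sigma_image`·Gaussian, normalized;
* ensemble member: image + `sigma_ensemble`·Gaussian, normalized.

Gaussian-perturb-then-normalize is used instead of exact von Mises–Fisher
sampling: it has the same qualitative geometry (isotropic scatter around
a spherical mean, concentration controlled by one scale), is trivially
reproducible from a seed, and needs no special functions. It is *not*
vMF; concentration parameters are not interchangeable with κ.

Defaults are chosen to emulate a desk-scale version of a syndromic
reference gallery: 50 syndromes × 3 subjects × 2 images (300 images —
the same many-small-cohorts shape as real galleries, at a size every
stage processes in seconds), `sigma_subject = 0.2`–`0.3`,
`sigma_image = 0.1`–`0.15`, `sigma_ensemble = 0.05` (subject identity
dominates photo noise, ensemble jitter is smallest — the ordering
observed in practice for ensembled face encoders). Test cohorts default
to 7 photos over 4 subjects, a realistic ultra-rare-cohort size. The
pipeline's default simulation uses `d = 64`, `E = 3` rather than the
full 512 × 12: cosine geometry on the sphere is already
high-dimensional at `d = 64` (random vectors are near-orthogonal), and
parameter-recovery behaviour is indistinguishable while runs stay fast.

What the generator does **not** model: age/sex/ancestry covariates,
photo quality artifacts, correlated (non-isotropic) embedding noise, and
between-syndrome similarity structure (all centers are exchangeable).
Passing recovery tests on synthetic data therefore shows the *pipeline*
is correct and well-calibrated under its own assumptions — not that any
particular real cohort shares a gestalt.

## Clinical tables

Phenotype tables use the `x/y (z n.a.)` convention: patients without a
recorded +/− value are excluded from the denominator, and the percent is
`floor(100·x/y)` — truncation, not rounding, inferred from the published
aggregates (5/12 → 41, 8/12 → 66, 7/11 → 63, 10/11 → 90, 5/8 → 62); a
complementary sex ratio prints as `floor` / `100 − floor`. The shipped
per-patient table is a synthetic reconstruction consistent with the
published aggregate counts (patient-level data beyond the two index
patients were not published); only its aggregates are meaningful.

ACMG-style evidence combining implements the standard pathogenic-side
rules over PVS1, PS1–4, PM1–6, PP1–5 (duplicates collapsed, order
irrelevant, monotone under added evidence): Pathogenic for PVS1 with
(≥1 PS | ≥2 PM | PM+PP | ≥2 PP), ≥2 PS, or 1 PS with (≥3 PM | 2 PM+≥2 PP
| 1 PM+≥4 PP); Likely pathogenic for PVS1+1 PM, 1 PS+1–2 PM, 1 PS+≥2 PP,
≥3 PM, 2 PM+≥2 PP, or 1 PM+≥4 PP; otherwise VUS. PP5 is accepted as an
ordinary supporting criterion despite its deprecation debates, because
published variant tables still use it. Two published combinations
(PP5+PM4+PM2 called Pathogenic; PM3+PM2+PP3 called Likely pathogenic) do
not follow these rules — both are 2 PM + 1 PP, which combines to VUS.
The package follows the standard algorithm and flags such rows as
discordant rather than special-casing them. Benign-side codes are out of
scope.

## Numerical and reproducibility choices

* Distances are clamped to `[0, 2]` against floating-point excursions;
  the aligned distance matrix is computed as one cross-product of
  flattened ensembles (`1 − FFᵀ/E`) and symmetrized.
* Every stochastic stage takes an explicit seed. The pipeline derives
  per-stage child seeds from the master seed by a stable hash of the
  stage name, so any stage rerun in isolation reproduces its output;
  reports embed the resolved configuration and all child seeds.
* Archives serialize numbers as `%.17g`, making write→load→write
  byte-stable.
* Degenerate inputs are errors, not warnings: zero-norm embedding rows,
  duplicate image ids, mixed `E`/`d`, sub-cohorts of one, empty sample
  vectors, unlabeled gallery images in syndrome tallies.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_syndromes = 50, subjects_per_syndrome = 3,
                        images_per_subject = 2, d = 64, E = 3,
                        sigma_subject = 0.2, sigma_image = 0.1,
                        sigma_ensemble = 0.05, seed = 11)
g  <- generate_gallery(cfg)
co <- generate_cohort(cfg, n_subjects = 4, images_per_subject = c(1, 3),
                      n_images = 7, seed = 12)

test   <- resample_test_distribution(co, n = 100, seed = 1)
same   <- build_same_distribution(g, size = 4, n = 100, seed = 2)
random <- build_random_distribution(g, size = 4, n = 100, seed = 3)

roc <- roc_from_samples(same, random)
fraction_below(test, roc$youden_threshold)
crossvalidate(same, random, k = 5, seed = 4)
pairwise_rank_matrix(co, g)
top_k_matches(co, g, k = 30)
```

Or, end to end with a report bundle:

```{r pipeline, eval = FALSE}
run_pipeline(pipeline_config("out", seed = 11))
```

## Known limitations

* The threshold is distribution-specific: a cutoff fitted on one
  gallery's nulls does not transfer to embeddings from another encoder.
* Mean pairwise distance depends on sub-cohort size; test and null
  sub-cohorts must use the same size for the fraction-below statistic to
  be calibrated.
* The generator's exchangeable syndrome centers make the "random" null
  slightly harsher than in real galleries, where related syndromes
  cluster; fraction-below on real data will sit closer to the threshold.
* Published percentages are reproduced from printed aggregate counts,
  not recomputed from raw patient records.
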