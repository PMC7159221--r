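---
title: "Readmission risk models and hospital risk standardization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Readmission risk models and hospital risk standardization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Hospitals in the United States are financially penalized for excess
30-day readmissions. Because patient mix differs across hospitals, the
penalties rest on *risk-standardized readmission rates* (RSRRs):
model-based rates that ask how a hospital would perform on a common
patient population. The standard instrument is a hierarchical logistic
regression (HLR) on age, sex and a fixed comorbidity summary
(29 Elixhauser-style binary indicators), with a Normal random intercept
per hospital. Its discrimination is modest, and a natural question is
whether richer models — gradient-boosted trees, feed-forward networks,
or networks that consume *learned embeddings* of the raw diagnosis and
procedure codes — predict readmission better, and, more consequentially,
whether they *rank hospitals differently* when used for
standardization.

`readmitr` implements that comparison end to end on synthetic claims:

1. a generator for admission-level claims with known ground truth,
2. cohort construction (exclusion cascade, first-admission selection,
   rare-code filtering, hospital-stratified 80/10/10 split),
3. GloVe-style embeddings of codes from record-level co-occurrence,
4. four risk models sharing one prediction contract,
5. predictive-margin (and predicted-over-expected) risk
   standardization, 20/60/20 hospital grouping, and reclassification
   analysis.

## The four models

All models emit `P(unplanned 30-day readmission)` in (0, 1).

**HLR.** `logit p_i = x_i' beta + u_{h(i)}`, `u_h ~ N(0, sigma_u^2)`,
with `x_i` = standardized age, sex and 29 comorbidity flags. Fitted by
Laplace-approximated ML via `lme4::glmer` (the conventional tool for
this model class).

**GBT.** Gradient-boosted trees (`xgboost`) on binary code indicators
(1 if the code appears in the record) plus age and sex. The learning
rate is a deliberately conservative 0.0002, so the round budget must be
large; the default cap is 20,000 rounds with early stopping on
validation log-loss.

**FFNN.** A feed-forward network on the same dummy features: two relu
hidden layers (widths 1,024 and 256 by default), one dropout layer
(rate 0.3), and a 2-unit softmax trained with categorical
cross-entropy and ADAM at learning rate 0.0002, early-stopped on
validation loss. Implemented in compiled code (RcppArmadillo) with a
sparse input layer.

**ME-DS.** The medical-code-embedding deep set. Codes are first
embedded unsupervised: presence of two codes in the same admission
record is a co-occurrence, and GloVe minimizes

    J = sum_{X_ij > 0} f(X_ij) (w_i' wc_j + b_i + bc_j - log X_ij)^2,
    f(x) = min(1, (x / x_max)^alpha)

over the nonzero co-occurrence counts (AdaGrad SGD; canonical
`x_max = 100`, `alpha = 0.75`; the embedding of a code is `w + wc`).
Diagnosis codes get 200-dimensional vectors and procedure codes
50-dimensional ones by default. The classifier is permutation-invariant
by construction: each secondary-diagnosis embedding passes through a
shared encoder phi, the encoded set is sum-pooled, and a post-pool map
rho produces the set representation (likewise for procedures); the
head combines [principal-diagnosis embedding, pooled dx, pooled proc, a
learned 1-d hospital embedding, age, sex] through one relu layer with
dropout into a 2-unit softmax, trained exactly like the FFNN.
Embeddings stay frozen during supervised training (`pretrained`
semantics); sum pooling (not mean) is used deliberately because set
cardinality is itself predictive — readmitted patients carry more
codes. An empty code set pools to a zero vector.

Design choices the source methods left open, resolved here: one joint
co-occurrence count feeds two separate GloVe fits on the dx–dx and
proc–proc blocks (the different target dimensions make a joint fit
awkward; cross-type counts remain available in the joint matrix);
counting is presence-based with no distance weighting, because records
are unordered sets; embeddings are trained on the train+validation
records only, never the test split; phi, rho and the head use one
hidden layer of width 64 each (the widths are configurable; only the
FFNN widths were pinned by the reference description); age enters all
models z-scored.

## Risk standardization

The *predictive margin* of hospital `h` is the average predicted
probability if **every** cohort record had been admitted to `h`: the
model's hospital effect (random intercept for HLR, 1-d embedding for
ME-DS) is forced to `h` for all records and predictions are averaged.
Models without a hospital effect (GBT, FFNN) do not support margins and
say so. The traditional comparator, `ratio_rsrr()`, is the CMS-style
predicted-over-expected ratio times the overall unadjusted rate; on
HLR the two methods agree to rank correlation > 0.99 in our synthetic
experiments, matching the qualitative claim that the approaches give
similar results.

Hospitals are then ranked (highest RSRR first — "top 20%" means the
worst readmission rates; the direction is a flag) and split 20/60/20:
top and bottom groups take `floor(0.2 N)` hospitals each, the middle
takes the remainder. This is the only rounding convention consistent
with the published margins for cohorts of 1,118, 1,708 and 1,919
hospitals (223/672/223, 341/1026/341, 383/1153/383). Reclassification
between two models is a 3x3 cross-tabulation whose off-diagonal cells
are reported as counts and half-up one-decimal percentages of all
hospitals.

## The synthetic claims generator

Real all-payer readmission data are restricted-access, so the package
ships a generator whose defaults emulate the documented statistical
structure of such data, and those defaults are the package's study
conditions:

- **Hospitals**: log-normal volumes; log-odds intercepts
  `u_h ~ N(0, sigma_hospital^2)`, default `sigma_hospital = 0.3`.
- **Code prevalence**: power law `rank^-1.3` rescaled so the top
  diagnosis code reaches 75% prevalence — mirroring a most-frequent
  code near 75% with three quarters of codes below 0.02%.
- **Cohort profiles** (AMI/HF/PNA) set age mean/SD (66.8/13.7,
  72.5/14.2, 69.2/16.8), female fraction (0.376, 0.489, 0.518),
  secondary-diagnosis count moments (negative binomial with mean/SD
  12.4/6.1, 15.1/5.5, 12.7/5.8, truncated at 29) and procedure count
  moments (5.6/3.3, 1.1/1.9, 0.7/1.5, truncated at 15).
- **Cluster structure**: codes are partitioned round-robin into 20
  latent disease clusters; each record activates 1–2 clusters and
  samples codes with an 8-fold weight tilt toward them, which gives the
  co-occurrence matrix a recoverable block structure (the synthetic
  analog of real diagnosis codes clustering by disease family).
- **Outcome model**:
  `logit p = beta0 + 0.25 z_age + 0.15 female + sum(code effects) +
  sum(interactions) + u_h`. Per-code effects are marginally
  `N(0, 0.3^2)` but decomposed as cluster mean + code noise with 75% of
  the variance shared within cluster, then prevalence-centered per
  universe. Interactions are 200 within-cluster pairs of magnitude 0.5
  whose sign is drawn once per cluster, so disease families compound
  risk coherently. This cluster-level structure is exactly what
  co-occurrence embeddings can recover and what dummy coding cannot
  express for rare codes; it is the mechanism that lets the nonlinear
  models, and the embedding model in particular, win downstream.
- **Intercept calibration**: with `beta0 = NULL` (default) the
  intercept is solved at generation time so the marginal readmission
  rate hits the profile target (12.0% AMI, 17.7% HF, 14.3% PNA). A
  fixed intercept cannot achieve this across universes because the
  realized interaction load varies between seeds; an explicit `beta0`
  bypasses calibration (useful for exact intercept-only checks).
- **Exclusion machinery**: configurable rates for in-hospital death,
  discharge against medical advice, transfer, zero length of stay,
  December discharge (no 30-day follow-up window) and under-18
  records; 10% of patients receive 2–4 admissions to exercise
  first-admission selection; 5% of readmissions are flagged planned,
  standing in for the full planned-readmission algorithm, which is out
  of scope. The analysis outcome is `readmit_30d & !planned_readmit`.

What the generator does **not** emulate: survey weights, payer and
state variables, true ICD-9 code semantics, calendar time (months are
categorical; "December" is the no-follow-up proxy), correlated
exclusion flags, or hospital-level case-mix differences beyond the
random intercept. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that the modelled mechanism behaves
as described under these conditions — not that any particular AUC
value would be attained on real claims.

## Numerical and procedural choices

- Exclusions are applied as a cascade in the listed order, each rule to
  the survivors of the previous one; the log records per-rule removals
  and conserves counts.
- Rare-code filtering counts presence once per record over the full raw
  table and needs >= 10 occurrences; it removes codes from records,
  never records.
- Splits are within-hospital largest-remainder allocations of
  80/10/10, so per-hospital deviations are below one record.
- GloVe uses AdaGrad (accumulators initialized at 1) at base step 0.05;
  each unordered pair is visited in both orientations per epoch;
  non-finite loss aborts with the learning rate named.
- The networks train in double precision with minibatches of 256,
  Glorot initialization, inverted dropout (inference is deterministic),
  early stopping on validation loss (patience 5 by default), and a
  seeded RNG so refits reproduce bit-for-bit.
- AUC is the Mann–Whitney statistic with half credit for ties (dummy
  models produce tied scores). Cross-validated intervals use
  `mean ± 1.96 sd/sqrt(k)` over hospital-stratified folds.
- Ties in hospital ranking break by hospital id, stably.

## Desk-scale problem sizes

`experiment_config()` defaults define the packaged experiment: ~55,000
generated admissions across 300 hospitals (cohort ~40,000 after
exclusions), a 1,500 + 500 code universe, 50-d diagnosis / 25-d
procedure embeddings, FFNN widths 256/64, GBT capped at 20,000 rounds,
and five seeded replicates of the stochastic trainers. These sizes keep
the full four-model comparison within minutes on one CPU while
preserving every qualitative property of the full-scale configuration;
the package defaults for the individual model fitters keep the
reference values (200/50-d embeddings, 1,024/256 widths). Replicates
vary network initialization, batch order and dropout; the data, split
and embeddings are held fixed within one experiment, and the HLR and
GBT fits are deterministic given the data, so they are fitted once.
The elderly sensitivity analysis (age >= 65) is exposed as
`run_experiment(..., age_min = 65)` and reported alongside the main
run without asserting numeric claims.

## Known limitations

- The embedding model's advantage over the dummy-feature networks is a
  mean-over-replicates property of the stated generator conditions; on
  individual universes the gap can fall within replicate noise.
- The hospital embedding of the deep set is 1-dimensional by design;
  hospitals outside the training set have no embedding and cannot be
  forced.
- `ratio_rsrr()` is defined for the hierarchical model only.
- The comorbidity map shipped for synthetic codes is a simplified
  cluster-based stand-in; real Elixhauser tables can be supplied as a
  two-column data frame.
- No bootstrap intervals on RSRRs, no calibration metrics, and no
  net-reclassification index beyond the cross-tabulation.

## A worked run

```{r}
library(readmitr)

cfg <- experiment_config(gen = generator_config(seed = 1), seed = 1)
report <- run_experiment(cfg)
report
autoplot(report)
plot_rsrr_distribution(report$rsrr)
write_experiment_report(report, "results/experiment")
```
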