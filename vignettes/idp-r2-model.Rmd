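---
title: "Predicting backbone amide R2 of disordered proteins from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting backbone amide R2 of disordered proteins from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpr2)
```

## The model and its assumptions

Backbone amide ¹⁵N transverse relaxation rates (R2) of intrinsically
disordered proteins report on dynamics in the tens-of-ns to µs window and
vary along the sequence far more strongly than R1 or NOE.  The premise of
this package is that most of that variation is coded by the *local*
sequence: transient contact clusters form among residues within a dozen or
so positions of each other, and the amino acids most active in such
clusters (aromatics, Arg, Ile/Leu) raise R2 locally while flexible or
short-polar residues (Gly, Ser, Asn, Asp, Thr) lower it.

The model makes this quantitative with a multiplicative form: the R2 of
residue $n$ in a chain of $N$ residues is

$$R_2(n) = \Upsilon \prod_{i=1}^{N} f(i;n), \qquad
  f(i;n) = 1 + \frac{q(\mathrm{aa}_i) - 1}{1 + b\,s^2}, \qquad s = |i - n|.$$

Each amino-acid type carries one positive propensity $q$; $q>1$ residues
raise the R2 of their neighborhood, $q<1$ residues lower it, and $q=1$ is
neutral.  The Lorentzian attenuation with coefficient $b$ decays the
influence of a neighbor with sequence distance; its **correlation length**
$L_\mathrm{corr} = b^{-1/2}$ is the distance at which the contributing
factor is midway between its value at $s=0$ (the full $q$) and at
$s\to\infty$ (1).  The product runs over *all* residues including the self
term ($s=0$, factor $q$ itself); no distance cutoff is applied, because
remote factors are within floating-point noise of 1 and chain lengths of
interest (tens to a few hundred residues) make the exact product cheap.
Terminal residues have fewer near neighbors, which yields the
characteristic falloff of R2 at both chain ends without any extra
mechanism — note that an expression tag changes this, so input sequences
are used verbatim, tags included.

The per-protein scale $\Upsilon$ (s⁻¹) is a deliberate confound sink:
temperature, magnetic field and viscosity all rescale R2 roughly uniformly
along the sequence, so datasets acquired under different conditions can be
mixed once each protein carries its own scale.  Everything the model
learns is profile *shape*.

A Gaussian alternative kernel $f = 1 + (q-1)e^{-b s^2}$ is available
behind `kernel = "gaussian"` in `model_params()`; the Lorentzian's slower
tail generally fits relaxation data better and is the default.  The
midpoint identity above is specific to the Lorentzian.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `q` (20 values) | — | trained; 1 = neutral | per-amino-acid slow-dynamics propensity |
| `b` | — | trained; `Lcorr = 5` at start | Lorentzian distance coefficient |
| `scale` ($\Upsilon$) | s⁻¹ | trained / `fit_scale()` | per-protein uniform scale |
| `cutoff` | — | 0.99 | helix-propensity filter for the boost |
| `min_length` | residues | 12 | helix run length required for the boost |
| `alpha` | — | 0.5 | boost amplitude: factor $1+\alpha\,p_\mathrm{Hlx}$ |

Pro has a trainable $q$ — Pro residues *do* act on their neighbors — but
Pro positions themselves are excluded from every residual, RMSE and
pooled statistic, because the missing backbone amide proton depresses
their measured R2 for chemical rather than dynamical reasons.  Predicted
values at Pro positions are still reported, flagged by the profile mask.

## Training, baselines, cross-validation

`train_model()` minimizes the sum over proteins of the mean squared error
over masked-in residues, so each protein carries equal weight regardless
of length.  The optimizer is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) over the 21 global parameters plus one scale per
protein, with an analytic Jacobian computed alongside the forward pass
(the log-product form makes both cheap: one $N\times N$ weight matrix per
protein).  Numerical choices:

* all parameters bounded below by a positivity floor of $10^{-6}$;
* initialization at the flat model — every $q=1$, $b$ such that
  $L_\mathrm{corr}=5$, each $\Upsilon$ at the protein's mean measured R2 —
  so optimization starts from the null model and adds structure;
* convergence tolerances (`ftol`, `ptol`, `gtol`) of $10^{-10}$, at most
  1024 iterations; non-convergence is flagged in the result, not thrown;
* the fit is deterministic given data and start; no stochastic restarts.

Two baselines calibrate any reported accuracy.  The **null model**
predicts each protein's mean everywhere; its RMSE *is* the standard
deviation of the measured values, which is why all standard deviations in
this package use the population (divide-by-$n$) convention — the identity
is then exact to machine precision, and it pins the upper bound of useful
RMSE.  The **one-residue model** assigns each residue its amino-acid mean
scaled R2 (msR2, pooled over residues across the training set after
dividing each protein by its mean) and refits a scale; it is exactly the
$L_\mathrm{corr}=0$ special case of the full model with $q$ set to msR2,
and `sweep_fixed_lcorr()` at 0 — implemented as the exact self-factor-only
model via $b=\infty$, never a large finite $b$ — reproduces its RMSE to
within optimizer tolerance.

Cross-validation: `loocv()` retrains without each protein in turn; the
held-out protein's scale cannot come from training, so it is refit with
the closed-form least-squares scale `fit_scale()` before scoring — the
only definition under which held-out RMSE is well defined.  `kfold_cv()`
partitions the proteins (seeded), returns per-fold parameter estimates
with mean ± sd, and `q_ttest()` runs Welch's two-sample t-test on a pair
of amino acids' fold estimates.  A caveat the tests document: fold
estimates share most of their training data, so they are far from
independent and the t-test is anti-conservative for truly equal
propensities — treat small p-values as suggestive ordering, not
calibrated error rates.

## The helix boost

Local coupling within $L_\mathrm{corr}\approx 5{-}6$ residues cannot
represent a stable helix of 12+ residues, which tumbles as a unit and
relaxes faster than the local model predicts.  The correction multiplies
the profile by $1 + \alpha\,p_\mathrm{Hlx}(n)$ — per-residue scores, not a
segment average — exactly inside helix predictions that survive a strict
filter: per-residue helix propensity (e.g. the helix column of a PsiPred
ss2 file, read by `read_ss2()`) at least 0.99 over at least 12 consecutive
residues.  The strict filter exists because secondary-structure predictors
are trained on folded proteins and overcall helices in IDPs; transient
short helices need no correction, as the base model already captures their
moderate R2 elevation.

## The synthetic-data generator

`generate_dataset()` emulates the statistical shape of a curated IDP R2
collection: by default 20 proteins of 80–150 residues, i.i.d. sequences
(uniform composition, or the documented `disorder_composition()` preset
with 5% Pro), per-protein scales drawn uniformly from 0.8–2.0 s⁻¹ (the
range most real uniform scale factors fall in), additive Gaussian noise of
0.3 s⁻¹ — a typical measurement-scale uncertainty — clipped from below at
0.05 s⁻¹ to keep rates physical, and the reference propensity ladder
`default_true_params()` (aromatics/Arg/branched aliphatics high, Gly and
short-polar residues low, $b = 3.164\times10^{-2}$).  The generating
truth travels with the dataset, so parameter recovery is exactly testable.

What the generator does **not** emulate — and therefore what passing
recovery tests do *not* show about real data: correlated residuals,
tertiary-contact or exchange contributions to R2, non-i.i.d. sequence
composition (real IDPs have compositional blocks), heteroscedastic
measurement error, and helical segments (synthetic data never triggers
the boost path; that path is tested on constructed score tracks).  On
model-consistent data the trainer recovers the generating parameters to
machine precision in the noiseless case; real-data accuracy is instead
bounded by model misspecification, which no synthetic test can measure.

## Degenerate inputs and ties

Single-residue sequences reduce to the self factor; a single-protein
training set warns (parameters are then heavily under-determined — a
sequence model trained on one protein can reproduce essentially any
profile and predicts nothing); amino acids absent from a training set
fall back to the global mean msR2 in the one-residue baseline (with a
message); `X` in a sequence is always an error, while other nonstandard
letters can be remapped through an explicit alias table (e.g. methylated
Cys scored as Ala).  Helix segments are maximal runs; a single
below-cutoff score splits a run and each fragment must requalify on
length.

## Problem sizes in the shipped tests

The test-suite and the reproduction script use 20 proteins of 80–150
residues for recovery/cross-validation properties and 5–10 proteins of
30–80 residues for unit-level trainer checks; these sizes were chosen to
match the dataset scale the model is meant for while keeping every
property cheap to verify.  The bundled benchmark summary
(`read_benchmark_summary()`) carries per-protein aggregate statistics for
a published 45-protein training and 9-protein test collection;
residue-level data for those proteins are not redistributed, so published
trained parameter values (e.g. individual $q$'s) are not reproduced here —
the training machinery is validated by synthetic-parameter recovery
instead, and the benchmark table supports dataset-level aggregate checks
only.
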