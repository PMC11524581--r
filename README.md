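# idpr2

Sequence-based prediction of per-residue backbone amide transverse
relaxation rates (R2) for intrinsically disordered proteins (IDPs).

## The problem

Backbone ¹⁵N R2 is the NMR relaxation observable most sensitive to the
slow (tens of ns to µs) local dynamics of disordered chains, and the one
with the strongest sequence dependence: aromatic, Arg and long branched
aliphatic residues form transient local contact clusters that slow
dynamics and raise R2, while Gly and short-polar residues interrupt them.
`idpr2` is for NMR spectroscopists and biophysicists who want a
quantitative per-residue R2 profile from sequence alone — to plan or
interpret relaxation experiments, flag residues whose measured R2 exceeds
the local-sequence expectation (candidate tertiary contacts or exchange),
or score sequence propensities related to phase separation.

## The model

The predicted rate of residue *n* in a chain of *N* residues is a product
of contributions from every residue *i*:

    R2(n) = Υ · Π_{i=1..N} f(i; n),      f(i; n) = 1 + (q(aa_i) − 1) / (1 + b·s²)

with *s* = |i − n| the sequence distance.  There are 21 global
parameters: a propensity factor `q` per amino-acid type (q > 1 raises the
R2 of its neighborhood, q < 1 lowers it) and the Lorentzian distance
coefficient `b`, whose correlation length `Lcorr = b^(−1/2)` is the
distance at which a neighbor's influence has decayed halfway.  One
uniform scale factor Υ (s⁻¹) per protein absorbs temperature, field and
viscosity.  Terminal residues have fewer neighbors, which reproduces the
characteristic falloff of R2 at chain ends.  Stable long helices tumble
more slowly than local coupling implies, so profiles can be corrected by
a boost factor `1 + α·pHlx(n)` inside helix predictions that survive a
strict filter (helix propensity ≥ 0.99 over ≥ 12 consecutive residues;
α = 0.5 by default).

Training minimizes the sum over proteins of the mean squared error over
scoreable residues (Pro and unobserved positions excluded) with all
parameters bounded positive, via bounded Levenberg–Marquardt least
squares with an analytic Jacobian.  Baselines (null model, one-residue
model), leave-one-out and k-fold cross-validation, and a fixed-`Lcorr`
sweep are included, as is a synthetic-data generator with known ground
truth that exercises the whole pipeline.

## Worked example

```r
library(idpr2)

# forward prediction with the package's reference parameter ladder
p <- default_true_params()
sq <- "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVAT"
prof <- predict_r2(sq, p, scale = 1.5)
round(prof$values[1:10], 3)
#> [1] 1.562 1.567 1.569 1.561 1.537 1.497 1.448 1.399 1.352 1.304
```

The profile rises where high-q residues cluster and falls off toward the
termini; values are in s⁻¹ after the Υ = 1.5 s⁻¹ scale.

```r
# train on a synthetic dataset with known generating parameters
ds  <- generate_dataset(synthetic_spec(n_proteins = 8,
                                       length_range = c(60, 90),
                                       noise_sd = 0.3, seed = 42))
fit <- train_model(ds)
fit
#> Model fit over 8 proteins
#>   cost = 0.651093  mean RMSE = 0.2847 s^-1
#>   b = 0.030039  Lcorr = 5.77  converged: TRUE ( 10 iterations )
round(fit$params$q[c("W", "G")], 3)
#>     W     G
#> 1.327 0.820     # generating values: 1.35 and 0.80
round(loocv(ds)$mean_rmse_heldout, 3)
#> [1] 0.317       # held-out error near the 0.3 s^-1 noise floor
```

The in-sample mean RMSE (0.28 s⁻¹) and held-out LOOCV RMSE (0.32 s⁻¹)
bracket the injected noise, and the recovered propensities track the
generating ladder.

A command-line front end ships in `inst/cli/idpr2` with subcommands
`predict`, `train`, `crossval`, `sweep`, `synth` and `summary`; it is a
thin wrapper over `cli_main()`.

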