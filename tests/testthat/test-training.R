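test_that("objective is zero at the generating truth and rises when perturbed", {
  ds <- tiny_dataset()
  truth <- attr(ds, "true_params")
  scales <- attr(ds, "true_scales")
  expect_equal(objective(truth, scales, ds), 0)
  # order invariance
  expect_equal(objective(truth, scales, rev(ds)), 0)
  # perturbing any single q strictly increases the cost on noiseless data
  for (aa in c("G", "W", "S")) {
    q2 <- truth$q
    q2[aa] <- q2[aa] + 0.05
    expect_gt(objective(model_params(q2, truth$b), scales, ds), 0)
  }
  expect_gt(objective(model_params(truth$q, truth$b * 1.2), scales, ds), 0)
})

test_that("fit_scale is the closed-form least-squares scale", {
  u <- c(1, 2, 3, 4)
  expect_equal(fit_scale(u, 2.5 * u), 2.5)
  expect_equal(fit_scale(c(1, 1), c(3, 5)), 4)
  # residuals orthogonal to the profile on masked-in positions
  set.seed(2)
  u2 <- runif(30, 0.5, 2)
  m2 <- 1.4 * u2 + rnorm(30, sd = 0.2)
  mask <- runif(30) > 0.2
  sc <- fit_scale(u2, m2, mask)
  expect_equal(sum((m2 - sc * u2)[mask] * u2[mask]), 0, tolerance = 1e-10)
  expect_error(fit_scale(rep(0, 3), 1:3), "degenerate")
  expect_error(fit_scale(1:3, 1:3, rep(FALSE, 3)), "masked")
})

test_that("training recovers generating parameters from noiseless data", {
  ds <- tiny_dataset(n_proteins = 8, len = c(40, 70), seed = 21)
  truth <- attr(ds, "true_params")
  fit <- train_model(ds)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$q - truth$q)), 1e-6)
  expect_lt(abs(fit$params$b - truth$b), 1e-7)
  expect_equal(unname(fit$scales), unname(attr(ds, "true_scales")),
               tolerance = 1e-6)
  expect_lt(fit$cost, 1e-12)
  # stationarity: refitting from the optimum does not move the cost
  refit <- train_model(ds, init = list(params = fit$params,
                                       scales = fit$scales))
  expect_lt(abs(refit$cost - fit$cost), 1e-10)
  # reported cost equals the sum of per-protein masked MSEs
  expect_equal(fit$cost, objective(fit$params, fit$scales, ds),
               tolerance = 1e-12)
})

test_that("uniform rescaling of all measurements leaves q and b fixed, scales the Upsilons", {
  ds <- tiny_dataset(seed = 31)
  fit1 <- train_model(ds)
  ds2 <- lapply(ds, apply_uniform_scaling, factor = 2)
  fit2 <- train_model(ds2)
  expect_equal(fit2$params$q, fit1$params$q, tolerance = 1e-6)
  expect_equal(fit2$params$b, fit1$params$b, tolerance = 1e-7)
  expect_equal(unname(fit2$scales), 2 * unname(fit1$scales),
               tolerance = 1e-6)
})

test_that("determinism: identical inputs yield bit-identical fits", {
  ds <- tiny_dataset(seed = 41)
  fit1 <- train_model(ds)
  fit2 <- train_model(ds)
  expect_identical(fit1$params$q, fit2$params$q)
  expect_identical(fit1$params$b, fit2$params$b)
  expect_identical(fit1$scales, fit2$scales)
})

test_that("null model RMSE equals sigma(R2) per protein", {
  ds <- tiny_dataset(noise = 0.3, seed = 51)
  nm <- null_model_eval(ds)
  for (rec in ds) {
    expect_equal(nm$per_protein_rmse[[rec$id]], protein_stats(rec)$sd_r2)
  }
  expect_equal(nm$mean_rmse, mean(nm$per_protein_rmse))
  one <- null_model_eval(ds[1])
  expect_equal(one$mean_rmse, protein_stats(ds[[1]])$sd_r2)
})

test_that("one-residue baseline behaves as the zero-correlation-length special case", {
  ds <- tiny_dataset(noise = 0.2, seed = 61)
  # homopolymer evaluation protein: no shape, so RMSE equals sigma
  hp <- protein_record("hp", strrep("G", 40),
                       measured_r2 = runif(40, 2, 5))
  one <- one_residue_model(ds, list(hp))
  expect_equal(one$per_protein_rmse[["hp"]], protein_stats(hp)$sd_r2)
  # full model with b -> Inf and q set to msR2 gives the same predictions
  pool <- pooled_msr2(ds)
  stopifnot(length(pool$msr2) == 19)  # P never pooled
  q <- c(pool$msr2, P = 1)[AA]
  p_inf <- model_params(setNames(q, AA), Inf)
  base <- one_residue_model(ds, ds)
  for (rec in ds[1:3]) {
    u <- predict_r2_unscaled(rec$sequence, p_inf)
    sc <- fit_scale(u, rec$measured_r2, rec$mask)
    expect_equal(rmse(sc * u, rec$measured_r2, rec$mask),
                 base$per_protein_rmse[[rec$id]], tolerance = 1e-12)
  }
  # RMSE scales linearly under uniform rescaling of the eval data
  ds2 <- lapply(ds, apply_uniform_scaling, factor = 3)
  base2 <- one_residue_model(ds, ds2)
  expect_equal(unname(base2$per_protein_rmse),
               3 * unname(base$per_protein_rmse), tolerance = 1e-10)
})

test_that("training on a single protein warns but proceeds", {
  ds <- tiny_dataset(n_proteins = 2, seed = 71)
  expect_warning(fit <- train_model(ds[1]), "single protein")
  # a single-protein fit can reproduce that protein's profile shape
  expect_lt(fit$per_protein_rmse[[1]], 0.05)
})

test_that("trainer accepts a fixed distance coefficient", {
  ds <- tiny_dataset(seed = 81)
  truth <- attr(ds, "true_params")
  fit <- train_model(ds, fixed_b = truth$b)
  expect_equal(fit$params$b, truth$b)
  expect_lt(max(abs(fit$params$q - truth$q)), 1e-6)
})
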