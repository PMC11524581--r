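#' Leave-one-out cross-validation
#'
#' Each protein in turn is held out; the model is trained on the remaining
#' proteins, the held-out protein receives a fresh least-squares scale
#' factor via [fit_scale()] (its scale cannot come from a training fold it
#' never joined), and the held-out RMSE is recorded.
#'
#' @param records list of [protein_record()]s with measured data (>= 2).
#' @param ... further arguments passed to [train_model()].
#' @return a `crossval_report`: list with `per_protein_rmse_heldout`
#'   (named), `mean_rmse_heldout`, `fold_params` (one [model_params()] per
#'   fold), `heldout_scales`, and `diagnostics` (per-fold convergence).
#' @export
loocv <- function(records, ...) {
  n <- length(records)
  if (n < 2L) stop("leave-one-out needs at least 2 proteins")
  ids <- vapply(records, `[[`, "", "id")
  out <- numeric(n)
  scales <- numeric(n)
  fold_params <- vector("list", n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    fit <- train_model(records[-i], ...)
    rec <- records[[i]]
    u <- predict_r2_unscaled(rec$sequence, fit$params)
    sc <- fit_scale(u, rec$measured_r2, rec$mask)
    out[i] <- rmse(sc * u, rec$measured_r2, rec$mask)
    scales[i] <- sc
    fold_params[[i]] <- fit$params
    conv[i] <- fit$converged
  }
  structure(list(per_protein_rmse_heldout = setNames(out, ids),
                 mean_rmse_heldout = mean(out),
                 fold_params = fold_params,
                 heldout_scales = setNames(scales, ids),
                 diagnostics = data.frame(id = ids, converged = conv)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Cross-validation over", length(x$per_protein_rmse_heldout),
      "held-out evaluations\n")
  cat("  mean held-out RMSE =", format(x$mean_rmse_heldout, digits = 4),
      "s^-1\n")
  if (!is.null(x$param_mean_sd)) {
    cat("  per-parameter spread over", length(x$fold_params), "folds available\n")
  }
  invisible(x)
}

#' k-fold cross-validation with parameter spread
#'
#' Partitions the proteins into k folds (seeded, so reproducible), trains on
#' each complement, and reports held-out RMSEs plus the k independent
#' estimates of every global parameter with their mean and standard
#' deviation.  Use [q_ttest()] on the result to ask whether two amino
#' acids' propensities differ significantly.
#'
#' @param records list of [protein_record()]s (>= k).
#' @param k number of folds (>= 2; `k = length(records)` reduces to
#'   leave-one-out folds).
#' @param seed integer seed for the fold assignment.
#' @param ... further arguments passed to [train_model()].
#' @return a `crossval_report` with the [loocv()] fields plus `folds`
#'   (assignment), `fold_params`, `param_mean_sd` (data.frame with one row
#'   per global parameter), and `fold_q` (k x 20 matrix).
#' @export
kfold_cv <- function(records, k = 5L, seed = 1L, ...) {
  n <- length(records)
  if (k < 2L || k > n) stop("k must be between 2 and the number of proteins")
  ids <- vapply(records, `[[`, "", "id")
  fold_of <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  })
  out <- numeric(n)
  scales <- numeric(n)
  fold_params <- vector("list", k)
  conv <- logical(k)
  for (f in seq_len(k)) {
    hold <- which(fold_of == f)
    fit <- train_model(records[-hold], ...)
    fold_params[[f]] <- fit$params
    conv[f] <- fit$converged
    for (i in hold) {
      rec <- records[[i]]
      u <- predict_r2_unscaled(rec$sequence, fit$params)
      sc <- fit_scale(u, rec$measured_r2, rec$mask)
      out[i] <- rmse(sc * u, rec$measured_r2, rec$mask)
      scales[i] <- sc
    }
  }
  fold_q <- do.call(rbind, lapply(fold_params, function(p) p$q))
  fold_b <- vapply(fold_params, function(p) p$b, 0)
  pm <- data.frame(
    parameter = c(AA20, "b"),
    mean = c(colMeans(fold_q), mean(fold_b)),
    sd = c(apply(fold_q, 2, sd), sd(fold_b))
  )
  structure(list(per_protein_rmse_heldout = setNames(out, ids),
                 mean_rmse_heldout = mean(out),
                 fold_params = fold_params,
                 heldout_scales = setNames(scales, ids),
                 folds = setNames(fold_of, ids),
                 fold_q = fold_q,
                 param_mean_sd = pm,
                 diagnostics = data.frame(fold = seq_len(k), converged = conv)),
            class = "crossval_report")
}

#' Compare two amino acids' propensities across folds
#'
#' Welch's two-sample t-test on the per-fold estimates of q for two amino
#' acids, answering whether their difference is statistically significant
#' given the fold-to-fold spread.
#'
#' @param report a `crossval_report` from [kfold_cv()].
#' @param aa1,aa2 one-letter amino-acid codes.
#' @return the `htest` object from [stats::t.test()].
#' @export
q_ttest <- function(report, aa1, aa2) {
  if (is.null(report$fold_q)) stop("report carries no per-fold q estimates")
  stopifnot(aa1 %in% AA20, aa2 %in% AA20)
  t.test(report$fold_q[, aa1], report$fold_q[, aa2])
}

#' Retrain with the correlation length fixed along a grid
#'
#' For each requested correlation length the distance coefficient is pinned
#' at `Lcorr^-2` (with `Lcorr = 0` handled as the exact self-factor-only
#' model) and all remaining parameters are retrained; the mean in-sample
#' RMSE traces how prediction accuracy depends on the coupling range.
#'
#' @param records list of [protein_record()]s with measured data.
#' @param lcorr_values non-negative correlation lengths in residues.
#' @param ... further arguments passed to [train_model()].
#' @return data.frame with columns `lcorr`, `b`, `mean_rmse`, `converged`.
#' @export
sweep_fixed_lcorr <- function(records, lcorr_values = 0:10, ...) {
  if (any(lcorr_values < 0)) stop("correlation lengths must be non-negative")
  rows <- lapply(lcorr_values, function(L) {
    b <- if (L == 0) Inf else L^-2
    fit <- train_model(records, fixed_b = b, ...)
    data.frame(lcorr = L, b = b, mean_rmse = mean(fit$per_protein_rmse),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
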