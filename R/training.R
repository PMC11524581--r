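#' Training objective: sum of per-protein mean squared errors
#'
#' Each protein contributes the mean, over its masked-in residues, of the
#' squared difference between its scaled prediction and its measurement, so
#' every protein carries equal weight regardless of length.  Pro and
#' unobserved positions never enter.
#'
#' @param params a [model_params()] object.
#' @param scales named numeric vector of positive per-protein scale factors,
#'   names matching record ids.
#' @param records list of [protein_record()]s with measured data.
#' @return non-negative cost (s^-2).
#' @export
objective <- function(params, scales, records) {
  stopifnot(inherits(params, "model_params"))
  cost <- 0
  for (rec in records) {
    if (!any(rec$mask)) stop("record '", rec$id, "' has no masked-in residues")
    sc <- scales[[rec$id]]
    if (is.null(sc) || is.na(sc) || sc <= 0) {
      stop("missing or non-positive scale for '", rec$id, "'")
    }
    pred <- sc * predict_r2_unscaled(rec$sequence, params)
    cost <- cost + mean((pred[rec$mask] - rec$measured_r2[rec$mask])^2)
  }
  cost
}

#' Closed-form least-squares scale factor
#'
#' For a fixed profile shape, the scale minimizing the masked squared error
#' against measurements is `sum(m * u) / sum(u^2)` over masked-in positions
#' (the normal equation of a one-parameter linear fit through the origin).
#' Used whenever a scale must be assigned to a protein that was not part of
#' training, e.g. held-out proteins in cross-validation.
#'
#' @param unscaled positive numeric vector, the model's unscaled profile.
#' @param measured numeric vector of measured rates, same length.
#' @param mask logical vector of positions to use.
#' @return scale factor in s^-1.
#' @export
fit_scale <- function(unscaled, measured, mask = rep(TRUE, length(measured))) {
  if (length(unscaled) != length(measured)) stop("length mismatch")
  if (!any(mask)) stop("no masked-in positions")
  u <- unscaled[mask]
  m <- measured[mask]
  denom <- sum(u^2)
  if (denom <= 0) stop("unscaled profile is degenerate (all zero)")
  sum(m * u) / denom
}

# assemble/unpack the free-parameter vector: q (20), optionally b, then
# one scale per protein
.pack <- function(q, b, scales, fit_b) {
  c(q, if (fit_b) b, scales)
}

#' Train the model by bounded nonlinear least squares
#'
#' Jointly fits the 20 amino-acid propensities q, the distance coefficient b
#' (unless held fixed) and one scale factor per protein, minimizing the sum
#' of per-protein mean squared errors with all parameters bounded below by a
#' small positive floor.  Uses the Levenberg-Marquardt implementation in
#' \pkg{minpack.lm} with an analytic Jacobian; the fit is deterministic
#' given the data and the starting point.
#'
#' Defaults start from the flat model: all q at 1, b at a correlation length
#' of 5 residues, and each protein's scale at its mean measured R2.
#'
#' @param records list of [protein_record()]s with measured data.
#' @param init optional list with components `params` (a [model_params()])
#'   and/or `scales` (named vector) overriding the default start.
#' @param fixed_b optional: hold b fixed at this value (use `Inf` for the
#'   exact self-factor-only model, i.e. correlation length 0).
#' @param lower positivity floor applied to every free parameter
#'   (default 1e-6).
#' @param ftol relative cost-decrease tolerance declaring convergence
#'   (default 1e-10; also used for the gradient test).
#' @param max_iter maximum optimizer iterations (default 1024, the most
#'   the backend accepts).
#' @param kernel distance kernel, see [model_params()].
#' @return a `fit_result`: list with `params`, `scales`, `per_protein_rmse`,
#'   `cost`, `converged`, `n_iter`, `message`.
#' @export
train_model <- function(records, init = NULL, fixed_b = NULL, lower = 1e-6,
                        ftol = 1e-10, max_iter = 1024L,
                        kernel = c("lorentzian", "gaussian")) {
  kernel <- match.arg(kernel)
  if (length(records) < 1L) stop("empty dataset")
  if (length(records) < 2L) {
    warning("training on a single protein: parameters will be ",
            "under-determined and biased to that profile")
  }
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  fit_b <- is.null(fixed_b)
  # precompute geometry and masked data once per protein
  geoms <- lapply(records, function(r) .sequence_geometry(r$aa))
  masks <- lapply(records, `[[`, "mask")
  meas <- lapply(records, function(r) r$measured_r2)
  for (i in seq_along(records)) {
    if (!any(masks[[i]])) stop("record '", ids[i], "' has no masked-in residues")
  }
  wts <- lapply(masks, function(m) 1 / sqrt(sum(m)))  # per-protein 1/sqrt(n)

  q0 <- setNames(rep(1, 20L), AA20)
  b0 <- if (fit_b) 1 / 25 else fixed_b
  s0 <- vapply(records, function(r) mean(r$measured_r2[r$mask]), 0)
  if (!is.null(init$params)) {
    q0 <- init$params$q
    if (fit_b) b0 <- init$params$b
  }
  if (!is.null(init$scales)) s0 <- unname(init$scales[ids])
  np <- length(records)

  residual_fn <- function(theta) {
    q <- setNames(theta[1:20], AA20)
    b <- if (fit_b) theta[21L] else fixed_b
    sc <- theta[(20L + fit_b + 1L):(20L + fit_b + np)]
    p <- model_params(q, b, kernel)
    unlist(lapply(seq_along(records), function(i) {
      pred <- exp(.predict_core(geoms[[i]], p)$logpred)
      wts[[i]] * (sc[i] * pred - meas[[i]])[masks[[i]]]
    }))
  }
  jacobian_fn <- function(theta) {
    q <- setNames(theta[1:20], AA20)
    b <- if (fit_b) theta[21L] else fixed_b
    sc <- theta[(20L + fit_b + 1L):(20L + fit_b + np)]
    p <- model_params(q, b, kernel)
    blocks <- lapply(seq_along(records), function(i) {
      core <- .predict_core(geoms[[i]], p, grad = TRUE)
      pred <- exp(core$logpred)
      m <- masks[[i]]
      w <- wts[[i]]
      spred <- sc[i] * pred[m]
      jq <- w * t(core$dq[, m, drop = FALSE] * rep(spred, each = 20L))
      jb <- if (fit_b) w * spred * core$db[m] else NULL
      jsc <- matrix(0, nrow = sum(m), ncol = np)
      jsc[, i] <- w * pred[m]
      cbind(jq, jb, jsc)
    })
    do.call(rbind, blocks)
  }

  theta0 <- pmax(.pack(unname(q0[AA20]), b0, s0, fit_b), lower)
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol,
                                     gtol = ftol,
                                     maxiter = min(max_iter, 1024L),
                                     maxfev = 100000L)
  fit <- minpack.lm::nls.lm(par = theta0, fn = residual_fn, jac = jacobian_fn,
                            lower = rep(lower, length(theta0)), control = ctrl)
  theta <- fit$par
  q <- setNames(theta[1:20], AA20)
  b <- if (fit_b) theta[21L] else fixed_b
  sc <- setNames(theta[(20L + fit_b + 1L):(20L + fit_b + np)], ids)
  params <- model_params(q, b, kernel)
  prmse <- setNames(vapply(seq_along(records), function(i) {
    pred <- sc[i] * exp(.predict_core(geoms[[i]], params)$logpred)
    rmse(pred, meas[[i]], masks[[i]])
  }, 0), ids)
  structure(list(params = params, scales = sc, per_protein_rmse = prmse,
                 cost = sum(prmse^2), converged = fit$info %in% 1:4,
                 n_iter = fit$niter, message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit over", length(x$scales), "proteins\n")
  cat("  cost =", format(x$cost, digits = 6),
      " mean RMSE =", format(mean(x$per_protein_rmse), digits = 4), "s^-1\n")
  cat("  b =", format(x$params$b, digits = 6),
      " Lcorr =", format(correlation_length(x$params$b), digits = 3),
      " converged:", x$converged, "(", x$n_iter, "iterations )\n")
  invisible(x)
}

#' Null-model evaluation
#'
#' The null model predicts each protein's mean measured R2 at every
#' position; its RMSE equals the population standard deviation of the
#' measured values, so this baseline needs no fitting.
#'
#' @param records list of [protein_record()]s with measured data.
#' @return list with `per_protein_rmse` (named) and `mean_rmse`.
#' @export
null_model_eval <- function(records) {
  r <- vapply(records, function(rec) protein_stats(rec)$sd_r2, 0)
  names(r) <- vapply(records, `[[`, "", "id")
  list(per_protein_rmse = r, mean_rmse = mean(r))
}

#' One-residue baseline
#'
#' Each residue is assigned the amino-acid mean scaled R2 (msR2) learned
#' from the training records, then one least-squares scale factor per
#' evaluation protein is applied.  Amino-acid types unseen in training fall
#' back to the global mean msR2 (with a message).  This baseline is the
#' zero-correlation-length special case of the full model with q set to
#' msR2.
#'
#' @param train_records records providing the pooled msR2.
#' @param eval_records records to score (may be the same list).
#' @return list with `per_protein_rmse` (named), `mean_rmse`, `msr2`,
#'   and `scales`.
#' @export
one_residue_model <- function(train_records, eval_records = train_records) {
  pool <- pooled_msr2(train_records)
  fallback <- mean(pool$msr2)
  out <- numeric(length(eval_records))
  scales <- numeric(length(eval_records))
  ids <- character(length(eval_records))
  for (i in seq_along(eval_records)) {
    rec <- eval_records[[i]]
    u <- pool$msr2[rec$aa]
    if (anyNA(u)) {
      miss <- unique(rec$aa[is.na(u)])
      message("one_residue_model: type(s) ", paste(miss, collapse = ","),
              " absent from training msR2; using global mean for '",
              rec$id, "'")
      u[is.na(u)] <- fallback
    }
    u <- unname(u)
    sc <- fit_scale(u, rec$measured_r2, rec$mask)
    out[i] <- rmse(sc * u, rec$measured_r2, rec$mask)
    scales[i] <- sc
    ids[i] <- rec$id
  }
  list(per_protein_rmse = setNames(out, ids), mean_rmse = mean(out),
       msr2 = pool$msr2, scales = setNames(scales, ids))
}
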