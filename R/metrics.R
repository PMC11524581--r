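#' Per-protein summary statistics of measured R2
#'
#' Mean and standard deviation of measured R2 over masked-in residues.  The
#' standard deviation uses the population convention (divide by n), which
#' makes it identical to the RMSE of the null model that predicts the
#' protein's mean at every position.
#'
#' @param record a [protein_record()] with measured data.
#' @return list with `mean_r2`, `sd_r2` (both s^-1) and `n_scored`.
#' @export
protein_stats <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  if (is.null(record$measured_r2)) stop("record has no measured R2 data")
  v <- record$measured_r2[record$mask]
  if (length(v) < 1L) stop("record '", record$id, "' has no masked-in residues")
  m <- mean(v)
  list(mean_r2 = m, sd_r2 = sqrt(mean((v - m)^2)), n_scored = length(v))
}

#' Root-mean-square error over masked-in positions
#'
#' @param predicted an [r2_profile()] or numeric vector of predictions.
#' @param measured numeric vector of measured rates, same length.
#' @param mask logical vector of positions to score.
#' @return RMSE in s^-1.
#' @export
rmse <- function(predicted, measured, mask = rep(TRUE, length(measured))) {
  pred <- if (inherits(predicted, "r2_profile")) predicted$values else predicted
  if (length(pred) != length(measured)) {
    stop("predicted and measured lengths differ (", length(pred), " vs ",
         length(measured), ")")
  }
  if (length(mask) != length(measured)) stop("mask length mismatch")
  if (!any(mask)) stop("no masked-in positions to score")
  sqrt(mean((pred[mask] - measured[mask])^2))
}

#' Scaled R2 profile of one protein
#'
#' Dividing each residue's measured R2 by the protein's mean R2 removes
#' uniform external factors (temperature, field strength, viscosity), making
#' profiles measured under different conditions comparable.  The masked-in
#' scaled values average to 1 by construction.
#'
#' @param record a [protein_record()] with measured data.
#' @return numeric vector of dimensionless scaled values (NA where
#'   unobserved).
#' @export
scaled_r2 <- function(record) {
  st <- protein_stats(record)
  if (st$mean_r2 <= 0) stop("mean R2 must be positive to scale")
  record$measured_r2 / st$mean_r2
}

#' Amino-acid mean scaled R2 over a dataset
#'
#' Pools the scaled R2 values of all masked-in residues across the dataset
#' and averages them per amino-acid type.  Pooling is over residues, not
#' over per-protein means, so longer proteins contribute more observations.
#' Amino acids with no masked-in occurrences are absent from the result.
#'
#' @param records list of [protein_record()]s with measured data.
#' @return list with `msr2` (named numeric, mean scaled R2 per amino acid)
#'   and `counts` (named integer, pooled residue counts).
#' @export
pooled_msr2 <- function(records) {
  if (length(records) < 1L) stop("dataset must contain at least one record")
  aa_all <- character(0)
  sr_all <- numeric(0)
  for (rec in records) {
    sr <- scaled_r2(rec)
    aa_all <- c(aa_all, rec$aa[rec$mask])
    sr_all <- c(sr_all, sr[rec$mask])
  }
  means <- tapply(sr_all, aa_all, mean)
  counts <- table(aa_all)
  aa <- intersect(AA20, names(means))
  list(msr2 = setNames(as.numeric(means[aa]), aa),
       counts = setNames(as.integer(counts[aa]), aa))
}

#' Aggregate statistics over the bundled benchmark summary
#'
#' Computes dataset-level summaries from a benchmark table of per-protein
#' statistics (mean R2, its standard deviation, and prediction RMSE for a
#' curated set of training and test IDPs): the mean sigma(R2) of the
#' training rows; how many training proteins fall in the typical disordered
#' mean-R2 window; how many have elevated mean R2 (low temperature,
#' glycerol, or residual structure); how many training/test proteins the
#' model predicts better than the null model; the test-set mean RMSE (using
#' the helix-boosted value where one exists); and the RMSE excess over
#' sigma(R2) for one named row.
#'
#' @param tbl benchmark data.frame as returned by
#'   [read_benchmark_summary()]; columns `name`, `set`, `mean_r2`, `sd_r2`,
#'   `rmse`, `rmse_boosted`.
#' @param typical_range mean-R2 window regarded as typical for IDPs
#'   (default 2.5--5.5 s^-1).
#' @param elevated_above mean-R2 threshold flagging externally or
#'   structurally elevated proteins (default 6.4 s^-1).
#' @param excess_row row name for the RMSE - sigma(R2) difference
#'   (default "Pdx1", the one test protein the model does not beat the null
#'   model on).
#' @return named list of the aggregate values.
#' @export
benchmark_aggregates <- function(tbl, typical_range = c(2.5, 5.5),
                                 elevated_above = 6.4, excess_row = "Pdx1") {
  need <- c("name", "set", "mean_r2", "sd_r2", "rmse")
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    stop("benchmark table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(tbl$set %in% c("train", "test"))) {
    stop("set column must be 'train' or 'test'")
  }
  tr <- tbl[tbl$set == "train", ]
  te <- tbl[tbl$set == "test", ]
  # prefer the helix-boosted RMSE where the table carries one
  best_rmse <- function(d) {
    r <- d$rmse
    if ("rmse_boosted" %in% names(d)) {
      hit <- !is.na(d$rmse_boosted)
      r[hit] <- d$rmse_boosted[hit]
    }
    r
  }
  ex <- tbl[tbl$name == excess_row, ]
  if (nrow(ex) != 1L) stop("row '", excess_row, "' not found (or duplicated)")
  list(
    n_train = nrow(tr),
    n_test = nrow(te),
    mean_train_sd = mean(tr$sd_r2),
    n_train_typical_mean = sum(tr$mean_r2 >= typical_range[1] &
                                 tr$mean_r2 <= typical_range[2]),
    n_train_elevated_mean = sum(tr$mean_r2 > elevated_above),
    n_train_beats_null = sum(tr$rmse < tr$sd_r2),
    mean_test_rmse = mean(best_rmse(te)),
    n_test_beats_null = sum(best_rmse(te) < te$sd_r2),
    excess = list(name = excess_row, rmse_minus_sd = ex$rmse - ex$sd_r2)
  )
}
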