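#' Contributing factor of a neighboring residue
#'
#' A residue of type with propensity `q_i` at sequence distance `s` from a
#' central residue multiplies that residue's R2 by
#' `1 + (q_i - 1)/(1 + b s^2)` (Lorentzian kernel).  At `s = 0` the factor is
#' `q_i` itself; it decays monotonically to 1 with distance, passing the
#' midpoint `(q_i + 1)/2` exactly at the correlation length `s = b^(-1/2)`.
#'
#' `s` is the absolute residue-index difference and is an integer in normal
#' use; real values are accepted so the midpoint identity can be evaluated
#' directly.
#'
#' @param q_i positive propensity factor of the contributing residue.
#' @param s non-negative sequence distance(s) in residues.
#' @param b positive distance coefficient; `Inf` gives the self-only limit.
#' @param kernel `"lorentzian"` (default) or `"gaussian"`.
#' @return contributing factor(s), same length as `s`.
#' @examples
#' contributing_factor(2, 3, 1)          # 1.1
#' contributing_factor(1.5, 0.03164^-0.5, 0.03164)  # midpoint 1.25
#' @export
contributing_factor <- function(q_i, s, b, kernel = c("lorentzian", "gaussian")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(q_i) || any(!is.finite(q_i)) || any(q_i <= 0)) {
    stop("q_i must be positive and finite")
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop("b must be a single positive number")
  }
  if (any(s < 0)) stop("sequence distance s must be non-negative")
  1 + (q_i - 1) * .kernel_weight(s, b, kernel)
}

# distance weight w(s) with w(0)=1, w(Inf)=0; b=Inf collapses to an
# indicator at s=0 for either kernel
.kernel_weight <- function(s, b, kernel) {
  if (is.infinite(b)) return((s == 0) + 0)  # keeps matrix dims
  if (kernel == "lorentzian") 1 / (1 + b * s^2) else exp(-b * s^2)
}

# residue indices into AA20 plus pairwise |i-n| matrix; cached by callers
.sequence_geometry <- function(aa) {
  n <- length(aa)
  idx <- match(aa, AA20)
  pos <- seq_len(n)
  list(aa_idx = idx, smat = abs(outer(pos, pos, "-")), n = n)
}

# core forward evaluation; geom from .sequence_geometry
# returns log-profile and, if grad, the pieces needed for analytic gradients
.predict_core <- function(geom, params, grad = FALSE) {
  w <- .kernel_weight(geom$smat, params$b, params$kernel)   # w[i, n]
  qv <- params$q[geom$aa_idx]
  f <- 1 + (qv - 1) * w
  logpred <- colSums(log(f))
  if (!grad) return(list(logpred = logpred))
  wf <- w / f
  # d log pred(n) / d q_a = sum over residues i of type a of w/f
  dq <- matrix(0, nrow = 20L, ncol = geom$n)
  for (a in unique(geom$aa_idx)) {
    dq[a, ] <- colSums(wf[geom$aa_idx == a, , drop = FALSE])
  }
  # d log pred(n) / d b = sum_i (q_i - 1) dw/db / f
  if (is.infinite(params$b)) {
    db <- rep(0, geom$n)
  } else if (params$kernel == "lorentzian") {
    db <- colSums((qv - 1) * (-geom$smat^2 * w^2) / f)
  } else {
    db <- colSums((qv - 1) * (-geom$smat^2 * w) / f)
  }
  list(logpred = logpred, dq = dq, db = db)
}

#' Unscaled per-residue R2 profile
#'
#' Evaluates the multiplicative model: the unscaled R2 at position `n` is the
#' product over all residues `i` of the chain (self term included) of
#' [contributing_factor()] at distance `|i - n|`.  No distance cutoff is
#' applied; remote residues contribute factors close to 1.  Terminal
#' positions have fewer near neighbors, which produces the characteristic
#' falloff of R2 at the N- and C-termini.
#'
#' @param sequence one-letter amino-acid string.
#' @param params a [model_params()] object.
#' @param alias,strict passed to [resolve_sequence()].
#' @return numeric vector of positive dimensionless values, one per residue.
#' @examples
#' q <- setNames(rep(1, 20), idpr2_amino_acids()); q["A"] <- 2
#' predict_r2_unscaled("AAA", model_params(q, b = 1))  # 3.6 4.5 3.6
#' @export
predict_r2_unscaled <- function(sequence, params, alias = NULL, strict = TRUE) {
  stopifnot(inherits(params, "model_params"))
  aa <- resolve_sequence(sequence, alias = alias, strict = strict)
  geom <- .sequence_geometry(aa)
  exp(.predict_core(geom, params)$logpred)
}

#' Predicted R2 profile in physical units
#'
#' Applies the per-protein uniform scale factor (s^-1), which absorbs
#' temperature, magnetic-field and viscosity effects, to the unscaled
#' profile.  Pro positions carry no backbone amide proton, so their measured
#' R2 is not comparable; the returned profile flags them as excluded from
#' scoring while still reporting a predicted value there.
#'
#' @inheritParams predict_r2_unscaled
#' @param scale positive per-protein scale factor, s^-1.
#' @return an [r2_profile()] with `values` (s^-1) and a logical `mask`
#'   (`FALSE` at Pro positions).
#' @export
predict_r2 <- function(sequence, params, scale, alias = NULL, strict = TRUE) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop("scale must be a single positive number (s^-1)")
  }
  aa <- resolve_sequence(sequence, alias = alias, strict = strict)
  vals <- scale * predict_r2_unscaled(sequence, params, alias = alias,
                                      strict = strict)
  r2_profile(vals, mask = aa != "P")
}
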