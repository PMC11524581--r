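#' Reference ground-truth parameters for synthetic data
#'
#' A plausible propensity ladder for generating synthetic datasets:
#' aromatics, Arg and the long branched aliphatics sit at the top (they
#' drive local pi-pi, cation-pi and hydrophobic contacts that slow
#' dynamics), Gly and the short-polar residues at the bottom, and the
#' distance coefficient corresponds to a correlation length of about 5.6
#' residues.  These are documented package constants for testing, not
#' fitted values.
#'
#' @param kernel distance kernel, see [model_params()].
#' @return a [model_params()] object.
#' @export
default_true_params <- function(kernel = "lorentzian") {
  q <- c(W = 1.35, I = 1.28, Y = 1.26, R = 1.22, H = 1.20, F = 1.18,
         L = 1.15, M = 1.10, K = 1.08, Q = 1.02, A = 1.00, E = 1.00,
         C = 0.95, T = 0.93, V = 0.92, D = 0.90, S = 0.88, N = 0.87,
         P = 0.85, G = 0.80)
  model_params(q, b = 3.164e-2, kernel = kernel)
}

#' Disorder-biased amino-acid composition
#'
#' A documented constant composition enriched in Gly, Ser, and other
#' disorder-promoting residues and depleted in aromatics and Cys, roughly
#' emulating typical IDP sequence bias; not an empirical estimate.
#'
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
disorder_composition <- function() {
  w <- c(A = 0.07, C = 0.01, D = 0.06, E = 0.09, F = 0.02, G = 0.09,
         H = 0.02, I = 0.03, K = 0.07, L = 0.05, M = 0.02, N = 0.04,
         P = 0.07, Q = 0.06, R = 0.05, S = 0.09, T = 0.06, V = 0.05,
         W = 0.01, Y = 0.02)
  w / sum(w)
}

#' Recipe for a synthetic dataset
#'
#' Collects everything needed to generate a reproducible model-consistent
#' dataset: number of proteins, length range, sequence composition, the
#' generating parameters, the range the per-protein scale factors are drawn
#' from, the additive noise level, the Pro frequency, and the seed.
#' Defaults emulate the statistical shape of a typical curated IDP R2
#' collection: a few dozen chains in the 80--150 residue range, scale
#' factors mostly between 0.8 and 2.0 s^-1, and measurement-scale noise of
#' 0.3 s^-1.
#'
#' @param n_proteins number of proteins (default 20).
#' @param length_range integer min/max sequence length, within [20, 500]
#'   (default c(80, 150)).
#' @param composition amino-acid frequency vector summing to 1 (default
#'   uniform over the 20 standard residues); Pro weight is overridden by
#'   `pro_frequency`.
#' @param true_params generating [model_params()]
#'   (default [default_true_params()]).
#' @param scale_range min/max of the uniform draw for per-protein scale
#'   factors, s^-1 (default c(0.8, 2.0)).
#' @param noise_sd sd of additive Gaussian noise on R2, s^-1 (default 0.3).
#' @param pro_frequency fraction of Pro residues (default 0.05); the rest of
#'   the composition is renormalized to 1 - pro_frequency.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 20L, length_range = c(80L, 150L),
                           composition = NULL,
                           true_params = default_true_params(),
                           scale_range = c(0.8, 2.0), noise_sd = 0.3,
                           pro_frequency = 0.05, seed = 1L) {
  stopifnot(inherits(true_params, "model_params"))
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 20L || length_range[2] > 500L) {
    stop("length_range must be min <= max within [20, 500]")
  }
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20L), AA20)
  }
  composition <- .validate_composition(composition)
  if (pro_frequency < 0 || pro_frequency >= 1) {
    stop("pro_frequency must be in [0, 1)")
  }
  composition["P"] <- 0
  composition <- composition / sum(composition) * (1 - pro_frequency)
  composition["P"] <- pro_frequency
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2]) {
    stop("scale_range must be positive with min <= max")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 composition = composition, true_params = true_params,
                 scale_range = scale_range, noise_sd = noise_sd,
                 pro_frequency = pro_frequency, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.validate_composition <- function(composition) {
  if (is.null(names(composition)) || !setequal(names(composition), AA20) ||
      length(composition) != 20L) {
    stop("composition must be named over the 20 standard amino acids")
  }
  composition <- composition[AA20]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8) {
    stop("composition must be non-negative and sum to 1")
  }
  composition
}

#' Draw a random amino-acid sequence
#'
#' i.i.d. draws from a composition vector.  Uses the current RNG state
#' unless a seed is given.
#'
#' @param length sequence length (>= 1).
#' @param composition amino-acid frequency vector (default uniform).
#' @param seed optional integer seed for a self-contained draw.
#' @return one-letter sequence string.
#' @export
generate_sequence <- function(length, composition = NULL, seed = NULL) {
  if (length < 1L) stop("length must be >= 1")
  if (is.null(composition)) composition <- setNames(rep(1 / 20, 20L), AA20)
  composition <- .validate_composition(composition)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(composition), length, replace = TRUE,
               prob = composition), collapse = "")
}

#' Generate a model-consistent synthetic dataset
#'
#' For each protein: a sequence is drawn from the composition, a scale
#' factor uniformly from `scale_range`, the noiseless profile is the scaled
#' model prediction under the generating parameters, and additive Gaussian
#' noise is applied and clipped from below at 0.05 s^-1 to keep rates
#' physical.  Pro positions are masked out of scoring as for real data.
#' The generating truth (parameters, scales, noiseless profiles) is
#' attached so parameter-recovery tests have an oracle.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [protein_record()]s with attributes `true_params`,
#'   `true_scales`, and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  recs <- vector("list", spec$n_proteins)
  true_scales <- numeric(spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    sq <- generate_sequence(len, spec$composition)
    sc <- runif(1, spec$scale_range[1], spec$scale_range[2])
    clean <- sc * predict_r2_unscaled(sq, spec$true_params)
    noisy <- pmax(clean + rnorm(len, sd = spec$noise_sd), 0.05)
    rec <- protein_record(sprintf("synth%03d", i), sq, measured_r2 = noisy,
                          scale = sc)
    rec$true_r2 <- clean
    recs[[i]] <- rec
    true_scales[i] <- sc
  }
  names(true_scales) <- vapply(recs, `[[`, "", "id")
  attr(recs, "true_params") <- spec$true_params
  attr(recs, "true_scales") <- true_scales
  attr(recs, "spec") <- spec
  recs
}

#' Uniformly rescale a record's measurements
#'
#' Emulates a change of temperature, magnetic field or viscosity, whose
#' effect on R2 is to a good approximation a uniform multiplicative factor
#' across the sequence.  Scaled R2 (and hence everything trained on profile
#' shape) is invariant; only the per-protein scale absorbs the factor.
#'
#' @param record a [protein_record()] with measured data.
#' @param factor positive multiplier.
#' @return a new [protein_record()] with rescaled measurements (mask
#'   unchanged).
#' @export
apply_uniform_scaling <- function(record, factor) {
  stopifnot(inherits(record, "protein_record"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0) {
    stop("factor must be a single positive number")
  }
  out <- record
  out$measured_r2 <- record$measured_r2 * factor
  if (!is.null(record$scale)) out$scale <- record$scale * factor
  out
}
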