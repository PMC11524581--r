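#' Model parameter set
#'
#' Bundles the 21 global parameters of the sequence model: one positive
#' propensity factor `q` per standard amino acid (Pro included: Pro residues
#' are excluded from scoring but still act as neighbors) and the positive
#' sequence-distance coefficient `b` of the Lorentzian attenuation.
#'
#' `b = Inf` is accepted as the exact zero-correlation-length limit, in which
#' each residue is influenced only by its own q (the one-residue special
#' case); the derived correlation length is then 0.
#'
#' @param q named numeric vector with exactly one positive entry per standard
#'   one-letter amino acid code (order free).
#' @param b positive sequence-distance coefficient (dimensionless); `Inf`
#'   selects the self-factor-only limit.
#' @param kernel distance kernel: `"lorentzian"` (default) gives contributing
#'   factors `1 + (q - 1)/(1 + b s^2)`; `"gaussian"` gives
#'   `1 + (q - 1) exp(-b s^2)`.
#' @return an object of class `model_params`.
#' @examples
#' p <- model_params(q = setNames(rep(1, 20), idpr2_amino_acids()), b = 0.04)
#' correlation_length(p$b)  # 5 residues
#' @export
model_params <- function(q, b, kernel = c("lorentzian", "gaussian")) {
  kernel <- match.arg(kernel)
  if (is.null(names(q)) || anyNA(names(q))) {
    stop("q must be a named vector of amino-acid factors")
  }
  if (length(q) != 20L || !setequal(names(q), AA20) || anyDuplicated(names(q))) {
    missing <- setdiff(AA20, names(q))
    extra <- setdiff(names(q), AA20)
    stop("q must have exactly one entry per standard amino acid",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ",")))
  }
  q <- q[AA20]
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0)) {
    stop("all q factors must be positive and finite")
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop("b must be a single positive number (Inf allowed for the ",
         "self-factor-only limit)")
  }
  structure(list(q = q, b = b, kernel = kernel), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Sequence-model parameters (", x$kernel, " kernel)\n", sep = "")
  cat("  b =", format(x$b), " (Lcorr =", format(correlation_length(x$b), digits = 3),
      "residues)\n")
  qo <- sort(x$q, decreasing = TRUE)
  cat("  q range:", format(min(x$q), digits = 4), "(", names(which.min(x$q)), ") to",
      format(max(x$q), digits = 4), "(", names(which.max(x$q)), ")\n")
  print(round(qo, 4))
  invisible(x)
}

#' Standard amino-acid alphabet
#'
#' @return the 20 standard one-letter amino-acid codes, alphabetical.
#' @export
idpr2_amino_acids <- function() AA20

#' Correlation length of the distance kernel
#'
#' The correlation length is the sequence distance at which a neighbor's
#' contributing factor has decayed halfway between its value at distance 0
#' (the full factor q) and its value at infinite distance (1).  For the
#' Lorentzian kernel this distance is `b^(-1/2)`.
#'
#' @param b positive distance coefficient; `Inf` maps to length 0.
#' @return correlation length in residues.
#' @examples
#' correlation_length(3.164e-2)  # about 5.6 residues
#' @export
correlation_length <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop("b must be a single positive number")
  }
  if (is.infinite(b)) return(0)
  b^(-0.5)
}

#' Resolve a sequence string to standard amino-acid codes
#'
#' Splits a one-letter sequence and optionally maps nonstandard letters to
#' standard ones through an alias table (e.g. chemically modified residues
#' recorded under a nonstandard code).  In strict mode any letter outside the
#' 20 standard codes is an error.  The ambiguity code `X` is rejected in both
#' modes: the model has no meaningful factor for an unknown residue.
#'
#' @param sequence one-letter amino-acid string.
#' @param alias named character vector mapping nonstandard letters to
#'   standard ones, e.g. `c(B = "N")`; applied before validation.
#' @param strict if `TRUE` (default) any unresolvable letter is an error.
#'   If `FALSE`, unresolvable letters other than `X` are still errors unless
#'   covered by `alias` (permissive mode only widens what `alias` may remap).
#' @return character vector of standard one-letter codes.
#' @export
resolve_sequence <- function(sequence, alias = NULL, strict = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    stop("sequence must be a non-empty character scalar")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!is.null(alias)) {
    if (is.null(names(alias)) || !all(alias %in% AA20)) {
      stop("alias must be a named vector mapping letters to standard codes")
    }
    if ("X" %in% names(alias)) stop("the ambiguity code X cannot be aliased")
    hit <- aa %in% names(alias)
    aa[hit] <- unname(alias[aa[hit]])
  }
  bad <- which(!(aa %in% AA20))
  if (length(bad)) {
    stop("unresolvable residue letter(s) ", paste(unique(aa[bad]), collapse = ","),
         " at position(s) ", paste(utils::head(bad, 5L), collapse = ","),
         if (strict) "" else " (not covered by the alias table)")
  }
  aa
}
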