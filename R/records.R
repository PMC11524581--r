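#' Per-residue R2 profile
#'
#' A container for per-residue rates aligned 1-based to a sequence, with a
#' logical mask separating scoreable positions from Pro/unobserved ones.
#'
#' @param values numeric vector of per-residue rates (s^-1); may contain `NA`
#'   at unobserved positions, which must be masked out.
#' @param mask logical vector, `TRUE` where the position participates in
#'   fitting and error metrics.
#' @return an object of class `r2_profile`.
#' @export
r2_profile <- function(values, mask = rep(TRUE, length(values))) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (!is.logical(mask) || length(mask) != length(values) || anyNA(mask)) {
    stop("mask must be a logical vector matching values in length, no NA")
  }
  if (anyNA(values[mask])) stop("masked-in values must not be NA")
  if (any(values[mask] <= 0)) stop("masked-in R2 values must be positive")
  structure(list(values = values, mask = mask), class = "r2_profile")
}

#' @export
print.r2_profile <- function(x, ...) {
  cat("R2 profile:", length(x$values), "residues,", sum(x$mask), "scored\n")
  print(summary(x$values[x$mask]))
  invisible(x)
}

#' @export
length.r2_profile <- function(x) length(x$values)

#' Protein record
#'
#' One protein's data: identifier, sequence, optional measured R2 profile
#' with a validity mask, optional per-residue helix-propensity track, and an
#' optional per-protein scale factor.  The mask is forced `FALSE` at Pro
#' positions (no backbone amide proton, so measured R2 is depressed for
#' chemical rather than dynamical reasons) and at positions with missing
#' measurements.
#'
#' @param id protein identifier.
#' @param sequence one-letter amino-acid string.
#' @param measured_r2 optional numeric vector of measured rates (s^-1),
#'   `NA` where unobserved; length must match the sequence.
#' @param mask optional logical vector of positions eligible for
#'   fitting/scoring; intersected with the Pro/missing-data constraints.
#' @param scale optional positive per-protein scale factor (s^-1).
#' @param helix_scores optional per-residue helix-propensity scores in [0, 1].
#' @param alias,strict passed to [resolve_sequence()].
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, measured_r2 = NULL, mask = NULL,
                           scale = NULL, helix_scores = NULL,
                           alias = NULL, strict = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string")
  }
  aa <- resolve_sequence(sequence, alias = alias, strict = strict)
  n <- length(aa)
  if (!is.null(measured_r2)) {
    if (!is.numeric(measured_r2) || length(measured_r2) != n) {
      stop("measured_r2 must be numeric of length ", n, " for '", id, "'")
    }
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!is.logical(mask) || length(mask) != n || anyNA(mask)) {
    stop("mask must be logical of length ", n)
  }
  mask <- mask & (aa != "P")
  if (!is.null(measured_r2)) mask <- mask & !is.na(measured_r2)
  if (!is.null(measured_r2) && any(measured_r2[mask] <= 0, na.rm = TRUE)) {
    stop("masked-in measured R2 values must be positive for '", id, "'")
  }
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
      stop("scale must be a single positive number")
    }
  }
  if (!is.null(helix_scores)) {
    if (!is.numeric(helix_scores) || length(helix_scores) != n) {
      stop("helix_scores must be numeric of length ", n)
    }
    if (any(is.na(helix_scores)) || any(helix_scores < 0 | helix_scores > 1)) {
      stop("helix_scores must lie in [0, 1]")
    }
  }
  structure(list(id = id, sequence = paste(aa, collapse = ""), aa = aa,
                 measured_r2 = measured_r2, mask = mask, scale = scale,
                 helix_scores = helix_scores),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("Protein record '", x$id, "': ", length(x$aa), " residues",
      if (!is.null(x$measured_r2)) paste0(", ", sum(x$mask), " scored R2 values"),
      if (!is.null(x$helix_scores)) ", helix scores present",
      "\n", sep = "")
  invisible(x)
}
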