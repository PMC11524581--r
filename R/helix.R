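#' Find long high-confidence helix segments
#'
#' Secondary-structure predictors overcall helices on disordered sequences;
#' filtering the per-residue helix-propensity scores with a very high cutoff
#' and requiring a minimum run length keeps only confidently predicted long
#' helices, which tumble slowly enough to need an R2 boost.
#'
#' @param helix_scores per-residue helix-propensity scores in [0, 1].
#' @param cutoff minimum score for a position to count as helical
#'   (default 0.99).
#' @param min_length minimum run length in residues (default 12).
#' @return a data.frame with columns `start`, `end` (1-based, inclusive),
#'   sorted and non-overlapping; zero rows when nothing qualifies.
#' @export
find_helix_segments <- function(helix_scores, cutoff = 0.99, min_length = 12L) {
  if (!is.numeric(helix_scores) || anyNA(helix_scores) ||
      any(helix_scores < 0 | helix_scores > 1)) {
    stop("helix_scores must be numeric in [0, 1] with no NA")
  }
  r <- rle(helix_scores >= cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep])
}

#' Boost predicted R2 inside long helical segments
#'
#' The base model couples residues only within the correlation length; a
#' stable long helix tumbles as a unit and slows dynamics beyond what local
#' coupling captures, so predicted R2 is underestimated there.  Within each
#' qualifying segment the profile is multiplied by `1 + alpha * pHlx(n)`,
#' using the per-residue helix score; positions outside every segment are
#' untouched.
#'
#' @param profile an [r2_profile()] (or plain numeric vector).
#' @param helix_scores per-residue helix-propensity scores in [0, 1].
#' @param segments segment table from [find_helix_segments()]; pass the
#'   result for the same scores so only filtered long helices are boosted.
#' @param alpha non-negative boost amplitude (default 0.5, so a fully
#'   confident helix position is boosted by a factor 1.5).
#' @return object of the same type as `profile` with boosted values.
#' @export
apply_helix_boost <- function(profile, helix_scores, segments, alpha = 0.5) {
  vals <- if (inherits(profile, "r2_profile")) profile$values else profile
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number")
  }
  if (length(helix_scores) != length(vals)) {
    stop("helix_scores length must match the profile")
  }
  if (nrow(segments) > 0) {
    if (any(segments$start < 1L) || any(segments$end > length(vals)) ||
        any(segments$end < segments$start)) {
      stop("segment indices out of range for this profile")
    }
    for (k in seq_len(nrow(segments))) {
      i <- segments$start[k]:segments$end[k]
      vals[i] <- vals[i] * (1 + alpha * helix_scores[i])
    }
  }
  if (inherits(profile, "r2_profile")) {
    r2_profile(vals, profile$mask)
  } else {
    vals
  }
}
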