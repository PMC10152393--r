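# LTR divergence dating.
#
# The two LTRs of a provirus are identical at integration; under neutrality
# their uncorrected p-distance divided by the host substitution rate clocks
# the insertion. The default rate is the monotreme genome-wide estimate of
# 2.6e-3 substitutions/site/MY; the default age convention T = d / r
# reproduces the published arithmetic (d = 3.9e-3 -> ~1.5 MY), while
# `two_lineage` (T = d / 2r) treats both LTRs as independently diverging.

MONOTREME_RATE <- 2.6e-3

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment (via Biostrings) under a +1/-1 match/mismatch
#' scheme with affine gaps: a gap of length L costs
#' `-(gap_open + (L - 1) * gap_extend)` with the defaults reading
#' gap_open = 5 for the first gapped position and gap_extend = 1 for each
#' further one.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend positive penalties (see above).
#' @return Object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `n_columns`, `n_ungapped_columns`,
#'   `n_mismatches`, `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap_open = 5,
                         gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(al))
  aligned_b <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  ungapped <- ca != "-" & cb != "-"
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 n_columns = length(ca),
                 n_ungapped_columns = sum(ungapped),
                 n_mismatches = sum(ca[ungapped] != cb[ungapped]),
                 score = Biostrings::score(al)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(paste0("<pairwise_alignment> %d columns, %d ungapped, ",
                     "%d mismatches\n"),
              x$n_columns, x$n_ungapped_columns, x$n_mismatches))
  invisible(x)
}

#' Uncorrected p-distance of a pairwise alignment
#'
#' Mismatches over ungapped columns (pairwise gap deletion), the EMBOSS
#' distmat default; no multiple-hit correction.
#'
#' @param alignment a [align_global()] result.
#' @return p-distance in substitutions/site.
#' @export
p_distance <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (alignment$n_ungapped_columns == 0L) {
    stop("all alignment columns are gapped")
  }
  alignment$n_mismatches / alignment$n_ungapped_columns
}

#' Percent identity between two aligned LTRs
#'
#' `100 * (1 - p_distance)`; report tables round to one decimal, the
#' returned value is unrounded.
#'
#' @param alignment a [align_global()] result.
#' @return Percent identity.
#' @export
ltr_identity <- function(alignment) {
  100 * (1 - p_distance(alignment))
}

#' Convert LTR divergence to insertion age
#'
#' @param d p-distance (substitutions/site).
#' @param rate neutral substitution rate in substitutions/site/MY
#'   (monotreme genome-wide default 2.6e-3).
#' @param convention `"paper"` (`T = d / rate`, reproducing the published
#'   worked example) or `"two_lineage"` (`T = d / (2 * rate)`).
#' @return Insertion age in MY.
#' @export
estimate_age <- function(d, rate = MONOTREME_RATE,
                         convention = c("paper", "two_lineage")) {
  convention <- match.arg(convention)
  if (any(d < 0)) stop("p-distance must be >= 0")
  if (rate <= 0) stop("substitution rate must be > 0")
  if (convention == "paper") d / rate else d / (2 * rate)
}

#' Date a provirus from its two LTR sequences
#'
#' Aligns the LTR pair, computes p-distance and identity, and converts the
#' distance to an insertion age.
#'
#' @param ltr5,ltr3 LTR nucleotide strings.
#' @param rate,convention passed to [estimate_age()].
#' @return Object of class `age_estimate`: fields `d`, `rate`, `age_my`,
#'   `identity_pct`, `convention`, `n_columns`, `n_ungapped_columns`.
#' @export
date_ltr_pair <- function(ltr5, ltr3, rate = MONOTREME_RATE,
                          convention = c("paper", "two_lineage")) {
  convention <- match.arg(convention)
  al <- align_global(ltr5, ltr3)
  d <- p_distance(al)
  structure(list(d = d, rate = rate,
                 age_my = estimate_age(d, rate, convention),
                 identity_pct = ltr_identity(al), convention = convention,
                 n_columns = al$n_columns,
                 n_ungapped_columns = al$n_ungapped_columns),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(paste0("<age_estimate> d = %.4g subs/site, identity = %.1f%%,",
                     " age = %.3g MY (%s convention, rate %.2g)\n"),
              x$d, x$identity_pct, x$age_my, x$convention, x$rate))
  invisible(x)
}
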