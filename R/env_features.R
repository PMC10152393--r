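# Envelope protein annotation: furin cleavage site, SU/TM split, and the
# RDR-group receptor-binding motif.
#
# Motif wildcards ("x") match any of the 20 residues or an ambiguous X;
# fixed positions match their exact letter only, so X never satisfies them.

AA_OR_X_CLASS <- "[ACDEFGHIKLMNPQRSTVWYX]"

#' Find the furin cleavage site of an Env protein
#'
#' Matches the minimal furin motif R-x-[RK]-R (covering RxRR and RxKR).
#' Among matches leaving at least `min_tail` residues downstream of the
#' final R, the most C-terminal is returned — the biologically plausible
#' SU/TM boundary when the motif recurs in SU.
#'
#' @param aa_seq amino-acid string.
#' @param min_tail minimum residues downstream of the cleavage site
#'   (default 80, roughly a TM ectodomain + anchor + tail).
#' @return 1-based position of the motif's final R, or `NA_integer_`.
#' @export
find_furin_site <- function(aa_seq, min_tail = 80L) {
  stopifnot(nzchar(aa_seq))
  pat <- paste0("(?=R", AA_OR_X_CLASS, "[RK]R)")
  starts <- overlapping_matches(aa_seq, pat)
  if (!length(starts)) return(NA_integer_)
  final_r <- starts + 3L
  ok <- (nchar(aa_seq) - final_r) >= min_tail
  if (!any(ok)) return(NA_integer_)
  max(final_r[ok])
}

#' Extract the TM subunit downstream of the furin site
#'
#' The suffix starting right after the cleavage site; this is the sequence
#' fed to the family alignment for group assignment. Note "TM region" means
#' the post-furin subunit, not a predicted membrane helix.
#'
#' @param aa_seq full Env protein.
#' @param furin_site position from [find_furin_site()].
#' @return TM subunit string.
#' @export
extract_tm_region <- function(aa_seq, furin_site) {
  if (is.na(furin_site)) stop("no furin site: cannot extract TM region")
  if (furin_site >= nchar(aa_seq)) stop("cleavage at final residue: empty TM")
  substr(aa_seq, furin_site + 1L, nchar(aa_seq))
}

#' Find RDR receptor-binding motifs
#'
#' All (possibly overlapping) start positions of the
#' S-D-G-G-G-x-x-D-x-x-R motif that marks the RD114/D-type interference
#' group's ASCT1/ASCT2 binding region.
#'
#' @param aa_seq amino-acid string.
#' @return Integer vector of 1-based match starts (possibly empty).
#' @export
find_rdr_motif <- function(aa_seq) {
  stopifnot(nzchar(aa_seq))
  pat <- paste0("(?=SDGGG", AA_OR_X_CLASS, AA_OR_X_CLASS, "D",
                AA_OR_X_CLASS, AA_OR_X_CLASS, "R)")
  overlapping_matches(aa_seq, pat)
}

overlapping_matches <- function(s, lookahead_pattern) {
  m <- gregexpr(lookahead_pattern, s, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) return(integer())
  as.integer(m)
}

#' Annotate an Env protein
#'
#' @param aa_seq Env protein string.
#' @param min_tail passed to [find_furin_site()].
#' @return list of class `env_annotation`: `furin_site`, `tm_region`
#'   (`NA` when no furin site; callers fall back to the full-length
#'   sequence), `rdr_positions`.
#' @export
annotate_env <- function(aa_seq, min_tail = 80L) {
  furin <- find_furin_site(aa_seq, min_tail)
  tm <- if (is.na(furin) || furin >= nchar(aa_seq)) NA_character_ else
    extract_tm_region(aa_seq, furin)
  structure(list(furin_site = furin, tm_region = tm,
                 rdr_positions = find_rdr_motif(aa_seq)),
            class = "env_annotation")
}

#' @export
print.env_annotation <- function(x, ...) {
  cat(sprintf("<env_annotation> furin at %s, TM %s aa, RDR motifs: %s\n",
              ifelse(is.na(x$furin_site), "-", x$furin_site),
              ifelse(is.na(x$tm_region), "-", nchar(x$tm_region)),
              if (length(x$rdr_positions))
                paste(x$rdr_positions, collapse = ",") else "-"))
  invisible(x)
}
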