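# Six-frame ORF enumeration.
#
# Two modes mirror the two rows of a provirus structure map: stop_to_stop
# segments (everything between two in-frame stop codons) and start_to_stop
# ORFs (5'-most ATG of a segment through its stop). Reported intervals
# include the terminal stop codon when one lies inside the contig; aa_len
# never counts the stop.

#' Find open reading frames
#'
#' Enumerates ORFs in all three frames of one or both strands. In
#' `start_to_stop` mode each stop-delimited segment contributes at most one
#' ORF, from its 5'-most ATG (set `all_starts = TRUE` to emit one ORF per
#' internal ATG instead). Codons containing N translate to `X` and do not
#' terminate an ORF; ORFs with more than 5% `X` are flagged low-confidence.
#'
#' @param genome a [genome_sequence()] record (or plain nucleotide string,
#'   in which case the contig id is `"seq"`).
#' @param min_codons minimum length in codons (excluding the terminal stop).
#'   The default 400 reproduces the full-length envelope screen
#'   (>= 400 amino acids, i.e. a 1,200-nt coding span); set
#'   `strict_greater = TRUE` for a strict > 400 reading.
#' @param mode `"start_to_stop"` or `"stop_to_stop"`.
#' @param both_strands scan the reverse complement as well.
#' @param all_starts emit every internal ATG as its own ORF.
#' @param strict_greater require `aa_len > min_codons` instead of `>=`.
#' @return data.frame with columns orf_id, contig, start, end, strand,
#'   frame, mode, aa_len, nt_seq, aa_seq, has_stop, low_confidence, sorted
#'   by contig then start.
#' @export
find_orfs <- function(genome, min_codons = 400L,
                      mode = c("start_to_stop", "stop_to_stop"),
                      both_strands = TRUE, all_starts = FALSE,
                      strict_greater = FALSE) {
  mode <- match.arg(mode)
  if (is.character(genome)) genome <- genome_sequence("seq", genome)
  stopifnot(inherits(genome, "genome_sequence"), min_codons >= 1L)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    s <- if (strand == "+") genome$seq else reverse_complement(genome$seq)
    for (frame in 0:2) {
      min_len <- if (strict_greater) min_codons + 1L else min_codons
      segs <- orf_segments(s, frame, mode, all_starts, min_len)
      if (!nrow(segs)) next
      segs <- segs[segs$aa_len >= min_len, , drop = FALSE]
      if (!nrow(segs)) next
      # map local plus-strand coordinates back to the forward strand
      if (strand == "-") {
        L <- genome$length
        tmp_start <- L - segs$end
        segs$end <- L - segs$start
        segs$start <- tmp_start
      }
      segs$contig <- genome$id
      segs$strand <- strand
      segs$frame <- frame
      segs$mode <- mode
      out[[length(out) + 1L]] <- segs
    }
  }
  if (!length(out)) return(empty_orf_frame())
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$start, df$end, df$strand), , drop = FALSE]
  df$orf_id <- sprintf("%s:%d-%d(%s)", df$contig, df$start, df$end,
                       df$strand)
  rownames(df) <- NULL
  df[, c("orf_id", "contig", "start", "end", "strand", "frame", "mode",
         "aa_len", "nt_seq", "aa_seq", "has_stop", "low_confidence")]
}

empty_orf_frame <- function() {
  data.frame(orf_id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), frame = integer(),
             mode = character(), aa_len = integer(), nt_seq = character(),
             aa_seq = character(), has_stop = logical(),
             low_confidence = logical(), stringsAsFactors = FALSE)
}

# Segment scan on one frame of one (already oriented) strand. Coordinates
# returned are 0-based half-open on that strand; terminal stop codon
# included in [start, end) when present.
orf_segments <- function(seq, frame, mode, all_starts, min_len = 1L) {
  aa <- translate_nt(seq, frame)
  n_aa <- nchar(aa)
  if (n_aa == 0L) return(data.frame())
  stops <- as.integer(gregexpr("*", aa, fixed = TRUE)[[1]])
  if (length(stops) == 1L && stops == -1L) stops <- integer()
  seg_start <- c(1L, stops + 1L)          # 1-based aa index of first codon
  seg_stop <- c(stops, n_aa + 1L)         # 1-based aa index of stop (or past end)
  # drop empty segments and those too short to yield a qualifying ORF
  keep <- (seg_stop - seg_start) >= max(1L, min_len)
  seg_start <- seg_start[keep]
  seg_stop <- seg_stop[keep]
  has_stop <- seg_stop <= n_aa
  rows <- list()
  for (i in seq_along(seg_start)) {
    seg_aa <- substr(aa, seg_start[i], seg_stop[i] - 1L)
    if (mode == "stop_to_stop") {
      starts_aa <- seg_start[i]
    } else {
      m_pos <- if (all_starts) {
        which(strsplit(seg_aa, "")[[1]] == "M")
      } else {
        regexpr("M", seg_aa, fixed = TRUE)[[1]]
      }
      if (length(m_pos) == 1L && m_pos[1] == -1L) next
      starts_aa <- seg_start[i] + m_pos - 1L
    }
    for (sa in starts_aa) {
      aa_len <- seg_stop[i] - sa
      nt_start <- frame + 3L * (sa - 1L)
      nt_end <- frame + 3L * (seg_stop[i] - 1L) + if (has_stop[i]) 3L else 0L
      orf_aa <- substr(aa, sa, seg_stop[i] - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        start = nt_start, end = nt_end, aa_len = aa_len,
        nt_seq = substr(seq, nt_start + 1L, nt_end),
        aa_seq = orf_aa, has_stop = has_stop[i],
        low_confidence = x_fraction(orf_aa) > 0.05,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

x_fraction <- function(aa) {
  if (!nchar(aa)) return(0)
  lengths(regmatches(aa, gregexpr("X", aa, fixed = TRUE))) / nchar(aa)
}

#' Annotate ORFs of a provirus sequence
#'
#' Returns the plus-strand ORFs longer than `min_nt` nucleotides in both
#' stop-to-stop and start-to-stop modes, the two rows of a provirus
#' structure map.
#'
#' @param provirus_seq provirus nucleotide string (plus strand).
#' @param min_nt ORFs whose nucleotide span (terminal stop included) is
#'   strictly greater than this are kept; 300 by default.
#' @return data.frame as [find_orfs()], both modes combined.
#' @export
annotate_provirus_orfs <- function(provirus_seq, min_nt = 300L) {
  rec <- if (inherits(provirus_seq, "genome_sequence")) provirus_seq else
    genome_sequence("provirus", provirus_seq)
  both <- lapply(c("stop_to_stop", "start_to_stop"), function(m) {
    find_orfs(rec, min_codons = 1L, mode = m, both_strands = FALSE)
  })
  df <- do.call(rbind, both)
  df <- df[(df$end - df$start) > min_nt, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write ORF records to disk
#'
#' Emits a protein FASTA (ids `contig:start-end(strand)`), a BED file of the
#' intervals and a TSV summary (ORF length, chromosome, locus, direction).
#'
#' @param orfs data.frame from [find_orfs()].
#' @param prefix output path prefix; files `<prefix>.faa`, `<prefix>.bed`
#'   and `<prefix>.tsv` are written.
#' @return Named character vector of paths, invisibly.
#' @export
write_orf_report <- function(orfs, prefix) {
  faa <- paste0(prefix, ".faa")
  bed <- paste0(prefix, ".bed")
  tsv <- paste0(prefix, ".tsv")
  seqs <- orfs$aa_seq
  names(seqs) <- orfs$orf_id
  if (nrow(orfs)) write_fasta(seqs, faa) else cat("", file = faa)
  bed_df <- data.frame(orfs$contig, orfs$start, orfs$end, orfs$orf_id,
                       rep(0L, nrow(orfs)), orfs$strand)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv_df <- data.frame(orf_id = orfs$orf_id, orf_length_aa = orfs$aa_len,
                       chromosome = orfs$contig, locus_start = orfs$start,
                       locus_end = orfs$end, direction = orfs$strand,
                       stringsAsFactors = FALSE)
  utils::write.table(tsv_df, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(faa = faa, bed = bed, tsv = tsv))
}
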