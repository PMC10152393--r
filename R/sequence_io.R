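# FASTA/GFF3 input-output and strand-aware coordinate arithmetic.
#
# All coordinates inside the package are 0-based half-open [start, end);
# GFF3 on disk is 1-based inclusive and the converters below do the shift.

DNA_LETTERS <- c("A", "C", "G", "T", "N")

#' Construct a genome sequence record
#'
#' @param id contig identifier (no whitespace).
#' @param seq nucleotide string over A/C/G/T/N (case-insensitive; stored
#'   upper-case).
#' @return An object of class `genome_sequence` with fields `id`, `seq` and
#'   `length`.
#' @export
genome_sequence <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a single non-empty string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    stop("illegal nucleotide character(s) in '", id, "': ",
         paste(bad, collapse = " "))
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased on load; characters outside A/C/G/T/N are
#' rejected. Record order follows the file.
#'
#' @param path path to a FASTA file.
#' @return A named list of [genome_sequence()] records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- lapply(seq_along(set), function(i) {
    genome_sequence(ids[[i]], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records a named character vector of sequences, or a list of
#'   [genome_sequence()] records.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.list(records) && length(records) &&
      inherits(records[[1]], "genome_sequence")) {
    seqs <- vapply(records, function(r) r$seq, character(1))
    names(seqs) <- vapply(records, function(r) r$id, character(1))
    records <- seqs
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a genomic interval
#'
#' 0-based half-open internal representation with an explicit strand flag;
#' minus-strand features keep forward-strand coordinates (GFF3 convention).
#'
#' @param contig contig id.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"` or `"-"`.
#' @param contig_length optional contig length used to bound-check `end`.
#' @return A one-row `data.frame` with columns contig/start/end/strand.
#' @export
genomic_interval <- function(contig, start, end, strand = "+",
                             contig_length = NULL) {
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (start < 0 || end <= start) {
    stop("need 0 <= start < end (got start=", start, ", end=", end, ")")
  }
  if (!is.null(contig_length) && end > contig_length) {
    stop("interval end ", end, " exceeds contig length ", contig_length)
  }
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract the sequence of an interval
#'
#' Minus-strand intervals return the reverse complement, so the result always
#' reads 5' to 3' on the feature's own strand.
#'
#' @param genome a [genome_sequence()] record.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string.
#' @export
extract_interval <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_sequence"))
  if (start < 0 || end > genome$length || end <= start) {
    stop("interval [", start, ",", end, ") out of bounds for ",
         genome$id, " (", genome$length, " bp)")
  }
  s <- substr(genome$seq, start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Reverse complement a nucleotide string
#'
#' N maps to N; the operation is an involution.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  if (grepl("[^ACGTNacgtn]", seq)) stop("illegal nucleotide character")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide string
#'
#' Standard genetic code; stop codons are rendered `*`; any codon containing
#' N translates to `X`; 1-2 trailing nucleotides beyond the last full codon
#' are dropped.
#'
#' @param nt nucleotide string.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  nt <- toupper(nt)
  n <- nchar(nt) - frame
  n_codons <- n %/% 3L
  if (n_codons <= 0L) return("")
  sub <- substr(nt, frame + 1L, frame + 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Write features to GFF3
#'
#' Internal 0-based half-open intervals are converted to the 1-based
#' inclusive coordinates of the GFF3 standard.
#'
#' @param features data.frame with columns contig, start, end, strand, type,
#'   and optionally ID, Parent and further attribute columns.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "ervmine") {
  stopifnot(all(c("contig", "start", "end", "strand", "type") %in%
                names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand
  )
  gr$source <- source
  gr$type <- features$type
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  extra <- setdiff(names(features),
                   c("contig", "start", "end", "strand", "type"))
  for (col in extra) {
    S4Vectors::mcols(gr)[[col]] <- features[[col]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  # drop the run-date header line so reruns are byte-identical
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read a GFF3 file into internal coordinates
#'
#' @param path GFF3 file.
#' @return data.frame with 0-based half-open contig/start/end/strand/type
#'   plus any attribute columns.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  keep <- setdiff(names(mc), c("source", "type", "score", "phase"))
  for (col in keep) {
    v <- mc[[col]]
    if (is.list(v)) v <- vapply(v, function(x) paste(x, collapse = ","),
                                character(1))
    df[[col]] <- v
  }
  df
}
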