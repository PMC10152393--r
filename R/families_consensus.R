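# env-ORF families: clustering, multiple alignment, column trimming,
# plurality consensus and a neighbour-joining helper.

#' Percent identity of two protein sequences
#'
#' Global alignment under BLOSUM62 with affine gaps; identity is matching
#' columns over all alignment columns.
#'
#' @param a,b amino-acid strings.
#' @return Percent identity in [0, 100].
#' @export
protein_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  ca <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Cluster env-ORFs into families
#'
#' Single-linkage clustering on pairwise global-alignment amino-acid
#' identity: sequences joined by a chain of pairs at or above the threshold
#' form one family. Families are named `<prefix>1`, `<prefix>2`, ... in
#' order of descending copy number, ties broken by the leftmost genomic
#' position of a member (parsed from ids of the form
#' `contig:start-end(strand)`) and then by the lexicographically smallest
#' member id, so the result is invariant to input order.
#'
#' @param aa_seqs named character vector of protein sequences.
#' @param identity_threshold linkage threshold in percent (default 80).
#' @param prefix family-name prefix.
#' @return data.frame with columns orf_id, family; plus attribute
#'   `"families"`: data.frame (family, copy_number, members).
#' @export
cluster_families <- function(aa_seqs, identity_threshold = 80,
                             prefix = "envF") {
  n <- length(aa_seqs)
  stopifnot(n >= 1L)
  ids <- names(aa_seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("aa_seqs must carry unique names")
  }
  ord <- order(ids)
  aa_seqs <- aa_seqs[ord]
  ids <- ids[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (protein_identity(aa_seqs[[i]], aa_seqs[[j]]) >=
            identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, comp)
  pos <- function(members) {
    p <- suppressWarnings(
      as.numeric(sub("^.*:(\\d+)-.*$", "\\1", members)))
    if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
  }
  ordg <- order(-lengths(groups),
                vapply(groups, pos, numeric(1)),
                vapply(groups, function(m) sort(m)[1], character(1)))
  groups <- groups[ordg]
  fam_names <- paste0(prefix, seq_along(groups))
  assign_df <- data.frame(
    orf_id = unlist(groups, use.names = FALSE),
    family = rep(fam_names, lengths(groups)),
    stringsAsFactors = FALSE)
  fam_df <- data.frame(
    family = fam_names, copy_number = as.integer(lengths(groups)),
    members = vapply(groups, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  attr(assign_df, "families") <- fam_df
  assign_df
}

#' Multiple sequence alignment of family members
#'
#' Alignments are computed with MAFFT (L-INS-i: `--localpair
#' --maxiterate 1000`), which must be on the PATH. A single sequence is
#' returned unchanged as a one-row alignment.
#'
#' @param seqs named character vector (nucleotide or protein).
#' @return Object of class `msa`: `ids`, `rows` (equal-length gapped
#'   strings), `n_columns`.
#' @export
progressive_msa <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) {
    return(new_msa(names(seqs), unname(seqs)))
  }
  if (Sys.which("mafft") == "") {
    stop("mafft was not found on the PATH")
  }
  fin <- tempfile(fileext = ".fa")
  fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin)
  out <- system2("mafft", c("--localpair", "--maxiterate", "1000",
                            "--quiet", shQuote(fin)), stdout = TRUE)
  writeLines(out, fout)
  aligned <- Biostrings::readBStringSet(fout)
  rows <- toupper(as.character(aligned))
  # mafft preserves input order
  new_msa(sub("\\s.*$", "", names(aligned)), unname(rows))
}

new_msa <- function(ids, rows) {
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in length")
  structure(list(ids = ids, rows = rows, n_columns = widths[1]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$rows),
              x$n_columns))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Remove sparse alignment columns
#'
#' Columns whose non-gap fraction is below `min_residue_fraction` are
#' deleted (the boundary, exactly the threshold, is kept). With the default
#' 0.6 this matches removing columns with more than 40% gaps.
#'
#' @param msa an [progressive_msa()] result.
#' @param min_residue_fraction minimum kept non-gap fraction.
#' @return Trimmed `msa`.
#' @export
trim_sparse_columns <- function(msa, min_residue_fraction = 0.6) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_matrix(msa)
  frac <- colMeans(m != "-")
  keep <- frac >= min_residue_fraction
  if (!any(keep)) stop("all alignment columns removed by trimming")
  m <- m[, keep, drop = FALSE]
  new_msa(msa$ids, apply(m, 1, paste, collapse = ""))
}

#' Plurality consensus of an alignment
#'
#' Per column, the most frequent residue among non-gap characters; ties are
#' broken by lexicographic order of the residue letters. Columns containing
#' only gaps are dropped (sparse columns are expected to be pre-trimmed).
#'
#' @param msa an `msa` object (usually after [trim_sparse_columns()]).
#' @return Consensus sequence string.
#' @export
consensus_sequence <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  if (!length(msa$rows)) stop("empty alignment")
  m <- msa_matrix(msa)
  picks <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    tab <- table(col)
    names(tab)[tab == max(tab)][1]   # table() names are sorted: lexicographic tie-break
  })
  paste(picks[!is.na(picks)], collapse = "")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via ape); negative branch lengths are
#' clamped to zero with a warning. A 2-taxon matrix returns the cherry with
#' each branch d/2.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/col names.
#' @return An `ape::phylo` tree; write with [ape::write.tree()].
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L, !is.null(rownames(d)))
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (n == 2L) {
    txt <- sprintf("(%s:%g,%s:%g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative neighbour-joining branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' p-distance matrix of an alignment
#'
#' Pairwise p-distances (mismatches over ungapped columns, pairwise
#' deletion) between all rows of an alignment; input for [nj_tree()].
#'
#' @param msa an `msa` object.
#' @return Symmetric matrix with the alignment ids as dimnames.
#' @export
msa_p_distance <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- m[i, ] != "-" & m[j, ] != "-"
        if (!any(ok)) stop("rows ", i, " and ", j, " share no ungapped columns")
        d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      }
    }
  }
  d
}
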