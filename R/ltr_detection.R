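# LTR pair detection: long direct repeats flanking an env-ORF.
#
# A candidate provirus window (env-ORF +/- 10 kbp) is split in two; exact
# k-mer seeds shared between the halves are grouped on diagonal bands and
# each band is polished by local alignment of the corresponding subregions.
# Candidate pairs are filtered on length and identity and ranked by
# alignment score; the best pair that brackets the env-ORF delimits the
# provirus.

#' Extract the provirus search window around an env-ORF
#'
#' @param genome a [genome_sequence()] record.
#' @param orf one-row data.frame (columns start, end) or list with `start`
#'   and `end` in 0-based genome coordinates.
#' @param flank extension on each side in bp (10 kbp by default).
#' @return list with `seq` (window nucleotides, forward strand), `offset`
#'   (genome coordinate of window position 0), `orf_start`/`orf_end`
#'   (ORF in window coordinates).
#' @export
extract_window <- function(genome, orf, flank = 10000L) {
  stopifnot(inherits(genome, "genome_sequence"))
  ws <- max(0L, as.integer(orf$start) - as.integer(flank))
  we <- min(genome$length, as.integer(orf$end) + as.integer(flank))
  list(seq = substr(genome$seq, ws + 1L, we), offset = ws,
       orf_start = as.integer(orf$start) - ws,
       orf_end = as.integer(orf$end) - ws)
}

#' Find direct-repeat (LTR) candidate pairs in a window
#'
#' Exact `k`-mer seeds between the left and right half of the window are
#' chained on common diagonal bands; each band is extended by local
#' alignment, and pairs satisfying the length and identity bounds are
#' returned best score first. Identity is the percentage of matching
#' columns of the pairwise alignment of the two repeat copies.
#'
#' @param window window nucleotide string (or list from [extract_window()]).
#' @param min_ltr_len,max_ltr_len length bounds for each repeat copy (bp).
#' @param min_identity minimum percent identity of the pair.
#' @param k seed k-mer size.
#' @param band diagonal band width for seed grouping.
#' @param margin bp of slack added around the seed span before polishing.
#' @return data.frame with columns left_start, left_end, right_start,
#'   right_end (0-based half-open window coordinates), identity_pct, score.
#' @export
find_direct_repeats <- function(window, min_ltr_len = 100L,
                                max_ltr_len = 3000L, min_identity = 80,
                                k = 12L, band = 32L, margin = 200L) {
  if (is.list(window)) window <- window$seq
  L <- nchar(window)
  if (L < 2L * min_ltr_len) return(empty_ltr_frame())
  mid <- L %/% 2L
  left <- substr(window, 1L, mid)
  right <- substr(window, mid + 1L, L)
  seeds <- seed_matches(left, right, k)
  if (!nrow(seeds)) return(empty_ltr_frame())
  # pb is in window coordinates already (offset mid); diagonal = pb - pa
  seeds$diag <- seeds$pb - seeds$pa
  seeds <- seeds[order(seeds$diag, seeds$pa), , drop = FALSE]
  grp <- cumsum(c(1L, diff(seeds$diag) > band))
  wc <- strsplit(window, "")[[1]]
  cands <- lapply(split(seeds, grp), function(g) {
    span <- max(g$pa) + k - min(g$pa)
    if (span < min_ltr_len %/% 2L) return(NULL)
    polish_candidate(wc, g, k, margin)
  })
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (!length(cands)) return(empty_ltr_frame())
  df <- do.call(rbind, cands)
  len_l <- df$left_end - df$left_start
  len_r <- df$right_end - df$right_start
  df <- df[len_l >= min_ltr_len & len_l <= max_ltr_len &
           len_r >= min_ltr_len & len_r <= max_ltr_len &
           df$identity_pct >= min_identity &
           df$left_end <= df$right_start, , drop = FALSE]
  if (!nrow(df)) return(empty_ltr_frame())
  # drop near-duplicate candidates from adjacent bands: keep best score
  # among pairs whose left copies overlap
  df <- df[order(-df$score, -(df$left_end - df$left_start),
                 df$left_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$left_start[i] < df$left_end[j] &&
          df$left_end[i] > df$left_start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_ltr_frame <- function() {
  data.frame(left_start = integer(), left_end = integer(),
             right_start = integer(), right_end = integer(),
             identity_pct = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

# Shared exact k-mers between two strings; returns 0-based positions, pb
# shifted by nchar(a) so both are window coordinates.
seed_matches <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) {
    return(data.frame(pa = integer(), pb = integer()))
  }
  ka <- substring(a, 1:(na - k + 1L), k:na)
  kb <- substring(b, 1:(nb - k + 1L), k:nb)
  common <- intersect(unique(ka), unique(kb))
  if (!length(common)) return(data.frame(pa = integer(), pb = integer()))
  ia <- split(seq_along(ka) - 1L, ka)[common]
  ib <- split(seq_along(kb) - 1L, kb)[common]
  # cross product per k-mer: every position in a paired with every one in b
  pa <- unlist(mapply(function(x, y) rep(x, each = length(y)),
                      ia, ib, SIMPLIFY = FALSE), use.names = FALSE)
  pb <- unlist(mapply(function(x, y) rep(y, times = length(x)),
                      ia, ib, SIMPLIFY = FALSE), use.names = FALSE)
  data.frame(pa = pa, pb = pb + na)
}

# Refine one seed band into a repeat-pair candidate. Every distinct seed
# diagonal in the band is scanned for its maximal-scoring ungapped segment
# (match +1, mismatch -2, roughly the log-likelihood ratio of "inside a
# slightly diverged repeat" vs "random flank"), and the best segment wins.
# Gapped divergence shifts copies onto several nearby diagonals; each is
# still scanned, at the cost of boundary precision for the shifted part.
polish_candidate <- function(wc, g, k, margin) {
  L <- length(wc)
  best <- NULL
  for (d in unique(g$diag)) {
    sub <- g[g$diag == d, , drop = FALSE]
    lo <- max(0L, min(sub$pa) - margin)
    hi <- min(max(sub$pa) + k + margin, L - d)
    if (hi - lo < k) next
    idx <- lo:(hi - 1L)
    m <- wc[idx + 1L] == wc[idx + d + 1L]
    seg <- max_scoring_segment(ifelse(m, 1, -2))
    if (is.null(seg)) next
    n_match <- sum(m[seg[1]:seg[2]])
    len <- seg[2] - seg[1] + 1L
    cand <- data.frame(
      left_start = lo + seg[1] - 1L, left_end = lo + seg[2],
      right_start = lo + seg[1] - 1L + d, right_end = lo + seg[2] + d,
      identity_pct = 100 * n_match / len,
      score = 2 * n_match - 3 * (len - n_match),
      stringsAsFactors = FALSE)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# Kadane scan; returns c(start, end) 1-based inclusive indices or NULL.
# Ties broken toward the earlier, longer segment deterministically.
max_scoring_segment <- function(score) {
  best <- -Inf
  best_s <- best_e <- 0L
  cur <- 0
  cur_s <- 1L
  for (i in seq_along(score)) {
    if (cur <= 0) {
      cur <- score[i]
      cur_s <- i
    } else {
      cur <- cur + score[i]
    }
    if (cur > best) {
      best <- cur
      best_s <- cur_s
      best_e <- i
    }
  }
  if (best <= 0) return(NULL)
  c(best_s, best_e)
}

#' Call a provirus from an env-ORF and its repeat candidates
#'
#' Selects the highest-scoring candidate pair that brackets the env-ORF
#' (ties: longer repeat, then smaller left start). When no candidate
#' brackets the ORF the call carries no LTR pair and the provirus interval
#' defaults to the ORF itself.
#'
#' @param env_orf list/one-row data.frame with `start` and `end` in window
#'   coordinates (use [extract_window()]'s `orf_start`/`orf_end`).
#' @param candidates data.frame from [find_direct_repeats()].
#' @param internal_orfs optional data.frame of gene-labelled internal ORFs.
#' @return list of class `provirus_call`: `env_orf`, `ltr_pair` (one-row
#'   data.frame or `NULL`), `internal_orfs`, `provirus_start`,
#'   `provirus_end` (window coordinates).
#' @export
call_provirus <- function(env_orf, candidates, internal_orfs = NULL) {
  os <- as.integer(env_orf$start)
  oe <- as.integer(env_orf$end)
  pair <- NULL
  if (nrow(candidates)) {
    br <- candidates[candidates$left_end <= os &
                     candidates$right_start >= oe, , drop = FALSE]
    if (nrow(br)) {
      len <- (br$left_end - br$left_start) + (br$right_end - br$right_start)
      br <- br[order(-br$score, -len, br$left_start), , drop = FALSE]
      pair <- br[1, , drop = FALSE]
    }
  }
  structure(list(
    env_orf = env_orf,
    ltr_pair = pair,
    internal_orfs = internal_orfs,
    provirus_start = if (is.null(pair)) os else pair$left_start,
    provirus_end = if (is.null(pair)) oe else pair$right_end
  ), class = "provirus_call")
}

#' @export
print.provirus_call <- function(x, ...) {
  cat(sprintf("<provirus_call> span [%d, %d)%s\n", x$provirus_start,
              x$provirus_end,
              if (is.null(x$ltr_pair)) ", no LTR pair (identity -)"
              else sprintf(", LTR identity %.1f%%", x$ltr_pair$identity_pct)))
  invisible(x)
}
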