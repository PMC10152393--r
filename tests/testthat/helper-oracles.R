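# Independent oracles, deliberately implemented with different machinery
# than the package code paths they check.

STOP_CODONS <- c("TAA", "TAG", "TGA")

oracle_revcomp <- function(seq) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(seq, "")[[1]])), collapse = "")
}

# Brute-force six-frame ORF scan: walks the codon vector of every frame and
# strand, cutting segments at stop codons.
oracle_find_orfs <- function(seq, min_codons,
                             mode = c("start_to_stop", "stop_to_stop")) {
  mode <- match.arg(mode)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    L <- nchar(s)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3L
      if (n_cod < 1L) next
      cod_start <- frame + 3L * (0:(n_cod - 1L))
      codons <- substring(s, cod_start + 1L, cod_start + 3L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      bounds <- c(0L, which(is_stop), n_cod + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        first <- bounds[b] + 1L                 # codon index after stop
        stop_at <- bounds[b + 1L]               # codon index of stop
        if (stop_at <= first) next
        has_stop <- stop_at <= n_cod
        start_cod <- if (mode == "stop_to_stop") first else {
          hits <- which(is_atg[first:(stop_at - 1L)])
          if (!length(hits)) next
          first + hits[1L] - 1L
        }
        aa_len <- stop_at - start_cod
        if (aa_len < min_codons) next
        nt_start <- cod_start[start_cod]
        nt_end <- frame + 3L * (stop_at - 1L) + if (has_stop) 3L else 0L
        if (strand == "-") {
          tmp <- L - nt_end
          nt_end <- L - nt_start
          nt_start <- tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          start = nt_start, end = nt_end, strand = strand, frame = frame,
          aa_len = aa_len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive enumeration of all profile-HMM state paths (local, uni-hit,
# free entry/exit at match states); feasible for M <= 3, short sequences.
oracle_viterbi <- function(profile, aa_seq) {
  x <- match(strsplit(aa_seq, "")[[1]], profile$alphabet)
  L <- length(x)
  M <- profile$M
  lom <- profile$match - matrix(profile$null, M, 20, byrow = TRUE)
  loi <- profile$insert - matrix(profile$null, M, 20, byrow = TRUE)
  tr <- profile$trans
  em <- function(k, i) if (is.na(x[i])) 0 else lom[k, x[i]]
  ei <- function(k, i) if (is.na(x[i])) 0 else loi[k, x[i]]
  best <- -Inf
  rec <- function(state, k, i, sc) {
    if (state == "M") best <<- max(best, sc)    # free exit from match
    if (k >= M) return(invisible())
    if (state == "M") {
      if (i < L) rec("M", k + 1L, i + 1L, sc + tr[k, 1] + em(k + 1L, i + 1L))
      if (i < L) rec("I", k, i + 1L, sc + tr[k, 2] + ei(k, i + 1L))
      rec("D", k + 1L, i, sc + tr[k, 3])
    } else if (state == "I") {
      if (i < L) rec("M", k + 1L, i + 1L, sc + tr[k, 4] + em(k + 1L, i + 1L))
      if (i < L) rec("I", k, i + 1L, sc + tr[k, 5] + ei(k, i + 1L))
    } else {
      if (i < L) rec("M", k + 1L, i + 1L, sc + tr[k, 6] + em(k + 1L, i + 1L))
      rec("D", k + 1L, i, sc + tr[k, 7])
    }
  }
  for (i in seq_len(L)) {
    for (k in seq_len(M)) rec("M", k, i, em(k, i))
  }
  max(best, 0) / log(2)
}

# Random toy profile over a reduced 4-letter emission alphabet (all mass on
# A/C/D/E), well-behaved transitions.
random_toy_profile <- function(M, name = "toy") {
  rnd_simplex <- function(n) {
    v <- stats::rgamma(n, 1)
    v / sum(v)
  }
  match <- t(vapply(seq_len(M), function(k) {
    p <- numeric(20)
    p[1:4] <- rnd_simplex(4)
    p
  }, numeric(20)))
  insert <- t(vapply(seq_len(M), function(k) {
    p <- numeric(20)
    p[1:4] <- rnd_simplex(4)
    p
  }, numeric(20)))
  trans <- t(vapply(seq_len(M), function(k) {
    c(rnd_simplex(3), rnd_simplex(2), rnd_simplex(2))
  }, numeric(7)))
  trans[M, ] <- c(trans[M, 1] + trans[M, 3], trans[M, 2], 0,
                  trans[M, 4], trans[M, 5], 1, 0)
  phmm_profile(name, match, insert, trans)
}

# Naive sliding-window motif matcher; `pattern` is a list of allowed
# character vectors per position (NULL = any residue or X).
oracle_motif_positions <- function(aa_seq, pattern) {
  chars <- strsplit(aa_seq, "")[[1]]
  w <- length(pattern)
  n <- length(chars)
  if (n < w) return(integer())
  hits <- integer()
  for (s in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      ch <- chars[s + j - 1L]
      if (is.null(pattern[[j]])) {
        if (ch == "*") { ok <- FALSE; break }
      } else if (!ch %in% pattern[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_aa <- function(n, letters = ervmine:::AA_ALPHABET) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
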