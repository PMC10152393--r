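# Profile hidden Markov models for retroviral protein classification.
#
# Profiles are read from (and written to) HMMER3 ASCII files and scored
# against ORF translations with a uni-hit local Viterbi: free entry into any
# match state, free exit from any match state, emissions as log-odds against
# a uniform amino-acid null. Scores are reported in bits and converted to
# E-values through the Viterbi Gumbel calibration (STATS LOCAL VITERBI).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# log-probability floor standing in for "probability zero"; kept moderate so
# chained forbidden transitions cannot overflow double precision
TRANS_FLOOR <- -1e5

#' Construct a profile HMM object
#'
#' Probabilities are supplied on the probability scale and stored as natural
#' logs. Rows of the emission matrices and the grouped outgoing transitions
#' of every state must each sum to 1.
#'
#' @param name profile name.
#' @param match M x 20 matrix of match-emission probabilities (columns in
#'   [AA_ALPHABET] order).
#' @param insert M x 20 matrix of insert-emission probabilities.
#' @param trans M x 7 matrix of transition probabilities per node, columns
#'   `m->m, m->i, m->d, i->m, i->i, d->m, d->d` (node M's `m->m` is its exit
#'   and `m->d`/`d->d` are 0).
#' @param null length-20 background distribution (default uniform).
#' @param mu,lambda Viterbi Gumbel location/scale in bits; `NA` marks an
#'   uncalibrated profile.
#' @param check_tol tolerance for the sum-to-one checks.
#' @return Object of class `phmm_profile`.
#' @export
phmm_profile <- function(name, match, insert, trans, null = rep(1 / 20, 20),
                         mu = NA_real_, lambda = NA_real_,
                         check_tol = 1e-6) {
  M <- nrow(match)
  stopifnot(ncol(match) == 20L, identical(dim(insert), dim(match)),
            nrow(trans) == M, ncol(trans) == 7L, length(null) == 20L)
  chk_rows <- function(p, what, rows = seq_len(nrow(p))) {
    s <- rowSums(p[rows, , drop = FALSE])
    if (any(abs(s - 1) > check_tol)) {
      stop(what, " rows do not sum to 1 (max deviation ",
           format(max(abs(s - 1))), ")")
    }
  }
  chk_rows(match, "match emission")
  chk_rows(insert, "insert emission")
  mm <- rowSums(trans[, 1:3, drop = FALSE])
  im <- rowSums(trans[, 4:5, drop = FALSE])
  dm <- rowSums(trans[, 6:7, drop = FALSE])
  if (any(abs(c(mm, im, dm) - 1) > check_tol)) {
    stop("state transition groups do not sum to 1")
  }
  if (abs(sum(null) - 1) > check_tol) stop("null model does not sum to 1")
  if (!is.na(lambda) && lambda <= 0) stop("lambda must be > 0")
  safe_log <- function(p) {
    lp <- log(p)
    lp[!is.finite(lp)] <- TRANS_FLOOR
    lp
  }
  structure(list(name = name, M = M, alphabet = AA_ALPHABET,
                 match = safe_log(match), insert = safe_log(insert),
                 trans = safe_log(trans), null = safe_log(null),
                 mu = mu, lambda = lambda,
                 calibrated = !is.na(mu) && !is.na(lambda)),
            class = "phmm_profile")
}

#' @export
print.phmm_profile <- function(x, ...) {
  cat(sprintf("<phmm_profile> %s: M=%d, %s\n", x$name, x$M,
              if (x$calibrated)
                sprintf("Gumbel(mu=%.3f, lambda=%.3f)", x$mu, x$lambda)
              else "uncalibrated"))
  invisible(x)
}

#' Parse HMMER3 ASCII profiles
#'
#' Reads one or more profiles from an HMMER3/f ASCII file. The file's
#' negative-log probability encoding is inverted back to probabilities
#' internally; a `STATS LOCAL VITERBI` line supplies the Gumbel (mu, lambda)
#' and its absence leaves the profile uncalibrated. Only amino-acid
#' profiles are supported.
#'
#' @param path a `.hmm` file.
#' @return A named list of [phmm_profile()] objects.
#' @export
parse_hmmer3 <- function(path) {
  if (!file.exists(path)) stop("HMM file not found: ", path)
  lines <- readLines(path)
  i <- 1L
  n <- length(lines)
  fail <- function(msg, at = i) {
    stop("malformed HMMER3 file ", path, " at line ", at, ": ", msg)
  }
  num <- function(tok, at = i) {
    v <- suppressWarnings(as.numeric(ifelse(tok == "*", Inf, tok)))
    if (anyNA(v)) fail("non-numeric field", at)
    v
  }
  profiles <- list()
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    if (!startsWith(lines[i], "HMMER3")) fail("expected HMMER3 header")
    i <- i + 1L
    name <- NULL; M <- NULL; alph <- NULL
    mu <- NA_real_; lambda <- NA_real_
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok)) {
        key <- tok[1]
        if (key == "NAME") name <- tok[2]
        if (key == "LENG") M <- as.integer(tok[2])
        if (key == "ALPH") alph <- tolower(tok[2])
        if (key == "STATS" && length(tok) >= 5 && tok[2] == "LOCAL" &&
            tok[3] == "VITERBI") {
          mu <- num(tok[4]); lambda <- num(tok[5])
        }
      }
      i <- i + 1L
    }
    if (i > n) fail("missing HMM line", n)
    if (is.null(name) || is.null(M)) fail("missing NAME or LENG")
    if (!identical(alph, "amino")) fail("only amino-acid profiles supported")
    hmm_tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!identical(hmm_tok[-1], AA_ALPHABET)) {
      fail("unexpected emission alphabet")
    }
    i <- i + 2L                          # skip transition-name header
    if (i <= n && grepl("^\\s*COMPO\\s", lines[i])) i <- i + 1L
    if (i + 1L > n) fail("truncated node 0", n)
    i <- i + 2L                          # node 0 insert + transition lines
    match <- matrix(NA_real_, M, 20)
    insert <- matrix(NA_real_, M, 20)
    trans <- matrix(NA_real_, M, 7)
    for (k in seq_len(M)) {
      if (i + 2L > n) fail(paste0("truncated node ", k), n)
      mt <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      node_no <- suppressWarnings(as.integer(mt[1]))
      if (length(mt) < 21L || is.na(node_no) || node_no != k) {
        fail(paste0("bad match line for node ", k))
      }
      match[k, ] <- num(mt[2:21])
      it <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
      if (length(it) < 20L) fail(paste0("bad insert line for node ", k),
                                 i + 1L)
      insert[k, ] <- num(it[1:20], i + 1L)
      tt <- strsplit(trimws(lines[i + 2L]), "\\s+")[[1]]
      if (length(tt) != 7L) fail(paste0("bad transition line for node ", k),
                                 i + 2L)
      trans[k, ] <- num(tt, i + 2L)
      i <- i + 3L
    }
    if (i > n || trimws(lines[i]) != "//") fail("missing // terminator")
    i <- i + 1L
    # file stores -ln(p); invert and rebuild on the probability scale
    profiles[[name]] <- phmm_profile(
      name, exp(-match), exp(-insert), exp(-trans),
      mu = mu, lambda = lambda, check_tol = 1e-4)
  }
  if (!length(profiles)) fail("no profiles found", n)
  profiles
}

#' Write profiles to HMMER3 ASCII
#'
#' @param profiles a [phmm_profile()] or list of them.
#' @param path output `.hmm` path.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(profiles, path) {
  if (inherits(profiles, "phmm_profile")) profiles <- list(profiles)
  fmt <- function(lp) {
    # stored natural log-probabilities back to the file's -ln encoding
    v <- -lp
    out <- sprintf("%.5f", v)
    out[v > 1e4] <- "*"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(c(
      "HMMER3/f [ervmine profile writer]",
      paste0("NAME  ", p$name),
      paste0("LENG  ", p$M),
      "ALPH  amino",
      "RF    no", "MM    no", "CONS  yes", "CS    no", "MAP   yes",
      if (p$calibrated) c(
        sprintf("STATS LOCAL MSV      %8.4f %8.5f", p$mu, p$lambda),
        sprintf("STATS LOCAL VITERBI  %8.4f %8.5f", p$mu, p$lambda),
        sprintf("STATS LOCAL FORWARD  %8.4f %8.5f", p$mu, p$lambda)),
      paste0("HMM          ",
             paste(sprintf("%-8s", AA_ALPHABET), collapse = " ")),
      paste("           ", paste(sprintf("%-8s",
            c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
            collapse = " "))
    ), con)
    uni <- sprintf("%.5f", rep(log(20), 20))
    writeLines(paste0("          ", paste(uni, collapse = "  ")), con)
    writeLines(paste0("          ",
                      paste(c("0.01005", "4.60517", "*", "0.00000", "*",
                              "0.00000", "*"), collapse = "  ")), con)
    for (k in seq_len(p$M)) {
      cons <- AA_ALPHABET[which.max(p$match[k, ])]
      writeLines(sprintf("  %5d   %s %6d %s - -", k,
                         paste(fmt(p$match[k, ]), collapse = "  "),
                         k, cons), con)
      writeLines(paste0("          ",
                        paste(fmt(p$insert[k, ]), collapse = "  ")), con)
      writeLines(paste0("          ",
                        paste(fmt(p$trans[k, ]), collapse = "  ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Local Viterbi bit score of a sequence against a profile
#'
#' Maximum-scoring local alignment (free entry into any match state, free
#' exit from any match state) of the sequence to the profile; emission
#' scores are log-odds against the profile's null model, transitions
#' contribute their log-probabilities. `X` residues (and any letter outside
#' the 20-letter alphabet) emit at background odds, i.e. contribute 0 bits.
#'
#' @param profile a [phmm_profile()].
#' @param aa_seq non-empty amino-acid string.
#' @return Score in bits (0 if no positive-scoring alignment exists).
#' @export
viterbi_score <- function(profile, aa_seq) {
  stopifnot(inherits(profile, "phmm_profile"))
  if (!is.character(aa_seq) || length(aa_seq) != 1L || !nzchar(aa_seq)) {
    stop("aa_seq must be a non-empty string")
  }
  x <- match(strsplit(toupper(aa_seq), "")[[1]], profile$alphabet)
  M <- profile$M
  lom <- profile$match - matrix(profile$null, M, 20, byrow = TRUE)
  loi <- profile$insert - matrix(profile$null, M, 20, byrow = TRUE)
  tr <- profile$trans
  tMM <- tr[, 1]; tMI <- tr[, 2]; tMD <- tr[, 3]
  tIM <- tr[, 4]; tII <- tr[, 5]; tDM <- tr[, 6]; tDD <- tr[, 7]
  NEG <- -1e9
  prevM <- rep(NEG, M); prevI <- rep(NEG, M); prevD <- rep(NEG, M)
  # D_j at a row depends on M_j-1/D_j-1 of the same row: solved with a
  # cumulative-max scan over the d->d chain instead of an inner loop
  S <- c(0, cumsum(tDD[-M]))
  best <- NEG
  for (i in seq_along(x)) {
    eo_m <- if (is.na(x[i])) numeric(M) else lom[, x[i]]
    eo_i <- if (is.na(x[i])) numeric(M) else loi[, x[i]]
    fromM <- c(NEG, prevM[-M] + tMM[-M])
    fromI <- c(NEG, prevI[-M] + tIM[-M])
    fromD <- c(NEG, prevD[-M] + tDM[-M])
    curM <- eo_m + pmax(0, fromM, fromI, fromD)
    curI <- eo_i + pmax(prevM + tMI, prevI + tII)
    A <- c(NEG, curM[-M] + tMD[-M])
    curD <- S + cummax(A - S)
    best <- max(best, max(curM))
    prevM <- curM; prevI <- curI; prevD <- curD
  }
  max(best, 0) / log(2)
}

#' Gumbel E-value of a bit score
#'
#' `E = db_size * P(score >= bits)` under the profile's Viterbi Gumbel
#' calibration, `P = 1 - exp(-exp(-lambda * (bits - mu)))`.
#'
#' @param profile calibrated [phmm_profile()].
#' @param bits bit score.
#' @param db_size number of profiles compared (hmmscan convention: size of
#'   the profile database).
#' @return Expected number of false positives at this score.
#' @export
evalue <- function(profile, bits, db_size = 1) {
  stopifnot(inherits(profile, "phmm_profile"))
  if (!profile$calibrated) stop("profile '", profile$name,
                                "' is uncalibrated")
  if (db_size <= 0) stop("db_size must be positive")
  db_size * -expm1(-exp(-profile$lambda * (bits - profile$mu)))
}

#' Calibrate a profile's Viterbi Gumbel
#'
#' Scores `n` random sequences drawn from the null model, fixes the Gumbel
#' slope at `lambda = log(2)` (the usual slope for bit scores) and places
#' `mu` by the method of moments (`mean = mu + gamma/lambda`).
#'
#' @param profile a [phmm_profile()].
#' @param n number of null sequences.
#' @param len length of each null sequence (default: profile length).
#' @param lambda fixed Gumbel slope.
#' @param seed integer seed for the null sample.
#' @return The profile with `mu`, `lambda` and `calibrated` set.
#' @export
calibrate_profile <- function(profile, n = 50L, len = NULL,
                              lambda = log(2), seed = 1L) {
  stopifnot(inherits(profile, "phmm_profile"))
  if (is.null(len)) len <- profile$M
  bg <- exp(profile$null)
  bg <- bg / sum(bg)
  scores <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(profile$alphabet, len, replace = TRUE, prob = bg),
                 collapse = "")
      viterbi_score(profile, s)
    }, numeric(1))
  })
  profile$lambda <- lambda
  profile$mu <- mean(scores) - 0.5772156649 / lambda
  profile$calibrated <- TRUE
  profile
}

#' Classify ORFs against a profile database
#'
#' For every ORF the best-scoring profile is retained iff its E-value is at
#' or below `e_threshold` (the full-length envelope screen used 1e-10). The
#' gene class of a hit comes from `class_map`, or by default from the
#' profile-name prefix before the first underscore (e.g. `env_F1` -> `env`).
#'
#' @param orfs data.frame from [find_orfs()] (columns orf_id, aa_seq), or a
#'   named character vector of protein sequences.
#' @param profiles named list of calibrated [phmm_profile()] objects.
#' @param e_threshold inclusion E-value threshold.
#' @param class_map optional named character vector, profile name -> class.
#' @param db_size database size for E-values (default: number of profiles).
#' @return data.frame with columns orf_id, profile, class, bits, evalue,
#'   one row per ORF whose best hit passes the threshold.
#' @export
classify_orfs <- function(orfs, profiles, e_threshold = 1e-10,
                          class_map = NULL, db_size = length(profiles)) {
  if (!length(profiles)) stop("empty profile set")
  if (is.character(orfs)) {
    orfs <- data.frame(orf_id = names(orfs), aa_seq = unname(orfs),
                       stringsAsFactors = FALSE)
  }
  empty <- data.frame(orf_id = character(), profile = character(),
                      class = character(), bits = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (!nrow(orfs)) return(empty)
  pnames <- vapply(profiles, function(p) p$name, character(1))
  get_class <- function(pn) {
    if (!is.null(class_map) && pn %in% names(class_map)) class_map[[pn]]
    else sub("_.*$", "", pn)
  }
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    bits <- vapply(profiles, viterbi_score, numeric(1),
                   aa_seq = orfs$aa_seq[i])
    b <- which.max(bits)
    ev <- evalue(profiles[[b]], bits[b], db_size = db_size)
    if (ev <= e_threshold) {
      data.frame(orf_id = orfs$orf_id[i], profile = pnames[b],
                 class = get_class(pnames[b]), bits = bits[b],
                 evalue = ev, stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a profile HMM from a single protein sequence
#'
#' A simple position-specific profile: each match state emits the template
#' residue with probability `match_p` and every other residue uniformly;
#' inserts emit at background. Used to model the envelope/gag/pro/pol
#' templates of the synthetic benchmark.
#'
#' @param aa_seq template protein (no `*`).
#' @param name profile name.
#' @param match_p emission probability of the template residue.
#' @return An uncalibrated [phmm_profile()]; see [calibrate_profile()].
#' @export
profile_from_protein <- function(aa_seq, name, match_p = 0.6) {
  chars <- strsplit(toupper(aa_seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) stop("template contains non-standard residues")
  M <- length(idx)
  match <- matrix((1 - match_p) / 19, M, 20)
  match[cbind(seq_len(M), idx)] <- match_p
  insert <- matrix(1 / 20, M, 20)
  trans <- matrix(rep(c(0.95, 0.03, 0.02, 0.7, 0.3, 0.7, 0.3), each = M),
                  M, 7)
  trans[M, ] <- c(0.97, 0.03, 0, 0.7, 0.3, 1, 0)  # node M exits
  phmm_profile(name, match, insert, trans)
}
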