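toy_single_state <- function(pA = 0.2) {
  # match state emitting A at pA against the uniform 1/20 null:
  # log-odds = log2(pA * 20) bits
  m <- matrix((1 - pA) / 19, 1, 20)
  m[1, 1] <- pA
  phmm_profile("one", m, matrix(1 / 20, 1, 20),
               matrix(c(1, 0, 0, 1, 0, 1, 0), 1, 7))
}

test_that("HMMER3 parser recovers a hand-encoded toy profile", {
  f <- withr::local_tempfile(fileext = ".hmm")
  # M=2 profile: -ln(p) encoding, emissions uniform except where stated
  u <- sprintf("%.5f", log(20))
  uni <- paste(rep(u, 20), collapse = "  ")
  em1 <- paste(c(sprintf("%.5f", -log(0.4)),
                 rep(sprintf("%.5f", -log(0.6 / 19)), 19)), collapse = "  ")
  tr <- paste(sprintf("%.5f", -log(c(0.9, 0.05, 0.05, 0.6, 0.4, 0.7, 0.3))),
              collapse = "  ")
  trM <- paste(c(sprintf("%.5f", -log(c(0.95, 0.05))), "*",
                 sprintf("%.5f", -log(c(0.6, 0.4, 1.0))), "*"),
               collapse = "  ")
  writeLines(c(
    "HMMER3/f [test]", "NAME  toy2", "LENG  2", "ALPH  amino",
    "STATS LOCAL VITERBI  -9.0000  0.70000",
    paste0("HMM          ",
           paste(sprintf("%-8s", ervmine:::AA_ALPHABET), collapse = " ")),
    "            m->m m->i m->d i->m i->i d->m d->d",
    paste0("          ", uni),                      # node 0 insert
    paste0("          ", tr),                       # node 0 transitions
    paste0("      1   ", em1, "      1 A - - -"),
    paste0("          ", uni),
    paste0("          ", tr),
    paste0("      2   ", uni, "      2 A - - -"),
    paste0("          ", uni),
    paste0("          ", trM),
    "//"), f)
  p <- parse_hmmer3(f)[[1]]
  expect_equal(p$M, 2L)
  expect_equal(p$mu, -9)
  expect_equal(p$lambda, 0.7)
  expect_true(p$calibrated)
  expect_equal(exp(p$match[1, 1]), 0.4, tolerance = 1e-4)
  expect_equal(exp(p$trans[1, ]), c(0.9, 0.05, 0.05, 0.6, 0.4, 0.7, 0.3),
               tolerance = 1e-4)
  # probability-zero transitions ("*") are floored, not -Inf
  expect_true(all(is.finite(p$trans)))

  writeLines(readLines(f)[1:9], f)
  expect_error(parse_hmmer3(f), "malformed|truncated")
})

test_that("profiles survive a write/parse round trip", {
  set.seed(5)
  pr <- profile_from_protein(random_aa(40), "env_X")
  pr <- calibrate_profile(pr, n = 20, len = 60, seed = 2)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(pr, f)
  back <- parse_hmmer3(f)[[1]]
  expect_equal(back$M, pr$M)
  expect_equal(back$mu, pr$mu, tolerance = 1e-3)
  expect_equal(max(abs(back$match - pr$match)), 0, tolerance = 1e-4)
  expect_equal(max(abs(back$trans - pr$trans)), 0, tolerance = 1e-4)
})

test_that("single-state alignment scores its emission log-odds in bits", {
  p <- toy_single_state(0.2)                 # log2(0.2 * 20) = 2 bits
  expect_equal(viterbi_score(p, "A"), 2, tolerance = 1e-9)
  # local alignment: flanking residues aligned outside the profile are free
  expect_equal(viterbi_score(p, "WWAWW"), 2, tolerance = 1e-9)
  # X emits at background odds
  expect_equal(viterbi_score(p, "X"), 0, tolerance = 1e-9)
  expect_error(viterbi_score(p, ""), "non-empty")
})

test_that("Viterbi DP equals exhaustive path enumeration on toy profiles", {
  set.seed(77)
  letters4 <- c("A", "C", "D", "E")
  seqs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(letters4), L)), 1, paste, collapse = "")
  }))
  for (M in 1:3) {
    prof <- random_toy_profile(M, paste0("toy", M))
    for (s in seqs) {
      expect_equal(viterbi_score(prof, s), oracle_viterbi(prof, s),
                   tolerance = 1e-9)
    }
  }
})

test_that("mismatching a positive-log-odds match column never raises the score", {
  set.seed(12)
  tpl <- random_aa(25)
  prof <- profile_from_protein(tpl, "m")
  base <- viterbi_score(prof, tpl)
  for (pos in c(3L, 12L, 20L)) {
    mutated <- tpl
    substr(mutated, pos, pos) <- setdiff(ervmine:::AA_ALPHABET,
                                         substr(tpl, pos, pos))[1]
    expect_lte(viterbi_score(prof, mutated), base)
  }
})

test_that("Gumbel E-values match the closed form and scale with db size", {
  p <- phmm_profile("cal", matrix(1 / 20, 1, 20), matrix(1 / 20, 1, 20),
                    matrix(c(1, 0, 0, 1, 0, 1, 0), 1, 7),
                    mu = 0, lambda = 0.693)
  expect_equal(evalue(p, 10, db_size = 1),
               1 - exp(-exp(-0.693 * 10)), tolerance = 1e-12)
  expect_equal(evalue(p, 10, db_size = 1), 9.77e-4, tolerance = 1e-2)
  # at bits = mu the Gumbel puts 1 - 1/e of the mass above
  expect_equal(evalue(p, 0, db_size = 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evalue(p, 7, db_size = 10), 10 * evalue(p, 7, db_size = 1),
               tolerance = 1e-12)
  # monotone non-increasing in bits
  bits <- seq(-5, 40, by = 0.5)
  ev <- vapply(bits, function(b) evalue(p, b, 3), numeric(1))
  expect_true(all(diff(ev) <= 0))
  uncal <- toy_single_state()
  expect_error(evalue(uncal, 5), "uncalibrated")
})

test_that("classification keeps planted templates and rejects shuffles", {
  set.seed(9)
  tpl <- random_aa(300)
  prof <- calibrate_profile(profile_from_protein(tpl, "env_t"),
                            n = 30, len = 300, seed = 4)
  shuffled <- paste(sample(strsplit(tpl, "")[[1]]), collapse = "")
  hits <- classify_orfs(c(planted = tpl, noise = shuffled), list(prof),
                        e_threshold = 1e-10)
  expect_equal(hits$orf_id, "planted")
  expect_equal(hits$class, "env")
  expect_lte(hits$evalue, 1e-10)
  expect_equal(nrow(classify_orfs(character(), list(prof))), 0L)
  expect_error(classify_orfs(c(a = "MKV"), list()), "empty profile set")
})
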