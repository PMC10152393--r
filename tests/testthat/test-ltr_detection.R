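rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

planted_window <- function(ltr_len = 300, gap = 6000, flank = 2000,
                           mutate_p = 0) {
  ltr <- rand_dna(ltr_len)
  l5 <- ervmine:::mutate_seq(ltr, mutate_p)
  l3 <- ervmine:::mutate_seq(ltr, mutate_p)
  list(win = paste0(rand_dna(flank), l5, rand_dna(gap), l3,
                    rand_dna(flank)),
       truth = c(flank, flank + ltr_len, flank + ltr_len + gap,
                 flank + 2 * ltr_len + gap),
       l5 = l5, l3 = l3)
}

test_that("windows are clipped at contig bounds and map back", {
  g <- genome_sequence("c", rand_dna(80000))
  w <- extract_window(g, list(start = 50000, end = 51500))
  expect_equal(w$offset, 40000L)
  expect_equal(nchar(w$seq), 21500L)
  expect_equal(w$orf_start, 10000L)
  # window coordinate + offset = genome coordinate
  expect_identical(substr(w$seq, w$orf_start + 1, w$orf_end),
                   substr(g$seq, 50001, 51500))
  w2 <- extract_window(g, list(start = 200, end = 1700))
  expect_equal(w2$offset, 0L)
  expect_equal(w2$orf_start, 200L)
})

test_that("identical planted repeats are recovered exactly", {
  set.seed(2)
  pw <- planted_window()
  cands <- find_direct_repeats(pw$win)
  expect_equal(nrow(cands), 1L)
  expect_equal(as.integer(cands[1, 1:4]), pw$truth)
  expect_equal(cands$identity_pct, 100)
})

test_that("diverged repeats are found with near-true identity", {
  set.seed(3)
  for (rep in 1:10) {
    pw <- planted_window(mutate_p = 0.0125)   # ~2.5% pairwise divergence
    cands <- find_direct_repeats(pw$win)
    expect_gte(nrow(cands), 1L)
    true_id <- 100 * mean(strsplit(pw$l5, "")[[1]] ==
                            strsplit(pw$l3, "")[[1]])
    expect_lt(abs(cands$identity_pct[1] - true_id), 2)
  }
})

test_that("repeats shorter than min_ltr_len are rejected", {
  set.seed(4)
  pw <- planted_window(ltr_len = 80)
  expect_equal(nrow(find_direct_repeats(pw$win, min_ltr_len = 100)), 0L)
  # but a lower bound admits them
  expect_gte(nrow(find_direct_repeats(pw$win, min_ltr_len = 60)), 1L)
})

test_that("candidate search is deterministic and never overlaps the ORF", {
  set.seed(5)
  pw <- planted_window(mutate_p = 0.01)
  c1 <- find_direct_repeats(pw$win)
  c2 <- find_direct_repeats(pw$win)
  expect_identical(c1, c2)
  orf <- list(start = pw$truth[2] + 500, end = pw$truth[3] - 500)
  call <- call_provirus(orf, c1)
  expect_false(is.null(call$ltr_pair))
  expect_lte(call$ltr_pair$left_end, orf$start)
  expect_gte(call$ltr_pair$right_start, orf$end)
})

test_that("the bracketing constraint dominates candidate score", {
  cands <- data.frame(
    left_start = c(100L, 2000L), left_end = c(400L, 2300L),
    right_start = c(9000L, 4000L), right_end = c(9300L, 4300L),
    identity_pct = c(90, 99), score = c(100, 500))
  orf <- list(start = 5000L, end = 6400L)
  call <- call_provirus(orf, cands)
  # the higher-scoring pair does not bracket the ORF and must lose
  expect_equal(call$ltr_pair$left_start, 100L)
  expect_equal(call$provirus_start, 100L)
  expect_equal(call$provirus_end, 9300L)
  # no bracketing candidate: call carries no pair
  call2 <- call_provirus(orf, cands[2, ])
  expect_null(call2$ltr_pair)
  expect_equal(call2$provirus_start, 5000L)
})

test_that("simulated proviruses yield accurate LTR boundaries", {
  cfg <- sim_config(seed = 424, background_length = 6e5,
                    copies_per_family = c(3L, 2L),
                    decayed_per_family = c(0L, 0L))
  sim <- make_genome(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    win <- extract_window(sim$genome,
                          list(start = tr$env_start, end = tr$env_end))
    call <- call_provirus(
      list(start = tr$env_start - win$offset, end = tr$env_end - win$offset),
      find_direct_repeats(win))
    expect_false(is.null(call$ltr_pair))
    lp <- call$ltr_pair
    got <- sort(c(lp$left_start, lp$left_end, lp$right_start,
                  lp$right_end) + win$offset)
    want <- sort(c(tr$ltr5_start, tr$ltr5_end, tr$ltr3_start, tr$ltr3_end))
    expect_lte(max(abs(got - want)), 5)
  }
})
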