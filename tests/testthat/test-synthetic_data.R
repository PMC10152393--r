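small_cfg <- function(seed = 77) {
  sim_config(seed = seed, background_length = 3e5,
             copies_per_family = c(2L, 1L), decayed_per_family = c(1L, 0L))
}

test_that("generation is bit-for-bit deterministic under a fixed seed", {
  s1 <- make_genome(small_cfg())
  s2 <- make_genome(small_cfg())
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$truth, s2$truth)
  s3 <- make_genome(small_cfg(seed = 78))
  expect_false(identical(s1$genome$seq, s3$genome$seq))
})

test_that("truth coordinates reproduce the planted provirus bytes", {
  sim <- make_genome(small_cfg())
  tr <- sim$truth
  expect_equal(nrow(tr), 3L)
  # inserts non-overlapping with >= 25 kb spacing
  ord <- order(tr$insert_start)
  gaps <- tr$insert_start[ord][-1] - tr$insert_end[ord][-nrow(tr)]
  expect_true(all(gaps >= 25000))
  for (i in seq_len(nrow(tr))) {
    got <- extract_interval(sim$genome, tr$insert_start[i],
                            tr$insert_end[i], tr$strand[i])
    expect_identical(got, unname(sim$provirus_seqs[tr$provirus_id[i]]))
  }
})

test_that("truth GFF3 round-trips through the annotation reader", {
  sim <- make_genome(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  back <- read_gff3(paths[["gff3"]])
  pv <- back[back$type == "provirus", ]
  pv <- pv[order(pv$start), ]
  expect_equal(pv$start, sort(sim$truth$insert_start))
  expect_equal(pv$end[order(pv$start)],
               sim$truth$insert_end[order(sim$truth$insert_start)])
  env <- back[back$type == "CDS", ]
  expect_setequal(env$start, sim$truth$env_start)
  genome_back <- read_fasta(paths[["fasta"]])[[1]]
  expect_identical(genome_back$seq, sim$genome$seq)
})

test_that("env templates carry their diagnostics and families stay apart", {
  set.seed(61)
  t1 <- make_env_template(450)
  t2 <- make_env_template(450)
  expect_gte(nchar(t1$aa), 420)
  expect_identical(find_rdr_motif(t1$aa), t1$rdr_pos)
  expect_identical(find_furin_site(t1$aa), t1$furin_site)
  expect_identical(translate_nt(t1$nt), t1$aa)
  expect_lt(protein_identity(t1$aa, t2$aa), 80)
})

test_that("LTR divergence matches the binomial expectation", {
  set.seed(63)
  n_rep <- 200
  ltr_len <- 600
  age <- 1.5
  mism <- vapply(seq_len(n_rep), function(i) {
    pair <- make_ltr_pair(age, ltr_len = ltr_len)
    sum(strsplit(pair$ltr5, "")[[1]] != strsplit(pair$ltr3, "")[[1]])
  }, numeric(1))
  expected <- ltr_len * age * 2.6e-3
  se <- sqrt(expected) / sqrt(n_rep)      # Poisson-scale error of the mean
  expect_lt(abs(mean(mism) - expected), 3 * se + 0.05)
  # age zero leaves the copies identical
  pair0 <- make_ltr_pair(0)
  expect_identical(pair0$ltr5, pair0$ltr3)
})

test_that("decayed copies fail the 400-codon screen and intact ones pass", {
  sim <- make_genome(small_cfg())
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    pv <- sim$provirus_seqs[[tr$provirus_id]]
    orfs <- find_orfs(pv, min_codons = 400, both_strands = FALSE)
    # local env coordinates on the provirus' own strand
    if (tr$strand == "+") {
      loc <- c(tr$env_start, tr$env_end) - tr$insert_start
    } else {
      loc <- tr$insert_end - c(tr$env_end, tr$env_start)
    }
    env_found <- any(orfs$start == loc[1] & orfs$end == loc[2])
    expect_equal(env_found, tr$env_intact)
  }
})

test_that("infeasible packing is refused", {
  cfg <- sim_config(seed = 1, background_length = 60000,
                    copies_per_family = c(3L, 1L),
                    decayed_per_family = c(0L, 0L))
  expect_error(make_genome(cfg), "infeasible packing")
})
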