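mutated_protein <- function(base, positions, letters = "W") {
  chars <- strsplit(base, "")[[1]]
  chars[positions] <- ifelse(chars[positions] == letters, "Y", letters)
  paste(chars, collapse = "")
}

test_that("family clustering is single linkage on percent identity", {
  set.seed(41)
  base <- random_aa(100)
  seqs <- c(x = base, y = base)
  fam <- cluster_families(seqs)
  expect_equal(attr(fam, "families")$copy_number, 2L)

  far <- c(a = random_aa(100), b = random_aa(100))
  fam2 <- cluster_families(far, identity_threshold = 80)
  expect_equal(nrow(attr(fam2, "families")), 2L)

  # chain: A~B 85%, B~C 85%, A~C 70% -> one family by single linkage
  # (substitutions scattered so alignments stay gap-free)
  A <- base
  B <- mutated_protein(A, seq(1, 85, by = 6))        # 15 sites, 85% to A
  C <- mutated_protein(B, seq(4, 88, by = 6))        # 15 more, 70% to A
  expect_equal(protein_identity(A, B), 85, tolerance = 0.5)
  expect_equal(protein_identity(A, C), 70, tolerance = 0.5)
  fam3 <- cluster_families(c(A = A, B = B, C = C), identity_threshold = 80)
  expect_equal(nrow(attr(fam3, "families")), 1L)
  expect_equal(attr(fam3, "families")$copy_number, 3L)
})

test_that("clustering partitions the input and ignores input order", {
  set.seed(43)
  g1 <- random_aa(80)
  g2 <- random_aa(80)
  seqs <- c(`c:500-740(+)` = g1,
            `c:100-340(+)` = mutated_protein(g1, 1:6),
            `c:900-1140(-)` = g2)
  f_fwd <- cluster_families(seqs)
  f_rev <- cluster_families(rev(seqs))
  expect_equal(f_fwd[order(f_fwd$orf_id), ],
               f_rev[order(f_rev$orf_id), ], ignore_attr = TRUE)
  # partition: every id exactly once
  expect_setequal(f_fwd$orf_id, names(seqs))
  expect_false(any(duplicated(f_fwd$orf_id)))
  # naming: bigger family first; it holds the leftmost member
  fams <- attr(f_fwd, "families")
  expect_equal(fams$copy_number, c(2L, 1L))
  expect_match(fams$members[1], "c:100-340")
})

test_that("multiple alignment preserves sequences and handles indels", {
  set.seed(47)
  base <- random_aa(60)
  msa <- progressive_msa(c(a = base, b = base, c = base))
  expect_equal(msa$rows, rep(base, 3))

  with_del <- paste0(substr(base, 1, 30), substr(base, 34, 60))
  msa2 <- progressive_msa(c(a = base, b = with_del))
  expect_equal(sum(strsplit(msa2$rows[2], "")[[1]] == "-"), 3L)
  # degapping recovers inputs
  expect_equal(gsub("-", "", msa2$rows[1]), base)
  expect_equal(gsub("-", "", msa2$rows[2]), with_del)

  single <- progressive_msa(c(only = base))
  expect_equal(single$rows, base)
})

test_that("sparse-column trimming keeps the 60% boundary", {
  rows <- c(a = "AC-A", b = "AC-A", c = "A--A", d = "A-CA", e = "A-CA")
  msa <- ervmine:::new_msa(names(rows), unname(rows))
  # col2: 2/5 = 40% residues -> removed; col3: 2/5 -> removed
  trimmed <- trim_sparse_columns(msa, 0.6)
  expect_equal(trimmed$rows, rep("AA", 5))
  # exactly at the boundary (3/5 = 60%) a column survives
  msa2 <- ervmine:::new_msa(c("a", "b", "c", "d", "e"),
                            c("AC", "AC", "AC", "A-", "A-"))
  expect_equal(trim_sparse_columns(msa2, 0.6)$n_columns, 2L)
  # gap-free alignments pass through unchanged
  msa3 <- ervmine:::new_msa(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(trim_sparse_columns(msa3, 0.6), msa3)
  expect_error(trim_sparse_columns(
    ervmine:::new_msa(c("a", "b"), c("-", "-")), 0.6), "all")
})

test_that("consensus takes the plurality with lexicographic ties", {
  msa <- ervmine:::new_msa(c("a", "b", "c"), c("AAT", "AAT", "TAT"))
  expect_equal(consensus_sequence(msa), "AAT")
  # column tie {A, T} -> A
  msa2 <- ervmine:::new_msa(c("a", "b"), c("AT", "TT"))
  expect_equal(consensus_sequence(msa2), "AT")
  # k identical rows reproduce the row for any k
  for (k in c(1, 2, 5)) {
    m <- ervmine:::new_msa(paste0("s", 1:k), rep("MKVLAW", k))
    expect_equal(consensus_sequence(m), "MKVLAW")
  }
})

test_that("neighbour joining matches closed forms and additive trees", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  tip_edge <- function(tree, label) {
    tree$edge.length[tree$edge[, 2] == match(label, tree$tip.label)]
  }
  expect_equal(tip_edge(tr, "A"), 1)
  expect_equal(tip_edge(tr, "B"), 1)
  expect_equal(tip_edge(tr, "C"), 3)

  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  tr2 <- nj_tree(d2)
  expect_equal(sort(tr2$edge.length), c(1.5, 1.5))

  # additive 4-taxon metric: ((A:1,B:2):1,(C:3,D:1)) with internal 1
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4, dimnames = list(lab, lab))
  tr4 <- nj_tree(d4)
  expect_equal(tip_edge(tr4, "A"), 1)
  expect_equal(tip_edge(tr4, "B"), 2)
  expect_equal(tip_edge(tr4, "C"), 3)
  expect_equal(tip_edge(tr4, "D"), 1)
  # recovered distances reproduce the additive matrix exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr4))[lab, lab], d4)

  bad <- d3
  bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
})

test_that("p-distance matrices from alignments feed the tree helper", {
  msa <- ervmine:::new_msa(c("a", "b", "c"),
                           c("ACGTAC", "ACGTAA", "TTTTAA"))
  d <- msa_p_distance(msa)
  expect_equal(d["a", "b"], 1 / 6)
  expect_equal(d["b", "c"], 3 / 6)
  expect_equal(d["a", "c"], 4 / 6)
  expect_equal(d, t(d))
})
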