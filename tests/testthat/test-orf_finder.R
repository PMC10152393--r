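make_coding <- function(n_codons, seed = 1) {
  # ATG + (n_codons - 1) random sense codons, no terminal stop
  set.seed(seed)
  aa <- c("M", sample(ervmine:::AA_ALPHABET, n_codons - 1L, TRUE))
  ervmine:::aa_to_nt(aa)
}

test_that("minimal and boundary ORFs are reported with exact spans", {
  o <- find_orfs("ATGTAA", min_codons = 1, both_strands = FALSE)
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_seq, "M")
  expect_equal(c(o$start, o$end), c(0L, 6L))
  expect_true(o$has_stop)

  # 400 codons from ATG + stop: 1,203-nt interval, passes the >=400 screen
  nt <- paste0(make_coding(400), "TAA")
  o <- find_orfs(nt, min_codons = 400, both_strands = FALSE)
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_len, 400L)
  expect_equal(o$end - o$start, 1203L)
  # strict > 400 reading excludes the boundary case
  expect_equal(nrow(find_orfs(nt, min_codons = 400, both_strands = FALSE,
                              strict_greater = TRUE)), 0L)
})

test_that("a segment truncated by the contig end has no terminal stop", {
  nt <- make_coding(30)
  o <- find_orfs(nt, min_codons = 10, both_strands = FALSE)
  o <- o[o$frame == 0L, ]      # other frames may hold chance ORFs
  expect_equal(nrow(o), 1L)
  expect_false(o$has_stop)
  expect_equal(o$end - o$start, 90L)
})

test_that("find_orfs agrees with the brute-force six-frame oracle", {
  set.seed(101)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    for (mode in c("start_to_stop", "stop_to_stop")) {
      got <- find_orfs(s, min_codons = 20, mode = mode)
      want <- oracle_find_orfs(s, 20, mode)
      expect_equal(got[, c("start", "end", "strand", "frame", "aa_len")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors coordinates", {
  set.seed(7)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    L <- nchar(s)
    fwd <- find_orfs(s, min_codons = 15)
    rev <- find_orfs(reverse_complement(s), min_codons = 15)
    mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                           strand = ifelse(rev$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$end,
                               mirrored$strand), ]
    orig <- fwd[order(fwd$start, fwd$end, fwd$strand),
                c("start", "end", "strand")]
    expect_equal(orig, mirrored, ignore_attr = TRUE)
  }
})

test_that("start ORFs nest uniquely inside stop-to-stop segments", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  starts <- find_orfs(s, min_codons = 10, mode = "start_to_stop")
  segs <- find_orfs(s, min_codons = 1, mode = "stop_to_stop")
  for (i in seq_len(nrow(starts))) {
    container <- segs$strand == starts$strand[i] &
      segs$frame == starts$frame[i] &
      segs$start <= starts$start[i] & segs$end >= starts$end[i]
    expect_equal(sum(container), 1L)
  }
  # one ORF per stop codon and strand
  expect_false(any(duplicated(
    starts[, c("strand", "frame", "end")])))
})

test_that("N-containing codons do not terminate ORFs and flag low confidence", {
  nt <- paste0("ATG", strrep("ANG", 20), "TAA")
  o <- find_orfs(nt, min_codons = 5, both_strands = FALSE)
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_len, 21L)
  expect_true(o$low_confidence)
})

test_that("provirus ORF maps keep both modes above the 300-nt bar", {
  coding <- make_coding(133)                  # 399 coding nt
  nt400 <- paste0("TAA", coding, "TAA")       # ORF span 402 nt > 300
  ann <- annotate_provirus_orfs(nt400)
  expect_setequal(unique(ann$mode), c("stop_to_stop", "start_to_stop"))
  st <- ann[ann$mode == "start_to_stop", ]
  expect_equal(nrow(st), 1L)
  ss <- ann[ann$mode == "stop_to_stop" & ann$frame == st$frame, ]
  expect_true(all(ss$start <= st$start & ss$end >= st$end))

  # 297-nt span (98 codons + stop) is excluded by the > 300 nt rule
  nt299 <- paste0("TAA", make_coding(98), "TAA")
  expect_equal(nrow(annotate_provirus_orfs(nt299)), 0L)

  # a pure stop-codon tract yields no start-to-stop ORFs in any frame
  allstop <- annotate_provirus_orfs(strrep("TAA", 200))
  expect_equal(nrow(allstop[allstop$mode == "start_to_stop", ]), 0L)
})
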