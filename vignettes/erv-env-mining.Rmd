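---
title: "Mining and dating endogenous retrovirus envelope genes"
author: "ervmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and dating endogenous retrovirus envelope genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervmine)
```

## The problem

Endogenous retroviruses (ERVs) are germ-line-integrated retroviral genomes,
structured 5'LTR–*gag*–*pro*–*pol*–*env*–3'LTR. Their envelope (*env*)
genes encode the receptor-binding (SU) and fusogenic (TM) subunits and have
repeatedly been co-opted by host genomes, most famously as placental
syncytins. ervmine implements a complete desk-scale workflow for finding
nearly full-length *env* open reading frames in a genome assembly,
delimiting the provirus around each one through its long terminal repeat
(LTR) pair, dating the insertion from LTR divergence, grouping copies into
families with consensus sequences, and annotating the diagnostic Env
motifs. A seeded simulator generates genomes with planted proviruses of
known age and family structure, so every stage is validated against ground
truth without any external download.

## Pipeline stages and their models

### 1. Long-ORF screen

Nearly full-length Env proteins are found as start-to-stop ORFs of at
least 400 codons (a 1,200-nt coding span), enumerated on all six frames.
Each stop-delimited segment contributes one ORF from its 5'-most ATG;
this counts each locus once rather than emitting nested ORFs for every
internal methionine (an `all_starts` mode exists for the alternative).
Two boundary decisions are deliberate and exposed as flags:

* the threshold is `aa_len >= 400` (`strict_greater = TRUE` gives the
  strict reading);
* the reported interval includes the terminal stop codon when one lies
  inside the contig, so a 400-codon ORF spans 1,203 nt; `aa_len` never
  counts the stop.

Codons containing N translate to `X` and do not terminate an ORF; ORFs
with more than 5% `X` are flagged low-confidence rather than dropped.
Soft-masked (lowercase) input is uppercased on load — masking is not
interpreted.

### 2. Profile-HMM classification

ORF translations are scored against retroviral protein profiles in
HMMER3 ASCII format with a uni-hit local Viterbi: free entry into any
match state, free exit from any match state, emissions as log-odds
against a uniform amino-acid null, insert/delete transitions from the
profile. Bit scores are converted to E-values through the Viterbi Gumbel
(`STATS LOCAL VITERBI` mu/lambda):

$$E = n_\text{profiles}\,\bigl(1 - e^{-e^{-\lambda (s - \mu)}}\bigr)$$

The per-ORF best profile is kept iff $E \le 10^{-10}$, the same
expectation threshold used for the full-scale hmmscan screen. Design
choices, deliberately documented as deviations from the HMMER pipeline:
Viterbi (not Forward) scores, because Viterbi has a clean exhaustive
path-enumeration oracle and a single calibration line; uni-hit local mode
only, since *env*/*gag*/*pol* are each expected as single domains at this
screening stage; `X` residues emit at background odds (0 bits), so N-rich
ORFs are neither favoured nor penalized; and the null model is uniform,
with the Gumbel calibration absorbing the difference for the bundled
profiles. Exact reproduction of hmmscan E-values is a non-goal; the
screen is reproduced in spirit and validated against planted/shuffled
sequences. Profiles built from simulator templates are calibrated by
scoring null sequences with $\lambda = \ln 2$ fixed and $\mu$ placed by
the method of moments.

### 3. LTR direct-repeat calling

The provirus around each *env*-ORF is delimited inside a window of the
ORF ±10 kbp. Exact 12-mer seeds shared between the two window halves are
grouped into diagonal bands (width 32); each distinct diagonal is then
scanned for its maximal-scoring ungapped segment with match +1 and
mismatch −2 — approximately the per-column log-likelihood ratio of
"inside a repeat diverged a few percent" versus "random flank". The
boundary scan replaced a banded local-alignment extension after that
design systematically absorbed chance flank similarity into the repeat
ends (6–8-bp overshoots); the ungapped scan keeps ~98% of boundary calls
within 5 bp at the simulator's divergence range. The cost is reduced
precision when indels split a repeat across diagonals (each diagonal is
still scanned; the best segment wins). Candidates must satisfy
length (100–3,000 bp) and identity (≥ 80%) bounds; the defaults bracket
typical retroviral LTR sizes and the identity floor observed in real
multicopy families (84.4%), and all are configurable. The
highest-scoring candidate that brackets the *env*-ORF becomes the call
(ties: longer repeat, then smaller left start); target-site duplications
and PBS/PPT features are intentionally not used.

### 4. Divergence dating

The two LTRs of a provirus are identical at integration, so under
neutrality their divergence clocks the insertion. The called pair is
globally aligned (match +1, mismatch −1, affine gaps: 5 for the first
gapped position, 1 for each further); the uncorrected p-distance is
mismatches over ungapped columns (pairwise gap deletion, the EMBOSS
distmat default — no Jukes–Cantor correction), identity is
$100(1-d)$ (tables round to one decimal), and the age is

$$T = d / r \quad (\texttt{convention = "paper"})$$

with $r = 2.6\times10^{-3}$ substitutions/site/MY, the genome-wide
neutral rate estimated for monotremes. This convention reproduces the
published arithmetic for the worked example
($d = 3.9\times10^{-3} \Rightarrow T \approx 1.5$ MY). The standard
two-lineage clock $T = d/(2r)$ is also implemented
(`convention = "two_lineage"`); whether the published division by $r$
was an intentional convention is unknowable, so both are provided and
neither is asserted as correct biology. Uncorrected distances saturate,
so estimates are increasingly downward-biased at high ages; within the
simulated regime (≤ 10 MY, $d \le 2.6\%$) the bias is under 2%.

### 5. Families and consensus

*env*-ORF translations are clustered by single linkage on pairwise
global-alignment identity at ≥ 80% — the grouping criterion is a free
parameter because the original grouping method is unstated; 80% cleanly
separates the simulator's within-family (≤ ~5%) from between-family
(≥ 50%) divergence. Families are named deterministically by descending
copy number, then leftmost genomic position. Multicopy families get a
nucleotide consensus: members are aligned with MAFFT L-INS-i
(`--localpair --maxiterate 1000`), columns with less than 60% residues
are removed (the boundary, exactly 60%, is kept — the `rm_gap 60`
semantic), and each column contributes its plurality residue, ties
broken lexicographically for determinism (plurality-tie behaviour of the
classic EMBOSS `cons` is version-dependent). A neighbour-joining tree on
alignment p-distances (negative branches clamped to 0) summarises group
structure; maximum-likelihood phylogenetics is out of scope.

### 6. Env annotation

The furin cleavage motif is the minimal basic site R-x-[RK]-R; among
matches leaving at least 80 residues downstream (a typical TM
ectodomain + anchor + tail), the most C-terminal is taken as the SU/TM
boundary, and the suffix after it is the "TM region" in the sense of the
post-furin subunit, not a predicted membrane helix. The
S-D-G-G-G-x-x-D-x-x-R motif marks the RD114/D-type (RDR) interference
group's ASCT1/ASCT2-binding region. In both patterns `x` matches any
residue including ambiguous `X`, while fixed positions match their exact
letter only, so `X` never satisfies them. Sequences without a furin site
fall back to full length for family alignment, with a warning.

## The synthetic benchmark

`sim_config()` defaults define the package's standard benchmark: a 2-Mb
i.i.d. background at GC 0.45 carrying 12 proviruses in 3 families —
copies 8/2/2, of which 2/1/1 are *env*-decayed, so 8 intact *env* across
3 families with one 6-copy family — with 600-bp LTRs, ages cycled
through 0.5/1.5/5/10 MY, and rate $2.6\times10^{-3}$; the documented
benchmark seed is 42. Each provirus is 5'LTR–gag–pro–pol–env–3'LTR with
a fresh LTR template per insertion; the two LTR copies are mutated
independently at per-site probability $p = d_\text{expected}/2$ so the
expected pairwise p-distance equals $\text{age} \times r$ under the
default convention. Mutation is substitutions-only, at most one hit per
site (bias < 1% for $d \le 0.1$, comfortably covering the observed
regime); an indel mode exists to stress the aligners but is off by
default because p-distance with pairwise deletion is the measured
quantity. Intact *env* copies are rejection-resampled so mutation never
introduces an internal stop or removes the start/stop codon; decayed
copies get stops planted at one and two thirds of *env*, guaranteeing
they fail the 400-codon screen. A tandem stop guard immediately upstream
of *env* pins the reported ORF start to the planted ATG.

What the simulator deliberately does **not** emulate: repeat landscapes
and GC isochores (the background is i.i.d., isolating the repeat
caller's false-positive behaviour), nested insertions, solo LTRs,
target-site duplications, and transcription. Passing the benchmark
therefore demonstrates the algorithms' correctness on clean insertions
of known age — not performance on a real, repeat-rich assembly, where
profile quality and nested elements dominate. The full-scale tallies of
the real platypus/echidna assemblies (2 vs 121 *env*-ORFs, the
seven-group echidna classification, copy numbers 18/77/19) require
multi-GB downloads and the GyDB profile collection and are an optional
integration run outside the test surface.

## Numerical choices

* Probability-zero transitions are floored at $e^{-10^5}$ rather than
  $-\infty$ so the delete-chain scan (a cumulative-max over the d→d
  telescoping sums) cannot produce NaN or catastrophic cancellation.
* E-values use `-expm1(-exp(...))`, stable in the far tail where
  `1 - exp(-x)` underflows.
* Viterbi scores are computed in nats and reported in bits.
* All tie-breaks (consensus residues, candidate ranking, family naming)
  are deterministic; pipeline artifacts are byte-identical across reruns
  of the same inputs, and the GFF3 writer strips the run-date header.
* Benchmark problem sizes (2-Mb genome, 50 repeat-recovery windows,
  200 dating replicates per age class) are the package's documented
  study conditions, sized so the whole validation suite runs on a
  laptop-class single core.

## Known limitations

* The LTR caller anchors on *env*-ORFs; it is not a genome-wide de novo
  LTR-element finder and does not catalogue solo LTRs.
* Dating accuracy is limited by boundary accuracy: a few bp of flank
  absorbed into a called LTR adds spurious mismatches, which matters
  most for very young insertions.
* At the youngest simulated age (0.5 MY) a 600-bp LTR pair expects less
  than one mismatch, so any mean-divergence summary over 200 replicates
  carries ~8% relative sampling error; single-insertion ages in that
  regime are order-of-magnitude statements.
* The Viterbi/Gumbel screen reproduces the hmmscan threshold in spirit;
  E-values are not bit-compatible with HMMER's Forward pipeline.
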