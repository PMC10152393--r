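# Synthetic provirus genomes with ground truth.
#
# The generator plants 5'LTR-gag-pro-pol-env-3'LTR proviruses of known age,
# family and env intactness into an i.i.d. background. The two LTRs of an
# insertion start identical and are mutated independently with per-site
# substitution probability p = expected_d / 2, so their expected pairwise
# p-distance equals age * rate (the "paper" age convention) or
# 2 * age * rate ("two_lineage"). Substitutions only by default (at most
# one hit per site; bias < 1% for d <= 0.1); an indel mode exists to stress
# the aligners.

#' Simulation configuration
#'
#' Defaults define the package's standard benchmark: a 2-Mb background at
#' GC 0.45 carrying 12 proviruses in 3 families (8 intact env-ORFs, of
#' which 6 in the first family; 4 env-decayed copies), 600-bp LTRs, ages
#' cycled from 0.5/1.5/5/10 MY, and the monotreme neutral rate 2.6e-3
#' substitutions/site/MY.
#'
#' @param seed integer seed fixing all outputs bit-for-bit.
#' @param background_length background genome size (bp).
#' @param gc_content background GC fraction in (0, 1).
#' @param copies_per_family integer vector: total copies per family.
#' @param decayed_per_family integer vector: how many of each family's
#'   copies carry ORF-disrupting stops in env.
#' @param ltr_len LTR length (bp).
#' @param age_grid ages (MY) assigned to copies in rotation.
#' @param rate neutral substitution rate (subs/site/MY).
#' @param age_convention `"paper"` or `"two_lineage"`.
#' @param env_codons,gag_codons,pro_codons,pol_codons gene template sizes.
#' @param min_spacing minimum gap between inserts (bp); 25 kb keeps the
#'   +/- 10 kb provirus windows from colliding.
#' @param indel_rate per-site indel probability as a fraction of the
#'   substitution probability (0 = substitutions only).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, background_length = 2e6,
                       gc_content = 0.45,
                       copies_per_family = c(8L, 2L, 2L),
                       decayed_per_family = c(2L, 1L, 1L),
                       ltr_len = 600L,
                       age_grid = c(0.5, 1.5, 5, 10),
                       rate = 2.6e-3,
                       age_convention = c("paper", "two_lineage"),
                       env_codons = 450L, gag_codons = 500L,
                       pro_codons = 280L, pol_codons = 820L,
                       min_spacing = 25000L, indel_rate = 0) {
  age_convention <- match.arg(age_convention)
  stopifnot(gc_content > 0, gc_content < 1, rate > 0, ltr_len >= 50L,
            length(copies_per_family) == length(decayed_per_family),
            all(decayed_per_family <= copies_per_family),
            all(copies_per_family >= 1L), all(age_grid >= 0),
            env_codons >= 420L, indel_rate >= 0)
  structure(list(seed = as.integer(seed),
                 background_length = as.integer(background_length),
                 gc_content = gc_content,
                 n_families = length(copies_per_family),
                 copies_per_family = as.integer(copies_per_family),
                 decayed_per_family = as.integer(decayed_per_family),
                 ltr_len = as.integer(ltr_len), age_grid = age_grid,
                 rate = rate, age_convention = age_convention,
                 env_codons = as.integer(env_codons),
                 gag_codons = as.integer(gag_codons),
                 pro_codons = as.integer(pro_codons),
                 pol_codons = as.integer(pol_codons),
                 min_spacing = as.integer(min_spacing),
                 indel_rate = indel_rate),
            class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# codons per amino acid, standard code, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_ALPHABET]
}

aa_to_nt <- function(aa_chars, codons = codon_table()) {
  paste(vapply(aa_chars, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# substitute each site independently with probability p (uniform over the
# other three bases); optional geometric-length indels at rate
# indel_frac * p
mutate_seq <- function(seq, p, indel_frac = 0) {
  if (p <= 0 && indel_frac <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(stats::runif(n) < p)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)), pick)]
  }
  if (indel_frac > 0) {
    q <- indel_frac * p
    ev <- which(stats::runif(n) < q)
    for (i in rev(ev)) {
      len <- stats::rgeom(1, 0.5) + 1L
      if (stats::runif(1) < 0.5) {
        chars <- append(chars, strsplit(random_dna(len), "")[[1]], after = i)
      } else {
        chars <- chars[-(i:min(length(chars), i + len - 1L))]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate an envelope gene template
#'
#' An ATG-initiated ORF (no internal stops) whose translation carries
#' exactly one planted RDR receptor-binding motif in SU and a furin
#' cleavage site leaving a >= 80-residue TM subunit; resampled until those
#' diagnostics hold exactly. Uses the current RNG state.
#'
#' @param n_codons template length (>= 420 so the 400-codon screen passes).
#' @return list: `aa`, `nt` (coding sequence, no terminal stop),
#'   `furin_site` (position of the motif's final R), `rdr_pos`.
#' @export
make_env_template <- function(n_codons = 450L) {
  n_codons <- as.integer(n_codons)
  stopifnot(n_codons >= 420L)
  codons <- codon_table()
  for (try in 1:200) {
    aa <- c("M", sample(AA_ALPHABET, n_codons - 1L, replace = TRUE))
    rdr_pos <- max(2L, n_codons %/% 3L)
    aa[rdr_pos:(rdr_pos + 10L)] <-
      c("S", "D", "G", "G", "G", sample(AA_ALPHABET, 2L, TRUE), "D",
        sample(AA_ALPHABET, 2L, TRUE), "R")
    fur <- n_codons - 120L
    aa[fur:(fur + 3L)] <- c("R", sample(AA_ALPHABET, 1L),
                            sample(c("R", "K"), 1L), "R")
    s <- paste(aa, collapse = "")
    if (!identical(find_rdr_motif(s), rdr_pos)) next
    if (!identical(find_furin_site(s, min_tail = 80L), fur + 3L)) next
    return(list(aa = s, nt = aa_to_nt(aa, codons), furin_site = fur + 3L,
                rdr_pos = rdr_pos, n_codons = n_codons))
  }
  stop("failed to generate an env template")
}

make_gene_template <- function(n_codons) {
  aa <- c("M", sample(AA_ALPHABET, n_codons - 1L, replace = TRUE))
  list(aa = paste(aa, collapse = ""), nt = aa_to_nt(aa), n_codons = n_codons)
}

#' Generate the per-family gene templates
#'
#' env/gag/pro/pol templates for each family; env templates of different
#' families are checked to be well below the 80% clustering threshold
#' (random templates sit near the alignment noise floor).
#'
#' @param config a [sim_config()].
#' @return list of per-family lists with elements env, gag, pro, pol.
#' @export
make_family_templates <- function(config) {
  tpl <- lapply(seq_len(config$n_families), function(f) {
    list(env = make_env_template(config$env_codons),
         gag = make_gene_template(config$gag_codons),
         pro = make_gene_template(config$pro_codons),
         pol = make_gene_template(config$pol_codons))
  })
  if (config$n_families > 1L) {
    for (i in seq_len(config$n_families - 1L)) {
      for (j in (i + 1L):config$n_families) {
        pid <- protein_identity(tpl[[i]]$env$aa, tpl[[j]]$env$aa)
        if (pid > 50) {
          stop("env templates of families ", i, " and ", j,
               " are too similar (", round(pid, 1), "% identity)")
        }
      }
    }
  }
  tpl
}

#' Build one provirus and its ground truth
#'
#' Structure: 5'LTR - gag - pro - pol - env - 3'LTR with short random
#' spacers, a tandem in-frame stop guard immediately upstream of env (so
#' the env ORF starts at its planted ATG), and env's own stop codon.
#' The LTR template is drawn fresh per insertion and the two copies are
#' mutated independently at p = expected_d / 2; the internal region is
#' mutated at the same per-copy rate. Intact copies are resampled until
#' env still begins with ATG, contains no internal stop and retains its
#' first stop codon; decayed copies get in-frame stops planted at one and
#' two thirds of env.
#'
#' @param family_tpl one element of [make_family_templates()].
#' @param age true insertion age (MY).
#' @param config a [sim_config()].
#' @param intact keep env open (`TRUE`) or plant disrupting stops.
#' @return list: `seq` (provirus, plus strand), `truth` (local 0-based
#'   coordinates of LTRs and env, expected_d, planted motif positions).
#' @export
make_provirus <- function(family_tpl, age, config, intact = TRUE) {
  expected_d <- if (config$age_convention == "paper") age * config$rate
                else 2 * age * config$rate
  p <- expected_d / 2
  gc <- config$gc_content
  ltr_tpl <- random_dna(config$ltr_len, gc)
  env_n <- config$env_codons
  env_coding <- family_tpl$env$nt
  spacers <- replicate(3, random_dna(40L, gc))
  pre <- paste0(family_tpl$gag$nt, "TAA", spacers[1],
                family_tpl$pro$nt, "TAA", spacers[2],
                family_tpl$pol$nt, "TAA", spacers[3],
                "TAATAA")                       # guard stops, env frame
  env_unit <- paste0(env_coding, "TAA")
  ltr5 <- mutate_seq(ltr_tpl, p, config$indel_rate)
  ltr3 <- mutate_seq(ltr_tpl, p, config$indel_rate)
  pre_mut <- mutate_seq(pre, p, config$indel_rate)
  if (intact) {
    for (try in 1:100) {
      env_mut <- mutate_seq(env_unit, p)        # never indels inside env
      aa <- translate_nt(env_mut)
      if (startsWith(env_mut, "ATG") &&
          !grepl("*", substr(aa, 1L, env_n), fixed = TRUE) &&
          substr(aa, env_n + 1L, env_n + 1L) == "*") break
      env_mut <- NULL
    }
    if (is.null(env_mut)) stop("failed to mutate env without disruption")
  } else {
    env_mut <- mutate_seq(env_unit, p)
    ch <- strsplit(env_mut, "")[[1]]
    for (cpos in c(env_n %/% 3L, 2L * (env_n %/% 3L))) {
      ch[(3L * cpos + 1L):(3L * cpos + 3L)] <- c("T", "A", "A")
    }
    env_mut <- paste(ch, collapse = "")
  }
  tail_spacer <- random_dna(20L, gc)
  seq <- paste0(ltr5, pre_mut, env_mut, tail_spacer, ltr3)
  env_off <- nchar(ltr5) + nchar(pre_mut)
  truth <- list(
    ltr5_start = 0L, ltr5_end = nchar(ltr5),
    ltr3_start = nchar(seq) - nchar(ltr3), ltr3_end = nchar(seq),
    env_start = env_off, env_end = env_off + 3L * (env_n + 1L),
    env_intact = intact, true_age = age, expected_d = expected_d,
    furin_site = family_tpl$env$furin_site,
    rdr_pos = family_tpl$env$rdr_pos)
  list(seq = seq, truth = truth)
}

#' Generate one diverged LTR pair
#'
#' Convenience generator for the dating benchmark: a fresh LTR template
#' whose two copies are mutated independently at p = expected_d / 2.
#'
#' @param age true age (MY).
#' @param ltr_len LTR length (bp).
#' @param rate substitution rate (subs/site/MY).
#' @param convention age convention as in [estimate_age()].
#' @param gc GC content of the template.
#' @return list: `ltr5`, `ltr3`, `expected_d`.
#' @export
make_ltr_pair <- function(age, ltr_len = 600L, rate = 2.6e-3,
                          convention = c("paper", "two_lineage"),
                          gc = 0.45) {
  convention <- match.arg(convention)
  expected_d <- if (convention == "paper") age * rate else 2 * age * rate
  tpl <- random_dna(ltr_len, gc)
  list(ltr5 = mutate_seq(tpl, expected_d / 2),
       ltr3 = mutate_seq(tpl, expected_d / 2),
       expected_d = expected_d)
}

#' Generate a synthetic genome with planted proviruses
#'
#' Fully deterministic for a fixed `config$seed`: i.i.d. background,
#' proviruses at non-overlapping positions (>= `min_spacing` apart) on
#' random strands, and a ground-truth table for every insertion.
#'
#' @param config a [sim_config()].
#' @return list of class `erv_sim`: `genome` ([genome_sequence()]),
#'   `truth` (data.frame, forward-strand 0-based coordinates),
#'   `provirus_seqs` (each provirus on its own strand), `templates`
#'   (per-family gene templates), `config`.
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    templates <- make_family_templates(config)
    copies <- list()
    idx <- 0L
    for (f in seq_len(config$n_families)) {
      n_cop <- config$copies_per_family[f]
      n_dec <- config$decayed_per_family[f]
      for (cidx in seq_len(n_cop)) {
        idx <- idx + 1L
        age <- config$age_grid[((idx - 1L) %% length(config$age_grid)) + 1L]
        intact <- cidx <= (n_cop - n_dec)
        pv <- make_provirus(templates[[f]], age, config, intact)
        copies[[idx]] <- c(pv, list(family = paste0("F", f),
                                    copy = sprintf("F%d.%d", f, cidx)))
      }
    }
    n <- length(copies)
    plens <- vapply(copies, function(x) nchar(x$seq), numeric(1))
    gap <- (config$background_length - sum(plens)) / (n + 1)
    if (gap < config$min_spacing) {
      stop("infeasible packing: ", n, " inserts of total ", sum(plens),
           " bp cannot keep ", config$min_spacing, " bp spacing in ",
           config$background_length, " bp")
    }
    jit_max <- max(0, (gap - config$min_spacing) / 2 - 1)
    jitter <- floor(stats::runif(n, -jit_max, jit_max))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    pieces <- character(2L * n + 1L)
    truth_rows <- vector("list", n)
    cursor <- 0L   # genome position reached so far
    nominal <- cumsum(c(0, plens[-n])) + gap * seq_len(n)
    starts <- as.integer(round(nominal + jitter))
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- random_dna(starts[i] - cursor, config$gc_content)
      pv <- copies[[i]]
      plen <- nchar(pv$seq)
      oriented <- if (strands[i] == "+") pv$seq else
        reverse_complement(pv$seq)
      pieces[2L * i] <- oriented
      tr <- pv$truth
      flip <- function(s, e) c(plen - e, plen - s)
      if (strands[i] == "+") {
        ltr5 <- c(tr$ltr5_start, tr$ltr5_end)
        ltr3 <- c(tr$ltr3_start, tr$ltr3_end)
        env <- c(tr$env_start, tr$env_end)
      } else {
        ltr5 <- flip(tr$ltr5_start, tr$ltr5_end)
        ltr3 <- flip(tr$ltr3_start, tr$ltr3_end)
        env <- flip(tr$env_start, tr$env_end)
      }
      truth_rows[[i]] <- data.frame(
        provirus_id = pv$copy, family = pv$family, strand = strands[i],
        true_age = tr$true_age, expected_d = tr$expected_d,
        env_intact = tr$env_intact,
        insert_start = starts[i], insert_end = starts[i] + plen,
        ltr5_start = starts[i] + ltr5[1], ltr5_end = starts[i] + ltr5[2],
        ltr3_start = starts[i] + ltr3[1], ltr3_end = starts[i] + ltr3[2],
        env_start = starts[i] + env[1], env_end = starts[i] + env[2],
        furin_site = tr$furin_site, rdr_pos = tr$rdr_pos,
        stringsAsFactors = FALSE)
      cursor <- starts[i] + plen
    }
    pieces[2L * n + 1L] <-
      random_dna(config$background_length - cursor, config$gc_content)
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    pv_seqs <- stats::setNames(vapply(copies, function(x) x$seq,
                                      character(1)),
                               vapply(copies, function(x) x$copy,
                                      character(1)))
    structure(list(genome = genome_sequence("sim_1",
                                            paste(pieces, collapse = "")),
                   truth = truth, provirus_seqs = pv_seqs,
                   templates = templates, config = config),
              class = "erv_sim")
  })
}

#' @export
print.erv_sim <- function(x, ...) {
  cat(sprintf(paste0("<erv_sim> %d bp genome, %d proviruses ",
                     "(%d intact env) in %d families, seed %d\n"),
              x$genome$length, nrow(x$truth), sum(x$truth$env_intact),
              x$config$n_families, x$config$seed))
  invisible(x)
}

#' Write simulator outputs
#'
#' Writes the genome FASTA plus ground-truth GFF3 and TSV.
#'
#' @param sim an [make_genome()] result.
#' @param dir output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "erv_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "truth.gff3")
  tsv <- file.path(dir, "truth.tsv")
  write_fasta(list(sim$genome), fa)
  tr <- sim$truth
  feats <- rbind(
    data.frame(contig = sim$genome$id, start = tr$insert_start,
               end = tr$insert_end, strand = tr$strand, type = "provirus",
               ID = tr$provirus_id, stringsAsFactors = FALSE),
    data.frame(contig = sim$genome$id, start = tr$ltr5_start,
               end = tr$ltr5_end, strand = tr$strand,
               type = "long_terminal_repeat",
               ID = paste0(tr$provirus_id, ".LTR5"),
               stringsAsFactors = FALSE),
    data.frame(contig = sim$genome$id, start = tr$ltr3_start,
               end = tr$ltr3_end, strand = tr$strand,
               type = "long_terminal_repeat",
               ID = paste0(tr$provirus_id, ".LTR3"),
               stringsAsFactors = FALSE),
    data.frame(contig = sim$genome$id, start = tr$env_start,
               end = tr$env_end, strand = tr$strand, type = "CDS",
               ID = paste0(tr$provirus_id, ".env"),
               stringsAsFactors = FALSE))
  feats <- feats[order(feats$start, feats$end), ]
  write_gff3(feats, gff, source = "ervmine_sim")
  utils::write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, tsv = tsv))
}

#' Build and calibrate profiles from simulator templates
#'
#' One profile per family and gene (`env_F1`, `gag_F1`, ...), calibrated
#' against null sequences; the class of each profile is its name prefix.
#'
#' @param sim an [make_genome()] result.
#' @param genes which gene templates to turn into profiles.
#' @param n_calib null sequences per profile for Gumbel calibration.
#' @return Named list of calibrated [phmm_profile()] objects.
#' @export
build_simulation_profiles <- function(sim,
                                      genes = c("env", "gag", "pro", "pol"),
                                      n_calib = 50L) {
  stopifnot(inherits(sim, "erv_sim"))
  profs <- list()
  for (f in seq_along(sim$templates)) {
    for (g in genes) {
      nm <- sprintf("%s_F%d", g, f)
      pr <- profile_from_protein(sim$templates[[f]][[g]]$aa, nm)
      profs[[nm]] <- calibrate_profile(pr, n = n_calib, len = 400L,
                                       seed = sim$config$seed + 7919L * f +
                                         match(g, genes))
    }
  }
  profs
}
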