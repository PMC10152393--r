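# End-to-end pipeline: genome -> env-ORFs -> provirus calls -> dating ->
# families/consensus -> Env annotation, with tabular/GFF3/FASTA artifacts.

PIPELINE_DEFAULTS <- list(
  min_codons = 400L,        # env screen: ORFs of >= 400 codons
  e_threshold = 1e-10,      # profile-HMM inclusion E-value
  flank = 10000L,           # provirus window extension (bp)
  min_ltr_len = 100L, max_ltr_len = 3000L, min_identity = 80,
  min_residue_fraction = 0.6,   # consensus column trimming
  rate = 2.6e-3, convention = "paper",
  family_identity = 80,     # family clustering threshold (% aa identity)
  min_tail = 80L,           # furin tail constraint (aa)
  min_internal_orf_nt = 300L,
  seed = 1L)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys (suggesting
#' the nearest valid one), applies defaults, checks types and ranges, and
#' reports all violations at once.
#'
#' @param config path to a YAML file, a list, or `NULL` for pure defaults.
#' @return Full configuration list with defaults applied.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            if (!file.exists(config)) stop("config file not found: ", config)
            y <- yaml::read_yaml(config)
            if (is.null(y)) list() else y
          } else if (is.list(config)) config
          else stop("config must be a path, a list or NULL")
  valid <- c(names(PIPELINE_DEFAULTS), "genome", "profiles", "out_dir",
             "class_map", "simulate")
  errs <- character()
  for (k in setdiff(names(user), valid)) {
    errs <- c(errs, sprintf("unknown key '%s' (did you mean '%s'?)",
                            k, nearest_key(k, valid)))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS,
                           user[intersect(names(user), valid)])
  num_pos <- c("min_codons", "flank", "min_ltr_len", "max_ltr_len",
               "rate", "min_tail", "min_internal_orf_nt")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      errs <- c(errs, sprintf("'%s' must be a single positive number", k))
    }
  }
  if (!is.numeric(cfg$e_threshold) || cfg$e_threshold <= 0) {
    errs <- c(errs, "'e_threshold' must be > 0")
  }
  for (k in c("min_identity", "family_identity")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 100) {
      errs <- c(errs, sprintf("'%s' must be a percentage in [0, 100]", k))
    }
  }
  if (!is.numeric(cfg$min_residue_fraction) ||
      cfg$min_residue_fraction <= 0 || cfg$min_residue_fraction > 1) {
    errs <- c(errs, "'min_residue_fraction' must be in (0, 1]")
  }
  if (!cfg$convention %in% c("paper", "two_lineage")) {
    errs <- c(errs, "'convention' must be 'paper' or 'two_lineage'")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[ervmine] ", fmt), ...))

#' Run the full mining and dating pipeline
#'
#' Stages: (1) long-ORF screen on both strands; (2) profile-HMM
#' classification, keeping env hits at the E-value threshold; (3) provirus
#' window extraction and LTR direct-repeat calling per env-ORF, plus
#' internal ORF structure labelling; (4) LTR alignment, p-distance and
#' insertion-age estimation; (5) family clustering, per-family multicopy
#' consensus and a neighbour-joining group tree; (6) Env motif annotation.
#' All intermediate artifacts are written under `out_dir`; reruns with
#' identical inputs produce byte-identical outputs.
#'
#' @param genome a [genome_sequence()], list of them, or FASTA path.
#' @param profiles named list of calibrated [phmm_profile()] objects, or a
#'   path to a `.hmm` file / directory of `.hmm` files.
#' @param out_dir output directory.
#' @param config list or YAML path accepted by [validate_config()].
#' @return Object of class `erv_report`: data.frames `orfs` (per env-ORF),
#'   `proviruses` (LTR coordinates, identity, p-distance, age),
#'   `families`, `env_features`, and `artifacts` (paths).
#' @export
run_pipeline <- function(genome, profiles, out_dir, config = NULL) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- load_genomes(genome)
  profiles <- load_profiles(profiles)
  class_map <- unlist(cfg$class_map %||% NULL)

  # stage 1: long-ORF screen
  orfs <- do.call(rbind, lapply(genomes, find_orfs,
                                min_codons = cfg$min_codons,
                                mode = "start_to_stop",
                                both_strands = TRUE))
  if (is.null(orfs)) orfs <- empty_orf_frame()
  rownames(orfs) <- NULL
  log_stage("ORF screen: %d ORFs of >= %d codons", nrow(orfs),
            cfg$min_codons)

  # stage 2: profile-HMM classification
  hits <- classify_orfs(orfs, profiles, e_threshold = cfg$e_threshold,
                        class_map = class_map)
  env_hits <- hits[hits$class == "env", , drop = FALSE]
  log_stage("profile scan: %d hits at E <= %g, of which %d env",
            nrow(hits), cfg$e_threshold, nrow(env_hits))
  env_orfs <- orfs[orfs$orf_id %in% env_hits$orf_id, , drop = FALSE]

  # stages 3-4: provirus calling and dating per env-ORF
  prov_rows <- list()
  gff_rows <- list()
  for (i in seq_len(nrow(env_orfs))) {
    orf <- env_orfs[i, ]
    g <- genomes[[orf$contig]]
    win <- extract_window(g, orf, flank = cfg$flank)
    cands <- find_direct_repeats(win, min_ltr_len = cfg$min_ltr_len,
                                 max_ltr_len = cfg$max_ltr_len,
                                 min_identity = cfg$min_identity)
    internal <- annotate_provirus_orfs(win$seq,
                                       min_nt = cfg$min_internal_orf_nt)
    big <- internal[internal$aa_len >= 100L &
                      internal$mode == "start_to_stop", , drop = FALSE]
    labels <- classify_orfs(big, profiles, e_threshold = 1e-5,
                            class_map = class_map)
    internal$class <- labels$class[match(internal$orf_id, labels$orf_id)]
    call <- call_provirus(list(start = win$orf_start, end = win$orf_end),
                          cands, internal)
    row <- data.frame(orf_id = orf$orf_id, contig = orf$contig,
                      provirus_start = call$provirus_start + win$offset,
                      provirus_end = call$provirus_end + win$offset,
                      stringsAsFactors = FALSE)
    if (!is.null(call$ltr_pair)) {
      lp <- call$ltr_pair
      ltr5 <- substr(win$seq, lp$left_start + 1L, lp$left_end)
      ltr3 <- substr(win$seq, lp$right_start + 1L, lp$right_end)
      est <- date_ltr_pair(ltr5, ltr3, rate = cfg$rate,
                           convention = cfg$convention)
      row$ltr5_start <- lp$left_start + win$offset
      row$ltr5_end <- lp$left_end + win$offset
      row$ltr3_start <- lp$right_start + win$offset
      row$ltr3_end <- lp$right_end + win$offset
      row$ltr_identity_pct <- round(est$identity_pct, 1)
      row$p_distance <- est$d
      row$age_my <- est$age_my
      gff_rows[[length(gff_rows) + 1L]] <- data.frame(
        contig = orf$contig,
        start = c(row$provirus_start, row$ltr5_start, row$ltr3_start),
        end = c(row$provirus_end, row$ltr5_end, row$ltr3_end),
        strand = "+",
        type = c("provirus", "long_terminal_repeat",
                 "long_terminal_repeat"),
        ID = paste0(orf$orf_id, c("", ".LTR5", ".LTR3")),
        stringsAsFactors = FALSE)
      labelled <- internal[!is.na(internal$class) &
                             internal$mode == "start_to_stop", ,
                           drop = FALSE]
      if (nrow(labelled)) {
        gff_rows[[length(gff_rows) + 1L]] <- data.frame(
          contig = orf$contig,
          start = labelled$start + win$offset,
          end = labelled$end + win$offset,
          strand = "+", type = "CDS",
          ID = paste0(orf$orf_id, ".", labelled$class, ".",
                      seq_len(nrow(labelled))),
          stringsAsFactors = FALSE)
      }
    } else {
      row[c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")] <-
        NA_integer_
      row$ltr_identity_pct <- NA_real_   # reported as "-" in the TSV
      row$p_distance <- NA_real_
      row$age_my <- NA_real_
    }
    prov_rows[[i]] <- row
  }
  proviruses <- if (length(prov_rows)) do.call(rbind, prov_rows) else
    data.frame()
  log_stage("provirus calling: %d/%d env-ORFs with an LTR pair",
            if (nrow(proviruses)) sum(!is.na(proviruses$ltr_identity_pct))
            else 0L, nrow(env_orfs))

  # stage 5: families and consensus
  fam_assign <- NULL
  fam_df <- data.frame(family = character(), copy_number = integer(),
                       members = character(), consensus_id = character(),
                       stringsAsFactors = FALSE)
  consensus <- character()
  tree <- NULL
  if (nrow(env_orfs)) {
    aa <- stats::setNames(env_orfs$aa_seq, env_orfs$orf_id)
    fam_assign <- cluster_families(aa,
                                   identity_threshold = cfg$family_identity)
    fam_df <- attr(fam_assign, "families")
    fam_df$consensus_id <- NA_character_
    for (f in seq_len(nrow(fam_df))) {
      members <- strsplit(fam_df$members[f], ",")[[1]]
      if (length(members) < 2L) next
      nt <- stats::setNames(
        env_orfs$nt_seq[match(members, env_orfs$orf_id)], members)
      msa <- progressive_msa(nt)
      msa <- trim_sparse_columns(msa, cfg$min_residue_fraction)
      cid <- paste0(fam_df$family[f], "_consensus")
      consensus[cid] <- consensus_sequence(msa)
      fam_df$consensus_id[f] <- cid
    }
    if (nrow(env_orfs) >= 3L) {
      msa_aa <- progressive_msa(aa)
      tree <- nj_tree(msa_p_distance(msa_aa))
    }
  }
  log_stage("families: %d (%d with consensus)", nrow(fam_df),
            sum(!is.na(fam_df$consensus_id)))

  # stage 6: Env annotation
  env_feat <- do.call(rbind, lapply(seq_len(nrow(env_orfs)), function(i) {
    ann <- annotate_env(env_orfs$aa_seq[i], min_tail = cfg$min_tail)
    data.frame(orf_id = env_orfs$orf_id[i],
               furin_site = ann$furin_site,
               tm_start = if (is.na(ann$furin_site)) NA_integer_ else
                 ann$furin_site + 1L,
               tm_length = if (is.na(ann$tm_region)) NA_integer_ else
                 nchar(ann$tm_region),
               rdr_positions = paste(ann$rdr_positions, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(env_feat)) {
    env_feat <- data.frame(orf_id = character(), furin_site = integer(),
                           tm_start = integer(), tm_length = integer(),
                           rdr_positions = character(),
                           stringsAsFactors = FALSE)
  }

  # per-ORF report: env hits with family and score columns
  orf_report <- if (nrow(env_orfs)) {
    data.frame(orf_id = env_orfs$orf_id,
               orf_length_aa = env_orfs$aa_len,
               chromosome = env_orfs$contig,
               locus_start = env_orfs$start, locus_end = env_orfs$end,
               direction = env_orfs$strand,
               family = fam_assign$family[match(env_orfs$orf_id,
                                                fam_assign$orf_id)],
               profile = env_hits$profile[match(env_orfs$orf_id,
                                                env_hits$orf_id)],
               evalue = env_hits$evalue[match(env_orfs$orf_id,
                                              env_hits$orf_id)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(orf_id = character(), orf_length_aa = integer(),
               chromosome = character(), locus_start = integer(),
               locus_end = integer(), direction = character(),
               family = character(), profile = character(),
               evalue = numeric(), stringsAsFactors = FALSE)
  }

  gff_feats <- if (length(gff_rows)) do.call(rbind, gff_rows) else NULL
  artifacts <- write_pipeline_artifacts(out_dir, orfs, hits, orf_report,
                                        proviruses, fam_df, consensus,
                                        env_feat, env_orfs, tree, gff_feats)
  structure(list(orfs = orf_report, hits = hits, proviruses = proviruses,
                 families = fam_df, env_features = env_feat,
                 artifacts = artifacts, config = cfg),
            class = "erv_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_genomes <- function(genome) {
  if (inherits(genome, "genome_sequence")) genome <- list(genome)
  if (is.character(genome)) genome <- read_fasta(genome)
  stopifnot(all(vapply(genome, inherits, logical(1), "genome_sequence")))
  names(genome) <- vapply(genome, function(g) g$id, character(1))
  genome
}

load_profiles <- function(profiles) {
  if (is.character(profiles)) {
    paths <- if (dir.exists(profiles)) {
      sort(list.files(profiles, pattern = "\\.hmm$", full.names = TRUE))
    } else profiles
    if (!length(paths)) stop("no .hmm files found in ", profiles)
    profiles <- do.call(c, lapply(paths, parse_hmmer3))
  }
  if (!length(profiles)) stop("empty profile set")
  stopifnot(all(vapply(profiles, inherits, logical(1), "phmm_profile")))
  profiles
}

write_pipeline_artifacts <- function(out_dir, orfs, hits, orf_report,
                                     proviruses, fam_df, consensus,
                                     env_feat, env_orfs, tree,
                                     gff_feats = NULL) {
  paths <- c(
    orfs = file.path(out_dir, "orfs"),
    hits = file.path(out_dir, "hits.tsv"),
    env_orfs = file.path(out_dir, "env_orfs.tsv"),
    env_fna = file.path(out_dir, "env_orfs.fna"),
    proviruses = file.path(out_dir, "proviruses.tsv"),
    gff = file.path(out_dir, "proviruses.gff3"),
    families = file.path(out_dir, "families.tsv"),
    consensus = file.path(out_dir, "consensus.fna"),
    env_features = file.path(out_dir, "env_features.tsv"),
    tree = file.path(out_dir, "env_tree.nwk"))
  write_orf_report(orfs, paths[["orfs"]])
  wt <- function(df, p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "-")
  }
  wt(hits, paths[["hits"]])
  wt(orf_report, paths[["env_orfs"]])
  if (nrow(env_orfs)) {
    write_fasta(stats::setNames(env_orfs$nt_seq, env_orfs$orf_id),
                paths[["env_fna"]])
  } else cat("", file = paths[["env_fna"]])
  pv <- proviruses
  if (nrow(pv)) pv$ltr_identity_pct <- sprintf("%.1f", pv$ltr_identity_pct)
  wt(pv, paths[["proviruses"]])
  if (!is.null(gff_feats) && nrow(gff_feats)) {
    write_gff3(gff_feats, paths[["gff"]])
  } else cat("##gff-version 3\n", file = paths[["gff"]])
  wt(fam_df, paths[["families"]])
  if (length(consensus)) {
    write_fasta(consensus, paths[["consensus"]])
  } else cat("", file = paths[["consensus"]])
  wt(env_feat, paths[["env_features"]])
  if (!is.null(tree)) {
    ape::write.tree(tree, paths[["tree"]])
  } else cat("", file = paths[["tree"]])
  paths
}

#' @export
print.erv_report <- function(x, ...) {
  cat("<erv_report>\n")
  cat(sprintf("  env-ORFs reported : %d\n", nrow(x$orfs)))
  cat(sprintf("  provirus calls    : %d (%d with LTR pair)\n",
              nrow(x$proviruses),
              if (nrow(x$proviruses))
                sum(!is.na(x$proviruses$ltr_identity_pct)) else 0L))
  cat(sprintf("  families          : %d\n", nrow(x$families)))
  if (nrow(x$families)) {
    cat(sprintf("    %s: %d copies\n", x$families$family,
                x$families$copy_number), sep = "")
  }
  invisible(x)
}
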