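AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n_aa, alphabet = AA20) {
  paste(sample(alphabet, n_aa, replace = TRUE), collapse = "")
}

# log-uniform draw in [lo, hi]
rlog_unif <- function(n, lo, hi) {
  exp(runif(n, log(lo), log(hi)))
}

#' Configuration for the synthetic survey generator
#'
#' Parameterizes genomes, locus composition, decoys, noise and phage
#' proteomes. Defaults emulate the broad statistical structure of a
#' large-scale type III CRISPR survey: roughly half of genomes carry a
#' locus, Cas10s are cyclase-positive in ~90% of cases, RN family weights
#' follow the relative abundances Csx20 > Csx16 > Crn1 > Crn3 > Csx15 >
#' Crn2, RN-given-effector probabilities differ by effector family
#' (high for Cam1 and Can1/Can2, low for Cami1), ~4% of RN-positive loci
#' carry two RNs, and phage-borne RNs are dominated by Crn2/AcrIII-1.
#' Decoy and spurious-hit rates default to zero; they are switched on
#' explicitly for filter stress tests.
#'
#' @param n_genomes number of cellular genomes.
#' @param contig_length contig length in bp (one contig per genome).
#' @param loci_per_genome named numeric vector of probabilities for 0..k
#'   loci per genome (names `"0"`, `"1"`, ...).
#' @param effector_weights named sampling weights over effector families.
#' @param rn_weights named sampling weights over RN families.
#' @param p_rn_given_effector named per-effector-family probability that a
#'   locus with that (first) effector also carries an RN; unnamed families
#'   fall back to `p_rn_default`.
#' @param p_rn_default fallback RN-given-effector probability.
#' @param p_no_effector_locus probability a locus carries no effector.
#' @param p_rn_no_effector probability an effector-less locus carries an RN.
#' @param p_two_effectors probability an effector locus carries a second
#'   effector.
#' @param p_multi_rn probability an RN-carrying locus carries a second RN
#'   of a different family.
#' @param p_cyclase,p_hd per-locus probabilities of Cas10 cyclase / HD
#'   motifs.
#' @param p_csx14_alias fraction of planted Crn1 genes whose hit is
#'   reported under the Csx14 profile alias.
#' @param decoys named list of planted decoy counts: `long_carf`
#'   (CARF-like effector >250 aa that also hits an RN profile),
#'   `missing_residue` (RN-like protein with one conserved residue
#'   substituted), `out_of_window` (true RN placed beyond the 6 kbp
#'   neighborhood), `orphan_rn` (RN in a genome with no locus).
#' @param orphan_family family for orphan RNs (`NULL` = sample from
#'   `rn_weights`).
#' @param spurious_rate expected number of spurious weak hits per genome.
#' @param spurious_evalue_range e-value range for spurious hits; the
#'   default sits entirely above the pipeline's 1e-4 ceiling so that
#'   threshold behaviour is testable (set a lower floor for hard-noise
#'   stress tests).
#' @param n_background_genes background protein-coding genes per genome.
#' @param rn_length_aa length of planted RN proteins (<= 250).
#' @param effector_length_range amino-acid length range for effectors.
#' @param cas10_length_aa Cas10 protein length.
#' @param n_msa_seqs,n_conserved,msa_mutation_rate reference-alignment
#'   model per RN family: number of sequences, number of absolutely
#'   conserved columns, per-column mutation probability away from the
#'   family template at non-conserved columns.
#' @param candidate_mutation_rate mutation probability at non-conserved
#'   positions for planted RN genes.
#' @param subtype_weights named weights over CRISPR subtypes.
#' @param n_phage number of phage proteomes.
#' @param p_phage_rn fraction of phages carrying one planted RN.
#' @param phage_rn_weights family weights for phage RNs (biased toward
#'   Crn2, the phage anti-CRISPR homologue AcrIII-1).
#' @param p_phage_missing_residue probability a planted phage RN has a
#'   conserved residue knocked out (expected verdict: rejected-by-screen).
#' @param phage_n_proteins background proteins per phage.
#' @param window,chain_gap layout constants matching the pipeline defaults.
#' @param seed RNG seed; all outputs are deterministic given the config.
#' @return list of class `rn_sim_config`.
#' @export
sim_config <- function(
    n_genomes = 20,
    contig_length = 100000,
    loci_per_genome = c("0" = 0.45, "1" = 0.40, "2" = 0.10, "3" = 0.05),
    effector_weights = c(Csx1 = 0.35, Csm6 = 0.12, `Csm6-2` = 0.04,
                         Can1 = 0.08, Can2 = 0.06, Cami1 = 0.08,
                         Cam1 = 0.08, CalpL = 0.05, NucC = 0.06,
                         Csx23 = 0.03, `TIR-SAVED` = 0.05),
    rn_weights = c(Csx20 = 78, Csx16 = 68, Crn1 = 44, Crn3 = 37,
                   Csx15 = 18, Crn2 = 7),
    p_rn_given_effector = c(Csx1 = 0.34, Cami1 = 0.30, Can1 = 0.66,
                            Can2 = 0.66, Cam1 = 0.81),
    p_rn_default = 0.39,
    p_no_effector_locus = 0.10,
    p_rn_no_effector = 0.5,
    p_two_effectors = 0.10,
    p_multi_rn = 0.04,
    p_cyclase = 0.9,
    p_hd = 0.1,
    p_csx14_alias = 0.3,
    decoys = list(long_carf = 0, missing_residue = 0, out_of_window = 0,
                  orphan_rn = 0),
    orphan_family = NULL,
    spurious_rate = 0,
    spurious_evalue_range = c(1e-3, 10),
    n_background_genes = 5,
    rn_length_aa = 120,
    effector_length_range = c(260, 450),
    cas10_length_aa = 750,
    n_msa_seqs = 20,
    n_conserved = 6,
    msa_mutation_rate = 0.15,
    candidate_mutation_rate = 0.10,
    subtype_weights = c(`III-A` = 0.45, `III-B` = 0.35, `III-C` = 0.10,
                        `III-D` = 0.10),
    n_phage = 0,
    p_phage_rn = 0.3,
    phage_rn_weights = c(Crn2 = 0.75, Csx20 = 0.12, Csx16 = 0.08,
                         Crn1 = 0.02, Crn3 = 0.02, Csx15 = 0.01),
    p_phage_missing_residue = 0,
    phage_n_proteins = 20,
    window = 6000,
    chain_gap = 500,
    seed = 1) {
  cfg <- as.list(environment())
  probs <- c(p_no_effector_locus, p_rn_no_effector, p_two_effectors,
             p_multi_rn, p_cyclase, p_hd, p_csx14_alias, p_phage_rn,
             p_phage_missing_residue, p_rn_default,
             unname(p_rn_given_effector), unname(loci_per_genome))
  if (any(probs < 0 | probs > 1))
    stop_fmt("all probabilities must lie in [0, 1]")
  for (w in list(effector_weights, rn_weights, subtype_weights,
                 phage_rn_weights))
    if (any(w < 0) || sum(w) == 0)
      stop_fmt("sampling weights must be non-negative and not all zero")
  class(cfg) <- "rn_sim_config"
  cfg
}

# One synthetic RN family: ungapped template, absolutely conserved columns,
# and a reference MSA in which every non-conserved column varies (so the
# conserved set recovered at t_cons = 1 is exactly the planted one).
make_family_model <- function(family, cfg) {
  L <- cfg$rn_length_aa
  template <- sample(AA20, L, replace = TRUE)
  conserved <- sort(sample.int(L, cfg$n_conserved))
  msa <- matrix(rep(template, cfg$n_msa_seqs), nrow = cfg$n_msa_seqs,
                byrow = TRUE)
  free <- setdiff(seq_len(L), conserved)
  for (i in seq_len(cfg$n_msa_seqs)) {
    mut <- free[runif(length(free)) < cfg$msa_mutation_rate]
    for (j in mut)
      msa[i, j] <- sample(setdiff(AA20, template[j]), 1L)
  }
  for (j in free) {                      # force variation at free columns
    if (length(unique(msa[, j])) == 1L)
      msa[1, j] <- sample(setdiff(AA20, msa[1, j]), 1L)
  }
  seqs <- apply(msa, 1, paste, collapse = "")
  names(seqs) <- sprintf("%s_ref%02d", family, seq_along(seqs))
  list(family = family, template = template, conserved = conserved,
       msa = seqs)
}

# Draw an RN-like protein from a family model; optionally knock out one
# conserved residue (missing-residue decoy).
draw_rn_protein <- function(model, cfg, knockout = FALSE) {
  s <- model$template
  free <- setdiff(seq_along(s), model$conserved)
  mut <- free[runif(length(free)) < cfg$candidate_mutation_rate]
  for (j in mut) s[j] <- sample(setdiff(AA20, s[j]), 1L)
  if (knockout) {
    j <- sample(model$conserved, 1L)
    s[j] <- sample(setdiff(AA20, model$template[j]), 1L)
  }
  paste(s, collapse = "")
}

draw_cas10_protein <- function(cfg, has_cyclase, has_hd) {
  # background alphabet excludes D so cyclase (GGDD-type) and HD (H..D)
  # motifs occur iff planted
  s <- sample(setdiff(AA20, "D"), cfg$cas10_length_aa, replace = TRUE)
  if (has_hd) {
    pos <- 100L
    s[pos:(pos + 3L)] <- c("H", "A", "A", "D")
  }
  if (has_cyclase) {
    pos <- 400L
    s[pos:(pos + 3L)] <- c("G", "G", "D", "D")
  }
  paste(s, collapse = "")
}

sample_weighted <- function(weights, n = 1L) {
  sample(names(weights), n, replace = FALSE,
         prob = weights / sum(weights))
}

strong_hit <- function(protein_id, family_id, len_aa) {
  data.frame(protein_id = protein_id, family_id = family_id,
             bitscore = round(runif(1, 60, 300), 1),
             evalue = signif(rlog_unif(1, 1e-50, 1e-10), 3),
             ali_start = 1L, ali_end = as.integer(len_aa),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cellular genome survey with planted ground truth
#'
#' Emits, for each genome, a gene table (GFF3-equivalent coordinates plus
#' protein sequences), a profile-hit table, and a truth table recording
#' every planted gene's role and the verdict the pipeline is expected to
#' reach. Loci are laid out in non-overlapping 30 kbp slots: a Cas10 gene
#' with cas accessory genes forms the cas span; effectors and RNs are
#' placed inside the 6 kbp neighborhood; decoy kinds are placed where
#' their rejection rule applies (long CARF-like and missing-residue decoys
#' inside the neighborhood, out-of-window RNs just beyond it, orphan RNs
#' in locus-free genomes). Reference alignments are generated per RN
#' family with a known absolutely conserved column set. All output is
#' deterministic given `config$seed`.
#'
#' @param config an [sim_config()].
#' @return list of class `rn_sim_dataset`: `genes`, `hits`,
#'   `contig_lengths`, `msas` (named list of aligned named character
#'   vectors), `family_models` (internal truth about conserved columns),
#'   `truth` (`genome_id`, `gene_id`, `locus_id`, `role`, `family`,
#'   `expected_verdict`), `subtype_table`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "rn_sim_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  slot <- 30000L
  max_loci_cfg <- max(as.integer(names(
    cfg$loci_per_genome[cfg$loci_per_genome > 0])))
  if (max_loci_cfg > 0 &&
      cfg$contig_length < slot * max_loci_cfg + 10000L)
    stop_fmt(
      "contig too short to host requested loci: length %d bp < %d bp needed for up to %d loci",
      cfg$contig_length, slot * max_loci_cfg + 10000L, max_loci_cfg)

  rn_fams <- names(cfg$rn_weights)
  models <- lapply(rn_fams, make_family_model, cfg = cfg)
  names(models) <- rn_fams

  genes <- list(); hits <- list(); truth <- list(); subtypes <- list()
  contig_lengths <- setNames(rep(as.integer(cfg$contig_length),
                                 cfg$n_genomes),
                             sprintf("G%03d_c1", seq_len(cfg$n_genomes)))
  n_loci_drawn <- as.integer(sample(names(cfg$loci_per_genome),
                                    cfg$n_genomes, replace = TRUE,
                                    prob = cfg$loci_per_genome))
  locusful <- which(n_loci_drawn > 0L)
  locusfree <- which(n_loci_drawn == 0L)

  # round-robin assignment of per-locus decoys over loci
  total_loci <- sum(n_loci_drawn)
  for (kind in c("long_carf", "missing_residue", "out_of_window"))
    if ((cfg$decoys[[kind]] %||% 0) > total_loci)
      stop_fmt("%d %s decoys requested but only %d loci drawn",
               cfg$decoys[[kind]], kind, total_loci)
  if ((cfg$decoys$orphan_rn %||% 0) > length(locusfree))
    stop_fmt("%d orphan_rn decoys requested but only %d locus-free genomes",
             cfg$decoys$orphan_rn, length(locusfree))
  decoy_slots <- function(n) if (n > 0) seq_len(n) else integer()
  plant_long <- decoy_slots(cfg$decoys$long_carf %||% 0)
  plant_miss <- decoy_slots(cfg$decoys$missing_residue %||% 0)
  plant_oow <- decoy_slots(cfg$decoys$out_of_window %||% 0)
  orphan_genomes <- locusfree[decoy_slots(cfg$decoys$orphan_rn %||% 0)]

  add_gene <- function(env, gid, genome, contig, start, len_aa, seq,
                       strand = "+") {
    env$genes[[length(env$genes) + 1L]] <- data.frame(
      gene_id = gid, genome_id = genome, contig_id = contig,
      start = as.integer(start),
      end = as.integer(start + 3L * len_aa - 1L),
      strand = strand, protein_seq = seq, length_aa = as.integer(len_aa),
      stringsAsFactors = FALSE)
  }
  env <- environment()
  locus_counter <- 0L

  for (g in seq_len(cfg$n_genomes)) {
    genome <- sprintf("G%03d", g)
    contig <- sprintf("%s_c1", genome)
    gene_n <- 0L
    next_gid <- function() {
      gene_n <<- gene_n + 1L
      sprintf("%s_g%03d", genome, gene_n)
    }
    for (li in seq_len(n_loci_drawn[g])) {
      locus_counter <- locus_counter + 1L
      locus_id <- sprintf("%s_L%02d", genome, li)
      base <- (li - 1L) * slot
      # --- cas span ---
      has_cyc <- runif(1) < cfg$p_cyclase
      has_hd <- runif(1) < cfg$p_hd
      cursor <- base + 4000L
      cas10_id <- next_gid()
      cas10_seq <- draw_cas10_protein(cfg, has_cyc, has_hd)
      add_gene(env, cas10_id, genome, contig, cursor,
               cfg$cas10_length_aa, cas10_seq)
      hits[[length(hits) + 1L]] <- strong_hit(cas10_id, "Cas10",
                                              cfg$cas10_length_aa)
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = genome, gene_id = cas10_id, locus_id = locus_id,
        role = "cas10",
        family = if (has_cyc) "cyclase" else "no_cyclase",
        expected_verdict = "annotated", stringsAsFactors = FALSE)
      cursor <- cursor + 3L * cfg$cas10_length_aa + 100L
      n_acc <- sample(2:4, 1L)
      cat <- family_catalogue()
      for (k in seq_len(n_acc)) {
        len <- sample(200:350, 1L)
        gid <- next_gid()
        add_gene(env, gid, genome, contig, cursor, len, rand_protein(len))
        prof <- sample(cat$cas_accessory_profiles, 1L)
        hits[[length(hits) + 1L]] <- strong_hit(gid, prof, len)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = locus_id,
          role = "cas_core", family = prof,
          expected_verdict = "annotated", stringsAsFactors = FALSE)
        cursor <- cursor + 3L * len + 100L
      }
      span_start <- base + 4000L
      span_end <- cursor - 101L
      subtypes[[length(subtypes) + 1L]] <- data.frame(
        genome_id = genome, contig_id = contig,
        start = span_start, end = span_end,
        subtype = sample_weighted(cfg$subtype_weights),
        stringsAsFactors = FALSE)
      # --- effectors and RNs, right of the span, inside the window ---
      cursor <- span_end + 200L
      eff_fams <- character()
      if (runif(1) >= cfg$p_no_effector_locus) {
        eff_fams <- sample_weighted(cfg$effector_weights)
        if (runif(1) < cfg$p_two_effectors) {
          others <- cfg$effector_weights[
            setdiff(names(cfg$effector_weights), eff_fams)]
          eff_fams <- c(eff_fams, sample_weighted(others))
        }
      }
      for (f in eff_fams) {
        len <- sample(cfg$effector_length_range[1]:
                        cfg$effector_length_range[2], 1L)
        gid <- next_gid()
        add_gene(env, gid, genome, contig, cursor, len, rand_protein(len))
        hits[[length(hits) + 1L]] <- strong_hit(gid, f, len)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = locus_id,
          role = paste0("effector:", f), family = f,
          expected_verdict = "annotated", stringsAsFactors = FALSE)
        cursor <- cursor + 3L * len + 200L
      }
      want_rn <- if (length(eff_fams) > 0L) {
        p <- cfg$p_rn_given_effector[eff_fams[1]]
        if (is.na(p)) p <- cfg$p_rn_default
        runif(1) < p
      } else runif(1) < cfg$p_rn_no_effector
      rn_planted <- character()
      if (want_rn) {
        rn_planted <- sample_weighted(cfg$rn_weights)
        if (runif(1) < cfg$p_multi_rn) {
          others <- cfg$rn_weights[setdiff(rn_fams, rn_planted)]
          rn_planted <- c(rn_planted, sample_weighted(others))
        }
      }
      for (f in rn_planted) {
        gid <- next_gid()
        seq <- draw_rn_protein(models[[f]], cfg)
        add_gene(env, gid, genome, contig, cursor, cfg$rn_length_aa, seq)
        prof <- if (f == "Crn1" && runif(1) < cfg$p_csx14_alias)
          "Csx14" else f
        hits[[length(hits) + 1L]] <- strong_hit(gid, prof,
                                                cfg$rn_length_aa)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = locus_id,
          role = paste0("rn:", f), family = f,
          expected_verdict = "annotated", stringsAsFactors = FALSE)
        cursor <- cursor + 3L * cfg$rn_length_aa + 200L
      }
      # --- decoys tied to this locus ---
      lcursor <- span_start - 2000L          # left side of span, in-window
      if (locus_counter %in% plant_long) {
        len <- 300L                          # > 250 aa: length rule fires
        f_eff <- sample_weighted(cfg$effector_weights)
        f_rn <- sample_weighted(cfg$rn_weights)
        gid <- next_gid()
        add_gene(env, gid, genome, contig, lcursor, len,
                 rand_protein(len))
        h1 <- strong_hit(gid, f_eff, len)
        h2 <- strong_hit(gid, f_rn, len)
        h2$bitscore <- h1$bitscore + 10     # RN hit even outscores it
        hits[[length(hits) + 1L]] <- h1
        hits[[length(hits) + 1L]] <- h2
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = locus_id,
          role = "decoy:long_carf", family = f_rn,
          expected_verdict = "rejected-by-length", stringsAsFactors = FALSE)
        lcursor <- lcursor + 3L * len + 100L
      }
      if (locus_counter %in% plant_miss) {
        f <- sample_weighted(cfg$rn_weights)
        gid <- next_gid()
        seq <- draw_rn_protein(models[[f]], cfg, knockout = TRUE)
        add_gene(env, gid, genome, contig, lcursor, cfg$rn_length_aa, seq)
        hits[[length(hits) + 1L]] <- strong_hit(gid, f, cfg$rn_length_aa)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = locus_id,
          role = "decoy:missing_residue", family = f,
          expected_verdict = "rejected-by-screen", stringsAsFactors = FALSE)
      }
      if (locus_counter %in% plant_oow) {
        f <- sample_weighted(cfg$rn_weights)
        gid <- next_gid()
        seq <- draw_rn_protein(models[[f]], cfg)
        start <- span_end + cfg$window + 401L   # starts beyond the window
        add_gene(env, gid, genome, contig, start, cfg$rn_length_aa, seq)
        hits[[length(hits) + 1L]] <- strong_hit(gid, f, cfg$rn_length_aa)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome, gene_id = gid, locus_id = NA_character_,
          role = "decoy:out_of_window", family = f,
          expected_verdict = "rejected-by-window", stringsAsFactors = FALSE)
      }
    }
    # --- orphan RN in a locus-free genome ---
    if (g %in% orphan_genomes) {
      f <- if (is.null(cfg$orphan_family))
        sample_weighted(cfg$rn_weights) else cfg$orphan_family
      gid <- next_gid()
      seq <- draw_rn_protein(models[[f]], cfg)
      add_gene(env, gid, genome, contig, 5000L, cfg$rn_length_aa, seq)
      hits[[length(hits) + 1L]] <- strong_hit(gid, f, cfg$rn_length_aa)
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = genome, gene_id = gid, locus_id = NA_character_,
        role = "decoy:orphan_rn", family = f,
        expected_verdict = "rejected-by-window", stringsAsFactors = FALSE)
    }
    # --- background genes after the last locus slot (and clear of any
    # orphan RN planted at 5 kbp in locus-free genomes) ---
    bg_base <- if (n_loci_drawn[g] == 0L) 7000L else
      n_loci_drawn[g] * slot + 1000L
    bcursor <- bg_base
    for (k in seq_len(cfg$n_background_genes)) {
      len <- sample(100:400, 1L)
      if (bcursor + 3L * len > cfg$contig_length) break
      gid <- next_gid()
      add_gene(env, gid, genome, contig, bcursor, len, rand_protein(len))
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = genome, gene_id = gid, locus_id = NA_character_,
        role = "background", family = NA_character_,
        expected_verdict = "none", stringsAsFactors = FALSE)
      bcursor <- bcursor + 3L * len + sample(100:500, 1L)
    }
  }

  genes <- do.call(rbind, genes) %||% empty_gene_table()
  hits <- do.call(rbind, hits) %||% empty_hit_table()
  truth <- do.call(rbind, truth) %||% data.frame(
    genome_id = character(), gene_id = character(),
    locus_id = character(), role = character(), family = character(),
    expected_verdict = character(), stringsAsFactors = FALSE)
  # spurious weak hits on random genes, e-values above the real-hit range
  n_spur <- rbinom(1L, cfg$n_genomes * 10L,
                   min(1, cfg$spurious_rate / 10))
  if (n_spur > 0L && nrow(genes) > 0L) {
    cat <- family_catalogue()
    all_profiles <- c(cat$cas10_profiles, cat$cas_accessory_profiles,
                      cat$effector_families, rn_fams, "Csx14")
    idx <- sample.int(nrow(genes), n_spur, replace = TRUE)
    spur <- data.frame(
      protein_id = genes$gene_id[idx],
      family_id = sample(all_profiles, n_spur, replace = TRUE),
      bitscore = round(runif(n_spur, 5, 25), 1),
      evalue = signif(rlog_unif(n_spur, cfg$spurious_evalue_range[1],
                                cfg$spurious_evalue_range[2]), 3),
      ali_start = 1L,
      ali_end = pmax(1L, genes$length_aa[idx] %/% 2L),
      stringsAsFactors = FALSE)
    hits <- rbind(hits, spur)
  }
  msas <- lapply(models, `[[`, "msa")
  structure(list(
    genes = genes, hits = hits, contig_lengths = contig_lengths,
    msas = msas, family_models = models, truth = truth,
    subtype_table = do.call(rbind, subtypes) %||% data.frame(
      genome_id = character(), contig_id = character(), start = integer(),
      end = integer(), subtype = character(), stringsAsFactors = FALSE),
    config = cfg), class = "rn_sim_dataset")
}

#' @export
print.rn_sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<rn_sim_dataset> %d genomes, %d genes, %d hits, %d planted loci\n",
    length(x$contig_lengths), nrow(x$genes), nrow(x$hits),
    length(unique(stats::na.omit(x$truth$locus_id)))))
  invisible(x)
}

#' Generate synthetic phage proteomes with planted ring nucleases
#'
#' A configurable fraction of phages carries exactly one planted RN, with
#' family weights biased toward Crn2 (the phage anti-CRISPR AcrIII-1);
#' optionally some planted RNs have a conserved residue knocked out and
#' are expected to fail the screen. Proteins get dummy sequential
#' coordinates (phage gene order carries no meaning here).
#'
#' @param config an [sim_config()] (fields `n_phage`, `p_phage_rn`,
#'   `phage_rn_weights`, `p_phage_missing_residue`, `phage_n_proteins`).
#' @param family_models family models from a [generate_dataset()] result,
#'   so that cellular and phage RNs share reference alignments; `NULL`
#'   generates fresh ones.
#' @return list of class `rn_sim_phage`: `genes`, `hits`, `truth`,
#'   `msas`, `family_models`.
#' @export
generate_phage_set <- function(config, family_models = NULL) {
  stopifnot(inherits(config, "rn_sim_config"))
  with_seed(config$seed + 7919L, {
    cfg <- config
    if (is.null(family_models)) {
      fams <- names(cfg$phage_rn_weights)
      family_models <- lapply(fams, make_family_model, cfg = cfg)
      names(family_models) <- fams
    }
    genes <- list(); hits <- list(); truth <- list()
    for (p in seq_len(cfg$n_phage)) {
      phage <- sprintf("P%04d", p)
      cursor <- 1L
      for (k in seq_len(cfg$phage_n_proteins)) {
        len <- sample(80:400, 1L)
        gid <- sprintf("%s_g%03d", phage, k)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, genome_id = phage,
          contig_id = phage, start = cursor,
          end = cursor + 3L * len - 1L, strand = "+",
          protein_seq = rand_protein(len), length_aa = len,
          stringsAsFactors = FALSE)
        cursor <- cursor + 3L * len + 50L
      }
      if (runif(1) < cfg$p_phage_rn) {
        f <- sample_weighted(cfg$phage_rn_weights)
        ko <- runif(1) < cfg$p_phage_missing_residue
        gid <- sprintf("%s_rn1", phage)
        seq <- draw_rn_protein(family_models[[f]], cfg, knockout = ko)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, genome_id = phage, contig_id = phage,
          start = cursor, end = cursor + 3L * cfg$rn_length_aa - 1L,
          strand = "+", protein_seq = seq,
          length_aa = cfg$rn_length_aa, stringsAsFactors = FALSE)
        hits[[length(hits) + 1L]] <- strong_hit(gid, f, cfg$rn_length_aa)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = phage, gene_id = gid, family = f,
          expected_verdict = if (ko) "rejected-by-screen" else "annotated",
          stringsAsFactors = FALSE)
      }
    }
    empty_truth <- data.frame(genome_id = character(),
                              gene_id = character(), family = character(),
                              expected_verdict = character(),
                              stringsAsFactors = FALSE)
    structure(list(
      genes = do.call(rbind, genes) %||% empty_gene_table(),
      hits = do.call(rbind, hits) %||% empty_hit_table(),
      truth = do.call(rbind, truth) %||% empty_truth,
      msas = lapply(family_models, `[[`, "msa"),
      family_models = family_models), class = "rn_sim_phage")
  })
}

#' Simulate a Cas10 gene tree over the planted loci
#'
#' Random topology (for layout/annotation testing only — no evolutionary
#' model) whose tips are the planted Cas10 gene ids.
#'
#' @param dataset an `rn_sim_dataset`.
#' @return an `ape::phylo` tree.
#' @export
simulate_cas10_tree <- function(dataset) {
  ids <- dataset$truth$gene_id[dataset$truth$role == "cas10"]
  if (length(ids) < 2L) stop_fmt("need >=2 planted Cas10 genes for a tree")
  with_seed(dataset$config$seed + 104729L, {
    tr <- ape::rtree(length(ids))
    tr$tip.label <- sample(ids)
    tr
  })
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Per genome: `<genome>.gff3` + `<genome>.faa` + `<genome>.domtbl`;
#' reference alignments under `msas/<family>.afa`; `truth.tsv`,
#' `subtypes.tsv` and `contig_lengths.tsv` at the top level.
#'
#' @param dataset an `rn_sim_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "msas"), showWarnings = FALSE)
  for (genome in unique(dataset$genes$genome_id)) {
    sub <- dataset$genes[dataset$genes$genome_id == genome, , drop = FALSE]
    cl <- dataset$contig_lengths[unique(sub$contig_id)]
    write_genome_annotation(sub,
                            file.path(dir, paste0(genome, ".gff3")),
                            file.path(dir, paste0(genome, ".faa")),
                            contig_lengths = cl)
    h <- dataset$hits[dataset$hits$protein_id %in% sub$gene_id, ,
                      drop = FALSE]
    write_domtbl(h, file.path(dir, paste0(genome, ".domtbl")),
                 target_lengths = setNames(sub$length_aa, sub$gene_id))
  }
  for (f in names(dataset$msas)) {
    aa <- Biostrings::AAStringSet(dataset$msas[[f]])
    Biostrings::writeXStringSet(aa, file.path(dir, "msas",
                                              paste0(f, ".afa")))
  }
  write_tsv_table(dataset$truth, file.path(dir, "truth.tsv"))
  write_tsv_table(dataset$subtype_table, file.path(dir, "subtypes.tsv"))
  write_tsv_table(
    data.frame(contig_id = names(dataset$contig_lengths),
               length = as.integer(dataset$contig_lengths),
               genome_id = sub("_c1$", "", names(dataset$contig_lengths)),
               stringsAsFactors = FALSE),
    file.path(dir, "contig_lengths.tsv"))
  invisible(dir)
}

#' Evaluate pipeline annotations against a planted truth table
#'
#' Computes RN precision/recall (screen-passing RN annotations vs genes
#' planted as in-locus RNs), effector precision/recall, and the locus
#' count error, for end-to-end validation on synthetic data.
#'
#' @param annotated an `rn_annotated_loci`.
#' @param truth truth table from [generate_dataset()].
#' @return list with `rn_precision`, `rn_recall`, `effector_precision`,
#'   `effector_recall`, `n_loci_found`, `n_loci_truth`.
#' @export
evaluate_truth_recovery <- function(annotated, truth) {
  pr <- function(pred, pos) {
    list(precision = if (length(pred)) mean(pred %in% pos) else NA_real_,
         recall = if (length(pos)) mean(pos %in% pred) else NA_real_)
  }
  rn_pred <- annotated$rns$gene_id[annotated$rns$screen_status != "fail"]
  rn_true <- truth$gene_id[startsWith(truth$role, "rn:") &
                             truth$expected_verdict == "annotated"]
  eff_pred <- annotated$effectors$gene_id
  eff_true <- truth$gene_id[startsWith(truth$role, "effector:") &
                              truth$expected_verdict == "annotated"]
  a <- pr(rn_pred, rn_true); b <- pr(eff_pred, eff_true)
  list(rn_precision = a$precision, rn_recall = a$recall,
       effector_precision = b$precision, effector_recall = b$recall,
       n_loci_found = nrow(annotated$loci),
       n_loci_truth = length(unique(stats::na.omit(truth$locus_id))))
}
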