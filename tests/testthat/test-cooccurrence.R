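test_that("summary of an empty locus set is all zeros", {
  ann <- make_annotated(character(), empty_rns(), empty_effs())
  s <- summarize_cooccurrence(ann)
  expect_equal(nrow(s$family_counts), 0L)
  expect_equal(s$n_rn_positive_loci, 0L)
  expect_equal(s$n_multi_rn_loci, 0L)
  expect_equal(s$n_rn_loci_without_effector, 0L)
})

test_that("one locus with two RN families is one multi-RN locus with one instance each", {
  ann <- make_annotated(
    "G1_L01",
    data.frame(locus_id = "G1_L01", family = c("Crn1", "Csx15"),
               stringsAsFactors = FALSE),
    empty_effs())
  s <- summarize_cooccurrence(ann)
  expect_equal(s$n_multi_rn_loci, 1L)
  expect_equal(s$family_counts$n_instances, c(1L, 1L))
  expect_equal(s$family_counts$family, c("Crn1", "Csx15"))
  expect_equal(s$n_rn_loci_without_effector, 1L)
})

test_that("duplicate genes of one family count once per locus in locus counts", {
  ann <- make_annotated(
    "G1_L01",
    data.frame(locus_id = "G1_L01", family = c("Csx20", "Csx20"),
               stringsAsFactors = FALSE),
    empty_effs())
  s <- summarize_cooccurrence(ann)
  fc <- s$family_counts
  expect_equal(fc$n_instances[fc$family == "Csx20"], 2L)
  expect_equal(fc$n_loci[fc$family == "Csx20"], 1L)
  # a same-family pair is still a multi-RN locus by instance count
  expect_equal(s$n_multi_rn_loci, 1L)
})

test_that("screen-failed RNs are excluded from every co-occurrence statistic", {
  ann <- make_annotated(
    c("G1_L01", "G2_L01"),
    data.frame(locus_id = c("G1_L01", "G2_L01"),
               family = c("Crn1", "Crn3"),
               screen_status = c("pass", "fail"),
               stringsAsFactors = FALSE),
    data.frame(locus_id = c("G1_L01", "G2_L01"),
               family = c("Csx1", "Csx1"), stringsAsFactors = FALSE))
  s <- summarize_cooccurrence(ann)
  expect_equal(s$n_rn_positive_loci, 1L)
  expect_false("Crn3" %in% s$family_counts$family)
  ra <- restricted_association(ann)
  expect_equal(ra$n_with_rn[ra$family == "Csx1"], 1L)
  expect_equal(ra$n_loci[ra$family == "Csx1"], 2L)
})

test_that("summary equals a brute-force recount of the planted truth", {
  cfg <- sim_config(n_genomes = 40, seed = 81)
  ds <- generate_dataset(cfg)
  ann <- run_full(ds)
  s <- summarize_cooccurrence(ann)
  tr <- ds$truth[startsWith(ds$truth$role, "rn:") &
                   ds$truth$expected_verdict == "annotated", ]
  expect_equal(s$n_rn_instances, nrow(tr))
  expect_equal(s$n_rn_positive_loci, length(unique(tr$locus_id)))
  for (f in unique(tr$family)) {
    fc <- s$family_counts
    expect_equal(fc$n_instances[fc$family == f], sum(tr$family == f))
    expect_equal(fc$n_loci[fc$family == f],
                 length(unique(tr$locus_id[tr$family == f])))
  }
  k <- table(tr$locus_id)
  expect_equal(s$n_multi_rn_loci, sum(k > 1))
})

test_that("count conservation holds: instances minus RN-positive loci equals extra RNs in multi-RN loci", {
  for (seed in 82:86) {
    cfg <- sim_config(n_genomes = 15, p_multi_rn = 0.3, seed = seed)
    ds <- generate_dataset(cfg)
    s <- summarize_cooccurrence(run_full(ds))
    k <- sum(s$family_counts$n_instances)
    rhs <- if (nrow(s$multi_rn) > 0) sum(s$multi_rn$n_rn - 1L) else 0L
    expect_equal(k - s$n_rn_positive_loci, rhs)
    expect_true(all(s$family_counts$n_loci <= s$family_counts$n_instances))
  }
})

test_that("restricted association excludes multi-effector and multi-RN loci", {
  ann <- make_annotated(
    c("L1", "L2", "L3", "L4"),
    data.frame(locus_id = c("L1", "L3", "L3"),
               family = c("Csx20", "Crn1", "Csx15"),
               stringsAsFactors = FALSE),
    data.frame(locus_id = c("L1", "L2", "L2", "L3", "L4"),
               family = c("Cam1", "Cam1", "Csx1", "Cam1", "Cam1"),
               stringsAsFactors = FALSE))
  ra <- restricted_association(ann)
  # L2 has two effectors, L3 has two RNs: both excluded everywhere
  expect_equal(ra$n_loci[ra$family == "Cam1"], 2L)     # L1, L4
  expect_equal(ra$n_with_rn[ra$family == "Cam1"], 1L)  # L1
  expect_equal(ra$proportion[ra$family == "Cam1"], 0.5)
  expect_equal(ra$n_loci[ra$family == "Csx1"], 0L)
  expect_true(is.na(ra$proportion[ra$family == "Csx1"]))
})

test_that("restricted association arithmetic is k/n", {
  rns <- data.frame(locus_id = sprintf("L%02d", 1:8), family = "Csx20",
                    stringsAsFactors = FALSE)
  effs <- data.frame(locus_id = sprintf("L%02d", 1:10), family = "Cam1",
                     stringsAsFactors = FALSE)
  ann <- make_annotated(sprintf("L%02d", 1:10), rns, effs)
  ra <- restricted_association(ann)
  expect_equal(ra$proportion[ra$family == "Cam1"], 0.8)
})

test_that("network weights equal a brute-force pairwise locus count and stay bipartite", {
  set.seed(87)
  for (rep in 1:100) {
    n_loci <- sample(3:12, 1)
    ids <- sprintf("L%02d", seq_len(n_loci))
    rns <- data.frame(
      locus_id = sample(ids, sample(2:8, 1), replace = TRUE),
      stringsAsFactors = FALSE)
    rns$family <- sample(c("Crn1", "Csx16", "Csx20"), nrow(rns),
                         replace = TRUE)
    rns$screen_status <- sample(c("pass", "pass", "fail"), nrow(rns),
                                replace = TRUE)
    effs <- data.frame(
      locus_id = sample(ids, sample(2:8, 1), replace = TRUE),
      stringsAsFactors = FALSE)
    effs$family <- sample(c("Csx1", "Csm6", "Cam1"), nrow(effs),
                          replace = TRUE)
    ann <- make_annotated(ids, rns, effs)
    net <- build_network(ann)
    ref <- bf_edge_weights(rns, effs)
    got <- net$edges; rownames(got) <- NULL; rownames(ref) <- NULL
    expect_equal(got, ref, info = paste("rep", rep))
    t1 <- net$nodes$type[match(net$edges$rn, net$nodes$id)]
    t2 <- net$nodes$type[match(net$edges$effector, net$nodes$id)]
    expect_true(all(t1 == "RN" & t2 == "effector"))
  }
})

test_that("three loci sharing a Csx20/Csx1 pair give one edge of weight three", {
  rns <- data.frame(locus_id = c("L1", "L2", "L3"), family = "Csx20",
                    stringsAsFactors = FALSE)
  effs <- data.frame(locus_id = c("L1", "L2", "L3"), family = "Csx1",
                     stringsAsFactors = FALSE)
  net <- build_network(make_annotated(c("L1", "L2", "L3"), rns, effs))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3L)
  expect_equal(net$nodes$signal[net$nodes$id == "Csx1"], "cA4")
})

test_that("background frequency handles the in-locus-only and mixed cases", {
  # family present only inside loci -> 0
  genome_rns <- data.frame(
    genome_id = c("G001", "G002"), gene_id = c("a", "b"),
    family = "Csx15", bitscore = 100, evalue = 1e-20,
    screen_status = "pass", stringsAsFactors = FALSE)
  ann <- make_annotated(c("G001_L01", "G002_L01"), empty_rns(),
                        empty_effs())
  expect_equal(background_frequency(genome_rns, ann, "Csx15")$fraction, 0)
  # 4 carrier genomes, 1 without a locus -> 0.25
  genome_rns2 <- data.frame(
    genome_id = sprintf("G%03d", 1:4), gene_id = letters[1:4],
    family = "Csx15", bitscore = 100, evalue = 1e-20,
    screen_status = "pass", stringsAsFactors = FALSE)
  ann2 <- make_annotated(sprintf("G%03d_L01", 1:3), empty_rns(),
                         empty_effs())
  bf <- background_frequency(genome_rns2, ann2, "Csx15")
  expect_equal(bf$fraction, 0.25)
  expect_equal(bf$n_genomes_with_family, 4L)
  # absent family -> undefined, reported as such
  expect_true(is.na(background_frequency(genome_rns2, ann2,
                                         "Crn2")$fraction))
})

test_that("planted orphan-RN genomes are recovered in the background fraction", {
  cfg <- sim_config(n_genomes = 40, seed = 88,
                    loci_per_genome = c("0" = 0.5, "1" = 0.5),
                    orphan_family = "Csx15",
                    decoys = list(long_carf = 0, missing_residue = 0,
                                  out_of_window = 0, orphan_rn = 6))
  ds <- generate_dataset(cfg)
  ann <- run_full(ds)
  profs <- make_profiles(ds)
  grns <- screen_proteome_rns(ds$genes, ds$hits, family_catalogue(),
                              profs)
  bf <- background_frequency(grns, ann, "Csx15")
  # truth-based recount
  tr <- ds$truth
  carriers <- unique(tr$genome_id[tr$family %in% "Csx15" &
                                    grepl("rn|orphan", tr$role)])
  locus_genomes <- unique(tr$genome_id[!is.na(tr$locus_id)])
  expect_equal(bf$n_genomes_with_family, length(carriers))
  expect_equal(bf$n_without_locus,
               sum(!carriers %in% locus_genomes))
})

test_that("phage counts deduplicate at genome level", {
  rns <- data.frame(
    genome_id = c("P1", "P1", "P2", "P3"),
    gene_id = c("P1_a", "P1_b", "P2_a", "P3_a"),
    family = c("Crn2", "Crn2", "Crn2", "Csx20"),
    bitscore = 100, evalue = 1e-20,
    screen_status = c("pass", "pass", "pass", "fail"),
    stringsAsFactors = FALSE)
  pc <- phage_family_counts(rns)
  expect_equal(pc$n_genomes[pc$family == "Crn2"], 2L)
  expect_false("Csx20" %in% pc$family)
  expect_equal(nrow(phage_family_counts(rns[0, ])), 0L)
})

test_that("tree annotation keeps every leaf and flags locus content", {
  cfg <- sim_config(n_genomes = 20, seed = 89)
  ds <- generate_dataset(cfg)
  ann <- run_full(ds)
  tree <- simulate_cas10_tree(ds)
  # add one leaf with no locus
  tree2 <- ape::bind.tree(tree, ape::rtree(2, tip.label = c("nolocus1",
                                                            "nolocus2")))
  ta <- tree_annotation(tree2, ann)
  expect_equal(nrow(ta), length(tree2$tip.label))
  expect_true(all(is.na(ta$locus_id[ta$leaf %in% c("nolocus1",
                                                   "nolocus2")])))
  # RN presence columns match the annotations
  rns <- ann$rns[ann$rns$screen_status != "fail", ]
  for (f in family_catalogue()$rn_families) {
    fl <- unique(rns$locus_id[rns$family == f])
    with_locus <- !is.na(ta$locus_id)
    expect_equal(ta[[f]][with_locus] == 1L,
                 ta$locus_id[with_locus] %in% fl)
  }
  # cyclase-absent flag mirrors the Cas10 annotation
  m <- match(ta$locus_id[!is.na(ta$locus_id)], ann$loci$locus_id)
  expect_equal(ta$cyclase_absent[!is.na(ta$locus_id)],
               !ann$loci$has_cyclase[m])
  # duplicate labels abort
  tree3 <- tree
  tree3$tip.label[2] <- tree3$tip.label[1]
  expect_error(tree_annotation(tree3, ann), "duplicate leaf")
})
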