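test_that("generation is deterministic: same config and seed give byte-identical files", {
  cfg <- sim_config(n_genomes = 6, n_phage = 5, seed = 61,
                    decoys = list(long_carf = 2, missing_residue = 2,
                                  out_of_window = 2, orphan_rn = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  cfg2 <- sim_config(n_genomes = 6, n_phage = 5, seed = 62,
                     decoys = cfg$decoys)
  write_dataset(generate_dataset(cfg2), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "truth.tsv"))),
    unname(tools::md5sum(file.path(d3, "truth.tsv")))))
})

test_that("with all decoy and spurious rates zero every planted gene is expected annotated", {
  cfg <- sim_config(n_genomes = 15, seed = 63)
  ds <- generate_dataset(cfg)
  planted <- ds$truth[ds$truth$role != "background", ]
  expect_true(all(planted$expected_verdict == "annotated"))
  expect_true(all(ds$truth$expected_verdict[ds$truth$role == "background"]
                  == "none"))
})

test_that("forcing multi-RN loci yields the constructed multi-RN count downstream", {
  cfg <- sim_config(n_genomes = 20, loci_per_genome = c("1" = 1),
                    p_no_effector_locus = 0, p_rn_default = 1,
                    p_rn_given_effector = c(Csx1 = 1), p_multi_rn = 1,
                    seed = 64)
  ds <- generate_dataset(cfg)
  rn_per_locus <- table(ds$truth$locus_id[startsWith(ds$truth$role, "rn:")])
  expect_equal(length(rn_per_locus), 20L)
  expect_true(all(rn_per_locus >= 2L))
  ann <- run_full(ds)
  expect_equal(summarize_cooccurrence(ann)$n_multi_rn_loci, 20L)
})

test_that("planted gene coordinates never overlap on a contig", {
  for (seed in 65:70) {
    cfg <- sim_config(n_genomes = 8, seed = seed, n_background_genes = 8,
                      loci_per_genome = c("1" = 0.5, "2" = 0.5),
                      decoys = list(long_carf = 3, missing_residue = 3,
                                    out_of_window = 3, orphan_rn = 0))
    ds <- generate_dataset(cfg)
    for (ct in unique(ds$genes$contig_id)) {
      g <- ds$genes[ds$genes$contig_id == ct, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1)
        expect_true(all(g$start[-1] > g$end[-nrow(g)]), info = ct)
    }
  }
})

test_that("planted RNs satisfy the pipeline's own admission rules", {
  cfg <- sim_config(n_genomes = 12, seed = 71,
                    decoys = list(long_carf = 3, missing_residue = 3,
                                  out_of_window = 0, orphan_rn = 0))
  ds <- generate_dataset(cfg)
  rn_ids <- ds$truth$gene_id[startsWith(ds$truth$role, "rn:")]
  expect_true(all(
    ds$genes$length_aa[ds$genes$gene_id %in% rn_ids] <= 250))
  long_ids <- ds$truth$gene_id[ds$truth$role == "decoy:long_carf"]
  expect_true(all(
    ds$genes$length_aa[ds$genes$gene_id %in% long_ids] >= 251))
  # long decoys carry an RN-profile hit by construction
  rn_prof <- c(family_catalogue()$rn_families, "Csx14")
  for (id in long_ids)
    expect_true(any(ds$hits$family_id[ds$hits$protein_id == id] %in%
                      rn_prof))
  # planted RNs pass their family screen; knockouts fail
  profs <- make_profiles(ds)
  for (i in which(startsWith(ds$truth$role, "rn:"))) {
    fam <- ds$truth$family[i]
    seq <- ds$genes$protein_seq[ds$genes$gene_id == ds$truth$gene_id[i]]
    expect_equal(screen_candidate(seq, profs[[fam]])$status, "pass")
  }
  for (i in which(ds$truth$role == "decoy:missing_residue")) {
    fam <- ds$truth$family[i]
    seq <- ds$genes$protein_seq[ds$genes$gene_id == ds$truth$gene_id[i]]
    expect_equal(screen_candidate(seq, profs[[fam]])$status, "fail")
  }
})

test_that("out-of-window RNs start beyond the 6 kbp neighborhood of their locus", {
  cfg <- sim_config(n_genomes = 10, loci_per_genome = c("1" = 1),
                    seed = 72,
                    decoys = list(long_carf = 0, missing_residue = 0,
                                  out_of_window = 8, orphan_rn = 0))
  ds <- generate_dataset(cfg)
  ls <- build_loci(ds$genes, ds$hits, family_catalogue(),
                   ds$contig_lengths)
  oow <- ds$truth[ds$truth$role == "decoy:out_of_window", ]
  for (i in seq_len(nrow(oow))) {
    g <- ds$genes[ds$genes$gene_id == oow$gene_id[i], ]
    l <- ls$loci[ls$loci$genome_id == oow$genome_id[i], ]
    expect_true(g$start > l$span_end + 6000)
  }
})

test_that("a contig too short for the requested loci aborts with sizes", {
  expect_error(
    sim_config(n_genomes = 2, contig_length = 50000,
               loci_per_genome = c("3" = 1), seed = 73) |>
      generate_dataset(),
    "contig too short.*50000")
})

test_that("phage generation covers the empty, uniform and knockout cases", {
  cfg0 <- sim_config(n_phage = 0, seed = 74)
  ph0 <- generate_phage_set(cfg0)
  expect_equal(nrow(ph0$genes), 0L)
  expect_equal(nrow(ph0$truth), 0L)

  cfg1 <- sim_config(n_phage = 10, p_phage_rn = 1,
                     phage_rn_weights = c(Crn2 = 1), seed = 75)
  ph1 <- generate_phage_set(cfg1)
  expect_equal(nrow(ph1$truth), 10L)
  expect_true(all(ph1$truth$family == "Crn2"))
  profs <- setNames(
    lapply(names(ph1$msas), function(f)
      build_conservation_profile(ph1$msas[[f]], family = f)),
    names(ph1$msas))
  rns <- screen_proteome_rns(ph1$genes, ph1$hits, family_catalogue(),
                             profs)
  expect_equal(phage_family_counts(rns),
               data.frame(family = "Crn2", n_genomes = 10L,
                          stringsAsFactors = FALSE))

  cfg2 <- sim_config(n_phage = 12, p_phage_rn = 1,
                     p_phage_missing_residue = 1, seed = 76)
  ph2 <- generate_phage_set(cfg2)
  expect_true(all(ph2$truth$expected_verdict == "rejected-by-screen"))
  profs2 <- setNames(
    lapply(names(ph2$msas), function(f)
      build_conservation_profile(ph2$msas[[f]], family = f)),
    names(ph2$msas))
  rns2 <- screen_proteome_rns(ph2$genes, ph2$hits, family_catalogue(),
                              profs2)
  expect_true(all(rns2$screen_status == "fail"))
  expect_equal(nrow(phage_family_counts(rns2)), 0L)
})

test_that("spurious hits sit above the default e-value ceiling and are filtered", {
  cfg <- sim_config(n_genomes = 15, spurious_rate = 5, seed = 77)
  ds <- generate_dataset(cfg)
  # real planted hits are drawn below 1e-10, spurious ones above 1e-3
  spurious <- ds$hits[ds$hits$evalue > 1e-9, ]
  expect_gt(nrow(spurious), 0)
  expect_true(all(spurious$evalue > 1e-4))
  ann <- run_full(ds)
  ev <- evaluate_truth_recovery(ann, ds$truth)
  expect_equal(ev$rn_precision, 1)
  expect_equal(ev$effector_precision, 1)
})

test_that("a dataset written to disk reads back into an equivalent pipeline input", {
  cfg <- sim_config(n_genomes = 8, seed = 78)
  ds <- generate_dataset(cfg)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(d)
  g1 <- ds$genes[order(ds$genes$gene_id), ]; rownames(g1) <- NULL
  g2 <- back$genes[order(back$genes$gene_id), ]; rownames(g2) <- NULL
  expect_equal(g2, g1)
  expect_equal(back$contig_lengths[names(ds$contig_lengths)],
               ds$contig_lengths)
  h1 <- ds$hits[order(ds$hits$protein_id, ds$hits$family_id), ]
  h2 <- back$hits[order(back$hits$protein_id, back$hits$family_id), ]
  expect_equal(h2$protein_id, h1$protein_id)
  expect_equal(h2$bitscore, h1$bitscore, tolerance = 0.05)
  # annotating from files equals annotating in memory
  ann_mem <- run_full(ds)
  profs <- read_reference_profiles(back$msa_dir)
  ann_disk <- annotate_loci(
    build_loci(back$genes, back$hits, family_catalogue(),
               back$contig_lengths, subtype_table = back$subtype_table),
    back$genes, back$hits, family_catalogue(), profs)
  expect_equal(ann_disk$rns[order(ann_disk$rns$gene_id), "screen_status"],
               ann_mem$rns[order(ann_mem$rns$gene_id), "screen_status"])
  expect_equal(sort(ann_disk$effectors$gene_id),
               sort(ann_mem$effectors$gene_id))
})
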