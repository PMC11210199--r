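# Synthetic cohort generator: determinism, genome validity, burden
# asymmetry, channel fidelity, constructed selection, hotspot placement.

test_that("simulated genomes are deterministic, stop-free, and sized as
           configured", {
  cfg <- small_sim_config(seed = 3, n_genes = 5L,
                          cds_length_range = c(300L, 300L),
                          escape_genes = "ESC1",
                          driver_genes = list())
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_length(g1$gene_models, 5L)
  for (gm in g1$gene_models) {
    expect_equal(nchar(gm$cds_seq), 300L)
    aa <- escapesel:::translate_cds(gm$cds_seq)
    expect_false(grepl("\\*", aa))
  }
})

test_that("cohort simulation is deterministic and conserves bookkeeping", {
  cfg <- small_sim_config(seed = 21)
  s1 <- simulate_escape_cohort(cfg)
  s2 <- simulate_escape_cohort(cfg)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$clinical, s2$clinical)
  expect_equal(nrow(s1$catalog), nrow(s1$truth$mutations))
  expect_identical(validate_catalog(s1$catalog, s1$genome$gene_models),
                   s1$catalog)
})

test_that("mean burden ratio tracks the configured 4x asymmetry", {
  cfg <- small_sim_config(tmb_mean_pos = 400, tmb_mean_neg = 100,
                          n_patients_escape_pos = 100L,
                          n_patients_escape_neg = 100L)
  genome <- simulate_genome(cfg)
  ratios <- vapply(1:5, function(s) {
    cfg$seed <- s
    sim <- simulate_cohort(genome, cfg)
    truth <- sim$truth$patients
    tmb <- table(factor(sim$catalog$patient_id,
                        levels = truth$patient_id))
    mean(tmb[truth$true_group == "escape_pos"]) /
      mean(tmb[truth$true_group == "escape_neg"])
  }, numeric(1))
  expect_true(all(ratios > 3.2 & ratios < 4.8))
})

test_that("single-signature channel histogram matches the signature column
           (total variation <= 0.05)", {
  mix <- c(SYN_FLAT = 0, SYN_CT = 1, SYN_CA = 0, SYN_TC = 0)
  cfg <- small_sim_config(
    seed = 8, signature_mix_pos = mix, signature_mix_neg = mix,
    tmb_mean_pos = 1000, tmb_mean_neg = 1000,
    n_patients_escape_pos = 50L, n_patients_escape_neg = 50L,
    driver_genes = list(), escape_genes = character(0), n_genes = 30L
  )
  sim <- simulate_escape_cohort(cfg)
  expect_gt(nrow(sim$catalog), 9e4)
  emp <- table(factor(sim$truth$mutations$channel96,
                      levels = sbs96_contexts()))
  emp <- as.numeric(emp) / sum(emp)
  # availability-adjusted expectation (channels absent from the genome
  # are redrawn by the generator)
  avail <- tabulate(sim$genome$opportunity$cls96, 96) > 0
  expected <- default_signature_catalog()$matrix[, "SYN_CT"]
  expected[!avail] <- 0
  expected <- expected / sum(expected)
  tv <- 0.5 * sum(abs(emp - expected))
  expect_lte(tv, 0.05)
})

test_that("a gene simulated at w_mis = 5 shows a counting dN/dS in [3.5, 7]", {
  # flat-per-site background: the counting estimator is exactly calibrated
  cfg <- small_sim_config(seed = 13, tmb_mean_pos = 120, tmb_mean_neg = 120)
  genome <- simulate_genome(cfg)
  cfg$signature_catalog <- opportunity_signature(genome)
  cfg$signature_mix_pos <- cfg$signature_mix_neg <- c(UNIF = 1)
  sim <- simulate_cohort(genome, cfg)
  sim$genome <- genome
  drv <- sim$catalog[sim$catalog$gene_id == "DRV1", ]
  expect_gt(nrow(drv), 200)
  im <- build_impact_matrix(sim$genome$gene_models$DRV1)
  L_syn <- sum(im$L[, "synonymous"])
  L_mis <- sum(im$L[, "missense"])
  n_syn <- sum(drv$variant_class == "synonymous")
  n_mis <- sum(drv$variant_class == "missense")
  w_count <- (n_mis / L_mis) / (n_syn / L_syn)
  expect_gt(w_count, 3.5)
  expect_lt(w_count, 7)
})

test_that("hotspot concentration applies to the configured group only", {
  cfg <- small_sim_config(
    seed = 17,
    hotspot_spec = list(DRV1 = list(aa_pos = 40L, rho = 0.9)),
    tmb_mean_pos = 120, tmb_mean_neg = 120
  )
  sim <- simulate_escape_cohort(cfg)
  truth <- stats::setNames(sim$truth$patients$true_group,
                           sim$truth$patients$patient_id)
  mis <- sim$catalog[sim$catalog$gene_id == "DRV1" &
                       sim$catalog$variant_class == "missense", ]
  aa <- genomic_to_protein(sim$genome$gene_models$DRV1, mis$position)
  grp <- truth[mis$patient_id]
  expect_gte(mean(aa[grp == "escape_neg"] == 40L), 0.7)
  expect_lte(mean(aa[grp == "escape_pos"] == 40L), 0.2)
})

test_that("escape guarantee and chance rate produce near-perfect group
           recovery from mutations alone", {
  cfg <- small_sim_config(seed = 23, n_patients_escape_pos = 100L,
                          n_patients_escape_neg = 100L)
  sim <- simulate_escape_cohort(cfg)
  lab <- classify_point_mutation(sim$catalog, cfg$escape_genes)
  truth <- stats::setNames(sim$truth$patients$true_group,
                           sim$truth$patients$patient_id)
  expect_gte(mean(lab$status == truth[lab$patient_id]), 0.99)
})

test_that("written cohort artifacts read back consistently", {
  cfg <- small_sim_config(seed = 29, n_patients_escape_pos = 10L,
                          n_patients_escape_neg = 10L, n_genes = 8L,
                          tmb_mean_pos = 20, tmb_mean_neg = 20,
                          escape_genes = paste0("ESC", 1:2))
  sim <- simulate_escape_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  gms <- read_gene_models(paths["genes"], paths["fasta"])
  rec <- read_maf(paths["maf"], gms)
  expect_equal(nrow(rec), nrow(sim$catalog))
  expect_equal(nrow(attr(rec, "rejected")), 0L)
  expect_equal(rec$context, sim$catalog$context)
  tabs <- read_tables(paths["clinical"], paths["expression"], paths["cnv"])
  expect_equal(nrow(tabs$clinical), 20L)
})
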