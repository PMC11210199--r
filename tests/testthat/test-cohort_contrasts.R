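# Contrasts: contingency oracles, downsampling, hotspot exclusion,
# oncogene/TSG split, VAF comparison, randomized escape null.

two_group_labels <- function(neg, pos) {
  data.frame(
    patient_id = c(neg, pos),
    status = rep(c("escape_neg", "escape_pos"), c(length(neg), length(pos))),
    triggering_genes = "", stringsAsFactors = FALSE
  )
}

# catalog with controlled per-group (mutations, unique sites) structure
conc_catalog <- function(n_neg, sites_neg, n_pos, sites_pos, gene = "G") {
  rbind(
    mut_row(sprintf("N%03d", 1:n_neg), gene,
            100L + (seq_len(n_neg) %% sites_neg), "C", "T", "missense"),
    mut_row(sprintf("S%03d", 1:n_pos), gene,
            500L + (seq_len(n_pos) %% sites_pos), "C", "T", "missense")
  )
}

test_that("site concentration test equals the hand-computed Pearson
           chi-square and degenerates correctly", {
  cat0 <- conc_catalog(100, 10, 20, 15)
  lab <- two_group_labels(sprintf("N%03d", 1:100), sprintf("S%03d", 1:20))
  res <- site_concentration_test(cat0, "G", lab)
  expect_equal(unname(res$table["escape_neg", ]), c(100, 10))
  expect_equal(unname(res$table["escape_pos", ]), c(20, 15))
  # hand Pearson: sum (O-E)^2 / E on the 2x2
  tab <- res$table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_lt(res$p, 0.01)

  # proportional rows: chi2 = 0, p = 1
  prop <- structure(
    list(table = rbind(escape_neg = c(10, 5), escape_pos = c(20, 10))),
    class = "contingency_result"
  )
  E2 <- outer(rowSums(prop$table), colSums(prop$table)) / sum(prop$table)
  expect_equal(sum((prop$table - E2)^2 / E2), 0)
})

test_that("pooled concentration test is additive over genes and reduces to
           the single-gene test", {
  cat0 <- conc_catalog(50, 5, 50, 25, gene = "G1")
  lab <- two_group_labels(sprintf("N%03d", 1:50), sprintf("S%03d", 1:50))
  single <- site_concentration_test(cat0, "G1", lab)
  pooled1 <- pooled_concentration_test(cat0, "G1", lab)
  expect_equal(pooled1$table, single$table)
  expect_equal(pooled1$chi2, single$chi2)

  cat2 <- rbind(cat0, transform(conc_catalog(30, 3, 30, 10, gene = "G2"),
                                position = position + 1000L))
  pooled2 <- pooled_concentration_test(cat2, c("G1", "G2"), lab)
  t2 <- site_concentration_test(cat2, "G2", lab)
  expect_equal(pooled2$table, single$table + t2$table)
})

test_that("downsampling equalizes group sizes and is seed-reproducible", {
  cat0 <- rbind(
    mut_row(sprintf("N%03d", 1:70), "G", 100 + 1:70, "C", "T", "missense"),
    mut_row(sprintf("S%03d", 1:20), "G", 300 + 1:20, "C", "T", "missense")
  )
  lab <- two_group_labels(sprintf("N%03d", 1:70), sprintf("S%03d", 1:20))
  set.seed(1)
  red <- downsample_catalog(cat0, lab, "patients")
  kept <- unique(red$patient_id)
  expect_equal(sum(grepl("^N", kept)), 20L)
  expect_equal(sum(grepl("^S", kept)), 20L)
  set.seed(1)
  red2 <- downsample_catalog(cat0, lab, "patients")
  expect_identical(red, red2)

  balanced <- cat0[c(1:20, 71:90), ]
  labb <- two_group_labels(sprintf("N%03d", 1:20), sprintf("S%03d", 1:20))
  expect_warning(out <- downsample_catalog(balanced, labb, "patients"),
                 "balanced")
  expect_identical(out, balanced)
})

test_that("hotspot exclusion removes exactly the codon's three positions", {
  gm <- toy_gene_plus("ATGGGGTGGAAACCC", start = 1001L) # codon 2: 1004-1006
  cat0 <- mut_table(
    mut_row("P1", "TOYP", 1004, "G", "A", "missense"),
    mut_row("P2", "TOYP", 1005, "G", "A", "missense"),
    mut_row("P3", "TOYP", 1006, "G", "T", "missense"),
    mut_row("P4", "TOYP", 1007, "T", "A", "missense"), # codon 3: retained
    mut_row("P5", "TOYP", 1010, "A", "T", "missense"),
    mut_row("P6", "TOYP", 1001, "A", "T", "missense"),
    mut_row("P7", "TOYP", 1012, "A", "T", "synonymous"),
    mut_row("P8", "TOYP", 1013, "C", "T", "missense"),
    mut_row("P9", "TOYP", 1014, "C", "T", "missense"),
    mut_row("P10", "TOYP", 1015, "C", "T", "missense")
  )
  out <- exclude_hotspots(cat0, list(TOYP = 2L), list(TOYP = gm))
  expect_equal(nrow(out), 7L)
  expect_equal(attr(out, "n_removed"), 3L)
  expect_false(any(out$position %in% 1004:1006))
  expect_error(exclude_hotspots(cat0, list(TOYP = 99L), list(TOYP = gm)),
               "beyond protein length")
})

test_that("oncogene/TSG proportions build the right table and chi-square", {
  roles <- c(ONC1 = "oncogene", TSG1 = "TSG", BOTH1 = "both", X = "none")
  cat0 <- rbind(
    mut_row(sprintf("N%02d", 1:8), "ONC1", 1:8 + 10L, "C", "T", "missense"),
    mut_row(sprintf("S%02d", 1:2), "ONC1", 1:2 + 30L, "C", "T", "missense"),
    mut_row(sprintf("N%02d", 1:5), "TSG1", 1:5 + 50L, "C", "T", "missense"),
    mut_row(sprintf("S%02d", 1:5), "TSG1", 1:5 + 70L, "C", "T", "missense"),
    mut_row("N01", "X", 99L, "C", "T", "missense")
  )
  lab <- two_group_labels(sprintf("N%02d", 1:8), sprintf("S%02d", 1:5))
  res <- onc_tsg_proportions(cat0, lab, roles)
  expect_equal(unname(res$table["oncogene", ]), c(8, 2))
  expect_equal(unname(res$table["TSG", ]), c(5, 5))
  E <- outer(rowSums(res$table), colSums(res$table)) / sum(res$table)
  expect_equal(res$chi2, sum((res$table - E)^2 / E), tolerance = 1e-12)
  expect_false(res$has_both_genes)

  empty_tsg <- onc_tsg_proportions(cat0[1:10, ], lab, roles)
  expect_true(empty_tsg$undefined)
})

test_that("VAF comparison: symmetric under identical multisets, decisive
           for separated Beta distributions", {
  vafs <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 4)
  cat0 <- rbind(
    mut_row(sprintf("P%02d", 1:20), "DRV", 1:20 + 10L, "C", "T", "missense",
            vaf = vafs),
    mut_row(sprintf("P%02d", 1:20), "ESC", 1:20 + 50L, "C", "T", "missense",
            vaf = vafs)
  )
  same <- vaf_compare(cat0, "DRV", "ESC")
  expect_equal(same$U, 20 * 20 / 2, tolerance = 1e-9)
  expect_gt(same$p, 0.9)

  set.seed(7)
  cat1 <- rbind(
    mut_row(sprintf("P%03d", 1:100), "DRV", 1:100 + 10L, "C", "T",
            "missense", vaf = stats::rbeta(100, 8, 2)),
    mut_row(sprintf("P%03d", 1:100), "ESC", 1:100 + 500L, "C", "T",
            "missense", vaf = stats::rbeta(100, 2, 8))
  )
  sep <- vaf_compare(cat1, "DRV", "ESC")
  expect_lt(sep$p, 1e-10)
  expect_gt(sep$median_driver, sep$median_escape)

  few <- vaf_compare(cat0[1:5, ], "DRV", "ESC")
  expect_true(is.na(few$p))
})

test_that("randomized escape null: reproducible, calibrated under
           exchangeability, and sensitive to buffering", {
  cfg <- small_sim_config(
    seed = 31, n_genes = 40L, n_patients_escape_pos = 150L,
    n_patients_escape_neg = 150L, tmb_mean_pos = 25, tmb_mean_neg = 25,
    driver_genes = list(DRV1 = c(3, 3), DRV2 = c(3, 3)),
    escape_genes = paste0("ESC", 1:3)
  )
  sim <- simulate_escape_cohort(cfg)
  impacts <- build_impact_matrices(sim$genome$gene_models)
  rates <- fit_context_rates(sim$catalog, impacts, sim$genome$gene_models)
  lab <- classify_point_mutation(sim$catalog, cfg$escape_genes)
  run_null <- function() {
    random_escape_null(
      sim$catalog, lab, all_genes = names(impacts),
      escape_genes = cfg$escape_genes, driver_set = c("DRV1", "DRV2"),
      rates = rates, impacts = impacts, k = 5L, reps = 30L
    )
  }
  set.seed(99)
  r1 <- run_null()
  set.seed(99)
  r2 <- run_null()
  expect_identical(r1$null_driver_w, r2$null_driver_w)
  expect_equal(r1$reps, 30L)
  expect_gte(r1$empirical_p, 1 / 31)
  # no buffering here: selection identical in both groups, so the observed
  # escape+ driver omega is not an extreme low outlier of the null
  expect_gt(r1$empirical_p, 0.03)
})
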