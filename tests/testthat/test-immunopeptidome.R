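# Protein <-> genome mapping and region-based filtering / masked dN/dS.

test_that("protein positions map to the documented genomic arithmetic", {
  # plus strand, CDS genomic start 1001: protein 2-3 -> genomic 1004-1009
  gmp <- toy_gene_plus("ATGGGGTGGAAACCC", start = 1001L)
  reg <- protein_to_genomic(gmp, 2L, 3L)
  expect_equal(reg$start, 1004L)
  expect_equal(reg$end, 1009L)

  # minus strand, CDS genomic end 2000: protein 1 -> genomic 1998-2000
  gmm <- toy_gene_minus(end = 2000L)
  reg2 <- protein_to_genomic(gmm, 1L)
  expect_equal(reg2$start, 1998L)
  expect_equal(reg2$end, 2000L)

  expect_error(protein_to_genomic(gmp, 4L, 99L), "outside")
})

test_that("regions spanning exon junctions split but conserve width, and
           the round trip is exact on both strands", {
  for (strand in c("+", "-")) {
    gm <- toy_gene_multiexon(strand) # exons 101-109 + 201-206
    n_aa <- nchar(gm$cds_seq) / 3
    # codon 4 spans the junction for the plus strand (CDS 10-12)
    for (aa in seq_len(n_aa)) {
      reg <- protein_to_genomic(gm, aa)
      expect_equal(sum(reg$end - reg$start + 1L), 3L, info = strand)
      gpos <- unlist(Map(seq, reg$start, reg$end))
      expect_setequal(genomic_to_protein(gm, gpos), aa)
    }
    # a multi-codon region splits across the junction
    reg_all <- protein_to_genomic(gm, 1L, n_aa)
    expect_equal(nrow(reg_all), 2L)
    expect_equal(sum(reg_all$end - reg_all$start + 1L), 3L * n_aa)
  }
})

test_that("filter modes partition the catalog and respect inclusive
           interval ends", {
  regions <- list(global = data.frame(chrom = "chr1", start = 1004L,
                                      end = 1009L, gene_id = "TOYP"))
  cat0 <- do.call(rbind, lapply(1001:1020, function(p) {
    mut_row("P1", "TOYP", p, "C", "T", "missense")
  }))
  excl <- filter_by_regions(cat0, regions, "exclude")
  restr <- filter_by_regions(cat0, regions, "restrict")
  expect_equal(nrow(excl) + nrow(restr), nrow(cat0))
  expect_false(1005 %in% excl$position)
  expect_true(1009 %in% restr$position) # inclusive end
  expect_false(1010 %in% restr$position)
  expect_equal(nrow(restr), 6L)
})

test_that("patient-specific regions override the global fallback", {
  regions <- list(
    global = data.frame(chrom = "chr1", start = 100L, end = 200L,
                        gene_id = "G"),
    P2 = data.frame(chrom = "chr1", start = 300L, end = 400L, gene_id = "G")
  )
  cat0 <- mut_table(
    mut_row("P1", "G", 150, "C", "T", "missense"), # in global -> excluded
    mut_row("P2", "G", 150, "C", "T", "missense"), # P2 has own set -> kept
    mut_row("P2", "G", 350, "C", "T", "missense") # in P2 set -> excluded
  )
  out <- filter_by_regions(cat0, regions, "exclude")
  expect_equal(nrow(out), 1L)
  expect_equal(out$patient_id, "P2")
  expect_equal(out$position, 150L)
})

test_that("immunopeptidome TSV reader validates and maps through
           transcripts", {
  gm <- toy_gene_plus("ATGGGGTGGAAACCC", start = 1001L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ip.tsv")
  utils::write.table(
    data.frame(patient_id = "global", transcript_id = gm$transcript_id,
               start_aa = 2L, end_aa = 3L),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  regions <- regions_to_genomic(read_immunopeptidome(path),
                                list(TOYP = gm))
  expect_equal(regions$global$start, 1004L)
  expect_equal(regions$global$end, 1009L)
})

test_that("region-masked dN/dS: identity under empty regions, and masking
           opportunity without mutations raises omega", {
  cfg <- small_sim_config(seed = 47, n_genes = 12L,
                          tmb_mean_pos = 15, tmb_mean_neg = 15)
  sim <- simulate_escape_cohort(cfg)
  gms <- sim$genome$gene_models
  impacts <- build_impact_matrices(gms)
  rates <- fit_context_rates(sim$catalog, impacts, gms)
  gene_set <- c("DRV1", "G001", "G002")

  empty <- list(global = data.frame(chrom = character(0),
                                    start = integer(0), end = integer(0),
                                    gene_id = character(0)))
  id <- filtered_dnds(sim$catalog, empty, gene_set, gms, rates)
  expect_equal(id$filtered$w, id$original$w, tolerance = 1e-12)

  # mask a stretch of G001 carrying opportunity but (by construction) no
  # observed mutations: n unchanged, E decreases, omega increases
  g1 <- gms$G001
  taken <- sort(unique(sim$catalog$position[sim$catalog$gene_id == "G001"]))
  aa_mutated <- unique(genomic_to_protein(g1, taken))
  aa_free <- setdiff(seq_len(nchar(g1$cds_seq) / 3), aa_mutated)
  block <- aa_free[1:20]
  mask <- do.call(rbind, lapply(block, function(a) {
    cbind(protein_to_genomic(g1, a), gene_id = "G001")
  }))
  res <- filtered_dnds(sim$catalog, list(global = mask), "G001", gms, rates)
  expect_equal(res$filtered$n_mis + res$filtered$n_non,
               res$original$n_mis + res$original$n_non)
  expect_lt(res$filtered$E_mis, res$original$E_mis)
  expect_gt(res$filtered$w, res$original$w)
})
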