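# Shared fixtures: tiny hand-built gene models and catalogs.

# single-exon plus-strand gene: CDS = chromosome[1001..(1000+len)]
toy_gene_plus <- function(cds = "ATGGGGTGGAAACCCTAA", start = 1001L,
                          gene_id = "TOYP") {
  cds <- sub("TAA$", "", cds) # drop stop if provided
  gene_model(
    gene_id = gene_id, chrom = "chr1", strand = "+",
    exons = cbind(start = start, end = start + nchar(cds) - 1L),
    cds_seq = cds, flank5 = "C", flank3 = "G"
  )
}

# single-exon minus-strand gene with CDS ending at genomic `end`
toy_gene_minus <- function(cds = "ATGGGGTGGAAACCC", end = 2000L,
                           gene_id = "TOYM") {
  gene_model(
    gene_id = gene_id, chrom = "chr1", strand = "-",
    exons = cbind(start = end - nchar(cds) + 1L, end = end),
    cds_seq = cds, flank5 = "C", flank3 = "G"
  )
}

# two-exon plus-strand gene (CDS split 9 + 6)
toy_gene_multiexon <- function(strand = "+") {
  cds <- "ATGGGGTGGAAACCC"
  gene_model(
    gene_id = paste0("TOYX", strand), chrom = "chr1", strand = strand,
    exons = cbind(start = c(101L, 201L), end = c(109L, 206L)),
    cds_seq = cds, flank5 = "C", flank3 = "G"
  )
}

# minimal catalog row builder
mut_row <- function(patient, gene, pos, ref, alt, vclass,
                    context = NA_character_, vaf = NA_real_,
                    cancer_type = "T01") {
  data.frame(
    patient_id = patient, gene_id = gene, chromosome = "chr1",
    position = as.integer(pos), ref_allele = ref, alt_allele = alt,
    variant_class = vclass, context = context, vaf = vaf,
    cancer_type = cancer_type, is_snv = nchar(ref) == 1 & nchar(alt) == 1,
    stringsAsFactors = FALSE
  )
}

mut_table <- function(...) do.call(rbind, list(...))

# small equal-mix simulation config for fast tests
small_sim_config <- function(seed = 1L, ...) {
  mix <- c(SYN_FLAT = 0.25, SYN_CT = 0.25, SYN_CA = 0.25, SYN_TC = 0.25)
  args <- list(
    seed = seed, n_patients_escape_pos = 40L, n_patients_escape_neg = 40L,
    n_genes = 20L, cds_length_range = c(450L, 900L),
    driver_genes = list(DRV1 = c(w_mis = 5, w_non = 5)),
    escape_genes = paste0("ESC", 1:3),
    hotspot_spec = list(),
    tmb_mean_pos = 60, tmb_mean_neg = 60,
    signature_mix_pos = mix, signature_mix_neg = mix
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_sim_config, args)
}

# labels table straight from a simulation's truth ledger
truth_labels <- function(sim) {
  data.frame(
    patient_id = sim$truth$patients$patient_id,
    status = sim$truth$patients$true_group,
    triggering_genes = "",
    stringsAsFactors = FALSE
  )
}
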