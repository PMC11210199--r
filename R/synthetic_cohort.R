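# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: an
# immune-escaped (escape+) group with ~4x the mutation burden of the
# non-escaped (escape-) group, positively selected driver genes (dN/dS = w
# by construction via rejection sampling), a missense hotspot concentrated
# in one group, group-specific mutational-signature mixtures, role-specific
# clonality (VAF) distributions, and a survival disadvantage for escape+
# patients confined to the inflammatory immune category (C3). Everything is
# deterministic under the config seed, and every latent assignment is
# recorded in a truth ledger.

#' Built-in synthetic signature catalog
#'
#' Four synthetic, well-separated single-base-substitution signatures
#' (pairwise cosine similarity < 0.9) used as the default catalog:
#' \describe{
#'   \item{SYN_FLAT}{uniform over all 96 channels}
#'   \item{SYN_CT}{C>T transitions, strongest in NCG contexts (ageing-like)}
#'   \item{SYN_CA}{C>A transversions in TCN contexts (tobacco/APOBEC-like)}
#'   \item{SYN_TC}{T>C transitions (mismatch-repair-like)}
#' }
#' These are synthetic stand-ins constructed in code, not COSMIC signatures.
#'
#' @return A `signature_catalog` with 4 columns.
#' @export
default_signature_catalog <- function() {
  ctx <- sbs96_contexts()
  sub <- substr(ctx, 3, 5)
  f5 <- substr(ctx, 1, 1)
  f3 <- substr(ctx, 7, 7)
  flat <- rep(1 / 96, 96)
  ct <- ifelse(sub == "C>T", ifelse(f3 == "G", 8, 1), 0.05)
  ca <- ifelse(sub == "C>A", ifelse(f5 == "T", 8, 1), 0.05)
  tc <- ifelse(sub == "T>C", 4, 0.05)
  mat <- cbind(
    SYN_FLAT = flat, SYN_CT = ct / sum(ct), SYN_CA = ca / sum(ca),
    SYN_TC = tc / sum(tc)
  )
  signature_catalog(mat)
}

#' Opportunity-weighted uniform signature for a simulated genome
#'
#' A single-column signature whose channel probabilities are proportional
#' to the genome's site opportunities, so that placement under it is
#' uniform per site. Under this flat-per-site mutational process the naive
#' counting estimator (n_N / L_N) / (n_S / L_S) is exactly calibrated,
#' which makes it the background of choice for oracle checks of the dN/dS
#' machinery.
#'
#' @param genome A [simulate_genome()] result.
#' @return A `signature_catalog` with one column `UNIF`.
#' @export
opportunity_signature <- function(genome) {
  n_c <- tabulate(genome$opportunity$cls96, nbins = 96L)
  signature_catalog(matrix(n_c / sum(n_c), ncol = 1,
                           dimnames = list(NULL, "UNIF")))
}

#' Simulation configuration for a synthetic escape cohort
#'
#' Defaults encode the study conditions the generator emulates: escape+
#' mean burden 426 mutations/patient vs 95 for escape- (~4.5x), every
#' escape+ patient carrying a non-silent escape-gene SNV, a handful of
#' positively selected driver genes, one escape-group-restricted missense
#' hotspot, group-differential signature mixtures, driver mutations more
#' clonal than escape mutations, and a survival hazard ratio > 1 for
#' escape+ applied only within immune category C3.
#'
#' @param seed Integer master seed.
#' @param n_patients_escape_pos,n_patients_escape_neg Group sizes.
#' @param n_genes Total genes (>= named driver + escape genes).
#' @param cds_length_range Integer pair; CDS lengths drawn uniformly and
#'   rounded to multiples of 3.
#' @param gene_length_overrides Optional named integer vector fixing the
#'   CDS length of specific genes (e.g. long driver genes), overriding the
#'   uniform draw.
#' @param driver_genes Named list `gene -> c(w_mis, w_non)` selection
#'   multipliers (>= 0).
#' @param driver_genes_escape_pos Optional named list overriding
#'   `driver_genes` selection multipliers for mutations arising in escape+
#'   patients; genes not named keep their `driver_genes` values. This
#'   models immune escape buffering selection on drivers (weaker positive
#'   selection once a tumor has escaped).
#' @param escape_genes Character vector of escape gene names.
#' @param escape_mutation_prob Probability an escape+ patient is guaranteed
#'   a non-silent escape-gene SNV (default 1).
#' @param escape_chance_rate Expected number of background escape-gene
#'   mutations per patient, either group (default 0.01). Escape genes are
#'   a tiny target in a real exome (88 of ~19,500 genes), so chance hits
#'   are rare; a desk-scale panel over-represents them, and the generator
#'   therefore reproduces the real-geometry hit rate directly instead of
#'   inheriting the panel's inflated escape-gene fraction.
#' @param tmb_mean_pos,tmb_mean_neg Expected mutations per patient within
#'   the simulated gene panel (defaults 426 and 95).
#' @param signature_catalog A `signature_catalog` (default the built-in
#'   synthetic one).
#' @param signature_mix_pos,signature_mix_neg Mixing weights over catalog
#'   columns, each summing to 1.
#' @param hotspot_spec Named list `gene -> list(aa_pos, rho)`; with
#'   probability `rho` a missense mutation in that gene (in
#'   `hotspot_group` patients) is relocated to the hotspot codon.
#' @param hotspot_group Group the hotspot concentration applies to
#'   (default `"escape_neg"`).
#' @param vaf_params Named list of beta shape pairs for `driver`, `escape`,
#'   `passenger` mutation VAFs.
#' @param survival_params List: `baseline_hazard` (per day), `hr_pos_c3`
#'   (hazard ratio for escape+ within C3), `horizon` (uniform censoring
#'   upper bound, days), `category_probs` (named probabilities over
#'   C1..C6).
#' @param n_cancer_types Cancer-type labels patients are spread over.
#' @param cnv_del_prob,cnv_homdel_prob Per patient x escape-gene
#'   probabilities of copy number 1 and 0.
#' @param pdl1_gene Expression gene symbol emitted (default "CD274").
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    seed = 1L,
    n_patients_escape_pos = 100L,
    n_patients_escape_neg = 100L,
    n_genes = 60L,
    cds_length_range = c(600L, 1200L),
    gene_length_overrides = NULL,
    driver_genes = list(
      DRV1 = c(w_mis = 5, w_non = 5), DRV2 = c(w_mis = 3, w_non = 3),
      DRV3 = c(w_mis = 3, w_non = 1), DRV4 = c(w_mis = 2, w_non = 4)
    ),
    driver_genes_escape_pos = list(),
    escape_genes = paste0("ESC", 1:8),
    escape_mutation_prob = 1.0,
    escape_chance_rate = 0.01,
    tmb_mean_pos = 426,
    tmb_mean_neg = 95,
    signature_catalog = default_signature_catalog(),
    signature_mix_pos = c(SYN_FLAT = 0.2, SYN_CT = 0.2, SYN_CA = 0.5,
                          SYN_TC = 0.1),
    signature_mix_neg = c(SYN_FLAT = 0.3, SYN_CT = 0.4, SYN_CA = 0.1,
                          SYN_TC = 0.2),
    hotspot_spec = list(DRV1 = list(aa_pos = 50L, rho = 0.9)),
    hotspot_group = "escape_neg",
    vaf_params = list(driver = c(9, 11), escape = c(6, 14),
                      passenger = c(5, 15)),
    survival_params = list(
      baseline_hazard = 1 / 1500, hr_pos_c3 = 2.5, horizon = 4000,
      category_probs = stats::setNames(rep(1 / 6, 6), paste0("C", 1:6))
    ),
    n_cancer_types = 1L,
    cnv_del_prob = 0.10,
    cnv_homdel_prob = 0.02,
    pdl1_gene = "CD274") {
  mix_ok <- function(m) abs(sum(m) - 1) < 1e-8 && all(m >= 0)
  if (!mix_ok(signature_mix_pos) || !mix_ok(signature_mix_neg)) {
    stop("signature mixes must be nonnegative and sum to 1")
  }
  if (length(signature_mix_pos) != length(signature_catalog$names) ||
      length(signature_mix_neg) != length(signature_catalog$names)) {
    stop("signature mix dimension must equal the catalog's K")
  }
  for (h in hotspot_spec) {
    if (h$rho < 0 || h$rho > 1) stop("hotspot rho must be in [0, 1]")
  }
  if (n_genes < length(driver_genes) + length(escape_genes)) {
    stop("n_genes smaller than the number of named driver + escape genes")
  }
  stopifnot(n_patients_escape_pos >= 0, n_patients_escape_neg >= 0,
            tmb_mean_pos > 0, tmb_mean_neg > 0)
  structure(as.list(environment()), class = "cohort_sim_config")
}

sense_codons <- function() {
  if (is.null(.pkg_cache$sense)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$sense <- names(gc)[gc != "*"]
  }
  .pkg_cache$sense
}

#' Simulate a synthetic genome (gene models + reference sequence)
#'
#' Genes are intronless, placed sequentially on one chromosome with short
#' random spacers, on randomly chosen strands. CDS sequences are built from
#' sense codons only, so they are guaranteed free of internal stops.
#' Deterministic under `config$seed`.
#'
#' @param config A [cohort_sim_config()].
#' @return List of class `sim_genome`: `gene_models` (named list), `genome`
#'   (named character, chromosome sequences), and a precomputed
#'   site-opportunity table (`opportunity`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  gene_ids <- c(names(config$driver_genes), config$escape_genes)
  n_fill <- config$n_genes - length(gene_ids)
  if (n_fill > 0) gene_ids <- c(gene_ids, sprintf("G%03d", seq_len(n_fill)))

  rng <- seq(config$cds_length_range[1], config$cds_length_range[2])
  lens <- rng[sample.int(length(rng), config$n_genes, replace = TRUE)]
  ov <- config$gene_length_overrides
  if (!is.null(ov)) {
    hit <- match(names(ov), gene_ids)
    lens[hit[!is.na(hit)]] <- as.integer(ov[!is.na(hit)])
  }
  lens <- pmax(3L * round(lens / 3), 9L)
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  spacer <- 5L
  chrom_parts <- character(0)
  models <- vector("list", config$n_genes)
  cursor <- 1L
  for (i in seq_len(config$n_genes)) {
    cds <- paste(sample(sense_codons(), lens[i] / 3, replace = TRUE),
                 collapse = "")
    gseq <- if (strands[i] == "+") cds else revcomp(cds)
    sp <- paste(sample(BASES, spacer, replace = TRUE), collapse = "")
    chrom_parts <- c(chrom_parts, sp, gseq)
    gstart <- cursor + spacer
    gend <- gstart + lens[i] - 1L
    cursor <- gend + 1L
    models[[i]] <- list(
      gene_id = gene_ids[i], start = gstart, end = gend,
      strand = strands[i], cds = cds
    )
  }
  tail_sp <- paste(sample(BASES, spacer, replace = TRUE), collapse = "")
  genome <- stats::setNames(paste(c(chrom_parts, tail_sp), collapse = ""),
                            "chr1")

  gms <- lapply(models, function(m) {
    chromseq <- genome[["chr1"]]
    up <- substring(chromseq, m$start - 1L, m$start - 1L)
    dn <- substring(chromseq, m$end + 1L, m$end + 1L)
    if (m$strand == "+") {
      f5 <- up; f3 <- dn
    } else {
      f5 <- comp_base(dn); f3 <- comp_base(up)
    }
    gene_model(
      gene_id = m$gene_id, transcript_id = paste0(m$gene_id, ".t1"),
      chrom = "chr1", strand = m$strand,
      exons = cbind(start = m$start, end = m$end),
      cds_seq = m$cds, flank5 = f5, flank3 = f3
    )
  })
  names(gms) <- gene_ids

  opp <- do.call(rbind, lapply(gms, enumerate_substitutions))
  rownames(opp) <- NULL
  structure(list(gene_models = gms, genome = genome, opportunity = opp,
                 config_seed = config$seed),
            class = "sim_genome")
}

# beta draw helper tolerant of empty n
.rbeta2 <- function(n, shape) {
  if (n == 0) return(numeric(0))
  stats::rbeta(n, shape[1], shape[2])
}

#' Simulate a synthetic mutation cohort on a simulated genome
#'
#' Per patient, the mutation count is Poisson with the group's burden mean;
#' each mutation's 96-channel is drawn from the group signature mixture and
#' placed uniformly on a genome site whose reference triplet matches the
#' channel. In driver genes, substitutions are accepted with probability
#' proportional to the configured selection multiplier per impact class
#' (synonymous anchored at 1), which makes the gene's true dN/dS equal w by
#' construction. With probability rho, a missense mutation in a hotspot
#' gene of a `hotspot_group` patient is relocated to the hotspot codon.
#' Escape+ patients receive a guaranteed non-silent escape-gene SNV with
#' probability `escape_mutation_prob`. VAFs are Beta-distributed per
#' mutation role; survival times are exponential with the configured hazard
#' ratio applied only to escape+ patients in immune category C3, censored
#' uniformly on (0, horizon).
#'
#' @param genome A [simulate_genome()] result.
#' @param config The same [cohort_sim_config()].
#' @return List of class `sim_cohort`: `catalog` (mutation table),
#'   `clinical`, `expression`, `cnv` (data.frames) and `truth` (ledger:
#'   `patients`, `genes`, `mutations`).
#' @export
simulate_cohort <- function(genome, config) {
  set.seed(config$seed + 1L)
  opp <- genome$opportunity
  cat96 <- config$signature_catalog$matrix
  K <- ncol(cat96)

  n_pos <- config$n_patients_escape_pos
  n_neg <- config$n_patients_escape_neg
  n_pat <- n_pos + n_neg
  patients <- sprintf("P%04d", seq_len(n_pat))
  group <- rep(c("escape_pos", "escape_neg"), c(n_pos, n_neg))
  cancer_type <- sprintf("T%02d", 1L + (seq_len(n_pat) - 1L) %%
                           config$n_cancer_types)

  # per-channel site lists for background placement; escape genes are kept
  # out of the background pool and hit at the configured per-patient rate
  # instead (see escape_chance_rate)
  bg_rows <- which(!opp$gene_id %in% config$escape_genes)
  opp_by_ch <- split(bg_rows, factor(opp$cls96[bg_rows], levels = 1:96))
  ch_avail <- lengths(opp_by_ch) > 0

  # per-row acceptance probabilities implementing selection in driver
  # genes (separately per group when escape+ overrides are configured)
  build_acc <- function(driver_list) {
    acc <- rep(1, nrow(opp))
    for (g in names(driver_list)) {
      w <- driver_list[[g]]
      w_mis <- unname(w[1])
      w_non <- unname(if (length(w) > 1) w[2] else w[1])
      gmax <- max(1, w_mis, w_non)
      rows <- opp$gene_id == g
      acc[rows & opp$impact == "synonymous"] <- 1 / gmax
      acc[rows & opp$impact == "missense"] <- w_mis / gmax
      acc[rows & opp$impact == "nonsense"] <- w_non / gmax
    }
    acc
  }
  drivers_neg <- config$driver_genes
  drivers_pos <- utils::modifyList(config$driver_genes,
                                   config$driver_genes_escape_pos %||% list())
  acc_neg <- build_acc(drivers_neg)
  acc_pos <- build_acc(drivers_pos)

  w_of <- function(lst, g, k) {
    if (!g %in% names(lst)) return(1)
    w <- lst[[g]]
    unname(if (k == 1 || length(w) == 1) w[1] else w[2])
  }
  gids <- names(genome$gene_models)
  w_tab <- data.frame(
    gene_id = gids,
    w_mis = vapply(gids, w_of, numeric(1), lst = drivers_neg, k = 1),
    w_non = vapply(gids, w_of, numeric(1), lst = drivers_neg, k = 2),
    w_mis_escape_pos = vapply(gids, w_of, numeric(1), lst = drivers_pos,
                              k = 1),
    w_non_escape_pos = vapply(gids, w_of, numeric(1), lst = drivers_pos,
                              k = 2),
    stringsAsFactors = FALSE
  )

  group_channel_probs <- function(mix) {
    p <- as.numeric(cat96 %*% mix)
    p[!ch_avail] <- 0 # channels with no matching genome site are redrawn
    p / sum(p)
  }
  p_pos <- group_channel_probs(config$signature_mix_pos)
  p_neg <- group_channel_probs(config$signature_mix_neg)

  counts <- stats::rpois(n_pat, ifelse(group == "escape_pos",
                                       config$tmb_mean_pos,
                                       config$tmb_mean_neg))
  pat_of_mut <- rep(seq_len(n_pat), counts)
  N <- length(pat_of_mut)

  draw_sites <- function(n, probs) {
    if (n == 0) return(integer(0))
    ch <- sample.int(96L, n, replace = TRUE, prob = probs)
    site <- integer(n)
    for (c in unique(ch)) {
      sel <- which(ch == c)
      pool <- opp_by_ch[[c]]
      site[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    }
    site
  }

  # draw with rejection implementing per-gene selection
  is_pos_mut <- group[pat_of_mut] == "escape_pos"
  site <- integer(N)
  pending <- seq_len(N)
  it <- 0L
  while (length(pending) > 0 && it < 100L) {
    pp <- pending[is_pos_mut[pending]]
    pn <- pending[!is_pos_mut[pending]]
    site[pp] <- draw_sites(length(pp), p_pos)
    site[pn] <- draw_sites(length(pn), p_neg)
    u <- stats::runif(length(pending))
    acc_here <- ifelse(is_pos_mut[pending], acc_pos[site[pending]],
                       acc_neg[site[pending]])
    pending <- pending[u > acc_here]
    it <- it + 1L
  }

  channel <- opp$cls96[site]

  # hotspot relocation (missense-only, one group)
  relocated <- rep(FALSE, N)
  target_grp <- if (config$hotspot_group == "escape_neg") "escape_neg"
                else "escape_pos"
  for (g in names(config$hotspot_spec)) {
    hs <- config$hotspot_spec[[g]]
    hs_rows <- which(opp$gene_id == g & opp$aa_pos == hs$aa_pos &
                       opp$impact == "missense")
    if (length(hs_rows) == 0) next
    cand <- which(opp$gene_id[site] == g & opp$impact[site] == "missense" &
                    group[pat_of_mut] == target_grp)
    if (length(cand) == 0) next
    move <- cand[stats::runif(length(cand)) < hs$rho]
    site[move] <- hs_rows[sample.int(length(hs_rows), length(move),
                                     replace = TRUE)]
    relocated[move] <- TRUE
  }

  # guaranteed escape-gene non-silent SNV for escape+ patients
  esc_rows <- which(opp$gene_id %in% config$escape_genes &
                      opp$impact %in% c("missense", "nonsense"))
  extra_pat <- which(group == "escape_pos" &
                       stats::runif(n_pat) < config$escape_mutation_prob)
  extra_site <- if (length(esc_rows) && length(extra_pat)) {
    esc_rows[sample.int(length(esc_rows), length(extra_pat), replace = TRUE)]
  } else {
    extra_pat <- integer(0)
    integer(0)
  }

  # rare background escape-gene mutations (any impact, both groups)
  esc_all_rows <- which(opp$gene_id %in% config$escape_genes)
  chance_counts <- stats::rpois(n_pat, config$escape_chance_rate)
  chance_pat <- rep(seq_len(n_pat), chance_counts)
  chance_site <- if (length(esc_all_rows) && length(chance_pat)) {
    esc_all_rows[sample.int(length(esc_all_rows), length(chance_pat),
                            replace = TRUE)]
  } else {
    chance_pat <- integer(0)
    integer(0)
  }

  all_pat <- c(pat_of_mut, extra_pat, chance_pat)
  all_site <- c(site, extra_site, chance_site)
  guaranteed <- c(rep(FALSE, N), rep(TRUE, length(extra_pat)),
                  rep(FALSE, length(chance_pat)))
  relocated <- c(relocated, rep(FALSE, length(extra_pat) +
                                  length(chance_pat)))

  o <- opp[all_site, ]
  is_driver_gene <- o$gene_id %in% names(config$driver_genes)
  is_escape_gene <- o$gene_id %in% config$escape_genes
  nonsyn <- o$impact != "synonymous"
  role <- ifelse(is_driver_gene & nonsyn, "driver",
                 ifelse(is_escape_gene & nonsyn, "escape", "passenger"))
  vaf <- numeric(length(role))
  for (r in c("driver", "escape", "passenger")) {
    idx <- which(role == r)
    vaf[idx] <- .rbeta2(length(idx), config$vaf_params[[r]])
  }

  catalog <- data.frame(
    patient_id = patients[all_pat],
    gene_id = o$gene_id,
    chromosome = "chr1",
    position = o$gpos,
    ref_allele = o$ref_gen,
    alt_allele = o$alt_gen,
    variant_class = as.character(o$impact),
    context = o$context,
    vaf = round(vaf, 4),
    cancer_type = cancer_type[all_pat],
    is_snv = TRUE,
    stringsAsFactors = FALSE
  )
  ord <- order(catalog$patient_id, catalog$position)
  catalog <- catalog[ord, ]
  rownames(catalog) <- NULL

  # clinical
  sp <- config$survival_params
  cats <- sample(names(sp$category_probs), n_pat, replace = TRUE,
                 prob = sp$category_probs)
  hazard <- sp$baseline_hazard *
    ifelse(group == "escape_pos" & cats == "C3", sp$hr_pos_c3, 1)
  t_event <- stats::rexp(n_pat, hazard)
  t_cens <- stats::runif(n_pat, 0, sp$horizon)
  clinical <- data.frame(
    patient_id = patients,
    survival_time = round(pmin(t_event, t_cens), 2),
    event = as.integer(t_event <= t_cens),
    immune_category = cats,
    cancer_type = cancer_type,
    stringsAsFactors = FALSE
  )
  clinical$survival_time[clinical$survival_time <= 0] <- 0.01

  # PD-L1-style expression, mildly higher in escape+ tumors
  expression <- data.frame(
    patient_id = patients,
    gene_id = config$pdl1_gene,
    fpkm = round(stats::rlnorm(n_pat, meanlog = 2 +
                                 0.4 * (group == "escape_pos"), sdlog = 0.8), 3),
    stringsAsFactors = FALSE
  )

  # copy number over escape genes
  cn_draw <- function(n) {
    u <- stats::runif(n)
    ifelse(u < config$cnv_homdel_prob, 0L,
           ifelse(u < config$cnv_homdel_prob + config$cnv_del_prob, 1L, 2L))
  }
  cnv <- expand.grid(patient_id = patients, gene_id = config$escape_genes,
                     stringsAsFactors = FALSE)
  cnv$copy_number <- cn_draw(nrow(cnv))

  truth <- list(
    patients = data.frame(
      patient_id = patients, true_group = group,
      immune_category = cats, cancer_type = cancer_type,
      tmb_drawn = counts + tabulate(extra_pat, nbins = n_pat) +
        chance_counts,
      stringsAsFactors = FALSE
    ),
    genes = transform(
      w_tab,
      is_escape = w_tab$gene_id %in% config$escape_genes,
      is_driver = w_tab$gene_id %in% names(config$driver_genes)
    ),
    mutations = data.frame(
      patient_id = patients[all_pat][ord],
      gene_id = o$gene_id[ord],
      position = o$gpos[ord],
      role = role[ord],
      channel96 = sbs96_contexts()[o$cls96[ord]],
      hotspot_relocated = relocated[ord],
      guaranteed_escape = guaranteed[ord],
      stringsAsFactors = FALSE
    )
  )

  structure(list(catalog = catalog, clinical = clinical,
                 expression = expression, cnv = cnv, truth = truth),
            class = "sim_cohort")
}

#' Simulate genome and cohort in one call
#' @param config A [cohort_sim_config()].
#' @return A `sim_cohort` with the `sim_genome` attached as `$genome`.
#' @export
simulate_escape_cohort <- function(config) {
  genome <- simulate_genome(config)
  sim <- simulate_cohort(genome, config)
  sim$genome <- genome
  sim
}

#' Write all synthetic cohort artifacts to a directory
#'
#' Writes MAF, reference FASTA, gene-model TSV, clinical / expression / CNV
#' TSVs and the truth ledger.
#'
#' @param sim A `sim_cohort` (with `$genome` attached, as returned by
#'   [simulate_escape_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    maf = file.path(dir, "cohort.maf"),
    fasta = file.path(dir, "reference.fa"),
    genes = file.path(dir, "gene_models.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    expression = file.path(dir, "expression.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    truth_patients = file.path(dir, "truth_patients.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_mutations = file.path(dir, "truth_mutations.tsv")
  )
  write_maf(sim$catalog, paths["maf"])
  write_genome_fasta(sim$genome$genome, paths["fasta"])
  write_gene_models(sim$genome$gene_models, paths["genes"])
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(sim$clinical, paths["clinical"])
  wt(sim$expression, paths["expression"])
  wt(sim$cnv, paths["cnv"])
  wt(sim$truth$patients, paths["truth_patients"])
  wt(sim$truth$genes, paths["truth_genes"])
  wt(sim$truth$mutations, paths["truth_mutations"])
  paths
}
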