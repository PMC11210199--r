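# End-to-end pipeline: simulate or ingest -> classify -> per-group dN/dS ->
# contrasts -> signatures -> survival, from one config, with a
# machine-readable run manifest.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  }
  config$q_threshold <- config$q_threshold %||% 0.1
  config$nonsilent_classes <- config$nonsilent_classes %||% NONSILENT_DEFAULT
  config$seed <- config$seed %||% 1L
  config
}

#' Run the full escape-selection pipeline
#'
#' Stages, in dependency order: (1) simulate a synthetic cohort or ingest
#' MAF + gene models + tables; (2) point-mutation escape classification and
#' cohort summary; (3) context-rate fit and per-gene + pooled dN/dS per
#' escape group, with driver calling; (4) hotspot site-concentration and
#' VAF contrasts; (5) cohort-level signature refitting and group
#' comparison; (6) survival stratified by immune category. Every output
#' table is written to `out_dir` and listed, with an md5 content hash, in
#' `manifest.json`. A stage failure leaves earlier outputs intact and
#' names the failed stage.
#'
#' @param config Path to a YAML file or an equivalent list. Must contain
#'   exactly one of `simulate` (arguments for [cohort_sim_config()]) or
#'   `inputs` (paths: `maf`, `fasta`, `gene_models`, `clinical`, optional
#'   `expression`, `cnv`); plus `out_dir`, optional `escape_genes`,
#'   `driver_genes`, `q_threshold`, `seed`.
#' @return The manifest, invisibly (list with per-stage outputs, file
#'   paths and hashes).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), files = list())
  written <- character(0)
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (completed stages are intact in ", out_dir, ")", call. = FALSE)
    })
    manifest$stages[[name]] <<- TRUE
    res
  }

  # stage 1: data
  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      cfg <- do.call(cohort_sim_config, sim_args)
      sim <- simulate_escape_cohort(cfg)
      written <- c(written, write_cohort(sim, out_dir))
      list(catalog = sim$catalog, clinical = sim$clinical,
           expression = sim$expression, cnv = sim$cnv,
           gene_models = sim$genome$gene_models,
           escape_genes = cfg$escape_genes,
           driver_genes = names(cfg$driver_genes), truth = sim$truth)
    } else {
      inp <- config$inputs
      gms <- read_gene_models(inp$gene_models, inp$fasta)
      cat <- read_maf(inp$maf, gms)
      tabs <- read_tables(inp$clinical, inp$expression, inp$cnv)
      esc <- config$escape_genes
      if (is.character(esc) && length(esc) == 1L && file.exists(esc)) {
        esc <- readLines(esc)
      }
      drv <- config$driver_genes
      if (is.character(drv) && length(drv) == 1L && file.exists(drv)) {
        drv <- readLines(drv)
      }
      list(catalog = cat, clinical = tabs$clinical,
           expression = tabs$expression, cnv = tabs$cnv, gene_models = gms,
           escape_genes = esc, driver_genes = drv, truth = NULL)
    }
  })

  # stage 2: classification
  labels <- stage("classify", {
    lab <- classify_point_mutation(dat$catalog, dat$escape_genes,
                                   config$nonsilent_classes)
    wt(lab, "escape_labels.tsv")
    cs <- cohort_summary(dat$catalog, lab, dat$escape_genes,
                         config$nonsilent_classes)
    wt(cs$summary, "cohort_summary.tsv")
    lab
  })

  # stage 3: dN/dS per group
  dnds <- stage("dnds", {
    set.seed(config$seed)
    impacts <- build_impact_matrices(dat$gene_models)
    split_cat <- function(st) {
      pats <- labels$patient_id[labels$status == st]
      dat$catalog[dat$catalog$patient_id %in% pats, , drop = FALSE]
    }
    per_group <- lapply(c(escape_neg = "escape_neg",
                          escape_pos = "escape_pos"), function(st) {
      cc <- split_cat(st)
      rates <- fit_context_rates(cc, impacts, dat$gene_models)
      res <- call_drivers(gene_dnds_all(cc, rates, impacts),
                          q_threshold = config$q_threshold)
      glob <- global_dnds(names(impacts), cc, rates, impacts,
                          label = "all_genes")
      drvw <- if (length(dat$driver_genes)) {
        global_dnds(dat$driver_genes, cc, rates, impacts,
                    label = "known_drivers")
      } else NULL
      wt(res, paste0("dnds_genes_", st, ".tsv"))
      list(results = res, global = glob, driver = drvw, rates = rates,
           catalog = cc)
    })
    glob_tab <- do.call(rbind, lapply(names(per_group), function(st) {
      g <- per_group[[st]]
      rbind(
        data.frame(group = st, set = "all_genes", w = g$global$w,
                   lo = g$global$ci[1], hi = g$global$ci[2]),
        if (!is.null(g$driver)) {
          data.frame(group = st, set = "known_drivers", w = g$driver$w,
                     lo = g$driver$ci[1], hi = g$driver$ci[2])
        }
      )
    }))
    wt(glob_tab, "dnds_global.tsv")
    c(per_group, list(impacts = impacts))
  })

  # stage 4: contrasts
  stage("contrasts", {
    vc <- vaf_compare(dat$catalog, dat$driver_genes, dat$escape_genes)
    wt(vc, "vaf_compare.tsv")
    if (length(dat$driver_genes)) {
      hs <- do.call(rbind, lapply(dat$driver_genes, function(g) {
        r <- site_concentration_test(dat$catalog, g, labels)
        data.frame(gene = g, chi2 = r$chi2, p = r$p,
                   stringsAsFactors = FALSE)
      }))
      wt(hs, "site_concentration.tsv")
      pooled <- pooled_concentration_test(dat$catalog, dat$driver_genes,
                                          labels)
      wt(data.frame(chi2 = pooled$chi2, p = pooled$p), "pandriver_test.tsv")
    }
    NULL
  })

  # stage 5: signatures
  stage("signatures", {
    sc <- config$signature_catalog_path
    sig_cat <- if (is.null(sc)) default_signature_catalog() else
      read_signature_catalog(sc)
    grp <- stats::setNames(labels$status, labels$patient_id)
    spectra <- tabulate_96(dat$catalog, dat$gene_models, by = grp)
    if (all(c("escape_neg", "escape_pos") %in% rownames(spectra))) {
      e_neg <- fit_exposures(spectra["escape_neg", ], sig_cat)
      e_pos <- fit_exposures(spectra["escape_pos", ], sig_cat)
      cmp <- compare_signature_proportions(e_neg, e_pos)
      wt(cmp, "signature_compare.tsv")
      expo <- rbind(
        data.frame(subject = "escape_neg",
                   signature = names(e_neg$weights),
                   weight = unname(e_neg$weights)),
        data.frame(subject = "escape_pos",
                   signature = names(e_pos$weights),
                   weight = unname(e_pos$weights))
      )
      wt(expo, "signature_exposures.tsv")
    }
    NULL
  })

  # stage 6: survival
  stage("survival", {
    if (!is.null(dat$clinical) && "immune_category" %in% names(dat$clinical)) {
      sv <- stratified_survival(dat$clinical, labels, by = "immune_category")
      wt(sv$tests, "survival_tests.tsv")
      wt(survival_curve_table(sv$curves), "survival_curves.tsv")
    }
    NULL
  })

  written <- unique(written)
  manifest$files <- lapply(written, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
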