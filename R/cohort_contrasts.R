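# Cohort-level contrasts: randomized escape-gene null, hotspot
# site-concentration tests, downsampling and hotspot-exclusion controls,
# oncogene/TSG proportions, and VAF clonality comparisons.

#' Randomized escape-gene null for the driver-set dN/dS
#'
#' Controls for mutation-burden bias in the escape stratification: per
#' replicate, `k` genes are drawn uniformly without replacement from the
#' non-escape genes; truly escape+ patients are removed; remaining patients
#' with a non-silent SNV in the drawn set become pseudo-escape+; the pooled
#' driver-set omega is computed on that pseudo cohort. The empirical
#' p-value is the (r+1)/(B+1)-corrected fraction of null omegas at or
#' below the observed escape+ driver omega (one-sided, lower).
#'
#' @param catalog Mutation table.
#' @param labels Point-mutation escape labels ([classify_point_mutation()]).
#' @param all_genes Universe of gene ids to draw from.
#' @param escape_genes The true escape gene list (excluded from draws).
#' @param driver_set Gene set whose pooled omega is measured.
#' @param rates,impacts As in [global_dnds()].
#' @param k Number of genes per draw (default 88).
#' @param reps Replicates (default 100).
#' @param min_pseudo Minimum pseudo-escape+ patients per replicate;
#'   smaller draws are redrawn (bounded retries).
#' @param nonsilent_classes Classes that mark a pseudo-escape+ patient.
#' @return List of class `random_null_result`: `observed_driver_w`,
#'   `null_driver_w` (length `reps`), `empirical_p`, `reps`.
#' @export
random_escape_null <- function(catalog, labels, all_genes, escape_genes,
                               driver_set, rates, impacts,
                               k = 88L, reps = 100L, min_pseudo = 5L,
                               nonsilent_classes = NONSILENT_DEFAULT) {
  pool <- setdiff(all_genes, escape_genes)
  if (length(pool) < k) stop("fewer than k non-escape genes to draw from")
  true_pos <- labels$patient_id[labels$status == "escape_pos"]

  # observed: pooled driver omega on the true escape+ cohort
  obs <- global_dnds(driver_set,
                     catalog[catalog$patient_id %in% true_pos, , drop = FALSE],
                     rates, impacts, label = "true_escape_pos")$w

  # precompute per-patient hits for speed
  neg_cat <- catalog[!catalog$patient_id %in% true_pos, , drop = FALSE]
  ns <- neg_cat[neg_cat$variant_class %in% nonsilent_classes, , drop = FALSE]
  hits_by_gene <- split(ns$patient_id, ns$gene_id)

  null_w <- numeric(reps)
  for (b in seq_len(reps)) {
    w_b <- NA_real_
    for (try in 1:50) {
      drawn <- sample(pool, k)
      pseudo <- unique(unlist(hits_by_gene[intersect(drawn, names(hits_by_gene))],
                              use.names = FALSE))
      if (length(pseudo) < min_pseudo) next
      sub <- neg_cat[neg_cat$patient_id %in% pseudo, , drop = FALSE]
      w_b <- tryCatch(
        global_dnds(driver_set, sub, rates, impacts,
                    label = "pseudo_escape_pos")$w,
        error = function(e) NA_real_
      )
      if (is.finite(w_b)) break
    }
    if (!is.finite(w_b)) {
      stop("could not obtain a defined pooled omega with >= ", min_pseudo,
           " pseudo-escape+ patients in 50 draws")
    }
    null_w[b] <- w_b
  }
  emp_p <- (1 + sum(null_w <= obs)) / (reps + 1)
  structure(
    list(reps = reps, observed_driver_w = obs, null_driver_w = null_w,
         empirical_p = emp_p),
    class = "random_null_result"
  )
}

# Pearson chi-square (no continuity correction) on a 2x2 table
.pearson_chisq <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, undefined = FALSE)
}

# nonsynonymous SNVs of a catalog
.nonsyn_snv <- function(catalog) {
  catalog[catalog$variant_class %in% c("missense", "nonsense") &
            (catalog$is_snv %||% TRUE), , drop = FALSE]
}

#' Mutation-count vs unique-site concentration test for one gene
#'
#' Builds the 2x2 contingency table rows = escape status, columns =
#' (total nonsynonymous mutation count, number of distinct mutated coding
#' positions), and applies Pearson's chi-square without continuity
#' correction. A hotspot-concentrated gene shows many mutations over few
#' sites in one group. Unique sites are distinct genomic positions by
#' default (`unit = "codon"` counts distinct codons via gene models).
#'
#' @param catalog Mutation table.
#' @param gene Gene id.
#' @param labels Escape labels.
#' @param unit `"position"` (default) or `"codon"`.
#' @param gene_models Needed when `unit = "codon"`.
#' @return List of class `contingency_result`: `table`, `chi2`, `df`, `p`,
#'   plus a per-position tally (`lolliplot`) for export.
#' @export
site_concentration_test <- function(catalog, gene, labels,
                                    unit = c("position", "codon"),
                                    gene_models = NULL) {
  unit <- match.arg(unit)
  status <- stats::setNames(labels$status, labels$patient_id)
  rows <- .nonsyn_snv(catalog)
  rows <- rows[rows$gene_id == gene, , drop = FALSE]
  rows$group <- status[rows$patient_id]
  if (unit == "codon") {
    if (is.null(gene_models)) stop("gene_models required for codon unit")
    rows$site <- genomic_to_protein(gene_models[[gene]], rows$position)
  } else {
    rows$site <- rows$position
  }
  tab <- t(vapply(c("escape_neg", "escape_pos"), function(g) {
    r <- rows[rows$group %in% g, , drop = FALSE]
    c(mutations = nrow(r), sites = length(unique(r$site)))
  }, numeric(2)))
  test <- .pearson_chisq(tab)
  lolli <- stats::aggregate(
    list(count = rows$patient_id),
    by = list(gene = rows$gene_id, position = rows$site, group = rows$group,
              class = rows$variant_class),
    FUN = length
  )
  structure(
    list(table = tab, chi2 = test$chi2, df = 1L, p = test$p,
         undefined = test$undefined,
         labels = list(rows = rownames(tab), cols = colnames(tab)),
         lolliplot = lolli),
    class = "contingency_result"
  )
}

#' Pooled site-concentration test over a gene set
#'
#' Element-wise sums the per-gene (mutations, unique sites) tables across
#' the gene set, then tests the pooled 2x2 table as in
#' [site_concentration_test()]. Unique sites are counted within gene, so
#' the pooled table is the sum of the per-gene tables.
#'
#' @inheritParams site_concentration_test
#' @param gene_set Nonempty character vector of gene ids.
#' @return A `contingency_result` (no lolliplot).
#' @export
pooled_concentration_test <- function(catalog, gene_set, labels,
                                      unit = c("position", "codon"),
                                      gene_models = NULL) {
  unit <- match.arg(unit)
  if (length(gene_set) == 0) stop("empty gene set")
  tabs <- lapply(gene_set, function(g) {
    site_concentration_test(catalog, g, labels, unit, gene_models)$table
  })
  tab <- Reduce(`+`, tabs)
  test <- .pearson_chisq(tab)
  structure(
    list(table = tab, chi2 = test$chi2, df = 1L, p = test$p,
         undefined = test$undefined,
         labels = list(rows = rownames(tab), cols = colnames(tab))),
    class = "contingency_result"
  )
}

#' Downsample the majority group to match the minority
#'
#' Equalizes the two escape groups by uniform sampling without replacement
#' of either patients or mutations. With `draws > 1` a list of reduced
#' catalogs is returned for stability assessment.
#'
#' @param catalog Mutation table.
#' @param labels Escape labels.
#' @param target `"patients"` or `"mutations"`.
#' @param draws Number of independent downsampling draws.
#' @return A reduced catalog (or list of them when `draws > 1`). When the
#'   groups are already balanced, the catalog is returned unchanged with a
#'   warning.
#' @export
downsample_catalog <- function(catalog, labels,
                               target = c("patients", "mutations"),
                               draws = 1L) {
  target <- match.arg(target)
  status <- stats::setNames(labels$status, labels$patient_id)
  grp <- status[catalog$patient_id]
  one <- function() {
    if (target == "patients") {
      pats <- split(labels$patient_id, labels$status)
      sizes <- lengths(pats)
      if (length(sizes) < 2 || sizes[1] == sizes[2]) {
        warning("groups already balanced; no-op")
        return(catalog)
      }
      big <- names(which.max(sizes))
      keep_big <- sample(pats[[big]], min(sizes))
      keep <- c(pats[[names(which.min(sizes))]], keep_big)
      catalog[catalog$patient_id %in% keep, , drop = FALSE]
    } else {
      idx <- split(seq_len(nrow(catalog)), grp)
      sizes <- lengths(idx)
      if (length(sizes) < 2 || sizes[1] == sizes[2]) {
        warning("groups already balanced; no-op")
        return(catalog)
      }
      big <- names(which.max(sizes))
      keep <- c(idx[[names(which.min(sizes))]],
                sample(idx[[big]], min(sizes)))
      catalog[sort(keep), , drop = FALSE]
    }
  }
  if (draws == 1L) one() else lapply(seq_len(draws), function(i) one())
}

#' Remove mutations at known hotspot codons
#'
#' Drops SNVs whose genomic position falls inside a listed protein
#' (codon) position of its gene, using gene models to map codons to their
#' three genomic positions.
#'
#' @param catalog Mutation table.
#' @param hotspots Named list `gene -> integer protein positions`.
#' @param gene_models Named list of gene models.
#' @return Reduced catalog with attribute `"n_removed"`.
#' @export
exclude_hotspots <- function(catalog, hotspots, gene_models) {
  drop <- rep(FALSE, nrow(catalog))
  for (g in names(hotspots)) {
    gm <- gene_models[[g]]
    if (is.null(gm)) stop("no gene model for hotspot gene ", g)
    aa <- hotspots[[g]]
    if (any(aa > nchar(gm$cds_seq) / 3)) {
      stop("hotspot protein position beyond protein length for ", g)
    }
    cds_idx <- as.vector(vapply(aa, function(p) (3L * p - 2L):(3L * p),
                                integer(3)))
    gpos <- cds_to_genomic(gm, cds_idx)
    drop <- drop | (catalog$gene_id == g & catalog$position %in% gpos)
  }
  out <- catalog[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Oncogene vs tumor-suppressor missense proportions by escape status
#'
#' Counts missense mutations per (escape status x gene role) and tests the
#' 2x2 oncogene/TSG table by Pearson chi-square. Genes annotated `both`
#' are counted in both roles (flagged); `none` genes are excluded.
#'
#' @param catalog Mutation table.
#' @param labels Escape labels.
#' @param role_annotation Named character vector `gene -> role` with roles
#'   in `oncogene`, `TSG`, `both`, `none`.
#' @return A `contingency_result` with `table` rows oncogene/TSG, columns
#'   escape_neg/escape_pos, and `has_both_genes` flag.
#' @export
onc_tsg_proportions <- function(catalog, labels, role_annotation) {
  if (length(role_annotation) == 0) stop("empty role annotation")
  status <- stats::setNames(labels$status, labels$patient_id)
  mis <- catalog[catalog$variant_class == "missense", , drop = FALSE]
  mis$group <- status[mis$patient_id]
  mis$role <- unname(role_annotation[mis$gene_id])
  cnt <- function(role, grp) {
    sum((mis$role %in% c(role, "both")) & mis$group %in% grp, na.rm = TRUE)
  }
  tab <- rbind(
    oncogene = c(escape_neg = cnt("oncogene", "escape_neg"),
                 escape_pos = cnt("oncogene", "escape_pos")),
    TSG = c(escape_neg = cnt("TSG", "escape_neg"),
            escape_pos = cnt("TSG", "escape_pos"))
  )
  test <- .pearson_chisq(tab)
  structure(
    list(table = tab, chi2 = test$chi2, df = 1L, p = test$p,
         undefined = test$undefined,
         labels = list(rows = rownames(tab), cols = colnames(tab)),
         has_both_genes = any(mis$role %in% "both")),
    class = "contingency_result"
  )
}

#' Compare VAF distributions of driver vs escape mutations
#'
#' Two-sided Mann-Whitney U on the VAFs of non-silent SNVs in driver genes
#' vs escape genes, pancancer or per cancer type (with BH adjustment
#' across types). Higher driver VAF indicates driver mutations are more
#' clonal (earlier) than escape mutations.
#'
#' @param catalog Mutation table with a `vaf` column.
#' @param driver_genes,escape_genes Gene lists.
#' @param scope `"pancancer"` or `"per_type"`.
#' @param min_n Minimum VAF observations per side (default 10).
#' @param nonsilent_classes Classes included.
#' @return data.frame with one row per stratum: `stratum`, `n_driver`,
#'   `n_escape`, medians, `U`, `p`, `q`.
#' @export
vaf_compare <- function(catalog, driver_genes, escape_genes,
                        scope = c("pancancer", "per_type"), min_n = 10L,
                        nonsilent_classes = NONSILENT_DEFAULT) {
  scope <- match.arg(scope)
  rows <- catalog[catalog$variant_class %in% nonsilent_classes &
                    !is.na(catalog$vaf), , drop = FALSE]
  rows$side <- ifelse(rows$gene_id %in% driver_genes, "driver",
                      ifelse(rows$gene_id %in% escape_genes, "escape", NA))
  rows <- rows[!is.na(rows$side), , drop = FALSE]
  strata <- if (scope == "pancancer") list(pancancer = seq_len(nrow(rows)))
            else split(seq_len(nrow(rows)), rows$cancer_type)
  out <- do.call(rbind, lapply(names(strata), function(s) {
    r <- rows[strata[[s]], , drop = FALSE]
    vd <- r$vaf[r$side == "driver"]
    ve <- r$vaf[r$side == "escape"]
    if (length(vd) < min_n || length(ve) < min_n) {
      return(data.frame(stratum = s, n_driver = length(vd),
                        n_escape = length(ve), median_driver = NA_real_,
                        median_escape = NA_real_, U = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wt <- stats::wilcox.test(vd, ve, exact = FALSE)
    data.frame(stratum = s, n_driver = length(vd), n_escape = length(ve),
               median_driver = stats::median(vd),
               median_escape = stats::median(ve),
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}
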