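# Patient escape-status stratification: point-mutation rule, overlapping
# copy-number categories A-F, and PD-L1 expression quartiles; plus cohort
# composition summaries.

#' Classify patients by escape-gene point mutations
#'
#' A patient is escape+ iff they carry at least one SNV in an escape gene
#' whose class is in `nonsilent_classes`. Synonymous escape-gene mutations
#' never trigger. Order of records is irrelevant and the classification is
#' idempotent.
#'
#' @param catalog Mutation table.
#' @param escape_genes Nonempty character vector of escape gene ids.
#' @param nonsilent_classes Variant classes that count as non-silent.
#' @return data.frame with `patient_id`, `status`
#'   (`"escape_pos"`/`"escape_neg"`) and comma-separated
#'   `triggering_genes`.
#' @export
classify_point_mutation <- function(catalog, escape_genes,
                                    nonsilent_classes = NONSILENT_DEFAULT) {
  if (length(escape_genes) == 0) stop("escape gene list is empty")
  patients <- sort(unique(catalog$patient_id))
  hit <- catalog[catalog$gene_id %in% escape_genes &
                   catalog$variant_class %in% nonsilent_classes, ,
                 drop = FALSE]
  trig <- vapply(split(hit$gene_id, factor(hit$patient_id, levels = patients)),
                 function(g) paste(sort(unique(g)), collapse = ","),
                 character(1))
  data.frame(
    patient_id = patients,
    status = ifelse(trig != "", "escape_pos", "escape_neg"),
    triggering_genes = unname(trig),
    stringsAsFactors = FALSE
  )
}

#' Overlapping copy-number escape categories A-F
#'
#' Categories follow fixed, deliberately non-disjoint definitions and are
#' therefore emitted as boolean flags rather than a partition:
#' \describe{
#'   \item{A}{no escape point mutation and no escape-gene deletion (all
#'     copy numbers >= 2)}
#'   \item{B}{>= 1 hemizygous deletion (CN = 1) in an escape gene, no
#'     escape point mutation}
#'   \item{C}{>= 1 homo- or hemizygous deletion (CN <= 1), no point
#'     mutation (C contains B)}
#'   \item{D}{escape point mutation or hemizygous deletion}
#'   \item{F}{any escape-gene mutation or deletion (F contains D)}
#' }
#'
#' @param catalog Mutation table.
#' @param cnv_table Long CNV table (`patient_id`, `gene_id`,
#'   `copy_number`); values outside [0, 20] are rejected.
#' @param escape_genes Escape gene list.
#' @param nonsilent_classes Classes counting as an escape point mutation.
#' @return data.frame with `patient_id`, logical `cat_A` .. `cat_F`.
#' @export
classify_cnv_categories <- function(catalog, cnv_table, escape_genes,
                                    nonsilent_classes = NONSILENT_DEFAULT) {
  if (any(cnv_table$copy_number < 0 | cnv_table$copy_number > 20)) {
    stop("copy numbers outside [0, 20]")
  }
  pm <- classify_point_mutation(catalog, escape_genes, nonsilent_classes)
  patients <- union(pm$patient_id, unique(cnv_table$patient_id))
  has_pm <- stats::setNames(rep(FALSE, length(patients)), patients)
  has_pm[pm$patient_id] <- pm$status == "escape_pos"

  esc_cnv <- cnv_table[cnv_table$gene_id %in% escape_genes, , drop = FALSE]
  min_cn <- tapply(esc_cnv$copy_number,
                   factor(esc_cnv$patient_id, levels = patients), min)
  min_cn[is.na(min_cn)] <- 2L # no CNV data -> treated as diploid
  hemi <- min_cn == 1
  any_del <- min_cn <= 1

  data.frame(
    patient_id = patients,
    cat_A = !has_pm & !any_del,
    cat_B = hemi & !has_pm,
    cat_C = any_del & !has_pm,
    cat_D = has_pm | hemi,
    cat_F = has_pm | any_del,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' PD-L1 expression strata (within-cancer-type quartiles)
#'
#' Within each cancer type, patients in the bottom 25% of expression are
#' `low`, the top 25% `high`, the remainder `mid`; ties at a cut-point go
#' to `mid`. Types with fewer than `min_n` expressed patients, and
#' patients without expression data, are `missing`. All-identical
#' expression yields everyone `mid` with a warning.
#'
#' @param expression_table Long expression table (`patient_id`, `gene_id`,
#'   `fpkm`).
#' @param gene Expression gene symbol (default `"CD274"`, i.e. PD-L1).
#' @param cancer_type Named character vector mapping patient_id ->
#'   cancer type; when `NULL` all patients form one stratum pool.
#' @param min_n Minimum patients per cancer type (default 8).
#' @return data.frame with `patient_id`, `pdl1_stratum` in
#'   `low`/`mid`/`high`/`missing`.
#' @export
classify_pdl1 <- function(expression_table, gene = "CD274",
                          cancer_type = NULL, min_n = 8L) {
  expr <- expression_table[expression_table$gene_id == gene, , drop = FALSE]
  if (nrow(expr) == 0) stop("no expression rows for gene ", gene)
  type <- if (is.null(cancer_type)) rep("all", nrow(expr)) else
    unname(cancer_type[expr$patient_id])
  out <- lapply(split(seq_len(nrow(expr)), type), function(idx) {
    x <- expr$fpkm[idx]
    if (length(idx) < min_n) {
      return(data.frame(patient_id = expr$patient_id[idx],
                        pdl1_stratum = "missing", stringsAsFactors = FALSE))
    }
    if (length(unique(x)) == 1L) {
      warning("all expression values identical; everyone assigned mid")
      return(data.frame(patient_id = expr$patient_id[idx],
                        pdl1_stratum = "mid", stringsAsFactors = FALSE))
    }
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    stratum <- ifelse(x < q[1], "low", ifelse(x > q[2], "high", "mid"))
    data.frame(patient_id = expr$patient_id[idx], pdl1_stratum = stratum,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort composition summary and escape-gene frequency clustering
#'
#' Per (escape status x cancer type): patient counts, mean tumor mutation
#' burden (all mutation classes) and mean counts per variant class. Also
#' returns the escape-gene frequency matrix (fraction of patients of a
#' cancer type with a non-silent SNV in each gene) together with
#' average-linkage (Euclidean) hierarchical clustering leaf orders for
#' genes and types.
#'
#' @param catalog Mutation table.
#' @param labels Output of [classify_point_mutation()].
#' @param escape_genes Genes for the frequency matrix (default: all genes
#'   appearing in `triggering_genes`).
#' @param nonsilent_classes Classes counted in the frequency matrix.
#' @return List with `summary` (data.frame), `freq_matrix`,
#'   `gene_order`, `type_order`, and the `hclust` objects.
#' @export
cohort_summary <- function(catalog, labels, escape_genes = NULL,
                           nonsilent_classes = NONSILENT_DEFAULT) {
  status <- stats::setNames(labels$status, labels$patient_id)
  ctype <- tapply(catalog$cancer_type, catalog$patient_id, `[`, 1)
  per_pat <- as.data.frame(table(catalog$patient_id),
                           stringsAsFactors = FALSE)
  names(per_pat) <- c("patient_id", "tmb")
  per_pat$status <- status[per_pat$patient_id]
  per_pat$cancer_type <- ctype[per_pat$patient_id]

  cls_tab <- table(catalog$patient_id, catalog$variant_class)
  grp <- interaction(per_pat$status, per_pat$cancer_type, drop = TRUE)
  summary_df <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    pats <- per_pat$patient_id[idx]
    cls_means <- colMeans(cls_tab[pats, , drop = FALSE])
    cbind(
      data.frame(
        status = per_pat$status[idx][1],
        cancer_type = per_pat$cancer_type[idx][1],
        n_patients = length(idx),
        mean_tmb = mean(per_pat$tmb[idx]),
        stringsAsFactors = FALSE
      ),
      as.data.frame(t(cls_means))
    )
  }))
  rownames(summary_df) <- NULL

  if (is.null(escape_genes)) {
    escape_genes <- sort(unique(unlist(
      strsplit(labels$triggering_genes[labels$triggering_genes != ""], ",")
    )))
  }
  types <- sort(unique(per_pat$cancer_type))
  freq <- matrix(0, length(escape_genes), length(types),
                 dimnames = list(escape_genes, types))
  hits <- catalog[catalog$gene_id %in% escape_genes &
                    catalog$variant_class %in% nonsilent_classes, ,
                  drop = FALSE]
  for (tt in types) {
    pats_t <- per_pat$patient_id[per_pat$cancer_type == tt]
    h <- hits[hits$patient_id %in% pats_t, , drop = FALSE]
    mutated <- tapply(h$patient_id, h$gene_id, function(p) length(unique(p)))
    freq[names(mutated), tt] <- as.numeric(mutated) / length(pats_t)
  }

  hc_genes <- if (nrow(freq) >= 3) {
    stats::hclust(stats::dist(freq), method = "average")
  } else NULL
  hc_types <- if (ncol(freq) >= 3) {
    stats::hclust(stats::dist(t(freq)), method = "average")
  } else NULL

  list(
    summary = summary_df,
    freq_matrix = freq,
    gene_order = if (is.null(hc_genes)) rownames(freq) else
      rownames(freq)[hc_genes$order],
    type_order = if (is.null(hc_types)) colnames(freq) else
      colnames(freq)[hc_types$order],
    hclust_genes = hc_genes,
    hclust_types = hc_types
  )
}
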