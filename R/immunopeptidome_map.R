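# Protein-coordinate immunopeptidome regions -> genomic intervals, mutation
# filtering by region, and region-masked dN/dS. Interval arithmetic is done
# with IRanges; all file/interface coordinates are 1-based inclusive.

#' Map a protein region to genomic intervals
#'
#' Protein positions p cover CDS nucleotides [3p-2, 3p]; the CDS range is
#' projected through the exon structure (splitting across junctions) with
#' strand honored, and the resulting genomic intervals merged.
#'
#' @param gm A [gene_model()].
#' @param start_aa,end_aa 1-based inclusive protein positions.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive, merged,
#'   sorted); total width is 3 x the aa span.
#' @export
protein_to_genomic <- function(gm, start_aa, end_aa = start_aa) {
  n_aa <- nchar(gm$cds_seq) / 3
  if (start_aa < 1 || end_aa > n_aa || start_aa > end_aa) {
    stop("protein region outside [1, ", n_aa, "] for ", gm$gene_id)
  }
  cds_idx <- (3L * start_aa - 2L):(3L * end_aa)
  gpos <- cds_to_genomic(gm, cds_idx)
  ir <- IRanges::reduce(IRanges::IRanges(start = gpos, width = 1L))
  data.frame(
    chrom = gm$chrom,
    start = IRanges::start(ir),
    end = IRanges::end(ir),
    stringsAsFactors = FALSE
  )
}

#' Read SOPRANO-style immunopeptidome regions
#'
#' TSV with columns `patient_id` (or the literal `"global"`),
#' `transcript_id`, `start_aa`, `end_aa`.
#'
#' @param path TSV file.
#' @return data.frame of protein regions.
#' @export
read_immunopeptidome <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "transcript_id", "start_aa", "end_aa")
  if (!all(need %in% names(tab))) {
    stop("immunopeptidome TSV must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(tab$start_aa < 1 | tab$end_aa < tab$start_aa)) {
    stop("invalid protein region bounds")
  }
  tab
}

#' Convert protein regions to per-patient genomic region sets
#'
#' @param regions data.frame as from [read_immunopeptidome()].
#' @param gene_models Named list of gene models; matched by
#'   `transcript_id`.
#' @return Named list (by patient id, `"global"` for shared regions) of
#'   merged genomic interval data.frames (`chrom`, `start`, `end`, plus
#'   `gene_id`).
#' @export
regions_to_genomic <- function(regions, gene_models) {
  tx <- vapply(gene_models, `[[`, character(1), "transcript_id")
  out <- lapply(split(regions, regions$patient_id), function(rr) {
    parts <- lapply(seq_len(nrow(rr)), function(i) {
      gi <- which(tx == rr$transcript_id[i])
      if (length(gi) == 0) {
        stop("transcript absent from gene models: ", rr$transcript_id[i])
      }
      gm <- gene_models[[gi[1]]]
      g <- protein_to_genomic(gm, rr$start_aa[i], rr$end_aa[i])
      g$gene_id <- gm$gene_id
      g
    })
    df <- do.call(rbind, parts)
    # merge per chromosome
    merged <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      data.frame(chrom = d$chrom[1], start = IRanges::start(ir),
                 end = IRanges::end(ir),
                 gene_id = paste(sort(unique(d$gene_id)), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(merged) <- NULL
    merged
  })
  out
}

# logical vector: catalog rows inside the region set applying to each row's
# patient (patient-specific regions, falling back to a "global" set)
.in_regions <- function(catalog, region_sets) {
  inside <- rep(FALSE, nrow(catalog))
  glob <- region_sets[["global"]]
  for (p in unique(catalog$patient_id)) {
    rs <- region_sets[[p]] %||% glob
    if (is.null(rs)) next
    idx <- which(catalog$patient_id == p)
    for (ch in unique(rs$chrom)) {
      r <- rs[rs$chrom == ch, , drop = FALSE]
      ii <- idx[catalog$chromosome[idx] == ch]
      if (length(ii) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(catalog$position[ii], width = 1L),
        IRanges::IRanges(r$start, r$end)
      )
      inside[ii[unique(IRanges::from(ov))]] <- TRUE
    }
  }
  inside
}

#' Filter a mutation catalog by genomic region sets
#'
#' `exclude` drops SNVs whose position lies in any interval of the
#' patient's region set (patient-specific matching; a `"global"` set
#' applies to patients without their own); `restrict` keeps only those.
#' The two modes partition the catalog for the same region set.
#'
#' @param catalog Mutation table.
#' @param region_sets Named list from [regions_to_genomic()].
#' @param mode `"exclude"` or `"restrict"`.
#' @return Filtered catalog with attribute `"n_removed"`.
#' @export
filter_by_regions <- function(catalog, region_sets,
                              mode = c("exclude", "restrict")) {
  mode <- match.arg(mode)
  inside <- .in_regions(catalog, region_sets)
  keep <- if (mode == "exclude") !inside else inside
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

# impact matrix over CDS positions whose genomic position is NOT in the mask
.masked_impact_matrix <- function(gm, mask_regions) {
  subs <- enumerate_substitutions(gm)
  if (!is.null(mask_regions) && nrow(mask_regions) > 0) {
    r <- mask_regions[mask_regions$chrom == gm$chrom, , drop = FALSE]
    if (nrow(r) > 0) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(subs$gpos, width = 1L),
        IRanges::IRanges(r$start, r$end)
      )
      subs <- subs[-unique(IRanges::from(ov)), , drop = FALSE]
    }
  }
  if (nrow(subs) == 0) return(NULL)
  L <- matrix(0L, nrow = 192L, ncol = 3L,
              dimnames = list(class192_all(), IMPACTS3))
  tab <- table(factor(subs$cls192, levels = 1:192), subs$impact)
  for (k in IMPACTS3) L[, k] <- as.integer(tab[, k])
  structure(list(gene_id = gm$gene_id, L = L,
                 cds_length = nchar(gm$cds_seq)),
            class = "impact_matrix")
}

#' Region-masked pooled dN/dS (original vs filtered)
#'
#' Recomputes the pooled gene-set omega after excluding mutations inside
#' the immunopeptidome regions. With `mask_opportunity = TRUE` (default)
#' the site opportunities are consistently restricted to the unmasked
#' positions, so numerator and denominator cover the same territory; with
#' `FALSE` only the observed mutations are filtered (the lighter-weight
#' behavior of filtering the catalog alone). Patient-specific region sets
#' are unioned for the opportunity mask.
#'
#' @param catalog Mutation table.
#' @param region_sets Named list from [regions_to_genomic()].
#' @param gene_set Gene ids pooled over.
#' @param gene_models Named list of gene models.
#' @param rates A `context_rate_model`.
#' @param mask_opportunity Mask L as well as n (default TRUE).
#' @return List with `original` and `filtered` `global_dnds` objects,
#'   their `ratio` (filtered / original), and genes dropped because fully
#'   masked.
#' @export
filtered_dnds <- function(catalog, region_sets, gene_set, gene_models,
                          rates, mask_opportunity = TRUE) {
  impacts <- build_impact_matrices(gene_models[gene_set])
  original <- global_dnds(gene_set, catalog, rates, impacts,
                          label = "original")

  filt_cat <- filter_by_regions(catalog, region_sets, "exclude")
  dropped <- character(0)
  if (mask_opportunity) {
    union_mask <- do.call(rbind, unname(region_sets))
    impacts_f <- list()
    for (g in gene_set) {
      im <- .masked_impact_matrix(gene_models[[g]], union_mask)
      if (is.null(im) || sum(im$L[, "synonymous"]) == 0) {
        dropped <- c(dropped, g)
        warning("gene fully masked (or no synonymous opportunity left), ",
                "dropped: ", g)
      } else {
        impacts_f[[g]] <- im
      }
    }
  } else {
    impacts_f <- impacts
  }
  filtered <- global_dnds(setdiff(gene_set, dropped), filt_cat, rates,
                          impacts_f, label = "filtered")
  list(original = original, filtered = filtered,
       ratio = filtered$w / original$w, dropped_genes = dropped)
}

#' Export genomic region sets as BED
#'
#' Converts the 1-based inclusive internal intervals to BED's 0-based
#' half-open convention at the file boundary only.
#'
#' @param region_sets Named list from [regions_to_genomic()].
#' @param path Output BED file.
#' @export
write_regions_bed <- function(region_sets, path) {
  rows <- do.call(rbind, lapply(names(region_sets), function(nm) {
    r <- region_sets[[nm]]
    data.frame(chrom = r$chrom, start = r$start - 1L, end = r$end,
               name = nm, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
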