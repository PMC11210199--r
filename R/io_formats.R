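# Readers/writers for external artifacts: MAF mutation catalogs, gene-model
# TSV + reference FASTA, COSMIC-style SBS signature matrices, and clinical /
# expression / copy-number tables. All coordinates in files are 1-based
# inclusive (MAF convention).

MAF_REQUIRED <- c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
  "Tumor_Seq_Allele2", "Variant_Classification", "Tumor_Sample_Barcode"
)

# MAF consequence vocabulary -> internal variant classes; second element says
# whether the row can be a true SNV in that class
MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Silent = "synonymous",
  Nonsense_Mutation = "nonsense",
  Splice_Site = "essential_splice",
  Splice_Region = "essential_splice",
  Nonstop_Mutation = "other_nonsilent",
  Translation_Start_Site = "other_nonsilent",
  Frame_Shift_Del = "frameshift",
  Frame_Shift_Ins = "frameshift",
  In_Frame_Del = "other_nonsilent",
  In_Frame_Ins = "other_nonsilent",
  "3'UTR" = "noncoding", "5'UTR" = "noncoding",
  "3'Flank" = "noncoding", "5'Flank" = "noncoding",
  Intron = "noncoding", IGR = "noncoding", RNA = "noncoding",
  lincRNA = "noncoding"
)

empty_mutation_table <- function() {
  data.frame(
    patient_id = character(0), gene_id = character(0),
    chromosome = character(0), position = integer(0),
    ref_allele = character(0), alt_allele = character(0),
    variant_class = character(0), context = character(0),
    vaf = numeric(0), cancer_type = character(0), is_snv = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a mutation catalog
#'
#' Checks the MutationRecord invariants: positive positions, single-base
#' ref != alt for SNV rows, context middle base equal to the coding-strand
#' ref, and VAF in [0, 1] where present.
#'
#' @param catalog Mutation table.
#' @param gene_models Optional named list of gene models; when given, the
#'   coding-strand ref is derived per gene strand.
#' @return `catalog`, invisibly; errors describe the first violation.
#' @export
validate_catalog <- function(catalog, gene_models = NULL) {
  stopifnot(all(c("patient_id", "gene_id", "position", "ref_allele",
                  "alt_allele", "variant_class") %in% names(catalog)))
  if (any(catalog$position < 1L)) stop("positions must be >= 1")
  snv <- if ("is_snv" %in% names(catalog)) catalog$is_snv else
    nchar(catalog$ref_allele) == 1L & nchar(catalog$alt_allele) == 1L
  bad <- snv & catalog$ref_allele == catalog$alt_allele
  if (any(bad)) stop("SNV with ref == alt at row ", which(bad)[1])
  if ("vaf" %in% names(catalog)) {
    v <- catalog$vaf
    if (any(!is.na(v) & (v < 0 | v > 1))) stop("VAF outside [0, 1]")
  }
  if (!is.null(gene_models) && "context" %in% names(catalog)) {
    strand <- vapply(gene_models, `[[`, character(1), "strand")
    known <- snv & catalog$gene_id %in% names(strand) & !is.na(catalog$context)
    if (any(known)) {
      ref_cod <- ifelse(strand[catalog$gene_id[known]] == "-",
                        comp_base(catalog$ref_allele[known]),
                        catalog$ref_allele[known])
      mid <- substr(catalog$context[known], 2, 2)
      if (any(mid != ref_cod)) {
        stop("context middle base disagrees with ref allele at row ",
             which(known)[which(mid != ref_cod)[1]])
      }
    }
  }
  invisible(catalog)
}

#' Read a MAF-style somatic mutation file
#'
#' Parses SNV rows into the internal mutation-record vocabulary; non-SNV
#' rows (indels, DNPs) are retained with class `frameshift` /
#' `other_nonsilent` and flagged `is_snv = FALSE` so that burden and escape
#' classification still see them while dN/dS ignores them. When gene models
#' are supplied, the reference allele of each SNV is checked against the
#' model sequence and its trinucleotide context derived from it; rows whose
#' ref allele disagrees with the model are rejected with a reason, never
#' corrected. Every input row is accounted for: `nrow(records) +
#' nrow(attr(records, "rejected"))` equals the number of data rows.
#'
#' @param path MAF file (tab-separated, standard column names).
#' @param gene_models Optional named list of [gene_model()] objects.
#' @return Mutation table with attribute `"rejected"` (data.frame of row
#'   numbers and reasons).
#' @export
read_maf <- function(path, gene_models = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing_cols <- setdiff(MAF_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("MAF is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  ref <- toupper(df$Reference_Allele)
  alt <- toupper(df$Tumor_Seq_Allele2)
  is_snv <- ref %in% BASES & alt %in% BASES & ref != alt

  vclass <- unname(MAF_CLASS_MAP[df$Variant_Classification])
  vclass[is.na(vclass)] <- "other_nonsilent"
  # non-SNV rows keep a non-silent class unless explicitly noncoding
  vclass[!is_snv & !vclass %in% c("frameshift", "noncoding")] <-
    "other_nonsilent"

  vaf <- rep(NA_real_, n)
  if ("VAF" %in% names(df)) {
    vaf <- as.numeric(df$VAF)
  } else if (all(c("t_alt_count", "t_depth") %in% names(df))) {
    vaf <- ifelse(df$t_depth > 0, df$t_alt_count / df$t_depth, NA_real_)
  }

  ctx <- if ("Context" %in% names(df)) toupper(df$Context) else
    rep(NA_character_, n)

  rec <- data.frame(
    patient_id = as.character(df$Tumor_Sample_Barcode),
    gene_id = as.character(df$Hugo_Symbol),
    chromosome = as.character(df$Chromosome),
    position = as.integer(df$Start_Position),
    ref_allele = ref, alt_allele = alt,
    variant_class = vclass, context = ctx,
    vaf = vaf,
    cancer_type = if ("Cancer_Type" %in% names(df))
      as.character(df$Cancer_Type) else NA_character_,
    is_snv = is_snv,
    stringsAsFactors = FALSE
  )

  reject <- rep(NA_character_, n)
  if (!is.null(gene_models)) {
    strand <- vapply(gene_models, `[[`, character(1), "strand")
    for (g in intersect(unique(rec$gene_id[rec$is_snv]), names(gene_models))) {
      gm <- gene_models[[g]]
      i <- which(rec$gene_id == g & rec$is_snv)
      cds_idx <- genomic_to_cds(gm, rec$position[i])
      inside <- !is.na(cds_idx)
      if (any(inside)) {
        ii <- i[inside]
        ref_cod <- if (gm$strand == "-") comp_base(rec$ref_allele[ii]) else
          rec$ref_allele[ii]
        model_ref <- substring(gm$cds_seq, cds_idx[inside], cds_idx[inside])
        bad <- ref_cod != model_ref
        reject[ii[bad]] <- "ref allele disagrees with gene model sequence"
        derived <- cds_context(gm, cds_idx[inside])
        have_ctx <- !is.na(rec$context[ii])
        mismatch <- have_ctx & !bad & rec$context[ii] != derived
        reject[ii[mismatch]] <- "context column disagrees with gene model"
        fill <- !have_ctx & !bad
        rec$context[ii[fill]] <- derived[fill]
      }
    }
  }
  rejected <- data.frame(
    row = which(!is.na(reject)), reason = reject[!is.na(reject)],
    stringsAsFactors = FALSE
  )
  out <- rec[is.na(reject), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  validate_catalog(out)
  out
}

#' Write a mutation catalog as a MAF-style file
#'
#' Inverse of [read_maf()] for the retained fields (SNV rows round-trip
#' bit-exactly).
#'
#' @param catalog Mutation table.
#' @param path Output file.
#' @export
write_maf <- function(catalog, path) {
  inv <- names(MAF_CLASS_MAP)[match(catalog$variant_class, MAF_CLASS_MAP)]
  inv[catalog$variant_class == "frameshift" & is.na(inv)] <- "Frame_Shift_Del"
  df <- data.frame(
    Hugo_Symbol = catalog$gene_id,
    Chromosome = catalog$chromosome,
    Start_Position = catalog$position,
    Reference_Allele = catalog$ref_allele,
    Tumor_Seq_Allele2 = catalog$alt_allele,
    Variant_Classification = inv,
    Tumor_Sample_Barcode = catalog$patient_id,
    VAF = catalog$vaf,
    Context = catalog$context,
    Cancer_Type = catalog$cancer_type,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF-like TSV plus a reference FASTA
#'
#' The TSV has one row per exon with columns `gene_id`, `transcript_id`,
#' `chrom`, `strand`, `exon_start`, `exon_end` (1-based inclusive). CDS
#' sequences and flanking bases are extracted from the reference FASTA
#' (chromosome sequences).
#'
#' @param tsv_path Gene model TSV.
#' @param fasta_path Reference FASTA of chromosome sequences.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(tsv_path, fasta_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "exon_start",
            "exon_end")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("gene model TSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ref <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- as.character(ref)
  names(seqs) <- sub("\\s.*$", "", names(ref))

  out <- lapply(split(tab, tab$gene_id), function(g) {
    g <- g[order(g$exon_start), , drop = FALSE]
    chrom <- g$chrom[1]
    if (!chrom %in% names(seqs)) stop("chromosome absent from FASTA: ", chrom)
    chromseq <- seqs[[chrom]]
    strand <- g$strand[1]
    exon_seqs <- substring(chromseq, g$exon_start, g$exon_end)
    cds <- paste(exon_seqs, collapse = "")
    gstart <- min(g$exon_start)
    gend <- max(g$exon_end)
    if (strand == "-") cds <- revcomp(cds)
    # flanks in coding orientation
    up <- if (gstart > 1) substring(chromseq, gstart - 1, gstart - 1) else "N"
    dn <- if (gend < nchar(chromseq)) substring(chromseq, gend + 1, gend + 1)
          else "N"
    if (strand == "+") {
      f5 <- up; f3 <- dn
    } else {
      f5 <- comp_base(dn); f3 <- comp_base(up)
    }
    gene_model(
      gene_id = g$gene_id[1], transcript_id = g$transcript_id[1],
      chrom = chrom, strand = strand,
      exons = cbind(start = g$exon_start, end = g$exon_end),
      cds_seq = cds, flank5 = f5, flank3 = f3
    )
  })
  out[unique(tab$gene_id)]
}

#' Write gene models as a GFF-like TSV
#' @param gene_models Named list of gene models.
#' @param path Output TSV.
#' @export
write_gene_models <- function(gene_models, path) {
  rows <- do.call(rbind, lapply(gene_models, function(gm) {
    data.frame(
      gene_id = gm$gene_id, transcript_id = gm$transcript_id,
      chrom = gm$chrom, strand = gm$strand,
      exon_start = gm$exons[, "start"], exon_end = gm$exons[, "end"],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write chromosome sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Construct a signature catalog
#'
#' @param mat 96 x K nonnegative matrix, rows in [sbs96_contexts()] order,
#'   columns named by signature; columns must sum to 1 within `tol`.
#' @param tol Column-sum tolerance before renormalization (default 1e-3).
#' @return Object of class `signature_catalog`.
#' @export
signature_catalog <- function(mat, tol = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 96L) stop("signature matrix must have 96 rows")
  if (any(mat < 0)) stop("signature matrix has negative entries")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > tol)) {
    stop("signature column sums deviate from 1 beyond tolerance: ",
         paste(colnames(mat)[abs(cs - 1) > tol], collapse = ", "))
  }
  mat <- sweep(mat, 2, cs, "/")
  rownames(mat) <- sbs96_contexts()
  structure(
    list(names = colnames(mat), matrix = mat, context_order = sbs96_contexts()),
    class = "signature_catalog"
  )
}

#' Read a COSMIC-style SBS signature TSV
#'
#' First column holds the 96 context labels (`"A[C>T]G"` style); remaining
#' columns are signatures. Rows are reordered to the canonical context
#' order; columns renormalized to sum 1 (tolerance 1e-3, else error).
#'
#' @param path Signature TSV.
#' @return A `signature_catalog`.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96L) stop("signature catalog must have 96 data rows, got ",
                            nrow(df))
  ctx <- df[[1]]
  ord <- match(sbs96_contexts(), ctx)
  if (anyNA(ord)) stop("signature catalog is missing context labels")
  mat <- as.matrix(df[ord, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  signature_catalog(mat)
}

#' Write a signature catalog as TSV
#' @param catalog A `signature_catalog`.
#' @param path Output TSV.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(Type = catalog$context_order, catalog$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clinical, expression and copy-number tables
#'
#' Clinical TSV: `patient_id`, `survival_time` (days), `event` (1 = death,
#' 0 = censored), `immune_category` (C1..C6 or empty), `cancer_type`.
#' Expression TSV (long): `patient_id`, `gene_id`, `fpkm`. CNV TSV (long):
#' `patient_id`, `gene_id`, `copy_number` (integer). Patients present in a
#' mutation catalog but absent from these tables are simply absent here and
#' get missing annotation downstream; they are never dropped from the
#' catalog. Duplicate patient x gene keys are a hard failure.
#'
#' @param clinical_path,expression_path,cnv_path File paths; expression and
#'   CNV are optional (`NULL`).
#' @return List with `clinical`, `expression`, `cnv` (NULL when not given).
#' @export
read_tables <- function(clinical_path, expression_path = NULL,
                        cnv_path = NULL) {
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(clin)) stop("clinical table lacks patient_id")
  if (any(duplicated(clin$patient_id))) stop("duplicate patient_id in clinical")
  if ("survival_time" %in% names(clin) &&
      any(!is.na(clin$survival_time) & clin$survival_time <= 0)) {
    stop("nonpositive survival_time in clinical table")
  }
  if ("event" %in% names(clin) &&
      !all(stats::na.omit(clin$event) %in% c(0, 1))) {
    stop("event must be 0/1")
  }
  if ("immune_category" %in% names(clin)) {
    ic <- clin$immune_category
    ic[ic == ""] <- NA
    bad <- !is.na(ic) & !ic %in% paste0("C", 1:6)
    if (any(bad)) stop("immune_category outside C1..C6: ", ic[bad][1])
    clin$immune_category <- ic
  }
  read_long <- function(path, value_col) {
    if (is.null(path)) return(NULL)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "gene_id", value_col)
    if (!all(need %in% names(tab))) {
      stop(basename(path), " must have columns ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(tab[c("patient_id", "gene_id")])) {
      stop("duplicate patient x gene keys in ", basename(path))
    }
    tab
  }
  list(
    clinical = clin,
    expression = read_long(expression_path, "fpkm"),
    cnv = read_long(cnv_path, "copy_number")
  )
}
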