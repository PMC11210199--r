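# Gene models: CDS structure with genome <-> CDS <-> protein coordinate maps.

#' Construct a gene model
#'
#' A gene model holds the coding structure of one canonical transcript: its
#' exons (1-based inclusive genomic intervals), strand, and the coding-strand
#' CDS sequence, plus one flanking reference base on each side of the CDS so
#' trinucleotide contexts are defined at the CDS edges.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame (start, end), 1-based
#'   inclusive, sorted by genomic start.
#' @param cds_seq Coding-strand CDS sequence; length must be a multiple of 3,
#'   equal the summed exon widths, and translate without internal stops.
#' @param flank5,flank3 Single reference bases flanking the first/last CDS
#'   base *in coding orientation*.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id = gene_id, chrom = "chr1",
                       strand = c("+", "-"), exons, cds_seq,
                       flank5 = "N", flank3 = "N") {
  strand <- match.arg(strand)
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] < exons[, "start"])) stop("exon end < start")
  if (is.unsorted(exons[, "start"])) stop("exons must be sorted by start")
  cds_seq <- toupper(cds_seq)
  L <- nchar(cds_seq)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3: ", gene_id)
  if (sum(exons[, "end"] - exons[, "start"] + 1L) != L) {
    stop("exon widths do not sum to CDS length for ", gene_id)
  }
  aa <- translate_cds(cds_seq)
  body <- substr(aa, 1, nchar(aa) - 1L)
  if (grepl("\\*", body)) stop("internal stop codon in CDS of ", gene_id)
  structure(
    list(
      gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
      strand = strand, exons = exons, cds_seq = cds_seq,
      flank5 = toupper(flank5), flank3 = toupper(flank3)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s (%s) %s%s, %d exon(s), CDS %d nt\n",
    x$gene_id, x$transcript_id, x$chrom, x$strand,
    nrow(x$exons), nchar(x$cds_seq)
  ))
  invisible(x)
}

cds_length <- function(gm) nchar(gm$cds_seq)

#' Genomic positions of every CDS base, in CDS order
#'
#' @param gm A `gene_model`.
#' @return Integer vector of length `nchar(cds_seq)`; element i is the
#'   genomic position of CDS base i (5' to 3' in coding orientation).
#' @export
cds_genomic_positions <- function(gm) {
  pos <- unlist(lapply(seq_len(nrow(gm$exons)), function(i) {
    seq.int(gm$exons[i, "start"], gm$exons[i, "end"])
  }), use.names = FALSE)
  if (gm$strand == "-") pos <- rev(pos)
  pos
}

#' Map CDS indices to genomic positions
#' @param gm A `gene_model`.
#' @param cds_idx 1-based CDS indices.
#' @return Integer genomic positions.
#' @export
cds_to_genomic <- function(gm, cds_idx) {
  pos <- cds_genomic_positions(gm)
  if (any(cds_idx < 1L | cds_idx > length(pos))) stop("CDS index out of range")
  pos[cds_idx]
}

#' Map genomic positions to CDS indices
#' @param gm A `gene_model`.
#' @param gpos Genomic positions; positions outside the CDS give `NA`.
#' @return Integer CDS indices (1-based) or `NA`.
#' @export
genomic_to_cds <- function(gm, gpos) {
  match(gpos, cds_genomic_positions(gm))
}

#' Map genomic positions to protein positions
#' @inheritParams genomic_to_cds
#' @return Integer protein (codon) positions or `NA`.
#' @export
genomic_to_protein <- function(gm, gpos) {
  idx <- genomic_to_cds(gm, gpos)
  as.integer(ceiling(idx / 3))
}

# coding-strand trinucleotide context of CDS position i
cds_context <- function(gm, cds_idx) {
  s <- strsplit(gm$cds_seq, "")[[1]]
  L <- length(s)
  f5 <- ifelse(cds_idx == 1L, gm$flank5, s[pmax(cds_idx - 1L, 1L)])
  f3 <- ifelse(cds_idx == L, gm$flank3, s[pmin(cds_idx + 1L, L)])
  paste0(f5, s[cds_idx], f3)
}

#' Enumerate all possible single-base substitutions of a gene's CDS
#'
#' For every CDS position and each of the three alternative bases, classifies
#' the substitution (synonymous / missense / nonsense) by translating the
#' mutated codon, and records genomic position, strand-specific (192-class)
#' and pyrimidine-collapsed (96-class) context channels, and the affected
#' codon. This table is the site-opportunity backbone for both the dN/dS
#' impact matrices and the cohort simulator.
#'
#' @param gm A `gene_model`.
#' @return data.frame with one row per (CDS position x alt base): columns
#'   `gene_id`, `cds_pos`, `gpos`, `ref_cod`, `alt_cod` (coding strand),
#'   `ref_gen`, `alt_gen` (genomic strand), `context` (coding-strand
#'   triplet), `cls192`, `cls96` (integer channel indices), `impact`
#'   (factor synonymous/missense/nonsense), `aa_pos`.
#' @export
enumerate_substitutions <- function(gm) {
  s <- strsplit(gm$cds_seq, "")[[1]]
  L <- length(s)
  gpos <- cds_genomic_positions(gm)
  f5 <- c(gm$flank5, s[-L])
  f3 <- c(s[-1], gm$flank3)
  codon_idx <- (seq_len(L) + 2L) %/% 3L
  offset <- (seq_len(L) - 1L) %% 3L + 1L
  codons <- substring(gm$cds_seq, 3L * codon_idx - 2L, 3L * codon_idx)
  aa_ref <- unname(Biostrings::GENETIC_CODE[codons])

  # three alternative bases per position
  alt_mat <- vapply(s, function(b) setdiff(BASES, b), character(3))
  idx <- rep(seq_len(L), each = 3L)
  alt <- as.vector(alt_mat)
  ref <- s[idx]

  cpos <- codon_idx[idx]
  off <- offset[idx]
  c1 <- s[3L * cpos - 2L]
  c2 <- s[3L * cpos - 1L]
  c3 <- s[3L * cpos]
  mut_cod <- paste0(
    ifelse(off == 1L, alt, c1),
    ifelse(off == 2L, alt, c2),
    ifelse(off == 3L, alt, c3)
  )
  aa_mut <- unname(Biostrings::GENETIC_CODE[mut_cod])
  aa0 <- aa_ref[idx]
  impact <- ifelse(aa_mut == aa0, "synonymous",
    ifelse(aa_mut == "*", "nonsense", "missense")
  )

  cls192 <- match(
    class192_of(f5[idx], ref, f3[idx], alt),
    class192_all()
  )
  cls96 <- match(class96_of(f5[idx], ref, f3[idx], alt), sbs96_contexts())

  minus <- gm$strand == "-"
  data.frame(
    gene_id = gm$gene_id,
    cds_pos = idx,
    gpos = gpos[idx],
    ref_cod = ref,
    alt_cod = alt,
    ref_gen = if (minus) comp_base(ref) else ref,
    alt_gen = if (minus) comp_base(alt) else alt,
    context = paste0(f5[idx], ref, f3[idx]),
    cls192 = cls192,
    cls96 = cls96,
    impact = factor(impact, levels = c("synonymous", "missense", "nonsense")),
    aa_pos = codon_idx[idx],
    stringsAsFactors = FALSE
  )
}
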