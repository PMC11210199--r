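# Internal sequence / context utilities shared across modules.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
SUBSTITUTIONS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' @importFrom Biostrings GENETIC_CODE
NULL

comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

revcomp <- function(x) {
  # vectorized reverse complement of short strings
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Canonical order of the 96 pyrimidine-centered substitution classes
#'
#' Classes are labelled \code{"A[C>T]G"} style and ordered COSMIC-fashion:
#' by substitution (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3'
#' flank, each alphabetical.
#'
#' @return Character vector of length 96.
#' @export
sbs96_contexts <- function() {
  out <- character(0)
  for (sub in SUBSTITUTIONS6) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out <- c(out, paste0(f5, "[", sub, "]", f3))
      }
    }
  }
  out
}

# 192 strand-specific classes: coding-strand triplet plus coding-strand alt,
# labelled "ACG>T" (triplet ACG, middle base C mutated to T).
class192_labels <- function() {
  trip <- character(64)
  i <- 0L
  for (f5 in BASES) for (m in BASES) for (f3 in BASES) {
    i <- i + 1L
    trip[i] <- paste0(f5, m, f3)
  }
  out <- character(0)
  for (tr in trip) {
    ref <- substr(tr, 2, 2)
    for (alt in setdiff(BASES, ref)) out <- c(out, paste0(tr, ">", alt))
  }
  out
}

.pkg_cache <- new.env(parent = emptyenv())

class192_all <- function() {
  if (is.null(.pkg_cache$cl192)) .pkg_cache$cl192 <- class192_labels()
  .pkg_cache$cl192
}

# strand-specific class label from coding-strand flanks/ref/alt
class192_of <- function(f5, ref, f3, alt) {
  paste0(f5, ref, f3, ">", alt)
}

# collapse a strand-specific class to its pyrimidine-centered 96 label
class96_of <- function(f5, ref, f3, alt) {
  pur <- ref %in% c("A", "G")
  o5 <- ifelse(pur, comp_base(f3), f5)
  o3 <- ifelse(pur, comp_base(f5), f3)
  oref <- ifelse(pur, comp_base(ref), ref)
  oalt <- ifelse(pur, comp_base(alt), alt)
  paste0(o5, "[", oref, ">", oalt, "]", o3)
}

# map each of the 192 strand-specific classes to its 96-class index
class192_to_96 <- function() {
  cl <- class192_all()
  f5 <- substr(cl, 1, 1)
  ref <- substr(cl, 2, 2)
  f3 <- substr(cl, 3, 3)
  alt <- substr(cl, 5, 5)
  match(class96_of(f5, ref, f3, alt), sbs96_contexts())
}

VARIANT_CLASSES <- c(
  "synonymous", "missense", "nonsense", "essential_splice",
  "frameshift", "other_nonsilent", "noncoding"
)

NONSILENT_DEFAULT <- c("missense", "nonsense", "essential_splice", "other_nonsilent")

`%||%` <- function(a, b) if (is.null(a)) b else a
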