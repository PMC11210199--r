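# 96-context spectra and signature exposure refitting by forward-selection
# constrained least squares (deconstructSigs-style), plus group comparisons
# of signature landscapes.

#' Tabulate the 96-context mutation spectrum
#'
#' Collapses each SNV to its pyrimidine-centered trinucleotide class
#' (purine-reference mutations are reverse-complemented) and counts per
#' subject. The class is `flank5[ref>alt]flank3` using the stored
#' coding-strand context. Records with ambiguous context bases are skipped
#' and counted in the `n_skipped` attribute; the retained count is
#' conserved: `sum(counts)` equals the number of admissible SNVs.
#'
#' @param catalog Mutation table (SNV rows with `context` used).
#' @param gene_models Named list of gene models (to orient alt alleles on
#'   the coding strand for minus-strand genes). May be `NULL` when all
#'   genes are plus-strand.
#' @param by `"patient"` (default), `"cohort"` (single pooled spectrum), or
#'   a named character vector patient_id -> group label.
#' @return Matrix of counts, one row per subject, 96 columns in
#'   [sbs96_contexts()] order; attribute `n_skipped`.
#' @export
tabulate_96 <- function(catalog, gene_models = NULL, by = "patient") {
  snv <- catalog[(catalog$is_snv %||% TRUE) & !is.na(catalog$context), ,
                 drop = FALSE]
  if (is.null(gene_models)) {
    alt_cod <- snv$alt_allele
  } else {
    strand <- vapply(gene_models, `[[`, character(1), "strand")
    minus <- !is.na(strand[snv$gene_id]) & strand[snv$gene_id] == "-"
    alt_cod <- ifelse(minus, comp_base(snv$alt_allele), snv$alt_allele)
  }
  f5 <- substr(snv$context, 1, 1)
  ref <- substr(snv$context, 2, 2)
  f3 <- substr(snv$context, 3, 3)
  cls <- match(class96_of(f5, ref, f3, alt_cod), sbs96_contexts())
  keep <- !is.na(cls)
  n_skipped <- sum(!keep)
  snv <- snv[keep, , drop = FALSE]
  cls <- cls[keep]

  subject <- if (identical(by, "patient")) {
    snv$patient_id
  } else if (identical(by, "cohort")) {
    rep("cohort", nrow(snv))
  } else {
    unname(by[snv$patient_id])
  }
  ok <- !is.na(subject)
  tab <- table(subject[ok], factor(cls[ok], levels = 1:96))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), sbs96_contexts()))
  attr(out, "n_skipped") <- n_skipped
  out
}

# golden-section minimization of f on [lo, hi]
.golden <- function(f, lo, hi, tol = 1e-7) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a)
  d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' Refit signature exposures to a spectrum by forward selection
#'
#' Normalizes the spectrum to proportions and greedily builds a nonnegative
#' exposure vector over the catalog columns (weights summing to at most 1):
#' start from the single signature minimizing the sum of squared errors;
#' then repeatedly re-optimize each selected weight by golden-section line
#' search (holding the others fixed, respecting the sum constraint) and add
#' the best next signature only while the relative SSE improvement exceeds
#' `stop_delta`. Weights below `threshold` are zeroed and the surviving set
#' re-optimized. Fully deterministic.
#'
#' @param spectrum Numeric vector of 96 counts (or one row of
#'   [tabulate_96()] output).
#' @param catalog A `signature_catalog`.
#' @param threshold Minimum reported weight (default 0.06).
#' @param stop_delta Minimum relative SSE improvement to add a signature
#'   (default 0.01).
#' @return List of class `exposure_result`: `weights` (named, all >=
#'   `threshold`, sum <= 1), `residual_sse`, `dominant` (name of the
#'   largest weight), `tie` flag.
#' @export
fit_exposures <- function(spectrum, catalog, threshold = 0.06,
                          stop_delta = 0.01) {
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != 96L) stop("spectrum must have 96 entries")
  total <- sum(spectrum)
  if (total <= 0) stop("zero-total spectrum")
  p <- spectrum / total
  S <- catalog$matrix
  K <- ncol(S)

  sse <- function(w) sum((p - as.numeric(S %*% w))^2)

  refine <- function(w, sweeps = 10L) {
    for (s in seq_len(sweeps)) {
      w_old <- w
      for (j in which(w > 0 | seq_len(K) %in% active)) {
        cap <- 1 - sum(w[-j])
        if (cap <= 0) { w[j] <- 0; next }
        w[j] <- .golden(function(x) { w2 <- w; w2[j] <- x; sse(w2) }, 0, cap)
      }
      if (max(abs(w - w_old)) < 1e-8) break
    }
    w
  }

  # best single signature
  single <- vapply(seq_len(K), function(j) {
    x <- .golden(function(x) sum((p - x * S[, j])^2), 0, 1)
    sum((p - x * S[, j])^2)
  }, numeric(1))
  active <- which.min(single)
  w <- numeric(K)
  w[active] <- .golden(function(x) sum((p - x * S[, active])^2), 0, 1)
  err <- sse(w)

  repeat {
    rest <- setdiff(seq_len(K), active)
    if (length(rest) == 0) break
    trial_err <- rep(Inf, K)
    trial_w <- vector("list", K)
    for (j in rest) {
      act2 <- c(active, j)
      w2 <- w
      cap <- 1 - sum(w2[-j])
      if (cap > 0) {
        w2[j] <- .golden(function(x) { w3 <- w2; w3[j] <- x; sse(w3) }, 0, cap)
      }
      act_save <- active
      active <- act2
      w2 <- refine(w2, sweeps = 4L)
      active <- act_save
      trial_err[j] <- sse(w2)
      trial_w[[j]] <- w2
    }
    j_best <- which.min(trial_err)
    if (err > 0 && (err - trial_err[j_best]) / err > stop_delta) {
      active <- c(active, j_best)
      w <- trial_w[[j_best]]
      err <- trial_err[j_best]
    } else {
      break
    }
  }

  w <- refine(w)
  w[w < threshold] <- 0
  active <- which(w > 0)
  if (length(active)) w <- refine(w)
  w[w < threshold] <- 0

  weights <- stats::setNames(w[w > 0], catalog$names[w > 0])
  dominant <- if (length(weights)) {
    mx <- max(weights)
    names(weights)[weights == mx][order(names(weights)[weights == mx])][1]
  } else NA_character_
  tie <- length(weights) > 1 && sum(weights == max(weights)) > 1
  structure(
    list(weights = weights, residual_sse = sse(w), dominant = dominant,
         tie = tie, total_mutations = total),
    class = "exposure_result"
  )
}

#' Exposures for every row of a spectrum matrix
#' @param spectra Matrix from [tabulate_96()].
#' @inheritParams fit_exposures
#' @return Named list of `exposure_result`, one per subject.
#' @export
fit_exposures_all <- function(spectra, catalog, threshold = 0.06,
                              stop_delta = 0.01) {
  out <- lapply(seq_len(nrow(spectra)), function(i) {
    fit_exposures(spectra[i, ], catalog, threshold, stop_delta)
  })
  names(out) <- rownames(spectra)
  out
}

#' Per-group frequency of dominant signatures
#'
#' The dominant signature of a patient is the one with the largest fitted
#' weight (ties broken lexicographically and flagged); frequencies are
#' normalized within escape group.
#'
#' @param exposures Named list of `exposure_result` (names = patient ids).
#' @param labels Escape labels.
#' @return data.frame `group`, `signature`, `n`, `frequency`, `any_tie`.
#' @export
dominant_signature_profile <- function(exposures, labels) {
  status <- stats::setNames(labels$status, labels$patient_id)
  dom <- vapply(exposures, `[[`, character(1), "dominant")
  tie <- vapply(exposures, `[[`, logical(1), "tie")
  grp <- status[names(exposures)]
  ok <- !is.na(dom) & !is.na(grp)
  tab <- table(grp[ok], dom[ok])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "signature", "n")
  tot <- stats::ave(out$n, out$group, FUN = sum)
  out$frequency <- ifelse(tot > 0, out$n / tot, NA)
  out$any_tie <- tapply(tie[ok], grp[ok], any)[out$group]
  out
}

#' Per-signature chi-square comparison of group signature proportions
#'
#' For each signature, attributes mutations to it per group (group cohort
#' exposure weight x group total mutation count, rounded) and tests the
#' 2x2 table (this signature vs all others) x (escape-, escape+) by
#' Pearson chi-square, BH-adjusted across signatures.
#'
#' @param exposure_neg,exposure_pos `exposure_result`s from cohort-level
#'   fits (pooled group spectra fitted as single samples).
#' @return data.frame `signature`, attributed counts per group, `chi2`,
#'   `p`, `q`.
#' @export
compare_signature_proportions <- function(exposure_neg, exposure_pos) {
  sigs <- union(names(exposure_neg$weights), names(exposure_pos$weights))
  if (length(sigs) == 0) stop("no signatures with nonzero exposure")
  tot_neg <- exposure_neg$total_mutations
  tot_pos <- exposure_pos$total_mutations
  attr_neg <- round(tot_neg * (exposure_neg$weights[sigs] %||% 0))
  attr_pos <- round(tot_pos * (exposure_pos$weights[sigs] %||% 0))
  attr_neg[is.na(attr_neg)] <- 0
  attr_pos[is.na(attr_pos)] <- 0
  out <- do.call(rbind, lapply(seq_along(sigs), function(i) {
    tab <- rbind(
      this = c(escape_neg = attr_neg[i], escape_pos = attr_pos[i]),
      other = c(escape_neg = tot_neg - attr_neg[i],
                escape_pos = tot_pos - attr_pos[i])
    )
    test <- .pearson_chisq(tab)
    data.frame(signature = sigs[i], attributed_neg = unname(attr_neg[i]),
               attributed_pos = unname(attr_pos[i]),
               total_neg = tot_neg, total_pos = tot_pos,
               chi2 = test$chi2, p = test$p, stringsAsFactors = FALSE)
  }))
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
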