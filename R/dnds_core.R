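# Trinucleotide-context maximum-likelihood dN/dS.
#
# Model: for a gene g with site opportunities L[s, k] (s = 192 strand-specific
# trinucleotide substitution classes, k = synonymous/missense/nonsense) and
# cohort-wide relative rates r_s anchored on synonymous mutations, observed
# counts are Poisson,
#     n_k ~ Poisson(t_g * lambda_k * w_k),   lambda_k = sum_s r_s L[s, k],
# with w_syn == 1. t_g absorbs the gene's mutation load; w_mis and w_non are
# the selection parameters (dN/dS). Estimation is by maximum likelihood with
# likelihood-ratio tests of w = 1 and profile-likelihood confidence
# intervals. This is a deliberately simplified take on the dNdScv family of
# models: plain Poisson (no negative-binomial overdispersion) and no
# gene-level covariates.

IMPACTS3 <- c("synonymous", "missense", "nonsense")

#' Per-gene substitution opportunity matrix
#'
#' Counts, for one gene, every possible single-base substitution of its CDS
#' by (strand-specific trinucleotide class, impact). The total count equals
#' 3 x CDS length.
#'
#' @param gm A [gene_model()].
#' @return Object of class `impact_matrix`: list with `gene_id`, `L`
#'   (192 x 3 integer matrix, rows = strand-specific classes, columns =
#'   synonymous/missense/nonsense) and `cds_length`.
#' @export
build_impact_matrix <- function(gm) {
  subs <- enumerate_substitutions(gm)
  if (anyNA(subs$cls192)) {
    stop(
      "gene ", gm$gene_id, " has ambiguous flanking bases; ",
      "provide real flank5/flank3 bases to build an impact matrix"
    )
  }
  L <- matrix(0L, nrow = 192L, ncol = 3L,
              dimnames = list(class192_all(), IMPACTS3))
  tab <- table(factor(subs$cls192, levels = 1:192), subs$impact)
  L[, IMPACTS3] <- as.integer(tab[, IMPACTS3])
  dim(L) <- c(192L, 3L)
  dimnames(L) <- list(class192_all(), IMPACTS3)
  structure(
    list(gene_id = gm$gene_id, L = L, cds_length = nchar(gm$cds_seq)),
    class = "impact_matrix"
  )
}

#' Impact matrices for a set of gene models
#'
#' Accepts either a named list of [gene_model()] objects or a
#' [simulate_genome()] result; for the latter the precomputed substitution
#' table is tabulated directly, which is much faster for large genomes.
#'
#' @param gene_models Named list of [gene_model()] objects, or a
#'   `sim_genome`.
#' @return Named list of `impact_matrix` objects.
#' @export
build_impact_matrices <- function(gene_models) {
  if (inherits(gene_models, "sim_genome")) {
    genome <- gene_models
    opp <- genome$opportunity
    tab <- table(factor(opp$gene_id, levels = names(genome$gene_models)),
                 factor(opp$cls192, levels = 1:192), opp$impact)
    out <- lapply(names(genome$gene_models), function(g) {
      L <- matrix(0L, 192L, 3L,
                  dimnames = list(class192_all(), IMPACTS3))
      for (k in IMPACTS3) L[, k] <- as.integer(tab[g, , k])
      structure(
        list(gene_id = g, L = L,
             cds_length = nchar(genome$gene_models[[g]]$cds_seq)),
        class = "impact_matrix"
      )
    })
    names(out) <- names(genome$gene_models)
    return(out)
  }
  out <- lapply(gene_models, build_impact_matrix)
  names(out) <- vapply(gene_models, `[[`, character(1), "gene_id")
  out
}

# strand-specific 192-class index for catalog rows (coding-strand context is
# stored on the record; the alt base must be flipped for minus-strand genes)
catalog_cls192 <- function(catalog, gene_models) {
  strand <- vapply(gene_models, `[[`, character(1), "strand")
  minus <- strand[catalog$gene_id] == "-"
  alt_cod <- ifelse(minus, comp_base(catalog$alt_allele), catalog$alt_allele)
  f5 <- substr(catalog$context, 1, 1)
  ref <- substr(catalog$context, 2, 2)
  f3 <- substr(catalog$context, 3, 3)
  match(class192_of(f5, ref, f3, alt_cod), class192_all())
}

#' Fit trinucleotide-context relative mutation rates
#'
#' Estimates the 192 strand-specific relative rates r_s of the dN/dS
#' model, anchored on synonymous mutations (the rates are rescaled so that
#' sum_s r_s L_s^syn equals the total synonymous count, putting expected
#' counts on the observed scale).
#'
#' Two estimators are provided. `method = "joint"` (default) maximizes the
#' Poisson likelihood over rates and one pooled selection parameter using
#' all coding SNVs: iterating r_s = (n_s^syn + n_s^non) / (L_s^syn + w
#' L_s^non) with w re-estimated from the rate-weighted opportunities. This
#' is the estimator of choice because synonymous-only rates are unstable
#' in classes with little synonymous opportunity, and that noise is
#' amplified multiplicatively into the nonsynonymous expectations (the
#' motivation for fitting rates inside the full likelihood, as the
#' dNdScv family of models does). `method = "synonymous"` is the plain
#' n_s^syn / L_s^syn estimator. In both, sparse classes (n < 1 and
#' L < 100) and classes with zero opportunity borrow the estimate of
#' their pyrimidine-collapsed 96-class partner.
#'
#' @param catalog MutationRecord table (coding SNVs used).
#' @param impacts List of `impact_matrix` from [build_impact_matrices()]
#'   over the calibration gene set.
#' @param gene_models The gene models the impacts were built from (needed to
#'   orient alt alleles on the coding strand).
#' @param method `"joint"` (default) or `"synonymous"`, see above.
#' @param n_iter Iterations for the joint fit (default 5; convergence is
#'   geometric).
#' @return Object of class `context_rate_model`: list with `r` (192 rates),
#'   `n_syn_total`, and the per-class synonymous counts/opportunities.
#' @export
fit_context_rates <- function(catalog, impacts, gene_models,
                              method = c("joint", "synonymous"),
                              n_iter = 5L) {
  method <- match.arg(method)
  snv <- catalog[catalog$variant_class %in% IMPACTS3 &
                   (catalog$is_snv %||% TRUE), , drop = FALSE]
  syn <- snv[snv$variant_class == "synonymous", , drop = FALSE]
  if (nrow(syn) == 0L) {
    stop(
      "no synonymous mutations in the catalog; pool cohorts or use ",
      "uniform_context_rates() instead"
    )
  }
  cls_all <- catalog_cls192(snv, gene_models)
  is_syn <- snv$variant_class == "synonymous"
  n_S <- tabulate(cls_all[is_syn], nbins = 192L)
  n_N <- tabulate(cls_all[!is_syn], nbins = 192L)
  L_S <- as.numeric(Reduce(`+`, lapply(impacts, function(im)
    im$L[, "synonymous"])))
  L_N <- as.numeric(Reduce(`+`, lapply(impacts, function(im)
    im$L[, "missense"] + im$L[, "nonsense"])))

  map96 <- class192_to_96()
  collapse_fill <- function(num, den, sparse) {
    # replace sparse-class ratios with their 96-collapsed estimates
    r <- ifelse(den > 0, num / den, NA_real_)
    num96 <- tapply(num, map96, sum)
    den96 <- tapply(den, map96, sum)
    r96 <- ifelse(den96 > 0, num96 / den96, 0)
    r[sparse] <- as.numeric(r96[as.character(map96)])[sparse]
    r[is.na(r)] <- 0
    r
  }

  if (method == "synonymous") {
    sparse <- (n_S < 1 & L_S < 100) | L_S == 0
    r <- collapse_fill(n_S, L_S, sparse)
  } else {
    w <- 1
    n_tot <- n_S + n_N
    for (it in seq_len(n_iter)) {
      den <- L_S + w * L_N
      sparse <- (n_tot < 1 & (L_S + L_N) < 100) | den == 0
      r <- collapse_fill(n_tot, den, sparse)
      lam_S <- sum(r * L_S)
      lam_N <- sum(r * L_N)
      if (lam_S <= 0 || lam_N <= 0) break
      t_hat <- sum(n_S) / lam_S
      w <- sum(n_N) / (t_hat * lam_N)
    }
  }

  denom <- sum(r * L_S)
  if (denom <= 0) stop("degenerate rate fit: no synonymous opportunity")
  r <- r * sum(n_S) / denom

  structure(
    list(r = r, n_syn_total = sum(n_S), n_s = n_S, L_s = L_S),
    class = "context_rate_model"
  )
}

#' Uniform context rates (every class equally mutable)
#'
#' Useful as a null background and for oracle checks: with uniform rates the
#' ML dN/dS reduces to the counting estimator (n_N / L_N) / (n_S / L_S).
#'
#' @param impacts List of `impact_matrix` (used only for the anchoring scale).
#' @param scale Total expected synonymous count the rates are anchored to.
#' @return A `context_rate_model` with all rates equal.
#' @export
uniform_context_rates <- function(impacts, scale = NULL) {
  L_s <- as.numeric(Reduce(`+`, lapply(impacts, function(im) im$L[, "synonymous"])))
  r <- rep(1, 192L)
  if (!is.null(scale)) r <- r * scale / sum(r * L_s)
  structure(
    list(r = r, n_syn_total = scale %||% NA_real_, n_s = NULL, L_s = L_s),
    class = "context_rate_model"
  )
}

# rate-weighted opportunities lambda_k for one gene
gene_lambdas <- function(im, rates) {
  as.numeric(crossprod(im$L, rates$r))
}

# profile log-likelihood in w for one impact class (t profiled out);
# constants independent of (w, t) dropped
.prof_ll <- function(w, n_syn, n_k, lam_s, lam_k) {
  t_hat <- (n_syn + n_k) / (lam_s + w * lam_k)
  mu_s <- t_hat * lam_s
  mu_k <- t_hat * w * lam_k
  ll <- -mu_s - mu_k
  if (n_syn > 0) ll <- ll + n_syn * log(mu_s)
  if (n_k > 0) ll <- ll + n_k * log(mu_k)
  ll
}

# profile-likelihood 95% CI for w (chi-square cutoff, 1 df)
.prof_ci <- function(w_hat, n_syn, n_k, lam_s, lam_k, level = 0.95) {
  if (lam_k <= 0) return(c(NA_real_, NA_real_))
  cut <- stats::qchisq(level, 1) / 2
  ll_max <- .prof_ll(max(w_hat, 0), n_syn, n_k, lam_s, lam_k)
  f <- function(w) .prof_ll(w, n_syn, n_k, lam_s, lam_k) - (ll_max - cut)
  lo <- 0
  if (n_k > 0 && w_hat > 0) {
    # lower bound strictly above 0 exists iff f(0) < 0 (it is -Inf when n_k>0)
    lo_br <- w_hat
    while (f(lo_br / 2) > 0) lo_br <- lo_br / 2
    lo <- stats::uniroot(f, c(lo_br / 2, w_hat), tol = 1e-9)$root
  }
  hi_br <- max(w_hat, 1e-3)
  it <- 0L
  while (f(hi_br * 2) > 0 && it < 200L) {
    hi_br <- hi_br * 2
    it <- it + 1L
  }
  hi <- if (it >= 200L) Inf else {
    stats::uniroot(f, c(max(w_hat, 1e-3), hi_br * 2), tol = 1e-9)$root
  }
  c(lo, hi)
}

#' Gene-level dN/dS estimate with tests and confidence intervals
#'
#' @param gene_id Gene to analyse.
#' @param catalog MutationRecord table (any genes; rows are filtered).
#' @param rates A `context_rate_model`.
#' @param impacts List of `impact_matrix` containing `gene_id`.
#' @param compute_ci Compute profile-likelihood CIs (default TRUE; skipping
#'   them speeds up large screens where only estimates and p-values are
#'   needed).
#' @return Object of class `gene_dnds_result`: one-row data.frame with
#'   observed counts, expected counts under neutrality, `w_mis`/`w_non` with
#'   95% profile CIs, LRT p-values (`p_mis`, `p_non`, and a 2-df `p_global`
#'   for joint neutrality of both classes). q-values are added cohort-wide
#'   by [call_drivers()].
#' @export
gene_dnds <- function(gene_id, catalog, rates, impacts, compute_ci = TRUE) {
  im <- impacts[[gene_id]]
  if (is.null(im)) stop("no impact matrix for gene ", gene_id)
  rows <- catalog[catalog$gene_id == gene_id, , drop = FALSE]
  n <- c(
    synonymous = sum(rows$variant_class == "synonymous"),
    missense = sum(rows$variant_class == "missense"),
    nonsense = sum(rows$variant_class == "nonsense")
  )
  lam <- gene_lambdas(im, rates)
  names(lam) <- IMPACTS3
  if (lam["synonymous"] <= 0) {
    stop("gene ", gene_id, " has zero synonymous opportunity; w undefined")
  }
  t_hat <- n[["synonymous"]] / lam[["synonymous"]]

  res <- list(gene_id = gene_id, n_syn = n[["synonymous"]],
              n_mis = n[["missense"]], n_non = n[["nonsense"]])
  for (k in c("missense", "nonsense")) {
    tag <- if (k == "missense") "mis" else "non"
    lam_k <- lam[[k]]
    n_k <- n[[k]]
    E_k <- t_hat * lam_k
    w <- if (t_hat > 0 && lam_k > 0) n_k / E_k else if (n_k > 0) Inf else NA_real_
    ci <- if (compute_ci) {
      .prof_ci(if (is.finite(w)) w else 1e6, n[["synonymous"]], n_k,
               lam[["synonymous"]], lam_k)
    } else {
      c(NA_real_, NA_real_)
    }
    # LRT of w = 1 with t profiled
    ll1 <- .prof_ll(1, n[["synonymous"]], n_k, lam[["synonymous"]], lam_k)
    ll_hat <- if (is.finite(w)) {
      .prof_ll(max(w, 0), n[["synonymous"]], n_k, lam[["synonymous"]], lam_k)
    } else {
      # supremum as w -> Inf with n_syn = 0: both counts fitted exactly
      (if (n_k > 0) n_k * log(n_k) - n_k else 0)
    }
    stat <- max(0, 2 * (ll_hat - ll1))
    res[[paste0("E_", tag)]] <- E_k
    res[[paste0("w_", tag)]] <- unname(w)
    res[[paste0("w_", tag, "_lo")]] <- ci[1]
    res[[paste0("w_", tag, "_hi")]] <- ci[2]
    res[[paste0("p_", tag)]] <- stats::pchisq(stat, 1, lower.tail = FALSE)
  }

  # joint 2-df LRT of (w_mis, w_non) = (1, 1)
  lam_tot <- sum(lam)
  n_tot <- sum(n)
  t0 <- n_tot / lam_tot
  ll0 <- sum(ifelse(n > 0, n * log(t0 * lam), 0)) - t0 * lam_tot
  ll_full <- sum(ifelse(n > 0, n * log(n) - n, 0))
  res$p_global <- stats::pchisq(max(0, 2 * (ll_full - ll0)), 2,
                                lower.tail = FALSE)
  out <- as.data.frame(res, stringsAsFactors = FALSE)
  class(out) <- c("gene_dnds_result", class(out))
  out
}

#' dN/dS for every gene in a catalog
#'
#' @inheritParams gene_dnds
#' @param gene_ids Genes to analyse (default: all genes with an impact
#'   matrix).
#' @return data.frame with one row per gene (see [gene_dnds()]).
#' @export
gene_dnds_all <- function(catalog, rates, impacts,
                          gene_ids = names(impacts), compute_ci = TRUE) {
  out <- do.call(rbind, lapply(gene_ids, gene_dnds,
                               catalog = catalog, rates = rates,
                               impacts = impacts, compute_ci = compute_ci))
  rownames(out) <- NULL
  out
}

#' Pooled (global or driver-set) dN/dS
#'
#' Pools observed and expected counts over a gene set as one super-gene:
#' t is estimated from the pooled synonymous counts and opportunity, and
#' the pooled omega is (sum n_nonsyn) / (sum E_nonsyn). The 95% CI is Wald
#' on log omega with variance 1/n_nonsyn + 1/n_syn. Missense-only and
#' nonsense-only pooled omegas are reported alongside.
#'
#' @param gene_set Character vector of gene ids (must have impact matrices).
#' @param catalog MutationRecord table.
#' @param rates A `context_rate_model`.
#' @param impacts List of `impact_matrix`.
#' @param label Label stored on the result (e.g. "all_genes",
#'   "known_drivers").
#' @return Object of class `global_dnds`: list with `w`, `ci`, `w_mis`,
#'   `w_non`, totals and the label.
#' @export
global_dnds <- function(gene_set, catalog, rates, impacts,
                        label = "custom") {
  gene_set <- intersect(gene_set, names(impacts))
  if (length(gene_set) == 0L) stop("empty gene set (no impact matrices)")
  rows <- catalog[catalog$gene_id %in% gene_set, , drop = FALSE]
  n_syn <- sum(rows$variant_class == "synonymous")
  n_mis <- sum(rows$variant_class == "missense")
  n_non <- sum(rows$variant_class == "nonsense")
  lam <- Reduce(`+`, lapply(impacts[gene_set], gene_lambdas, rates = rates))
  names(lam) <- IMPACTS3
  if (lam[["synonymous"]] <= 0 || n_syn == 0) {
    stop("pooled synonymous count or opportunity is zero; omega undefined")
  }
  t_hat <- n_syn / lam[["synonymous"]]
  E_mis <- t_hat * lam[["missense"]]
  E_non <- t_hat * lam[["nonsense"]]
  n_N <- n_mis + n_non
  w <- n_N / (E_mis + E_non)
  wald_ci <- function(w, n_num, n_den) {
    if (w <= 0 || n_num == 0) return(c(0, NA_real_))
    se <- sqrt(1 / n_num + 1 / n_den)
    exp(log(w) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  structure(
    list(
      gene_set_label = label,
      w = w, ci = wald_ci(w, n_N, n_syn),
      w_mis = n_mis / E_mis, ci_mis = wald_ci(n_mis / E_mis, n_mis, n_syn),
      w_non = if (E_non > 0) n_non / E_non else NA_real_,
      ci_non = if (E_non > 0) wald_ci(n_non / E_non, n_non, n_syn)
               else c(NA_real_, NA_real_),
      n_syn = n_syn, n_mis = n_mis, n_non = n_non,
      E_mis = E_mis, E_non = E_non, n_genes = length(gene_set)
    ),
    class = "global_dnds"
  )
}

#' @export
print.global_dnds <- function(x, ...) {
  cat(sprintf(
    "<global_dnds> %s: omega = %.4f [%.4f, %.4f] (n_syn=%d, n_mis=%d, n_non=%d, %d genes)\n",
    x$gene_set_label, x$w, x$ci[1], x$ci[2], x$n_syn, x$n_mis, x$n_non,
    x$n_genes
  ))
  invisible(x)
}

#' Call significantly selected (driver) genes
#'
#' Benjamini-Hochberg adjustment is applied separately within each impact
#' class (missense, nonsense/truncating) over all tested genes; a gene is
#' called significant for a class when omega > 1 and q < `q_threshold`.
#' Olfactory receptor genes, which accumulate passenger mutations at high
#' rates without a driver role, can be removed before the adjustment.
#'
#' @param results data.frame from [gene_dnds_all()].
#' @param q_threshold FDR threshold (default 0.1).
#' @param exclude_olfactory Remove olfactory-receptor genes before BH.
#' @param olfactory_pattern Regex identifying olfactory receptor symbols.
#' @return `results` (minus excluded genes) with `q_mis`, `q_non`,
#'   `q_global`, and logical `sig_mis`, `sig_non` columns.
#' @export
call_drivers <- function(results, q_threshold = 0.1,
                         exclude_olfactory = FALSE,
                         olfactory_pattern = "^OR[0-9]+[A-Z]") {
  stopifnot(nrow(results) > 0)
  if (exclude_olfactory) {
    results <- results[!grepl(olfactory_pattern, results$gene_id), ,
                       drop = FALSE]
  }
  results$q_mis <- stats::p.adjust(results$p_mis, method = "BH")
  results$q_non <- stats::p.adjust(results$p_non, method = "BH")
  results$q_global <- stats::p.adjust(results$p_global, method = "BH")
  results$sig_mis <- !is.na(results$w_mis) & results$w_mis > 1 &
    results$q_mis < q_threshold
  results$sig_non <- !is.na(results$w_non) & results$w_non > 1 &
    results$q_non < q_threshold
  results
}

#' Patient-bootstrap replicates of a pooled dN/dS
#'
#' Resamples patients with replacement and recomputes the pooled gene-set
#' omega per replicate, holding context rates fixed at the full-cohort fit.
#'
#' @param catalog MutationRecord table for one group.
#' @param gene_set Gene ids pooled over.
#' @param rates,impacts As in [global_dnds()].
#' @param B Number of bootstrap replicates.
#' @return Numeric vector of length `B` of pooled omega replicates.
#' @export
bootstrap_global_dnds <- function(catalog, gene_set, rates, impacts, B = 200) {
  gene_set <- intersect(gene_set, names(impacts))
  lam <- Reduce(`+`, lapply(impacts[gene_set], gene_lambdas, rates = rates))
  names(lam) <- IMPACTS3
  rows <- catalog[catalog$gene_id %in% gene_set, , drop = FALSE]
  patients <- unique(catalog$patient_id)
  # per-patient synonymous / nonsynonymous counts within the gene set
  pid <- factor(rows$patient_id, levels = patients)
  syn_by <- tabulate(pid[rows$variant_class == "synonymous"],
                     nbins = length(patients))
  non_by <- tabulate(pid[rows$variant_class %in% c("missense", "nonsense")],
                     nbins = length(patients))
  lam_N <- lam[["missense"]] + lam[["nonsense"]]
  vapply(seq_len(B), function(b) {
    idx <- sample.int(length(patients), replace = TRUE)
    ns <- sum(syn_by[idx])
    nn <- sum(non_by[idx])
    if (ns == 0) return(NA_real_)
    nn / ((ns / lam[["synonymous"]]) * lam_N)
  }, numeric(1))
}

#' Compare two groups' dN/dS via bootstrap replicate vectors
#'
#' Two-sided Wilcoxon-Mann-Whitney test on patient-bootstrap omega
#' replicates from the two groups (see [bootstrap_global_dnds()]), plus a
#' flag for non-overlap of the percentile 95% intervals.
#'
#' @param rep_a,rep_b Numeric replicate vectors (length >= 20 each).
#' @return List with `p`, `statistic`, `median_a`, `median_b`,
#'   `ci_a`, `ci_b`, and `ci_disjoint`.
#' @export
compare_group_dnds <- function(rep_a, rep_b) {
  rep_a <- rep_a[is.finite(rep_a)]
  rep_b <- rep_b[is.finite(rep_b)]
  if (length(rep_a) < 20 || length(rep_b) < 20) {
    stop("need >= 20 finite bootstrap replicates per group")
  }
  if (stats::var(c(rep_a, rep_b)) == 0) {
    # fully tied replicate vectors: no evidence of a difference
    wt <- list(p.value = 1,
               statistic = length(rep_a) * length(rep_b) / 2)
  } else {
    wt <- stats::wilcox.test(rep_a, rep_b, exact = FALSE)
  }
  ci_a <- stats::quantile(rep_a, c(0.025, 0.975), names = FALSE)
  ci_b <- stats::quantile(rep_b, c(0.025, 0.975), names = FALSE)
  list(
    p = wt$p.value, statistic = unname(wt$statistic),
    median_a = stats::median(rep_a), median_b = stats::median(rep_b),
    ci_a = ci_a, ci_b = ci_b,
    ci_disjoint = ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1]
  )
}
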