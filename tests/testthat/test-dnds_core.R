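# dN/dS core: impact matrices, rate fitting, ML estimates vs independent
# oracles, driver calling, group comparison.

# hand-built impact matrix: all opportunity in two uniform-rate classes
fake_impact <- function(gene_id, L_syn, L_mis, L_non = 0L) {
  L <- matrix(0L, 192L, 3L,
              dimnames = list(escapesel:::class192_all(),
                              c("synonymous", "missense", "nonsense")))
  L[1, ] <- c(L_syn, L_mis, L_non)
  structure(list(gene_id = gene_id, L = L,
                 cds_length = sum(L) / 3),
            class = "impact_matrix")
}

counts_catalog <- function(gene_id, n_syn, n_mis, n_non = 0L) {
  rows <- list()
  add <- function(k, cls) {
    if (k > 0) {
      rows[[length(rows) + 1]] <<- mut_row(
        sprintf("P%03d", seq_len(k)), gene_id, seq_len(k) + 100L,
        "C", "A", cls
      )
    }
  }
  add(n_syn, "synonymous")
  add(n_mis, "missense")
  add(n_non, "nonsense")
  do.call(rbind, rows)
}

test_that("with uniform rates the ML omega equals the counting estimator", {
  im <- list(TOY = fake_impact("TOY", L_syn = 100L, L_mis = 200L,
                               L_non = 20L))
  rates <- uniform_context_rates(im)
  cat0 <- counts_catalog("TOY", n_syn = 5L, n_mis = 30L, n_non = 2L)
  res <- gene_dnds("TOY", cat0, rates, im)
  expect_equal(res$w_mis, (30 / 200) / (5 / 100), tolerance = 1e-8)
  expect_equal(res$w_non, (2 / 20) / (5 / 100), tolerance = 1e-8)
  expect_equal(res$E_mis, (5 / 100) * 200, tolerance = 1e-8)
})

test_that("LRT maximum agrees with brute-force optimization of the raw
           Poisson likelihood", {
  im <- list(TOY = fake_impact("TOY", 100L, 200L))
  rates <- uniform_context_rates(im)
  cat0 <- counts_catalog("TOY", n_syn = 5L, n_mis = 30L)
  res <- gene_dnds("TOY", cat0, rates, im)

  # independent oracle: maximize the joint Poisson log-likelihood in
  # (log t, log w) numerically, and at w = 1 in log t alone
  ll <- function(logt, logw) {
    t <- exp(logt); w <- exp(logw)
    mu_s <- t * 100; mu_m <- t * w * 200
    stats::dpois(5, mu_s, log = TRUE) + stats::dpois(30, mu_m, log = TRUE)
  }
  free <- stats::optim(c(0, 0), function(p) -ll(p[1], p[2]),
                       method = "BFGS",
                       control = list(reltol = 1e-14))
  null <- stats::optimize(function(lt) -ll(lt, 0), c(-10, 10),
                          tol = 1e-12)
  stat_oracle <- 2 * (-free$value + null$objective)
  stat_pkg <- stats::qchisq(res$p_mis, 1, lower.tail = FALSE)
  expect_equal(stat_pkg, stat_oracle, tolerance = 1e-6)
  expect_equal(exp(free$par[2]), res$w_mis, tolerance = 1e-5)
})

test_that("profile CI brackets the estimate and hits the chi-square cutoff", {
  im <- list(TOY = fake_impact("TOY", 100L, 200L))
  rates <- uniform_context_rates(im)
  cat0 <- counts_catalog("TOY", n_syn = 20L, n_mis = 60L)
  res <- gene_dnds("TOY", cat0, rates, im)
  expect_lt(res$w_mis_lo, res$w_mis)
  expect_gt(res$w_mis_hi, res$w_mis)
  # at the bounds, the profile deviance equals qchisq(.95, 1)
  dev_at <- function(w) {
    2 * (escapesel:::.prof_ll(res$w_mis, 20, 60, 100, 200) -
           escapesel:::.prof_ll(w, 20, 60, 100, 200))
  }
  expect_equal(dev_at(res$w_mis_lo), stats::qchisq(0.95, 1),
               tolerance = 1e-5)
  expect_equal(dev_at(res$w_mis_hi), stats::qchisq(0.95, 1),
               tolerance = 1e-5)
})

test_that("zero observed missense gives w = 0 with CI floored at 0", {
  im <- list(TOY = fake_impact("TOY", 100L, 200L))
  rates <- uniform_context_rates(im)
  cat0 <- counts_catalog("TOY", n_syn = 10L, n_mis = 0L)
  res <- gene_dnds("TOY", cat0, rates, im)
  expect_equal(res$w_mis, 0)
  expect_equal(res$w_mis_lo, 0)
  expect_gt(res$w_mis_hi, 0)
})

test_that("adding a missense mutation never decreases the estimate", {
  im <- list(TOY = fake_impact("TOY", 100L, 200L))
  rates <- uniform_context_rates(im)
  w_seq <- vapply(0:15, function(n_mis) {
    gene_dnds("TOY", counts_catalog("TOY", 8L, n_mis), rates, im)$w_mis
  }, numeric(1))
  expect_true(all(diff(w_seq) >= 0))
})

test_that("pooled omega of a single-gene set equals the gene-level pooled
           omega, and duplication narrows the CI without moving it", {
  im <- list(TOY = fake_impact("TOY", 100L, 200L, 20L))
  rates <- uniform_context_rates(im)
  cat0 <- counts_catalog("TOY", 10L, 25L, 3L)
  g1 <- global_dnds("TOY", cat0, rates, im)
  res <- gene_dnds("TOY", cat0, rates, im)
  pooled_gene <- (res$n_mis + res$n_non) / (res$E_mis + res$E_non)
  expect_equal(g1$w, pooled_gene, tolerance = 1e-12)

  cat2 <- rbind(cat0, transform(cat0, patient_id = paste0(patient_id, "b")))
  g2 <- global_dnds("TOY", cat2, rates, im)
  expect_equal(g2$w, g1$w, tolerance = 1e-12)
  expect_lt(g2$ci[2] - g2$ci[1], g1$ci[2] - g1$ci[1])
})

test_that("context rate fitting: scale invariance and single-channel mass", {
  cfg <- small_sim_config(seed = 5, n_genes = 10L, driver_genes = list(),
                          escape_genes = character(0))
  genome <- simulate_genome(cfg)
  impacts <- build_impact_matrices(genome$gene_models)
  sim <- simulate_cohort(genome, cfg)
  # synonymous-anchored estimator: doubling every synonymous observation
  # leaves relative rates unchanged
  r1 <- fit_context_rates(sim$catalog, impacts, genome$gene_models,
                          method = "synonymous")
  syn <- sim$catalog[sim$catalog$variant_class == "synonymous", ]
  doubled <- rbind(sim$catalog,
                   transform(syn, patient_id = paste0(patient_id, "b")))
  r2 <- fit_context_rates(doubled, impacts, genome$gene_models,
                          method = "synonymous")
  nz <- r1$r > 0
  ratio <- r2$r[nz] / r1$r[nz]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-9)

  # joint estimator: doubling the whole catalog leaves relative rates
  # unchanged (scale lives in the anchoring, not the rate profile)
  j1 <- fit_context_rates(sim$catalog, impacts, genome$gene_models)
  all2 <- rbind(sim$catalog,
                transform(sim$catalog, patient_id = paste0(patient_id, "b")))
  j2 <- fit_context_rates(all2, impacts, genome$gene_models)
  nzj <- j1$r > 0
  ratioj <- (j2$r[nzj] / 2) / j1$r[nzj]
  expect_equal(max(ratioj) / min(ratioj), 1, tolerance = 1e-9)

  # a single observed channel carries the full normalization mass
  one <- syn[1, , drop = FALSE]
  rs <- fit_context_rates(one, impacts, genome$gene_models)
  expect_equal(sum(rs$r * rs$L_s), 1, tolerance = 1e-9)
})

test_that("driver calling applies the w>1 AND q<threshold rule with BH", {
  res <- data.frame(
    gene_id = c("A", "B", "C", "D"),
    w_mis = c(2.0, 0.5, 1.5, 1.2), p_mis = c(0.01, 0.001, 0.02, 0.5),
    w_non = 1, p_non = 0.9, p_global = c(0.01, 0.001, 0.02, 0.5),
    stringsAsFactors = FALSE
  )
  out <- call_drivers(res, q_threshold = 0.1)
  # hand BH on (0.01, 0.001, 0.02, 0.5): q = (0.02, 0.004, 0.0267, 0.5)
  expect_equal(out$q_mis, c(0.02, 0.004, 0.08 / 3, 0.5), tolerance = 1e-12)
  expect_true(out$sig_mis[out$gene_id == "A"])
  expect_false(out$sig_mis[out$gene_id == "B"]) # fails w > 1
  expect_true(out$sig_mis[out$gene_id == "C"])
  expect_false(out$sig_mis[out$gene_id == "D"]) # fails q

  # olfactory receptors removed before adjustment
  res$gene_id[4] <- "OR2A1"
  out2 <- call_drivers(res, exclude_olfactory = TRUE)
  expect_false("OR2A1" %in% out2$gene_id)
  expect_equal(out2$q_mis, stats::p.adjust(res$p_mis[1:3], "BH"))
})

test_that("group comparison: identical replicates give p near 1, separated
           replicates give extreme p and disjoint CIs", {
  set.seed(42)
  reps <- rep(1.25, 200)
  same <- compare_group_dnds(reps, reps)
  expect_gt(same$p, 0.99)
  a <- stats::rnorm(200, 1.2, 0.05)
  b <- stats::rnorm(200, 1.6, 0.05)
  diff <- compare_group_dnds(a, b)
  expect_lt(diff$p, 1e-10)
  expect_true(diff$ci_disjoint)
  expect_error(compare_group_dnds(a[1:5], b), ">= 20")
})

test_that("bootstrap replicates center on the full-cohort pooled omega", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_escape_cohort(cfg)
  impacts <- build_impact_matrices(sim$genome$gene_models)
  rates <- fit_context_rates(sim$catalog, impacts, sim$genome$gene_models)
  g <- global_dnds("DRV1", sim$catalog, rates, impacts)
  set.seed(1)
  reps <- bootstrap_global_dnds(sim$catalog, "DRV1", rates, impacts, B = 100)
  expect_gt(mean(reps, na.rm = TRUE), g$ci[1])
  expect_lt(mean(reps, na.rm = TRUE), g$ci[2])
})
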