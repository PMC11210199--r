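# escapesel

Tumors that acquire a non-silent point mutation in a gene of the antigen
presentation machinery (or another immune-evasion gene) can grow without
being edited by T cells. `escapesel` compares the somatic selection
landscape of such immune-**escaped** (escape+) tumors with non-escaped
(escape−) tumors: which genes are under positive selection in each group,
whether driver mutations concentrate in hotspots differently, how the
mutational-signature composition differs, whether driver mutations are more
clonal than escape mutations, and whether escape status carries prognostic
information within immune microenvironment categories.

The package is written for cancer-genomics analysts working with
MAF-style somatic mutation catalogs plus standard clinical, expression and
copy-number tables. Everything runs end-to-end on a built-in synthetic
cohort generator, so no external download is needed to exercise or test
any stage.

## The model at the core

Selection is measured by dN/dS (ω) with trinucleotide-context correction.
For a gene *g*, every possible single-base substitution of its CDS is
enumerated and classified (synonymous / missense / nonsense), giving
opportunity counts `L[s, k]` over `s = 192` strand-specific trinucleotide
substitution classes. Observed counts are modeled as Poisson:

    n_k ~ Poisson( t_g · λ_k · ω_k ),   λ_k = Σ_s r_s · L[s, k],  ω_syn ≡ 1

where `r_s` are cohort-wide relative context rates (estimated by maximum
likelihood from all coding SNVs with a pooled selection parameter
absorbed, anchored so expected synonymous counts match observed), `t_g`
absorbs the gene's mutation load, and `ω_mis`, `ω_non` are the selection
parameters. Tests of ω = 1 are likelihood-ratio tests; gene-level CIs are
profile likelihood; pooled (global / driver-set) ω uses a log-scale Wald
interval; driver calling is ω > 1 with Benjamini–Hochberg q < 0.1 per
impact class. This is a deliberately simplified relative of the dNdScv
family: plain Poisson, no gene-level covariates.

Around that core the package provides: escape classification (point
mutation, overlapping copy-number categories A–F, PD-L1 expression
quartiles); a randomized escape-gene null (re-drawing the escape list to
control for burden bias); mutation-vs-unique-site hotspot χ² contrasts
with downsampling and hotspot-exclusion controls; deconstructSigs-style
signature refitting by forward-selection constrained least squares;
Mann–Whitney VAF clonality contrasts; Kaplan–Meier / log-rank survival by
immune category (C1–C6); and protein→genome mapping of immunopeptidome
regions with region-masked dN/dS.

## Worked example

```r
library(escapesel)

cfg <- cohort_sim_config(seed = 7)        # the default study conditions
sim <- simulate_escape_cohort(cfg)        # catalog + clinical + truth ledger
impacts <- build_impact_matrices(sim$genome)

labels <- classify_point_mutation(sim$catalog, cfg$escape_genes)
neg <- sim$catalog[sim$catalog$patient_id %in%
                     labels$patient_id[labels$status == "escape_neg"], ]
rates <- fit_context_rates(neg, impacts, sim$genome$gene_models)
global_dnds(names(cfg$driver_genes), neg, rates, impacts, "known_drivers")
#> <global_dnds> known_drivers: omega = 2.9644 [2.2871, 3.8423]
#>   (n_syn=65, n_mis=436, n_non=33, 4 genes)

site_concentration_test(sim$catalog, "DRV1", labels)$p
#> [1] 7.894709e-08
```

The pooled driver-set ω ≈ 3 recovers the generator's configured selection
strength (drivers simulated at ω = 3–5), and the hotspot test flags the
escape−-restricted hotspot the generator placed at codon 50 of DRV1. The
whole analysis (classification → per-group dN/dS → contrasts → signatures
→ survival) can also be run from one YAML config with `run_pipeline()`,
which writes every stage table plus a hash manifest.

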