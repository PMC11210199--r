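---
title: "Selection landscapes of immune-escaped tumors: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection landscapes of immune-escaped tumors: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapesel)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The question

A tumor that loses antigen presentation — a non-silent point mutation in
B2M, an HLA gene, or another immune-evasion gene — escapes T-cell
surveillance. Escape status should then reshape selection on the rest of
the genome: driver mutations that would have been immunogenic can persist,
so escaped (escape+) tumors are expected to evolve closer to neutrality
while non-escaped (escape−) tumors show stronger positive selection
concentrated at non-immunogenic hotspot residues. The package quantifies
this with cohort dN/dS contrasts, hotspot site-concentration tests,
signature refitting, VAF clonality contrasts, and survival comparisons
within immune microenvironment categories.

## The dN/dS model

For each gene, every possible single-base substitution of the CDS is
enumerated and classified by translating the mutated codon. Opportunities
are indexed by 192 strand-specific trinucleotide substitution classes
(coding-strand triplet × alternative base); the pyrimidine-collapsed
96-class representation is used only for signature work. Observed counts
per impact class are modeled as independent Poisson draws:

$$ n_{g,k} \sim \mathrm{Poisson}\!\left(t_g \,\omega_k \sum_s r_s
L_{g,s,k}\right), \qquad \omega_{\mathrm{syn}} \equiv 1 . $$

Assumptions worth stating: mutations are independent across sites and
patients given the rates (no overdispersion); one shared rate profile
$r_s$ per cohort; selection acts multiplicatively per impact class, not
per site; indels and splice-site changes are excluded from the likelihood
(they are retained in the catalog for burden and escape classification).
The model is a simplified relative of dNdScv: no negative-binomial
variance component and no gene-level covariates, which is why real-cohort
estimates from the full covariate model are not expected to be reproduced
numerically.

**Context rates.** The default estimator fits $r_s$ by maximum likelihood
from *all* coding SNVs, iterating
$r_s = (n_s^{S} + n_s^{N}) / (L_s^{S} + \hat\omega L_s^{N})$ with the
pooled selection parameter $\hat\omega$ re-estimated each pass, then
anchors the scale so expected synonymous counts equal observed. A
synonymous-only estimator ($r_s = n_s^{S}/L_s^{S}$) is available as
`method = "synonymous"`, but it is noticeably worse at moderate cohort
sizes: classes with little synonymous opportunity get noisy rates, and
that noise propagates multiplicatively into the nonsynonymous
expectations — in 50-gene neutral simulations it inflates pooled ω by
about 2.5% and drags 95% CI coverage from ~95/100 down to ~62/100. The
joint fit removes the bias because nonsynonymous counts stabilize exactly
the classes where synonymous information is scarce. Classes that are
sparse even jointly (n < 1 and L < 100) or empty borrow their
pyrimidine-collapsed partner's estimate.

**Inference.** Gene-level tests of $\omega_k = 1$ are likelihood-ratio
tests with $t_g$ profiled out (χ², 1 df; a 2-df joint test of both impact
classes is also reported). Gene-level 95% intervals are profile
likelihood (deviance cutoff χ²₀.₉₅(1)); they behave correctly at the
boundary ($n_k = 0 \Rightarrow$ lower bound 0). Pooled gene-set ω — the
"global" (all genes) and "driver" (known-driver set) quantities — treats
the set as one super-gene and uses a log-scale Wald interval with
variance $1/n_N + 1/n_S$, which is cheap and accurate at the counts where
pooled estimates are interesting. Driver calling requires ω > 1 *and*
BH-adjusted q < 0.1, with BH applied separately within the missense and
truncating classes; olfactory receptors can be excluded beforehand since
they accumulate passenger mutations at high rates without any driver
role.

**Group contrasts.** Escape− vs escape+ differences in pooled ω are
tested by Wilcoxon–Mann–Whitney on patient-bootstrap replicate vectors
(B ≥ 200), with non-overlap of the percentile intervals reported
alongside; context rates are held at each group's full-cohort fit during
resampling.

## Escape classification

A patient is escape+ iff they carry ≥ 1 SNV in an escape gene with class
in {missense, nonsense, essential splice, other non-silent}; synonymous
hits never trigger. The escape-gene list is an input file (the study this
design follows used 88 genes). Copy-number categories A–F are reported as
overlapping boolean flags because their definitions are non-disjoint
(C contains B, F contains D); there is no category E in the scheme and
the vocabulary is kept as-is. PD-L1 strata are within-cancer-type
quartiles of CD274 expression (bottom 25% low, top 25% high, ties to
mid); within-type was chosen over pooled quartiles to avoid expression
batch artifacts between cancer types, and both strata are emitted
because which of them plays the "escape-like" role in any given contrast
is a user decision.

## The synthetic cohort generator

The generator is first-class, tested code. Its defaults encode the study
conditions the analysis expects:

* **Burden asymmetry** — mean 426 mutations/patient for escape+ vs 95
  for escape− (Poisson per patient), the ~4.5× asymmetry reported for
  real escaped cohorts.
* **Guaranteed escape lesions** — every escape+ patient carries a
  non-silent escape-gene SNV with probability 1 (configurable).
* **Rare chance hits** — background mutations are placed outside escape
  genes; escape-gene background hits instead arrive at a small
  per-patient rate (0.01). In a real exome the 88 escape genes are a tiny
  target, so chance hits are rare (~1% of patients); a desk-scale panel
  over-represents escape genes, and inheriting the panel's proportions
  would make every simulated patient escape+ by accident. Reproducing the
  hit *rate* rather than the panel *share* keeps the classification
  geometry honest.
* **Selection by construction** — each mutation's 96-channel is drawn
  from the group's signature mixture, then placed uniformly among genome
  sites whose reference triplet matches; in driver genes a rejection step
  accepts nonsynonymous opportunities with probability ∝ ω (synonymous
  anchored), making the gene's true dN/dS equal ω by construction.
  `driver_genes_escape_pos` overrides ω for mutations arising in escape+
  patients, which is how escape buffering of driver selection (strong
  selection before escape, weaker after) is simulated.
* **Hotspots** — with probability ρ, a missense mutation in a hotspot
  gene of an escape− patient is relocated to the hotspot codon
  (missense-only semantics, matching IDH1-R132/KRAS-G12-style hotspots).
* **Clonality** — VAFs are Beta-distributed per mutation role; the
  defaults give driver mutations a higher clonal fraction (mean ≈ 0.45)
  than escape (≈ 0.30) or passenger (≈ 0.25) mutations, emulating early
  clonal driver expansions preceding evasion.
* **Survival** — exponential event times with a hazard ratio (default
  2.5) applied only to escape+ patients in immune category C3, uniform
  censoring on (0, horizon); categories are assigned uniformly. No
  mechanism links survival to the mutation catalog beyond escape status.

What the generator does **not** emulate: subclonal structure and copy
number evolution, purity/ploidy distortion of VAFs, inter-patient rate
heterogeneity (overdispersion), gene-level covariates of mutability,
indels, and transcription-strand asymmetries. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness to every feature of real tumor data — in particular, real
cohorts are overdispersed, which the Poisson model does not absorb.

The built-in signature catalog (`default_signature_catalog()`) contains
four synthetic, well-separated columns (uniform; ageing-like NCG-focused
C>T; tobacco-like TCN-focused C>A; T>C) constructed in code; they are
stand-ins, not COSMIC signatures. `opportunity_signature()` builds a
single column proportional to a simulated genome's channel opportunities,
under which placement is uniform per site — the background of choice for
oracle checks, because the naive counting estimator
$(n_N/L_N)/(n_S/L_S)$ is then exactly calibrated.

## Signature refitting

Per-patient or per-cohort 96-channel spectra are refit against a
signature catalog by forward selection with nonnegative weights summing
to at most 1: start from the best single signature, re-optimize weights
coordinate-wise by golden-section search, and add the next signature only
while the relative SSE improvement exceeds `stop_delta` (default 0.01);
weights below `threshold` (default 0.06) are zeroed and the survivors
re-optimized. The defaults mirror the deconstructSigs conventions; both
are configurable. The procedure is deterministic and scale-invariant.
Known limitation: when a signature's true weight is small (~0.1) and the
catalog contains a near-uniform column, the relative-improvement stopping
rule can drop it — visible in simulations as occasional dropped minor
components; the group-comparison χ² machinery is robust to this because a
dropped component shows up as a maximal attribution difference. Group
comparisons attribute mutations per signature (cohort exposure × cohort
total, rounded) and test each signature's 2×2 table by Pearson χ²
(no continuity correction), BH-adjusted across signatures.

## Contrasts and survival

Hotspot concentration compares, per gene, total nonsynonymous mutation
counts vs distinct mutated coding positions between groups (Pearson χ²
without Yates correction — one consistent convention for all 2×2 tests in
the package, and the one the hand oracles in the tests reproduce).
"Unique sites" are distinct genomic positions by default; a codon-level
switch exists because either reading of "site" is defensible. The pooled
(pan-driver) test sums per-gene tables. Downsampling equalizes patients
or mutations by seeded uniform sampling without replacement; hotspot
exclusion removes the three genomic positions of listed codons. The
randomized escape-gene null re-draws k = 88 pseudo-escape genes (100
times by default), marks patients carrying non-silent SNVs in the drawn
set after removing truly escape+ patients, and compares the true escape+
driver-set ω against the null vector with the (r+1)/(B+1) one-sided
empirical p.

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package behind a stable tabular interface; the package's tests
pin them to closed-form and hand-enumerated oracles. Stratified contrasts
skip strata with fewer than 5 patients per arm and BH-adjust across
strata (the correction is reported alongside raw p-values since
per-category tests are a multiple-testing situation whether or not one
chooses to correct).

Immunopeptidome regions arrive as protein coordinates per transcript;
protein position p maps to CDS nucleotides [3p−2, 3p], projected through
the exon structure honoring strand. Filtering can exclude or restrict to
regions (the modes partition the catalog). For region-masked dN/dS the
default also recomputes the opportunity counts over unmasked positions —
masking only the observed mutations while leaving L intact would deflate
ω mechanically; a flag restores the mutations-only behavior for
comparison with analyses that filtered catalogs alone.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; BED export converts to
  0-based half-open at the file boundary only.
* Profile-CI roots are found by bisection-bracketed `uniroot` at
  tolerance 1e−9; LRT statistics are floored at 0.
* Zero observed counts give ω = 0 with a zero lower bound; zero
  synonymous opportunity is an error naming the gene; a catalog with no
  synonymous mutations is an error suggesting pooling or uniform rates.
* Dominant-signature ties break lexicographically and are flagged.
* Fully tied bootstrap replicate vectors give p = 1 rather than NaN.
* All-identical expression values put every patient in the mid stratum
  with a warning.
* Mutation records whose reference allele contradicts the gene model are
  rejected with a reason, never corrected; every input row is accounted
  for as parsed or rejected.

## Problem sizes used by the tests

The acceptance checks run on seeded synthetic cohorts sized for stable
statistics: null calibration uses 100 cohorts of 200 patients × 50 genes
at 100 mutations/patient; driver recovery uses 100 replicates with ~100
expected missense mutations in the ω = 5 gene; the randomization null
uses a 298-gene genome with thirty 6-kb driver genes, 500 patients per
group and ~3 mutations/patient, chosen so that a random 88-gene draw
marks ~25% of patients — the marking fraction of the real cohort — while
the driver set still accumulates countable synonymous mutations. At panel
scale the draw universe excludes the measured driver set: a random 88-gene
draw from ~290 genes overlaps it heavily and the marking mutation itself
would bias the pseudo-cohort ω, an artifact that is negligible when 88
genes are drawn from ~19,500. The survival criterion uses 600 patients
per arm so the C3-confined hazard ratio has power within one of six
categories.

## Known limitations

No overdispersion means gene-level p-values on real (overdispersed)
cohorts would be anticonservative; the package is calibrated under its
stated model. One canonical transcript per gene; no isoform resolution.
Indel selection, de novo signature extraction, HLA typing and
peptide–MHC binding prediction are out of scope. Headline estimates from
full-scale real tumor cohorts depend on the whole exome, a
covariate-bearing rate model and external annotation, and are not
desk-scale reproduction targets; the package's claims are the
property-based ones its tests compute.
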