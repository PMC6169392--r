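---
title: "Predicting deleterious variants with per-codon likelihood ratio tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting deleterious variants with per-codon likelihood ratio tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

An amino acid variant is likely to be deleterious when it disrupts a codon
that has been conserved across species. `codonLRT` quantifies that
constraint with a likelihood ratio test at each codon of interest: the
neutral hypothesis fixes the nonsynonymous/synonymous rate ratio at
$\omega = 1$ ($dN = dS$), the alternative allows a free site-specific
$\omega$ ($dN = \omega\, dS$). Because synonymous changes act as an
internal clock, even closely related homologs are informative, provided
synonymous sites have accumulated change.

Codon evolution follows a Muse–Gaut (MG94) generator over the 61 sense
codons of the universal code: a single-nucleotide change from codon $i$ to
codon $j$ has rate $\pi_{n(j)}$ (the frequency of the target nucleotide,
F1x4), multiplied by $\omega$ when the change is nonsynonymous; changes
needing more than one nucleotide have rate 0. The generator is rescaled so
the expected *synonymous* substitution rate at stationarity equals one,
which puts branch lengths in dS units: the tree length is the gene's
"total dS". We chose the minimal MG94×F1x4 parameterisation — no
transition/transversion parameter, frequencies estimated by nucleotide
counting — because it is identifiable on small per-gene alignments and
carries exactly the $dN = \omega\,dS$ semantics of the test; a
transition/transversion ratio is a natural extension point.

Per gene, `fit_gene()` jointly maximises the likelihood over all branch
lengths and a single gene-wide $\omega$ (the gene-wide $\omega$ absorbs
average constraint so branch lengths are not distorted; whether to instead
fix $\omega = 1$ during branch estimation was genuinely open, and joint
estimation is the more conservative choice because it cannot bias dS
through misfit of dN). Estimated branch lengths above 3 dS are set to 3 —
beyond that, synonymous sites are saturated and long estimates are
spurious — and the reported log-likelihood is re-evaluated at the capped
values so that reported parameters and likelihood stay consistent (the
alternative, reporting the pre-cap likelihood, would pair a likelihood
with parameters that are never used downstream).

`lrt_site()` then holds the capped branch lengths fixed and compares the
site's likelihood at $\omega = 1$ against the maximum over
$\omega \in [10^{-6}, 50]$. The statistic $2\Delta\ell$ is floored at 0
(absorbing optimizer noise) and referred to $\chi^2_1$. The $\chi^2_1$
reference rather than a 50:50 boundary mixture is deliberate: $\omega = 1$
is interior to the alternative's range ($\omega$ may exceed 1), so the
usual boundary correction does not apply. The package's own calibration
check (1,000 simulated neutral sites on the default benchmark tree, run in
the test suite and the acceptance script) shows rejection rates at
$\alpha = 0.05$ within the exact binomial 99% envelope.

P-values are floored at $10^{-16}$ and the site $\hat\omega$ ("constraint")
is capped at 10, so classifier features are bounded.

## Reference masking and alignment features

An unmasked query contributes its own allele as evidence that the
reference amino acid is conserved — a reference bias. `mask_query()`
replaces the entire query sequence with `N`; under the pruning algorithm a
fully missing tip contributes a partial vector of ones, which is exactly
equivalent to pruning the tip from the tree (asserted to $10^{-8}$ in the
tests). The per-gene fit is computed once, on the unmasked alignment, and
reused for both modes.

Instead of the hard site filters used by older formulations of this test
(drop sites with $dN > dS$, with the derived allele elsewhere, or with few
species), the information enters as features of a logistic model: the
$\log_{10}$ LRT p-value, the capped constraint, and the counts `Rn` and
`An` of alignment sequences carrying the reference and alternate amino
acid at the column. In unmasked mode the query row is included in the
counts (it plainly is "observed in the alignment"); masked mode excludes
it. The masked model replaces `(Rn, An)` with `(max(Rn, An), |Rn − An|)`,
which no longer distinguishes reference from alternate — as it must not,
since the masked likelihood cannot see which allele is the reference.

The two shipped coefficient vectors are published full-data fits:

    logit(p) = −2.407 − 0.2139·log10(p) − 0.2056·constraint + 0.07368·Rn − 0.1236·An      (unmasked)
    logit(p) = −2.453 − 0.1904·log10(p) − 0.1459·constraint + 0.2199·max(Rn,An) − 0.2951·|Rn−An|  (masked)

`fit_logistic()` refits custom models by IRLS (tolerance $10^{-8}$), with
a tiny-ridge ($10^{-6}$) fallback under perfect separation, flagged rather
than silent. `cross_validate()` uses stratified folds: a seeded shuffle
within each class followed by round-robin assignment.

## Evaluation machinery

`roc_curve()` sweeps all distinct score thresholds; sensitivity is the
proportion of phenotype-altering (positive) variants called deleterious,
specificity the proportion of negatives called neutral. AUC uses the
rank-statistic form with midpoint tie handling, identical to trapezoidal
integration, and is checked against brute-force pair counting. Confidence
intervals are percentile intervals from 2,000 stratified bootstrap
replicates, each preserving the original class counts; percentile rather
than BCa because the statistic is bounded and the intervals are reported
descriptively. Calling thresholds are chosen at a target specificity
(default 95%), taking the most permissive qualifying threshold so
sensitivity is maximised among qualifying cutpoints.

Frequency-class enrichment uses minor-allele-count classes 1, 2, 3–4,
5–8, >8 (out of 80 chromosomes). Approach disagreement is the pairwise
count of discordant binary calls (pairwise-complete); approaches are
clustered by average linkage (UPGMA) — the linkage is a package choice;
with disagreement counts, average linkage is the natural match to the
distance's additive scale — with node support equal to the fraction of
variant-resampled bootstrap trees containing the same bipartition.
Rows with missing calls are excluded listwise from agreement summaries and
pairwise from distances, with the exclusion counts reported.

For nucleotide-level conservation scores (GERP-style), the per-codon rule
scores a substitution by the position whose single-nucleotide change can
produce the alternate amino acid; when several positions qualify, their
scores are averaged (the symmetric resolution of a rule stated only for
the single-position case), and when none does — a multi-nucleotide change —
the average of the first and second codon positions is used.

## The simulator and what it does (not) show

`simulate_alignment()` evolves codon sites forward on a phylogeny: the
root codon is drawn from the stationary distribution and each branch
applies the exact transition probabilities of the site's $\omega$-specific
model, so stop codons never arise. Defaults mirror the regime the method
is meant for: a 12-taxon pure-birth tree rescaled to total dS 20 (per-gene
alignments in practice typically carry total dS of a few tens), an even
mixture of neutral ($\omega = 1$) and constrained sites
($\omega \sim U(0.01, 0.2)$), uniform nucleotide frequencies, and a 15%
per-codon gap-injection rate in non-query sequences to emulate the sparse
columns that genuinely occur in multi-genome alignments. Benchmark
variants place "deleterious" changes at constrained sites and "neutral"
changes at neutral sites, with alternate amino acids drawn among
single-nucleotide neighbours of the query codon; minor allele counts on 80
chromosomes follow a neutral $1/i$ spectrum for neutral variants and a
singleton-skewed $1/i^2$ spectrum for deleterious ones.

What passing these simulations shows: the likelihood engine, the test's
calibration and power, the masking semantics, and the scoring/evaluation
plumbing are correct under the model's own assumptions. What it does not
show: performance on real data, where alignments carry misalignment,
paralog contamination, ascertainment bias in curated mutant sets,
selection on synonymous sites, and rate variation the model ignores.
Nothing here reproduces published real-data AUCs; those require curated
mutant databases and multi-genome alignments.

## Numerical choices

* Transition probabilities come from a symmetric eigendecomposition of
  the reversible generator ($D Q D^{-1}$ with $D = \mathrm{diag}\sqrt\pi$);
  the same decomposition gives the action of $P(t)$ and $\partial_t P(t)$
  on partial-likelihood matrices without forming $P$.
* Pruning rescales partials per site at every internal node, so deep
  trees cannot underflow.
* `fit_gene()` seeds $\omega$ with a bounded line search, then runs
  L-BFGS-B jointly over log branch lengths and log $\omega$ with analytic
  branch gradients computed from one up/down pass (coordinate ascent was
  tried first and converged impractically slowly on deep trees whose
  likelihood surface is nearly flat along branch/branch directions).
  Bounds: branch lengths $[10^{-8}, 50]$ before capping, $\omega \in
  [10^{-6}, 50]$; up to 3 jittered restarts on non-convergence.
* The site-level $\omega$ search is Brent's method on $\log\omega$ with
  tolerance $10^{-8}$; the null value $\omega = 1$ is evaluated explicitly
  so nesting ($\ell_{alt} \ge \ell_{null}$) holds by construction.
* Stop codons in homolog sequences are set to missing with a warning
  inside `fit_gene()` (a sequencing/annotation artifact should not discard
  a whole sequence); `site_log_likelihood()` on raw data treats them as an
  error naming the offending species and site.
* Degenerate columns (fewer than two resolved sequences) return a flagged
  result with p = 1 rather than an error, so batch runs are not aborted
  by sparse columns.
* A variant whose stated reference amino acid disagrees with the query's
  translated codon is flagged (`ref_mismatch`), not rejected — the
  disagreement usually signals a coordinate or isoform problem the caller
  should inspect.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use: exhaustive-enumeration
likelihood oracles on 3–4 tip trees; 1,000 neutral sites for calibration
and 200 sites at $\omega = 0.02$ for power on the 12-taxon benchmark
tree; a 6-taxon, 500-codon gene for parameter recovery; 200 synthetic
datasets (200+200 variants) for bootstrap coverage; 50+50 variant
benchmarks end-to-end; and $n = 5{,}000$–$10{,}000$ for logistic recovery
and cross-validation stability. These sizes make the whole validation run
in minutes on one CPU while leaving the statistical checks well powered.

## Known limitations

* F1x4 frequencies and a single gap-injection process are crude relative
  to real codon usage and alignment error.
* No among-site rate variation beyond the per-site $\omega$ of the test;
  no transition/transversion parameter.
* The universal genetic code only (the code table is internally
  selectable but no alternative tables ship).
* Branch lengths are estimated once per gene and treated as known by the
  site test; uncertainty in dS is not propagated.
* The ensemble combiner is the logistic model only; other combiners are
  out of scope.
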