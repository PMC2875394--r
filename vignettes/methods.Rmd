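---
title: "Population structure, introgression and admixture mapping with paddymix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure, introgression and admixture mapping with paddymix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`paddymix` analyzes panels of inbred crop accessions genotyped at a sparse
set of biallelic SNPs — the situation of classic rice diversity panels
(hundreds of landraces and cultivars, roughly a thousand array SNPs spread
over twelve chromosomes). This vignette explains the models behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Data model

Accessions are inbred lines, so each contributes a single allele per locus
and calls are stored haploid-coded: 0 (reference), 1 (alternate), `NA`
(missing). Diploid input (VCF, STRUCTURE two-line) is collapsed on read;
heterozygous calls — which for inbred material are mostly genotyping
artifacts or residual heterozygosity — are handled by an explicit policy.
The default, `het_as_missing`, sets them to `NA`; `het_as_major` replaces
them by the marker's major allele. Both are exposed because published
array datasets of this kind do not state their convention, and the choice
is consequential at low marker counts.

QC keeps SNPs with minor allele frequency *strictly* greater than
`maf_min` (default 0.01 — "more than 1%") and missingness at most
`max_missing` (default 0.2). The strict inequality means a MAF of exactly
0.01 is removed.

## Global ancestry: the admixture model by multi-restart EM

Each accession $i$ has ancestry proportions $q_{ik}$ over $K$ clusters
(rows on the simplex) and each cluster has allele frequencies $p_{kl}$.
A haploid call is a Bernoulli draw with success probability
$\sum_k q_{ik} p_{kl}$. The package maximizes this likelihood by EM:
the E-step computes per-call responsibilities
$r_{ilk} \propto q_{ik} p_{kl}^{g}(1-p_{kl})^{1-g}$, the M-step updates
$q_{ik}$ as the mean responsibility over observed loci and $p_{kl}$ as the
responsibility-weighted allele frequency. Missing calls contribute
nothing.

The original analyses this reproduces used MCMC (STRUCTURE) with ten
replicate runs, keeping the maximum-likelihood replicate. We keep the
inferential target — point estimates of $Q$ and $P$ and a best-of-replicates
rule — but make the fit deterministic given a seed: `fit_admixture()` runs
`n_restarts = 10` EM restarts and returns the one with the highest final
log-likelihood. EM never decreases the likelihood, and the returned trace
is checked for that in the tests.

Numerical choices:

* frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ so fixed sites cannot
  produce $\log 0$;
* convergence is declared at an absolute log-likelihood gain below
  `tol = 1e-4`, capped at `max_iter = 2000`;
* restarts differ in the frequency initialization only: each cluster's
  $p_{k\cdot}$ starts at the panel frequencies plus independent
  uniform(-0.2, 0.2) noise, while all $q_{ik}$ start at $1/K$. Starting
  points therefore do not depend on accession order, which makes the whole
  fit exactly equivariant under permuting accessions — a property the test
  suite asserts. (Dirichlet-random $Q$ starts would break that exactness
  while adding little restart diversity: in this model separation is
  driven by the frequency profiles.)

Cluster labels are arbitrary; `align_components()` resolves label
switching against any reference $Q$ (exhaustively over permutations for
$K \le 8$), maximizing summed column correlations.

`classify_accessions()` applies the 80% rule: an accession is assigned to
its majority cluster if $\max_k q_{ik} \ge 0.8$ and is otherwise ADMIXED.
The boundary is inclusive because only "less than 80%" counts as admixed.

`K` itself is not chosen automatically: as in the source protocol, the
user inspects fits across `K` (the log-likelihood is reported per fit).

## Local ancestry: the linkage HMM

Conditional on a fitted $Q$ and $P$ (an empirical-Bayes simplification of
the joint linkage model), the cluster of origin along a chromosome is a
hidden Markov chain: initial distribution $q_{i\cdot}$; between adjacent
SNPs at distance $d$ bp the state is kept with probability $e^{-rd}$ and
otherwise redrawn from $q_{i\cdot}$; emissions are
$p_{kl}^{g}(1-p_{kl})^{1-g}$, and missing calls emit 1 for every state.
Chromosomes are independent. `posterior_ancestry()` computes exact
posteriors by a scaled forward–backward pass — per-site normalization is
mandatory at $L \approx 10^3$ to avoid underflow — and the forward and
backward total likelihoods are compared in the tests (they agree to
$10^{-8}$; posteriors match brute-force path enumeration to $10^{-10}$ on
small instances).

The per-bp switch intensity $r$ is not reported by the studies this
mirrors, so `fit_switch_rate()` selects it by maximum marginal likelihood
on a log-spaced grid (default $10^{-9}$–$10^{-6.5}$). With ~260 kb marker
spacing, $r = 5\times 10^{-8}$ corresponds to a ~1.3% switch probability
between neighbors.

Two refinements matter when scanning *assigned* accessions for
introgression:

* `q_floor` (default 0.01 in the pipeline) floors the HMM's mixing
  distribution. The fitted global ancestry of a typical assigned
  accession is numerically one-hot, which would make every other cluster
  unreachable for the chain regardless of the evidence; the floor plays
  the role of the positive Dirichlet mass a Bayesian fit keeps on every
  component.
* `refine_iter` runs linkage-EM sweeps that re-estimate the cluster
  allele frequencies from the local posteriors (and optionally the
  mixing distributions) before the final pass. This corrects a
  structural bias of the two-stage fit: when a fraction $c$ of a
  recipient subpopulation shares the same introgressed block — the
  signature of artificial selection — the linkage-free global EM
  estimates the recipient's frequencies *at the block* as the mixture
  $(1-c)p_{rec} + c\,p_{don}$, capping the per-SNP donor evidence at
  $\log(1/c)$ and hiding exactly the shared segments of interest. The
  sweeps let the block migrate to the donor's frequency profile (each
  sweep increases the linkage-model likelihood; in the recovery checks
  the carrier donor-posterior at a planted block rises from ~0.01 to
  ~0.9). A joint MCMC over local ancestry and frequencies resolves the
  same identifiability problem by sampling.

**Introgression** is defined relative to the carrier's assignment: donor
ancestry at a locus in an accession assigned to a different subpopulation.
Two summaries are produced:

* `mean_introgression()` — the per-SNP mean donor component over all
  accessions assigned to a recipient subpopulation, with the
  top-5-percent background cutoff computed per recipient/donor pair as the
  95th *nearest-rank* percentile of the per-SNP means. The nearest-rank
  (ceiling) convention is fixed deliberately: with 95 values at 0.01 and 5
  at 0.50, the cutoff is the 95th smallest, 0.01, so the five elevated
  SNPs sit above background.
* `call_segments()` — per-accession maximal runs of consecutive SNPs
  (within a chromosome) whose donor posterior exceeds `post_min = 0.5`
  (majority ancestry), emitted only when the run spans at least
  `min_snps = 5` SNPs. The five-SNP rule comes from the source protocol;
  the posterior cutoff is ours, since only the run-length rule was stated.

## Divergence: unbiased F_ST

`fst_per_snp()` implements the Weir mean-square estimator that corrects
for unequal sample sizes: with $m$ groups of $n_i$ haploid calls and group
frequencies $p_i$,
$MSG = \sum n_i p_i(1-p_i) / \sum(n_i-1)$,
$MSP = \sum n_i(p_i-\bar p)^2/(m-1)$,
$n_c = (\sum n_i - \sum n_i^2/\sum n_i)/(m-1)$, and
$\hat F_{ST} = (MSP - MSG)/(MSP + (n_c-1)MSG)$, with negative estimates
set to 0 (they have no biological meaning). Inbred accessions contribute
one allele each, so $n_i$ counts non-missing calls. A SNP needs at least
two groups with two or more calls; otherwise it is NA and counted.

Aggregation uses the ratio of sums of the per-SNP numerators and
denominators (Weir's recommendation); the mean of per-SNP values is also
reported because published tables do not always say which was used.
`fst_windows()` tiles chromosomes into half-open physical windows
(default 100 kb) — a SNP at exactly 100,000 bp falls in the second window
— and applies the same ratio-of-sums within each window.

Calibration: across Balding–Nichols replicates at $F \in \{0.1, 0.3,
0.5\}$ (2 × 50 haploids, 1,000 SNPs), the mean genome-wide estimate is
within ±0.02 of the generating value (acceptance suite).

## Trees and kinship

The allele-sharing distance between two accessions is the proportion of
mismatching calls over SNPs observed in both (pairwise deletion); a pair
sharing no SNP is an error rather than a silent 0. Neighbor joining is
delegated to `ape::nj` after validation; negative branch-length estimates
are clamped to zero with the signed amount transferred to the sibling
edge, preserving the path length through the pair. Newick output orders
children by the lexicographically smallest leaf in each subtree, so
equivalent trees serialize identically. Kinship for the mixed model is
allele-sharing similarity, $1 - d$, with unit diagonal.

## Mapping

Two complementary strategies, mirroring the amylose/grain-length analyses
of sparse-marker rice panels:

* **Admixture mapping** (`admixture_map()`): within the ADMIXED class,
  the trait is regressed by OLS on the donor-cluster local-ancestry
  posterior at each SNP (two-sided t-test on the slope). Ancestry blocks
  extend over neighboring SNPs, so power does not require LD between the
  causal variant and any single marker — but the causal locus must have
  divergent allele frequencies between the donor and recipient ancestries
  to be visible at all, and resolution is block-scale, not SNP-scale.
  Because the same global ancestry underlies every SNP of an accession,
  p-values are strongly correlated along the genome; they are uniform
  under the null *marginally* (per SNP across traits), which is what the
  tests check.
* **Mixed-model association** (`mixed_model_assoc()`): $y = \mu +
  \mathrm{SNP}\,\beta + Q\gamma + u + e$ with $u \sim N(0, \sigma_g^2
  \mathrm{Kin})$. The variance ratio $\delta = \sigma_e^2/\sigma_g^2$ is
  estimated once by REML on the null model via a single spectral
  decomposition of the kinship matrix and reused for all SNPs (the
  standard approximation for panel-scale scans; the alternative of
  re-estimating per SNP changes little and costs a full eigenproblem per
  marker). Per-SNP inference is generalized least squares with a Wald
  t-test; one $Q$ column is dropped against the intercept; missing calls
  are mean-imputed so the rotation can be shared, with the observed-call
  count reported per SNP. With identity kinship the model collapses to
  OLS exactly (tested to $10^{-8}$).

`bonferroni()` divides $\alpha$ (default 0.05) by the number of non-NA
tests and flags $p \le \alpha/m$.

## The synthetic-panel generator

`simulate_panel()` produces panels with the statistical structure the
analyses assume, so every stage is testable without external downloads:

* **Subpopulation frequencies** follow the Balding–Nichols model: an
  ancestral frequency $p$ uniform on [0.05, 0.95] per locus, then
  $p_{kl} \sim \mathrm{Beta}(p\frac{1-F_k}{F_k}, (1-p)\frac{1-F_k}{F_k})$
  independently per subpopulation. The default five-group divergence
  vector (indica 0.18, aus 0.25, tropical japonica 0.35, Group V 0.45,
  temperate japonica 0.62) was calibrated once, by least squares against
  the published pairwise F_ST table for the five rice subpopulations, so
  realized pairwise Weir estimates span roughly 0.23–0.52 (the published
  range is 0.23–0.53). A purely additive model cannot reproduce every
  cell of that table (aus–indica 0.23 vs aus–temperate 0.53 is
  non-additive), so the span, not the individual cells, is the target.
* **Accessions**: pure lines get one-hot ancestry; admixed lines draw
  proportions from a Dirichlet(0.5) over 2–3 randomly chosen components
  (mimicking the mostly two-way admixture seen in such panels) and a
  Markov mosaic along each chromosome with per-bp switch intensity
  `switch_rate` (default $5 \times 10^{-8}$, about one switch per 20 Mb —
  a handful of outcrossing generations) whose stationary distribution is
  the accession's own $Q$ row.
* **Introgression events** are shared identical-by-state blocks: the same
  donor interval overwrites local ancestry in a random `carrier_fraction`
  of the recipient subpopulation, emulating segments fixed by artificial
  selection and carried by many accessions.
* **Phenotypes**: $y_i = \sum_c \mathrm{effect}_c\, g_{ic} + e_i$, with
  noise variance set so the genetic variance fraction equals `h2`;
  missing causal calls contribute the panel mean.

What the generator does **not** emulate: linkage disequilibrium beyond
the ancestry mosaic (within-subpopulation LD is absent), coalescent noise
and recombination-history structure, selection dynamics, genotyping error
beyond uniform missingness, and multi-allelic or structural variation.
Passing tests on these panels therefore demonstrate correctness of the
estimators and the pipeline under the assumed generative model — they do
not guarantee the biological findings of any particular real panel.

## Problem sizes used in the checks

The test and acceptance runs use study-shaped but desk-scale designs,
chosen once: the five-group recovery panel uses 230 pure + 20 admixed
accessions at 1,300 SNPs (the real panels this mirrors are ~395 × 1,311),
fitted with four EM restarts at a 1e-2 log-likelihood tolerance — past
that point further iterations change the ancestry estimates only in the
third decimal, so the full ten-restart/1e-4 default is reserved for real
analyses;
F_ST calibration uses 2 × 50 haploids × 1,000 SNPs per replicate;
introgression recovery plants a 25-SNP donor block (a multi-Mb selected
segment) at the most donor/recipient-differentiated window, carried by
20 of 100 recipients at indica/temperate-japonica-level divergence;
mapping power panels simulate 220 Dirichlet(3) admixtures so that about
100 accessions land in the ADMIXED class at the 80% rule, with a causal
locus at maximal frequency divergence explaining ~35% of trait variance. Full-size reproduction of published numbers requires the
released rice dataset, which the I/O layer reads directly
(`read_panel()`, then `fst_pairwise()`, `classify_accessions()` at the
80% rule, and `mean_introgression()` reproduce the published summaries'
definitions).

## Segment-call resolution

The segment caller emits runs of SNPs whose donor posterior exceeds 0.5.
Its boundary resolution is limited by the flanking markers' information:
after a true block ends, the posterior stays above 0.5 until the
accumulated flanking log-likelihood (~1 nat per SNP at study-level
divergence) overcomes the state-exit cost (~4 nats at
$r = 2\times10^{-7}$), so calls systematically overhang the true edges
by roughly 3–4 SNPs (~1 Mb at array spacing). In the planted-block
benchmark this bounds cell-level precision near 0.8 even when the true
generating parameters are supplied, while cell-level sensitivity is
~0.99; raising $r$ sharpens boundaries (precision ~0.93) but destroys
the linkage pooling that detection of weaker blocks relies on
(sensitivity can fall below 0.4). A MAP-path (Viterbi) caller sits on
the same trade-off curve. Users should treat call boundaries as
approximate to the marker spacing scale, exactly as for any sparse-array
local-ancestry method.

## Known limitations

* The admixture fit is maximum-likelihood, not Bayesian: no posterior
  uncertainty on $Q$, and no $\alpha$/prior updating as in MCMC
  implementations.
* Local ancestry conditions on point estimates of $Q$ and $P$; with weak
  divergence ($F_{ST} \lesssim 0.1$) posteriors are diffuse and segment
  calls unreliable.
* Physical distances only (bp, not cM); the switch rate absorbs the
  genome-average recombination rate.
* One variance-component pair in the mixed model; no dominance or
  epistasis; Bonferroni is the only multiplicity correction, matching the
  protocol it mirrors.
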