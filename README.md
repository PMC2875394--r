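# paddymix

Genome-wide population structure, introgression and trait mapping for
panels of **inbred accessions** genotyped at sparse biallelic SNPs — the
situation of rice (*Oryza sativa*) diversity panels: a few hundred
landraces and cultivars, ~1,300 array SNPs spread over 12 chromosomes,
five deeply diverged subpopulations (*indica*, *aus*, *temperate
japonica*, *tropical japonica*, Group V) connected by historical
admixture and selection-driven introgression.

The package provides, as composable R functions plus an end-to-end
pipeline:

* **Admixture model fitting** — maximum-likelihood estimation of global
  ancestry proportions `Q` (n × K) and subpopulation allele frequencies
  `P` (K × L) for haploid-coded calls, by multi-restart EM
  (`fit_admixture`), with the 80% rule for subpopulation assignment
  (`classify_accessions`) and label-switching alignment
  (`align_components`).
* **Local ancestry** — a linkage HMM over each chromosome (hidden state =
  cluster of origin; stay probability `exp(-r d)` between SNPs `d` bp
  apart; emissions from `P`), solved exactly by scaled forward–backward
  (`posterior_ancestry`), with ML selection of the switch rate
  (`fit_switch_rate`), subpopulation-mean introgression profiles with a
  top-5% background cutoff (`mean_introgression`) and ≥5-SNP
  introgression segment calls (`call_segments`).
* **Divergence** — Weir's unbiased F_ST correcting for unequal sample
  sizes, `F̂ = (MSP − MSG) / (MSP + (n_c − 1) MSG)` with negative values
  clamped to 0; per SNP, genome-wide (ratio of sums), pairwise between
  groups, and in 100-kb physical windows (`fst_per_snp`, `fst_overall`,
  `fst_pairwise`, `fst_windows`).
* **Phylogeny** — allele-sharing distances (proportion of mismatching
  calls over shared SNPs) and neighbor-joining trees with deterministic
  Newick output (`allele_sharing_distance`, `nj_tree`, `write_newick`).
* **Mapping** — admixture mapping (trait regressed on the donor-ancestry
  component within the admixed class, `admixture_map`) and mixed-model
  association (`y = μ + SNP·β + Q·γ + u + e`, `u ~ N(0, σ²_g · Kin)`,
  REML by spectral decomposition, `mixed_model_assoc`), both with
  Bonferroni thresholds (`bonferroni`).
* **Synthetic panels** — a Balding–Nichols generator
  (`simulate_panel`, `simulate_phenotype`) producing genotypes, ancestry
  truth sets, shared introgression blocks and heritable phenotypes with
  the structure the analyses assume, so the whole stack is testable
  offline.
* **I/O** — TSV matrix (+ map/metadata sidecars), VCF v4.2 and STRUCTURE
  formats (`read_panel`, `write_panel`), strict-MAF QC (`apply_qc`).

## Worked example

```r
library(paddymix)

# a rice-like panel: 3 subpopulations, 12 admixed accessions, and a
# shared introgression block from temperate japonica into indica
cfg <- simulation_config(
  K = 3, F_k = c(indica = 0.25, temperate_japonica = 0.5,
                 tropical_japonica = 0.35),
  n_pure_per_pop = 30, n_admixed = 12,
  chrom_layout = rice_chrom_layout(360, 6),
  introgression_events = list(list(donor = "temperate_japonica",
                                   recipient = "indica", chrom = 2,
                                   start_bp = 260000 * 20,
                                   end_bp = 260000 * 29,
                                   carrier_fraction = 0.5)),
  seed = 11)
sim <- simulate_panel(cfg)
panel <- apply_qc(sim$panel)
panel
#> genotype_panel: 102 accessions x 337 SNPs on 6 chromosome(s)
#>   missing calls: 0.00%
#>   assignments: UNASSIGNED=102

fit <- fit_admixture(panel, K = 3, n_restarts = 5, seed = 1)
fit
#> admixture_fit: K = 3 , 102 accessions, 337 SNPs
#>   loglik -13071.281 after 647 iterations (restart 4 of 5)

labels <- classify_accessions(fit, threshold = 0.80)
table(labels)
#> ADMIXED    pop1    pop2    pop3
#>       8      32      32      30

round(fst_pairwise(panel, labels), 2)
#>      pop1 pop2 pop3
#> pop1   NA 0.32 0.27
#> pop2 0.32   NA 0.38
#> pop3 0.27 0.38   NA
```

90 of 102 accessions are assigned to a subpopulation (maximum ancestry ≥
80%), 8 are admixed (4 of the 12 simulated admixtures happen to exceed
80% in one component), and pairwise divergence reflects the generating
Balding–Nichols parameters. Local ancestry then localizes the planted
donor block in a carrier:

```r
rate <- fit_switch_rate(panel, fit)   # ML grid selection: 3.2e-07 per bp
la <- posterior_ancestry(panel, fit, as.numeric(rate))
donor <- names(which.max(colMeans(
  fit$Q[sim$truth$pop_true == "temperate_japonica", , drop = FALSE])))
carrier <- sim$truth$introgression_carriers[[1]][1]
call_segments(la, panel$markers, carrier, donor)
#>   accession_id donor_pop chrom start_bp  end_bp n_snps mean_posterior
#> 1       acc002      pop2     2  2600000 5200000     10      0.5786299
#> 2       acc002      pop2     4  5460000 6760000      6      0.7487910
```

The caller reports maximal runs of ≥5 consecutive SNPs whose donor
posterior exceeds 0.5. At this deliberately low recipient divergence
(F = 0.25) the posterior is diffuse, so boundaries are approximate and a
spurious segment can appear — the methods vignette quantifies recovery at
study-like divergence (sensitivity and precision ≥ 0.9 for 10-SNP blocks
carried by 20 accessions).

The whole analysis can also be driven by a YAML config:

```r
run_pipeline(parse_config("config.yaml"))   # QC -> structure -> tree ->
                                            # F_ST -> HMM -> introgression -> mapping
```

writing `Q.tsv`, `P.tsv`, `assignments.tsv`, `nj_tree.nwk`,
`fst_pairwise.tsv`, `fst_windows.tsv`, `introgression_calls.tsv`/`.bed`,
per-trait `mapping_*.tsv` and a `manifest.json` with hashes and the seed.
A 60-accession synthetic demo panel ships in `inst/extdata/`.

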