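# aviqtl

QTL and expression-QTL mapping for two-line advanced intercross lines
(AILs), written for genetical-genomics studies of the kind used to
dissect bone metabolism in wild x domestic chicken crosses: quantitative
traits and transcript abundances are mapped jointly in a segregating
population, trait loci and expression loci are intersected, and the
genes whose expression is associated with the trait become candidate
quantitative trait genes.

It is aimed at quantitative geneticists analysing experimental crosses
(or building simulation studies of them) who need the full chain —
genotype probabilities, genome scans, empirical thresholds, support
intervals, cis/trans eQTL, candidate prioritisation, hotspot detection —
in one place, with every stochastic step seeded and every threshold
recorded.

## The statistics at the core

* **Genotype probabilities.** Genotypes along a chromosome form a Markov
  chain with transition probabilities from the Haldane map function
  r = (1 - e^(-2d/100))/2; forward-backward smoothing of the intercross
  HMM gives P(AA), P(AB), P(BB) at markers and pseudomarkers, from which
  the Haley-Knott regressors x = P(BB) - P(AA) and z = P(AB) derive.
* **Haley-Knott regression.** At each position, least squares
  y ~ covariates + x + z, scored as
  LOD = (n/2) log10(RSS0/RSS1) against the covariates-only null;
  pairwise scans add full-vs-additive two-locus models with
  lod_int = lod_full - lod_add for digenic epistasis.
* **Empirical thresholds.** Phenotype scans: permute (trait, covariates)
  rows jointly against genotypes, keep the genome-wide maximum LOD,
  take the 95th percentile. eQTL scans: per iteration permute the
  expression-to-genotype individual mapping, subsample probesets, scan
  each (within its 100 cM local window for cis, genome-wide for trans),
  save the subsample maximum; the 95th percentile is the threshold.
* **Support intervals.** 1.8-LOD drop around each peak, expanded to the
  closest flanking markers (approximate 95% intervals).
* **Candidates.** Overlap trait-QTL and cis-eQTL intervals (Mb), regress
  trait on expression with body weight (and, where used for the QTL, egg
  production) as covariates, Bonferroni-correct by the number of
  uncorrelated cis-eQTL genes in the interval (connected components of
  the correlation-link graph).
* **Hotspots.** Exact sweep-line coverage of trans-eQTL intervals versus
  the 95th percentile of the maximum coverage of the same interval
  lengths placed uniformly on a concatenated genome axis.

A full account of the models, defaults and limitations is in
`vignettes/aviqtl-methods.Rmd`.

## Worked example

Simulate a small study (five 90 cM chromosomes, 150 birds, one additive
QTL for a bone trait at chr1:40 cM plus a cis-eQTL there), then scan:

```r
library(aviqtl)
cfg <- sim_config(n_markers = 50, n_chromosomes = 5, chrom_length_cM = 90,
                  n_individuals_final = 150, pop_per_generation = 80,
                  n_probesets = 40, n_expr_individuals = 60,
                  qtl_spec = data.frame(chr = "1", pos_cM = 40, a = 0.8,
                                        d = 0, trait = "bone"),
                  eqtl_spec = data.frame(probeset = "ps0001", chr = "1",
                                         pos_cM = 40, effect = 1.2,
                                         cis = TRUE),
                  seed = 1)
study <- simulate_study(cfg)
study$cross
#> cross_ail: 150 individuals, 50 markers on 5 chromosomes
#> traits:    bone
#> covariates: sex, batch, body_weight, eggs

probs <- calc_genoprob(study$cross, step_cM = 1)
thr <- permutation_threshold(probs, study$cross, "bone",
                             c("sex", "batch", "body_weight"),
                             n_perm = 1000, seed = 1)
round(thr, 2)
#> [1] 3.49

sc <- scanone(probs, study$cross, "bone", c("sex", "batch", "body_weight"))
(pk <- max_scan(sc))
#>    chr pos_cM     name is_marker      lod
#> 43   1     42 loc_1_42     FALSE 11.38382

as.data.frame(lod_support_interval(sc, pk, 1.8, study$cross$map))[
  , c("chr", "start", "end", "peak_lod")]
#>   chr start end peak_lod
#> 1   1    30  50 11.38382
```

Reading: the genome-wide 5% significance threshold from 1000
permutations is LOD 3.49; the scan peaks at LOD 11.4 at 42 cM on
chromosome 1 (2 cM from the simulated locus — within one marker
spacing), and the marker-expanded 1.8-LOD support interval [30, 50] cM
covers the true position. `run_full(run_config(...))` chains the same
steps with eQTL mapping, candidate calling and hotspot detection, and
writes per-stage tables plus `summary.json` and `run_metadata.json`.

A command-line interface covers the same stages
(`inst/cli/aviqtl simulate|scanone|permtest|eqtl|candidates|hotspots|run`).

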