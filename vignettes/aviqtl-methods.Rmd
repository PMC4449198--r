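---
title: "Methods: QTL and eQTL mapping in an advanced intercross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL and eQTL mapping in an advanced intercross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviqtl)
```

## What this package does

`aviqtl` implements a genetical-genomics workflow for two-line advanced
intercross lines (AILs), of the kind used to map bone and production
traits in wild x domestic chicken crosses: single- and two-locus
Haley-Knott genome scans for quantitative traits, expression-QTL (eQTL)
mapping with a local/distal (cis/trans) classification, permutation-based
genome-wide significance thresholds, LOD-drop support intervals, a
two-phase candidate-gene procedure that intersects trait-QTL and cis-eQTL
support intervals and then tests expression-trait association, and
trans-eQTL hotspot detection against a uniform-placement coverage null.
A synthetic-data generator reproduces the statistical structure of such a
study so the entire pipeline is exercised and tested without any external
data.

## Genotype probabilities

Genome scans need the conditional distribution of the unobserved genotype
at every evaluated position. For a two-line intercross the genotype at a
locus is AA, AB or BB with prior (1/4, 1/2, 1/4), and genotypes along a
chromosome form a Markov chain whose transition matrix over a distance
$d$ is built from the Haldane recombination fraction
$r = \tfrac{1}{2}(1 - e^{-2d/100})$ (d in cM; no crossover interference).
`calc_genoprob()` runs forward-backward smoothing over each chromosome,
marginalising missing genotypes and supporting a symmetric genotyping
error rate in the emissions (default 0). Posterior triples are computed
at all markers and at pseudomarkers every `step_cM` (default 1 cM).
The Haley-Knott regressors are the additive dosage
$x = P(BB) - P(AA) \in [-1, 1]$ and the dominance regressor $z = P(AB)$.

The HMM is the F2 intercross model even though the data are F8: this
mirrors how such crosses are analysed in practice with standard cross
software. The extra intermating generations expand the effective map;
`map_expand()` provides the standard constant-factor approximation when
map distances were estimated in an earlier generation. Both analysis
paths (raw and expanded map) are available because which one a given
dataset needs depends on how its map was estimated.

## Single-locus scans and thresholds

`scanone()` fits, at every position, least squares
$y \sim \text{covariates} + x + z$ and reports
$\mathrm{LOD} = \tfrac{n}{2}\log_{10}(RSS_0 / RSS_1)$ against the
covariates-only null. Individuals with a missing trait value or
incomplete covariates are removed listwise, and $n$ is the count actually
used. Degenerate fits are guarded: the residual sum of squares is floored
at $10^{-15} RSS_0$, so a noise-free trait yields a large, finite, capped
LOD and a `perfect_fit` flag rather than an overflow. Ties at the maximum
break to the lowest position on the earliest chromosome, so peak
reporting is deterministic.

Significance is empirical: `permutation_threshold()` permutes the
phenotype rows *jointly with the covariate rows* against the genotypes —
preserving both the trait-covariate relationship and the genotype
correlation structure — rescans, and takes the $(1-\alpha)$ quantile of
the genome-wide maximum LOD. The default $\alpha = 0.05$ and
`n_perm = 1000` follow field convention; the calibration suite verifies
the realised genome-wide type-I error lies in [0.02, 0.09] at nominal
0.05.

Population structure from the breeding design can confound an AIL scan;
`pca_covariates()` supplies the first $k$ genotype principal components
(markers coded -1/0/1, mean-imputed) as covariates. The number of PCs is
not prescribed; components are orthogonal so adding more never biases the
fixed effects, only spends degrees of freedom.

For female traits, egg production competes with bone for calcium, so a
fecundity covariate is offered: `select_egg_covariate()` includes the egg
column if and only if it is itself associated with the trait
(p < 0.05 in a regression that also carries body weight), and logs the
decision. The function accepts either an egg-count or total-egg-mass
column — sources differ on which was recorded — and the decision is
audit-logged either way.

## Two-locus scans and multiple-QTL models

`scantwo()` fits, for every pair of distinct positions, a full model
(both loci's $x, z$ terms plus all four pairwise products) and an
additive model, giving `lod_full`, `lod_add` and the interaction score
`lod_int = lod_full - lod_add`. Same-position pairs are excluded. The
interaction score gets its own permutation threshold
(`scantwo_permutation_threshold()`), since no analytic null is assumed.

`forward_select()` builds a multiple-QTL model: repeatedly scan
conditional on the already-selected loci (their dosages enter as
covariates) and add the best locus while its conditional LOD exceeds the
single-locus threshold; then screen the selected loci's pairs for
interactions above the interaction threshold. The stopping rule is the
conditional-LOD threshold itself — no information-criterion penalty —
and every step is logged. Variance explained is reported as the
difference in $R^2$ (x100) between the full model and the covariates-only
model, with per-term drop-one contributions; the stored LOD reproduces on
refit to 1e-6 by construction (`fit_qtl_model()`).

## Support intervals

`lod_support_interval()` returns the smallest contiguous region around a
peak where the LOD stays within `drop` (default 1.8, the conventional
approximate-95% choice for an intercross of this design) of the peak,
then expands each endpoint outward to the closest flanking marker, so
interval ends are marker positions. Intervals hitting a chromosome end
before dropping are flagged `truncated`; flat curves return the whole
chromosome flagged `degenerate`. Coverage of the true locus by the
1.8-LOD interval is verified empirically (about 95%, tested at >= 90%
over 200 simulated studies).

## eQTL mapping

Each probeset's expression is scanned genome-wide like any trait
(by default without covariates — whether batch or weight entered the
original expression scans is not documented, so none is the default and
any covariate set can be passed). Classification is geometric:

* the **local window** is the 100 cM interval centred on the probe's
  genetic position, each endpoint moved outward to the nearest marker at
  least 50 cM away (`build_local_window()`), truncated and flagged at
  chromosome ends;
* a **cis** record is emitted when the LOD passes the cis threshold
  anywhere inside the window; a **trans** record when it passes the
  (higher) trans threshold outside it.

Probe positions are usually physical; `coordinate_convert()` maps Mb to
cM (and back) by piecewise-linear interpolation between markers carrying
both coordinates, extrapolating terminal segments with the nearest
slope and flagging extrapolated values. Probesets on unmapped scaffolds
get trans-only scans, with a notice.

Thresholds use a dual permutation scheme
(`eqtl_permutation_threshold()`): per iteration, the expression-to-
genotype individual mapping is permuted (permutation, not bootstrap —
resampling with replacement would break the permutation-null logic), a
subsample of probesets (100 at full scale) is drawn, each is scanned
(window-restricted for the cis scope, genome-wide for trans), and the
maximum LOD over the subsample is saved; the threshold is the 95th
percentile of the saved maxima over the iterations (10000 at full scale;
tests use scaled-down iteration counts and note it). The maximum is taken
over the whole subsample, which is the stricter, family-wise reading of
the procedure; a per-probeset reading is possible and matters for power
(see Limitations).

## Candidate quantitative-trait genes

`call_candidates()` implements the two-phase procedure. Phase 1:
intersect trait-QTL and cis-eQTL 1.8-LOD intervals (`overlap_pairs()`),
in physical Mb after conversion, with touching endpoints counting as
overlap (closed intervals; configurable). Phase 2: for each overlapping
pair, regress the trait on the probeset's expression with body weight as
covariate (plus the egg covariate when the QTL in question was detected
with it), and take the two-sided t-test p-value on the expression
coefficient (`association_test()`; Pearson-scale least squares by
default, a residualised-trait mode is provided for plotting parity).

The Bonferroni denominator `m` is the number of *uncorrelated* cis-eQTL
genes in the QTL interval (`count_uncorrelated()`): genes whose
expression vectors show a significant pairwise correlation (test
p <= 0.05) are linked, and `m` counts connected components of the link
graph. Component counting is the default because it always yields
m >= 1 and agrees with the plain count in both extremes (all genes
independent; all copies of one signal); the alternative literal reading
("genes uncorrelated with every other gene") is available as
`mode = "pairwise"`. A caveat follows from linearity of expectation:
with $g$ genes in an interval the expected number of chance passes after
correction is $g\alpha/m$ whatever the dependence, so the calibration
bound (mean chance passes <= alpha x m) is guaranteed only when clusters
are genuinely redundant or genes mostly uncorrelated (g close to m or
g <= m^2). Weakly-but-significantly correlated gene sets undercount the
effective number of tests under component counting — a known limitation
of this style of correction, inherited deliberately.

`merge_regions()` unions overlapping or touching intervals per
chromosome into maximal disjoint regions; it provides the "N separate
genomic regions" style counts and is oracle-tested against an
independent sweep-line implementation.

## Trans-eQTL hotspots

`coverage()` computes the exact sweep-line depth profile of eQTL support
intervals over per-chromosome axes (the integral of depth equals total
interval length, asserted in tests). The null (`null_max_coverage()`)
re-places the *observed* interval lengths uniformly on one concatenated
axis of total genome length — chromosome boundaries are ignored in the
null, by design, while observed coverage respects them — and records the
maximum depth per iteration (1000 by default). `call_hotspots()` takes
the 95th-percentile order statistic of the null maxima as the depth
threshold and calls maximal observed regions with depth strictly above
it, annotating calls with overlapping trait-QTL labels when provided.
Preserving observed lengths in the null is the default (a fixed-length
variant would understate clustering of long intervals); a per-chromosome
null is available as an option through per-chromosome genome vectors.

## The synthetic generator: what it emulates, and what it does not

`simulate_ail()` generates a two-line F8 AIL under the line-cross
idealisation: founders fixed for alternate alleles at every marker, F1
fully heterozygous, then random mating (distinct dams and sires) with
about one hundred individuals per intermating generation, expanding to
the mapped generation. Defaults state the emulated design: 652 markers,
generation 8, 100 per generation, 456 mapped individuals, expression in
125 females. Map geometry defaults to 20 autosomes of 150 cM at
0.33 Mb/cM — a round chicken-like genome (~1 Gb over ~3000 cM); the
real genome's heterogeneous chromosome sizes are not reproduced because
nothing downstream depends on them. Meioses follow Haldane's model (no
interference), matching the analysis HMM. Covariates are balanced sex,
five hatch batches, sex-shifted Gaussian body weight (females ~N(1500,
150^2) g, males ~N(2000, 200^2) g at cull age), and total egg mass for
females (~N(350, 80^2) g, floored at 0). Missingness defaults to 2%
per cell in genotypes and phenotypes.

Traits are intercept + sex + batch + body-weight + additive/dominance
terms ($a x + d z$, $x \in \{-1,0,1\}$) + digenic products
($\gamma x_1 x_2$) + expression-mediated terms + Gaussian noise.
Expression is baseline + cis effects at the probe's own locus + shared
trans effects from hotspot regulator loci + noise; mediated effects are
true trait <- expression <- genotype chains, so the candidate procedure
has genuine positives to recover. `additive_effect_for_r2()` converts a
target variance fraction into an effect size at the realised dosage
variance, so simulation studies can state effects the way power
calculations do.

Not emulated: the real pedigree (a fixed set of F7 pairings rather than
random mating), crossover interference, sex chromosomes, microarray
noise structure (probe GC effects, batch intensity drift), and medullary
bone physiology. A green test therefore establishes that the
*statistical machinery* behaves as specified under the stated design —
not that any biological conclusion about a real cross is reproduced.

## Numerical and policy choices

* Haldane map function only; closed-form oracles in the tests depend on it.
* Genotyping-error rate defaults to 0 (pure Haley-Knott); nonzero rates
  enter the HMM emissions only.
* RSS floored at $10^{-15} RSS_0$; LOD clipped at 0 from below.
* Probability triples renormalised to sum to 1 within 1e-9.
* Quantiles: phenotype thresholds use the default empirical quantile;
  hotspot depth thresholds use the order statistic (type 1), since depth
  is integer; "above the threshold" is strict.
* Peak ties break leftmost; interval endpoints expand to markers.
* All randomness flows from explicit seeds; a run's config + seed
  reproduce its outputs byte-identically (asserted in tests).

## Known limitations

* Under the family-wise (subsample-max) eQTL threshold, a cis effect of
  15% expression variance at n = 125 is detected in about two thirds of
  simulated studies, not >= 80%: the acceptance suite keeps that
  criterion at its stated bound and it fails honestly. Under the
  per-probeset threshold reading the same effect is detected in ~87% of
  studies.
* Component-counted `m` can under-correct when genes are weakly but
  significantly correlated (see above).
* Recomputation of the source study's published interval counts needs
  its deposited supplementary tables, which cannot be bundled; the
  acceptance test documents the expected file layout and stays red until
  they are supplied locally.
* No mixed-model or FDR-based eQTL calling, no EM interval mapping, no
  X-chromosome handling, no pedigree-exact AIL probabilities.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_markers = 50, n_chromosomes = 5, chrom_length_cM = 90,
                  n_individuals_final = 150, n_probesets = 40,
                  qtl_spec = data.frame(chr = "1", pos_cM = 40, a = 0.8,
                                        d = 0, trait = "bone"),
                  eqtl_spec = data.frame(probeset = "ps0001", chr = "1",
                                         pos_cM = 40, effect = 1.2,
                                         cis = TRUE),
                  seed = 1)
study <- simulate_study(cfg)
run_full(run_config(study$cross, study$expr, out_dir = "run1",
                    n_perm = 200, eqtl_n_iter = 200, eqtl_subsample = 20,
                    seed = 1))
```

The run directory then holds `qtl.tsv`, `eqtl.tsv`, `candidates.tsv`,
`hotspots.tsv` (when trans records exist), `summary.json` and
`run_metadata.json` with every threshold recorded before use.
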