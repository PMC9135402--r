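---
title: "Genotypic fitness networks: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotypic fitness networks: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitnet)
```

## The problem

Adaptive radiations pose a classic question about the topography of the
fitness landscape: are the genotypes of derived specialist species reachable
from a generalist ancestor through a sequence of single mutational steps that
never decreases fitness, and does the answer depend on where the adaptive
alleles came from (standing genetic variation, adaptive introgression, or de
novo mutation)?

`fitnet` implements an empirical approach to this question built around
hybrid field experiments. Hybrids between a generalist and its specialist
relatives scatter broadly across genotype space; measuring their fitness in
the wild attaches an empirical fitness value to each observed multilocus
genotype. The package estimates *genotypic fitness networks* from such data
and quantifies the accessibility and ruggedness of adaptive walks on them.

## The network model

Genotypes at a chosen set of biallelic SNPs are encoded as unphased diploid
dosages (0 = homozygous reference, 1 = heterozygote, 2 = homozygous
alternate). A *node* of the network is a distinct multilocus dosage vector
("haplotype" in the loose, unphased sense) observed in at least one
individual; individuals sharing the vector are the node's carriers. A
*mutational step* changes one allele copy at one locus, so the distance
between two haplotypes is the Manhattan distance of their dosage vectors
(0↔2 at a locus counts two steps). Edges join nodes within
`max_edge_distance` steps: 1 for all accessibility analyses, up to 5 for
visualisation.

Node fitness is the arithmetic mean (configurable to median) of a fitness
measure over the node's *hybrid* carriers. Three measures are supported:

* **survival** — a 0/1 recovery indicator from the field exposure;
* **growth** — proportional increase in standard length,
  $(\mathrm{SL}_{final}-\mathrm{SL}_{initial})/\mathrm{SL}_{initial}$;
* **composite** — survival × growth: growth for survivors, 0 for
  non-survivors. This is the default, being the most information-rich.

Negative growth (shrinkage) is retained by default; composite fitness can be
floored at zero with `floor_composite_at_zero` but the monotone-walk logic
uses raw values. Nodes carried only by parental (wild-caught) individuals
have *undefined* fitness: fitness is an attribute of experimental hybrids.

## Accessibility and ruggedness

An *accessible path* between two nodes is a sequence of observed,
unit-step-adjacent haplotypes whose fitness increases strictly at every step.
Three conventions deserve note:

* **Strictness.** "No fitter neighbour" and "monotonically increasing" are
  read strictly: an equal-fitness neighbour neither disqualifies a peak nor
  supports a step. Strictness makes the directed traversal graph acyclic, so
  path counts are computed exactly by dynamic programming; ties passable
  (`strict_increase = FALSE`) would create cycles and is supported only via
  bounded exhaustive enumeration on small networks.
* **Undefined endpoints.** Interior nodes of a path must carry hybrid
  fitness — a walk can only be validated through genotypes whose fitness was
  measured. The two endpoint nodes are typically parental haplotypes and may
  lack fitness; they then impose no constraint at their own step. Undefined
  nodes other than the endpoints never enter a path.
* **Path counts are exact integers.** Counts grow combinatorially; the
  dynamic programme accumulates in doubles while they remain exactly
  representable and switches to an add-only arbitrary-precision integer
  representation beyond that, reporting both a numeric and a decimal-string
  count.

A *peak* is a fitness-defined node with no unit-step neighbour of strictly
greater defined fitness; peak count measures landscape ruggedness. Per
replicate network the package reports: node and edge counts, the number of
accessible paths between a randomly drawn generalist and specialist
individual (scaled by node count, since larger networks mechanically hold
more paths), the shortest accessible path length in nodes, the peak count,
the accessible paths from the two endpoint nodes to peaks (scaled), and the
minimum accessible distance in steps from either endpoint to a peak.
Path length between the species pair is reported in nodes; distance to peaks
in steps (nodes − 1) — both conventions appear in the field's figures, so
both are documented here once. Replicates whose two endpoints collapse onto
one node, or whose endpoint individual was dropped for missing genotypes,
are flagged degenerate and redrawn; undefined shortest lengths are excluded
from means rather than imputed, with their frequency reported.

## The resampling engines

Two replication schemes mirror the field workflow:

* `run_accessibility_ensemble()` — draws `snps_per_network` (default 5)
  loci from the focal specialist's adaptive pool, `n_replicates` (default
  5000) times, with rejection sampling enforcing at least one SNP per
  requested source of variation when sources are mixed; per replicate it
  draws one generalist and one specialist individual uniformly from the
  sequenced parentals, builds the unit-step network over all samples, and
  emits the summary row. Per-replicate RNG streams derive from the master
  seed, so ensembles are reproducible and parallelisable.
* `interspecies_distances()` — draws panels of `k = 10` loci 100 times and
  averages pairwise mutational distances within the six species-pair
  classes, reporting means, medians, and `SE = sd/\sqrt{n}` over replicates
  plus pairwise Tukey HSD with an FDR-adjusted column. Means are used for
  headline comparisons; medians are also emitted.

Ensembles are compared with a logistic regression of ensemble membership on
each summary statistic: the exponentiated slope is an odds ratio (reference
ensemble coded 0; OR > 1 means the other ensemble's statistic is larger),
with 95% Wald CIs (profile-likelihood optional — the default matches R's
`confint.default` convention), likelihood-ratio significance, and
Benjamini–Hochberg FDR across the comparisons of one analysis block.
Complete or quasi-separation — easy to trigger when one ensemble has
near-constant statistics — is detected and flagged instead of reporting a
spurious CI. Ruggedness–accessibility coupling is tested with
`glm(min_dist_to_peak ~ n_peaks, family = poisson)`. Multi-ensemble
contrasts use ANOVA plus Kruskal–Wallis omnibus tests with Dunn-type rank
post hoc comparisons (BH-adjusted); the rank tests matter because the
summary statistics are strongly skewed.

## The synthetic hybrid swarm

`simulate_study()` generates data with the statistical structure the
analysis assumes, so every stage is testable without the original field
data. Defaults emulate the study conditions: 17 generalist, 27 molluscivore
and 25 scale-eater parentals; 139 hybrids pooled from two experimental
cohorts (an F2/backcross cohort and an F4–F5 cohort from crosses among all
three species); adaptive loci labelled by source with the scale-eater mix
(92% standing variation, 6% introgression, 2% de novo); and ~60% hybrid
survival.

Design choices worth making explicit:

* **Standing variation segregates in the generalist** (`sgv_generalist_freq`,
  default 0.15). That is what "standing" means — the allele predates the
  sweep — and it is what the observed within-generalist and
  generalist-to-specialist mutational distances imply. Introgressed and de
  novo alleles are absent from generalists by default. The `fst` locus
  annotation stores the specialist-pair Hudson F_ST, the contrast behind the
  sweep-based locus filter, which is 1 by construction at fixed differences.
* **Loci are unlinked**; the adaptive SNPs of interest span many scaffolds
  and the accessibility machinery is linkage-agnostic.
* **Fitness models.** `additive` (weighted dosage sum; a smooth, single-peak
  landscape), `NK` (per-locus contribution tables indexed by the locus's own
  state and `K` random partner loci; ruggedness grows with `K`), and
  `two_peak` (a bimodal mixture over the additive score). Note that `K = 0`
  is per-locus independent but *not* single-peaked in general: a locus whose
  heterozygote contribution is its own minimum contributes two
  coordinate-local maxima, so the full-space peak count is the product of
  per-locus local-maxima counts — the test suite asserts exactly this.
* **Measurement model.** Survival is Bernoulli with logit
  `qlogis(survival_rate) + survival_slope · z(w)`; survivor growth is linear
  in scaled latent fitness plus Gaussian noise. The field-realistic defaults
  (`survival_slope = 1`, `growth_noise_sd = 0.05`) make composite fitness
  strongly zero-inflated and node fitness noisy, as in real enclosure data.
* **Ground truth.** For up to 8 loci, `ground_truth()` enumerates all
  `3^m` genotypes and computes exact peak sets and exact monotone path
  counts, providing the oracle for everything downstream.

## What the generator does and does not emulate

The generator reproduces the features the method relies on: three divergent
parental gene pools, Mendelian hybrid swarms covering the genotype cube,
fitness tied to genotype through a configurable landscape, and
source-labelled loci. It does not attempt demographic realism (no
coalescent history, no linkage, no selection during the crosses) and the
source labels are behaviourally meaningful only through the landscape roles
a configuration assigns them. Passing tests therefore demonstrate that the
*estimator machinery* is correct and that known landscape contrasts are
recovered under controlled conditions — not that any particular empirical
system behaves this way.

Two regimes are used deliberately in the validation experiments:

* **Study emulation** (139 hybrids, field-level noise) for the input
  contract, distance analyses and ensemble mechanics. At this density and
  noise level accessible generalist-to-specialist walks are rare (a few
  percent of replicate networks), and observed peak counts are dominated by
  the sparsity of the sampled networks — many nodes simply have few
  observed neighbours.
* **Landscape recovery** (500 hybrids, 8 loci, `survival_slope = 10`,
  `growth_noise_sd = 0.005`) for experiments whose purpose is to detect a
  known landscape difference. The denser swarm and low measurement noise
  let the observed networks reflect the generating landscape: smooth
  (additive) pools then show far more accessible walks and significantly
  fewer peaks than rugged (NK, K = 4) pools, in the expected directions and
  robustly across seeds. At study-scale density the same contrast is
  diluted — partly because 5-SNP panels drawn from a larger NK system
  average epistatic partners out of the panel — which is itself an
  instructive caveat for empirical work.

The ruggedness regression is fit within one study's replicate ensemble
(peaks vary across SNP panels; dataset-level idiosyncrasies would otherwise
confound a pooled cross-dataset fit); its slope is reliably negative, with
magnitude depending on density.

## Numerical and degenerate-input conventions

* MAF and call-rate filters use inclusive thresholds (ties kept), with MAF
  computed from allele counts over non-missing calls; the depth filter
  applies only when the VCF carries DP, otherwise it is skipped with a
  warning.
* Multiallelic records and indels are rejected at read time with a count.
* Individuals with missing calls at a replicate's loci are dropped for that
  replicate (never imputed) and logged; endpoints dropped this way trigger a
  redraw.
* Equal-fitness edges are excluded from directed traversal but retained in
  exports.
* Constant statistics, empty groups, fewer than two distinct peak counts, or
  all-degenerate ensembles raise errors rather than returning silent
  defaults; separation in the logistic fits is flagged.

## Problem sizes

The shipped tests and the reproduction script run at desk scale: ensembles
of 150–600 replicate networks, 1000-network oracle-equivalence sweeps at
≤ 4 loci, 10,000-draw peak-expectation checks, and 200-repetition coverage
experiments at 5000 observations per group. The study-scale default of 5000
replicates per ensemble remains the package default and runs in minutes.

## Limitations

* Accessibility is purely topographic: no fixation probabilities, waiting
  times, or population-genetic dynamics on the network.
* Node fitness is a point estimate; carrier counts per node are small in
  sparse regions and the uncertainty is not propagated into path counts.
* The "haplotypes" are unphased multilocus genotype vectors; phase-aware
  analyses are out of scope.
* LD pruning, variant calling, and sweep detection are upstream of the
  package: the locus annotation table is taken as given.
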