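---
title: "Methods: mitochondrial selection signatures and life-form evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial selection signatures and life-form evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collemsel)
```

## The analysis

collemsel implements a comparative pipeline that asks whether shifts in a
discrete ecological trait — the springtail (Collembola) life-form
classification: aquatic, myrmecophilous, euedaphic, hemiedaphic,
epiedaphic — are associated with altered selection on mitochondrial
protein-coding genes (PCGs). The inputs are a rooted, dated (ultrametric)
phylogeny with branch durations in Ma, a taxon-to-life-form table, and
in-frame codon alignments of the 13 mitochondrial PCGs under the
invertebrate mitochondrial genetic code (NCBI table 5: TGA = Trp,
AGA/AGG = Ser, ATA = Met; stops TAA/TAG, 62 sense codons).

The pipeline has five stages:

1. **Ancestral life-form reconstruction** — Fitch/Hartigan parsimony,
   Mk maximum likelihood (Mk1 one-rate and AsymmMk all-rates-different,
   compared by a likelihood-ratio test), and a Bayesian MCMC
   reconstruction at a focal clade. Homoplasy per state is scored by the
   retention index RI = (g − s)/(g − r).
2. **Ancestral codon reconstruction and change counting** — marginal
   ML codon states at internal nodes under a GY94 M0 fit, then
   Nei–Gojobori-style pathway counting of synonymous (dS) and
   nonsynonymous (dN) changes per branch and gene.
3. **Site-model selection tests** — GY94 site models M0, M1a, M2a with
   the M1a-vs-M2a likelihood-ratio test and a Naive Empirical Bayes
   site posterior for the positive-selection class (sites called at
   posterior ≥ 0.95).
4. **Comparative statistics** — per-branch nonsynonymous proportions
   P = dN/(dN + dS), shift-versus-sister clade comparisons with paired
   t tests, ordinary least-squares regressions of P on branch age with a
   group-equality F test, and selection-direction classification from
   branch-level ω.
5. **Physicochemical screening** — a TreeSAAP-style scan assigning every
   inferred amino-acid replacement to one of eight magnitude categories
   per property and flagging radical (category 7–8) excesses by binomial
   z-score against a neutral expectation, whole-gene and in 15-codon
   sliding windows.

A Gillespie simulator (birth–death trees, Mk traits, GY94 codon
evolution with per-branch ω multipliers and site-class mixtures)
generates data with known truth, so every stage is calibrated by
simulation rather than against external data.

## Models and assumptions

### Discrete trait models

The Mk1 model places a single rate q on every ordered state pair; AsymmMk
gives every ordered pair its own rate — k(k − 1) parameters for k states,
the natural generalisation of the classic two-state asymmetric model,
with LRT degrees of freedom k(k − 1) − 1. Likelihoods use Felsenstein
pruning with transition matrices from an eigendecomposition of Q (with a
scaling-and-squaring fallback for numerically defective rate settings).
The root prior is uniform over states for parsimony-style and ML
reconstructions (the Mesquite convention), configurable to the
stationary distribution.

The Bayesian reconstruction samples the all-rates model under a
hierarchical prior — each rate exponential with mean m, m itself uniform
on (0, 30) — as a fixed-model stand-in for reversible-jump averaging
over rate-class partitions. Two choices matter and are deliberate:

* **Tree scaling.** Branch durations are rescaled so the mean branch
  length is 0.1 before sampling (the convention of trait-MCMC tools).
  On a tree measured in hundreds of Ma, rates from an Exp(m), m ≤ 30
  prior would saturate every branch and the sampler could never reach
  the data-informative regime; the rescaling is a pure
  reparameterisation of rate × time and leaves state probabilities
  unchanged.
* **Root prior.** The Bayesian module defaults to the stationary
  distribution of the sampled rate matrix. Under an all-rates model with
  a uniform root prior, regimes with a very high return rate into the
  majority state have near-maximal likelihood yet carry no information
  about the root, and they dominate the posterior; the stationary prior
  treats the root as a draw from the process itself, which is the
  coherent choice for a stationary Markov chain.

Samples whose state probabilities are essentially flat (maximum
probability ≤ 1/k + 0.02, i.e. "0.2 for each state" with five states)
are discarded as equivocal; a state is called supported only when its
averaged probability exceeds 0.7. Effective sample sizes use the
integrated autocorrelation time with Geyer-style truncation, and chains
with ESS < 200 are flagged. The desk-scale defaults are 3 chains of
30,000 iterations with 25% burn-in; analyses of real datasets should
scale these up and check the ESS flag.

### Retention index conventions

For a state carried by n1 of n tips, g = min(n1, n − n1) is the maximum
number of binary Fitch steps any tree could require, r = 1 when both
presence and absence occur, and s is the observed step count. For an
autapomorphic state g = s = r = 1 and the ratio is 0/0; it is reported
as 0 with `defined = FALSE`, matching the convention of reporting 0 for
single-taxon life forms.

### Codon models and counting

The GY94 rate matrix sets q_ij = pi_j · kappa^[transition] ·
omega^[nonsynonymous] for single-nucleotide codon changes, zero
otherwise, normalised so the mixture-averaged rate is one expected
substitution per codon per unit branch length. Codon frequencies default
to F3×4 (per-position nucleotide frequencies, renormalised over sense
codons), with an empirical-codon option. Site models are fit with
clock-proportional branch lengths: the dated tree's durations times a
single free scale parameter rho (substitutions per codon per Ma). This
keeps the parameter count fixed as trees grow, matches the simulator
(which is also clock-scaled), and reflects the pipeline's use of a dated
tree throughout; it is a stricter assumption than free per-branch
lengths, and strong rate variation among lineages will be absorbed into
counts rather than branch lengths.

Counting follows the Nei–Gojobori logic on reconstructed ancestral
sequences: per-codon site opportunities split each position into the
synonymous fraction of its non-stop single-nucleotide neighbours, and
changes between codons are averaged over all minimal stop-avoiding
pathways (fractional counts are therefore possible). No multiple-hit
correction is applied to branch counts — branch-wise divergences after
reconstruction are small, but this biases ω̂ downward at high
divergence, which is why the ω recovery bands below widen with true ω.
The branch statistic ω = (dN/N)/(dS/S) is undefined (reported `NA`, not
infinite) when dS = 0. A branch is classified neutral when
|ω − 1| ≤ 0.05 (configurable); the tolerance is our reading of taxa
"satisfying the assumptions of neutrality" without a stated cut-off.

The per-site positive-selection posterior is Naive Empirical Bayes at
the MLEs; full Bayes Empirical Bayes integration over parameter
uncertainty is out of scope, and the 0.95 call threshold is applied to
the NEB posterior.

### Shift-versus-sister comparisons

A shift event is a maximal subtree reconstructed in a derived state
whose parent retains the ancestral state. The shift side comprises every
terminal and internal branch on the paths from the member taxa back to
(but excluding) the divergence node; the sister side is built
symmetrically from the divergence node's other child lineages,
restricted to branches reconstructed in the ancestral state, so nested
second shifts are excluded. Branch proportions are averaged with equal
weight per branch (a per-path option exists); each event yields
complementary percentage shares, and a paired t test compares sides
across events. The per-branch age covariate is the parent-node age,
which for terminal branches of an ultrametric tree equals the branch
length.

The gene/complex report statistic is the printed standardisation:
total nonsynonymous changes / (gene size × number of branches) × 100,
with gene size in codons (nucleotide lengths can be supplied instead);
complex-level values sum counts and sizes before applying the formula.

### Physicochemical categories

For each of 20 amino-acid properties, all single-nucleotide
nonsynonymous sense-codon changes are enumerated, and the range
[0, max |Δproperty|] is divided into eight equal-width bins (1 most
conservative, 8 most radical). The neutral expectation weights each
change by source-codon frequency divided by its number of non-stop
neighbours; the default is the unweighted (uniform-frequency)
enumeration, with observed codon frequencies as an option recorded in
outputs. Observed replacements inherit the pathway averaging of the
counting stage, so counts may be fractional. z-scores are binomial per
category; |z| > 3.09 (the one-sided p < 0.001 normal quantile) flags
significance, and when categories 7 and 8 are both significant the
category-8 z is reported. Property values are taken at runtime from the
published AAindex compilation shipped with seqinr, under a documented
name-to-accession map (e.g. equilibrium constant (ionisation of COOH) →
FASG760105; solvent accessible reduction ratio → PONP800107; buriedness
→ CHOC760103). Multiple testing across properties × categories ×
windows is reported but not corrected, following the source tool's
convention; a Bonferroni column is emitted for transparency.

Note that the neutral expectation ignores transition/transversion bias:
under strong bias the realised category distribution shifts even without
selection, a limitation shared with the original tool. The calibration
study below therefore simulates with kappa = 1, isolating the binomial
machinery from that bias.

## The simulator and what it does not emulate

Trees are birth–death (ape's constant-rate sampler) conditioned on tip
count and rescaled to a chosen root age. Traits evolve by Gillespie
jumps under an Mk rate matrix. Codon alignments evolve site by site
under GY94 with events drawn explicitly, so per-branch synonymous and
nonsynonymous event counts are recorded truth, not estimates; the root
sequence is drawn from the target frequencies (the stationary law, so no
burn-in is needed). Shift scenarios multiply ω on designated clades'
branches and assign those clades derived states.

The simulator is deliberately simpler than real mitogenomes: no indels,
no among-site rate variation other than ω classes, no base-composition
heterogeneity across lineages, no saturation-level divergence, and a
strict clock. Passing calibrations therefore demonstrate that the
pipeline's statistics behave as designed under their own model
assumptions; they do not certify behaviour under model violation
(saturation, compositional drift) that real deep-time mitogenome data
can show.

## Numerical choices

* Codon pruning runs in compiled code with per-node rescaling;
  the reversible GY94 matrix is exponentiated through a symmetric
  eigendecomposition after a pi^(1/2) similarity transform.
* Site-model optimisation is bounded multistart L-BFGS-B on transformed
  parameters (kappa in [0.1, 50], omega in [1e-4, 20]); nested models
  warm-start from the simpler fit, and M2a adds a deterministic start
  probing a clearly positive omega2. The default stopping rule resolves
  the log-likelihood to roughly 1e-6, which is far inside the
  statistical uncertainty; the (p2, omega2) ridge near p2 = 0 is flat,
  and polishing it further multiplies runtime without changing any
  conclusion.
* Mk1 rates at the optimiser's lower bound (constant characters) are
  flagged, not clamped silently.
* Parsimony ties are broken toward a supplied preferred state when it is
  optimal, else toward the first state in the state-set order, with root
  ties reported.

## Calibration studies shipped as tests

The test suite runs, at sizes chosen for a single desk CPU:

* Oracle equivalence — Fitch vs exhaustive labeling (≤ 6 tips, 500
  random cases), Mk pruning vs brute-force state sums (≤ 5 tips, 500
  cases, 1e-9), codon pruning vs explicit enumeration (3 taxa, 50
  cases, 1e-8), and MCMC vs exact 2-D quadrature of the
  hierarchical-prior posterior on an 8-tip tree.
* ω recovery by counting at true ω of 0.2, 1 and 2 (500 codons,
  8 taxa): acceptance bands 0.10–0.35, 0.5–1.75 and 1.0–3.5 — the same
  multiplicative width at every ω, anchored at the stated band for 0.2,
  with the downward counting bias at high ω in mind.
* M1a-vs-M2a type-I error at 200 null replicates (5 taxa, 60 codons)
  and power at the M2a alternative (p2 = 0.15, omega2 = 4, 300 codons,
  8 taxa, 100 replicates). The type-I band assumes the chi-squared
  df = 2 reference is exact; because the null puts p2 on the boundary,
  that reference is conservative and rejection rates fall below nominal
  — the suite reports the observed rate honestly rather than retuning
  the band.
* Shift pipeline calibration: null scenarios (ω multiplier 1.0, 16
  tips, 4 shift events, 2 genes × 120 codons) for the paired-test
  rejection rate, and power scenarios (multiplier 5.0) for the
  shift-side share exceeding 50%.
* Physicochemical calibration at ω = 1 (200 gene replicates, kappa = 1)
  for the radical-call rate, and the fixture reconstruction of the
  collembolan ancestor by all three ASR methods.

## Known limitations

* Counting-based branch ω has no multiple-hit correction and is biased
  downward as divergence grows.
* The regressions of P on age are ordinary least squares, not
  phylogenetically corrected (no PGLS), mirroring the GLM-style analysis
  this pipeline reproduces; branches are not independent data points and
  the equality test should be read descriptively.
* The Bayesian module is a fixed all-rates model with a hierarchical
  prior, not reversible-jump model averaging.
* M7/M8/M8a beta site models, branch-site models and synonymous-rate
  variation are out of scope; topology is always an input, never
  inferred.
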