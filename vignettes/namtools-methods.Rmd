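---
title: "Methods behind namtools: simulating and analysing NAM RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind namtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namtools)
```

## The design being modelled

A nested association mapping (NAM) population crosses one recurrent
founder (RF) — typically an elite, well-characterized line — to a panel of
diverse alternative founders, and advances each F1 by single-seed descent
(SSD) to recombinant inbred lines (RILs). The families share half their
ancestry, which lets a single analysis borrow strength across crosses:
segregation distortion can be scanned per family on a common coordinate
frame, linkage disequilibrium (LD) decays much faster in the pooled
population than in any single biparental family, and a kinship
mixed-model association scan can use all RILs at once.

`namtools` implements the full chain — genotype QC, marker placement,
distortion scanning, LD decay, diversity structure, trial BLUPs and
mixed-model GWAS — and, crucially, a forward simulator of the breeding
design itself. The simulator is first-class, tested code: it is the source
of ground truth against which every downstream stage is validated.

## The simulator

### Genome and founders

A `genome_model` couples physical (bp) and genetic (cM) coordinates for a
set of marker loci. When only bp positions are given, cM positions are
interpolated piecewise-linearly between anchor points; with no interior
anchors this is proportional scaling, the simplest defensible choice when
no family-specific genetic map exists. `wheat_genome()` provides a
tetraploid-wheat-like default: 14 chromosomes (1A–7B), 590–830 Mb and
160–180 cM each, with ~12 000 markers placed uniformly — the scale of a
mid-density wheat array.

Founders are fully homozygous, so one haplotype each suffices. The RF
draws allele B with probability 1/2 per marker; every other founder
differs from the RF at a marker with probability `divergence`
(default 0.6), independently across markers. One consequence worth
knowing: the differentiation between two *alternative* founders is
2d(1 − d), maximal at d = 0.5 and vanishing as d → 1, where all
alternative founders collapse onto the complement of the RF. Family-level
structure (monophyletic NJ clusters, PC separation) therefore requires
intermediate divergence *and* many independently segregating segments —
which is why the structure-oriented tests use 10–14 chromosomes rather
than two. Founders are typed as modern varieties (MV: the RF and, by
default, one alternative founder) or farmer varieties (FV), a distinction
used only by the ascertainment-bias layer.

### Meiosis and single-seed descent

Meiosis follows the Haldane model: per chromosome the crossover count is
Poisson with mean L/100 for genetic length L in cM, breakpoints are
uniform on the genetic map, and there is no interference. This is the
simplest model consistent with standard map-function conventions; the
implied recombinant fraction between loci d cM apart,
r = ½(1 − e^(−2d/100)), is checked directly in the test suite at
d ∈ {1, 10, 50, 100}.

SSD is literal: each RIL line advances exactly one selfed offspring per
generation (default 5 selfings, giving F6 from the F1). Residual
heterozygosity (1/2)^k and allele-frequency drift are emergent, not
imposed. Viability selection is rejection sampling within a line: an
offspring whose genotype at the selected locus falls in the targeted
class (RF homozygote, heterozygote or alternative homozygote, defined by
founder origin) is discarded with probability *s* and a sibling seed is
drawn — a new meiosis from the same parent — up to a retry cap (default
100), after which the line dies; a family with no survivors raises an
error naming the locus. Because rejection resamples from the *same
parent*, the implied Markov chain on genotype classes renormalizes the
selfing transition row-wise per parent, not population-wise; the test
oracle implements exactly this chain, and it caught a real bug during
development (re-testing already-accepted offspring, which silently
inflates the effective selection pressure for s < 1).

All randomness flows from a single master seed through deterministic
substreams per family and layer, so a fixed seed reproduces the entire
dataset byte for byte.

### Array artifacts

`inject_array_artifacts()` degrades clean calls in three layers, each
logged: (i) ascertainment masking — a fraction (default 0.15) of
FV-private polymorphic markers (markers whose non-RF allele is carried
only by FV founders) is collapsed to the RF homozygote everywhere, as if
the probe never detected the exotic allele; (ii) heterozygote miscalls —
true homozygotes flipped to AB (default 0.5%); (iii) missingness (default
2%). The defaults reflect a high-quality SNP array on inbred material.
What the generator does *not* emulate: genotyping batch effects, marker-
or sample-specific error rates, segmental aneuploidy, outcrossing,
pedigree errors beyond the relabelling used to test the misassignment
rule, and sequence-level variation (markers are abstract biallelic loci).
Passing tests therefore validate the *methods* under a clean generative
model, not the idiosyncrasies of any particular array.

### Field trials

`simulate_trial()` mirrors the analysis model exactly: a plot value is
μ + genotype effect + location effect + G×L draw + replication + column-
within-replication + row-within-replication + residual, with every
genotype appearing once per location × replication on a randomized
rows × columns grid. Genotype and location effects are inputs; the rest
are independent Gaussians with stated variances. This is deliberately the
same model the REML fit assumes — parameter-recovery tests then measure
estimation error, not model mismatch.

## Analysis methods and their numerical choices

**QC thresholds** are applied strictly as stated (call rate < 0.8
removed, heterozygosity > 0.2 removed; boundary values retained), samples
before markers, with marker rates computed on retained samples.
Heterozygosity is always a fraction of *non-missing* calls, so
missingness is not conflated with heterozygosity. The sequential pass is
idempotent away from the boundaries; at the generator's artifact rates a
second pass removes nothing, which the suite asserts.

**Distortion scan.** Per informative marker (both founders typed,
polymorphic between them, RIL heterozygotes set as failed) a 1-df
chi-squared test against 50:50; per 5-Mb bin the *mean* of p-values is
−log-transformed and signed by the bin's majority direction weighted by
informative calls. Signing per-bin rather than per-marker avoids
averaging quantities of mixed sign. Bins need at least three markers
("more than two"). The threshold is −log(α/m) with m the population
marker count — a conservative choice, since bins, not markers, are
reported. Natural log is the default base: it is the only base under
which the conventional printed thresholds for ~12k markers at α = 0.05
(≈ 12.4) are self-consistent; the base is configurable.

**LD.** r² is the squared Pearson correlation of allele dosages over
pairwise-complete samples — for near-inbred RILs genotype ≈ haplotype, so
this composite r² is essentially the haplotype r². Pairs with fewer than
10 complete samples, or involving a monomorphic marker, are missing, not
zero. The Hill–Weir expectation is fitted with one free coefficient
(C = a·d) and n fixed at the sample size; the 1-D least-squares problem
is solved by golden-section search on log10(a) over a ∈ [1e−15, 10] with
a local refinement (tolerance 1e−12 on log10 a), which recovers noise-free
coefficients to well within 1%. Flat r² above the C = 0 plateau returns
the a = 0 boundary with a warning. The decay distance solves
E[r²](d) = 0.2 by doubling-bracket plus bisection to 0.5 bp; a curve that
never crosses returns Inf with a warning, and a threshold at or above the
d = 0 value returns 0.

**Neighbour joining** is the Saitou–Nei algorithm with a deterministic
tie-break (among minimal-Q pairs, join the pair whose clusters carry the
lexicographically smallest leaf labels), negative branch lengths clamped
to zero with a message, and the final three-way join resolved by the
closed-form three-point formulas. It reproduces reference topologies
(Robinson–Foulds distance 0 against `ape::nj`) on random additive
matrices and recovers additive trees exactly, branch lengths included.
`ape` remains the container and serialization layer; it is never the NJ
implementation, so the cross-check stays independent.

**PCA** mean-imputes missing dosages per marker (deterministic and
exactly neutral after centering), then uses the SVD of the centered
matrix; explained fractions are squared singular values over total
centered variance.

**Trial model.** REML via lme4 with location fixed and genotype, G×L,
replication, column-in-rep and row-in-rep random. Genotype is treated as
random — BLUPs are undefined for fixed effects, and prediction across a
population of RILs is exactly the random-effects use case. The spatial
terms are included only when row/column identifiers are present; without
them, balanced designs admit the closed-form shrinkage
σ²G/(σ²G + σ²ε/r) of genotype means, which the suite verifies against
the fitted components. Heritability is on the entry-mean basis,
h² = σ²G / (σ²G + σ²GL/l + σ²ε/(lr)), with l and r taken from the
realized design.

**Association scan.** Kinship is the centered-dosage cross-product scaled
by marker count, with a 1e−6 diagonal ridge guaranteeing positive
semi-definiteness. The null variance components are estimated once by
maximizing the REML log-likelihood profiled over δ = σ²e/σ²g on the
spectral decomposition of K, searching log δ ∈ [−12, 12] (tolerance
1e−8); each marker is then a GLS fit with intercept + 3 PC covariates
(computed from the same genotype matrix as K) and a Wald t test with
residual degrees of freedom. With K = I and no covariates this reduces
*exactly* to OLS — the suite requires agreement to 1e−8. Markers under
1% MAF are skipped and logged. A single-pass scan was chosen over
iterative pseudo-QTN schemes: it is transparent, exactly testable against
OLS, and sufficient for the power regimes of interest (a 3-unit allele
effect at MAF 0.5 and n = 1200 is mapped in ≥ 90% of replicates).

## Problem sizes

The suite and acceptance script run at desk scale, chosen once as
realistic-but-small: 2–14 chromosomes of 50–60 Mb with 20–120 markers
each; families of 100–500 RILs (200 for the distortion-power replicates,
12 × 100 = 1200 for the GWAS power study); 200 replicate families for the
distortion type-I/power checks, 50 phenotype replicates for QTN power, 20
for variance-component recovery. The full default genome
(`wheat_genome()`, 12k markers, 12 × 100 RILs) simulates in a few minutes
and is exercised by the command-line wrapper rather than the test suite.

## Known limitations

- Haldane meiosis ignores crossover interference and chromatid
  interference; map distances are exact but crossover spacing is not.
- The founder model is exchangeable given `divergence`; it does not
  encode geographic or pedigree structure among founders, so
  founder-level phylogenies carry no deep structure to recover.
- Selection acts on single loci with genotype-class viabilities; no
  epistatic or gametic selection.
- The composite r² assumes near-complete inbreeding; it is not a phased
  haplotype r² and will differ in early generations.
- The scan tests one marker at a time; closely linked QTNs are reported
  as one association region, and effect estimates at linked markers are
  attenuated by incomplete LD with the causal locus.
- `fit_trial_model` assumes the randomization structure it is given;
  strongly unbalanced designs fall back on lme4's general machinery and
  may fit singular variance components (reported via `converged` and
  lme4 messages).
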