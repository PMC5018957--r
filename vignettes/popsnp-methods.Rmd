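---
title: "Methods: consensus SNP discovery and population genomics in popsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SNP discovery and population genomics in popsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popsnp implements the downstream half of a transcriptome- (or exome-)
based variant-discovery study on a panel of inbred plant accessions: from
per-caller variant files to a reliable per-accession SNP set, to a
panel-wide bi-allelic genotype matrix, to the population-genomic summaries
built on it. This vignette explains the models and procedures, the
parameters that matter, the synthetic-data generator the test suite is
built on, and the design decisions taken where the problem was genuinely
open.

## 1. Consensus SNP discovery

Each accession is called by three independent variant callers against a
common reference. Two hard filters define a *putative homozygous SNP*:

* position read depth ≥ 5 (`min_depth`), and
* alternative-allele fraction strictly above 90% (`min_alt_frac`).

The strictness of the second threshold matters at the boundary: a 9/10
call sits exactly at 0.90 and is discarded. We read "above" as a strict
inequality; the threshold is exposed so an inclusive policy is one
argument away. Records with zero depth are counted separately rather than
silently merged into the rejects. When a per-position depth track derived
from genome coverage is available it overrides the caller-reported `DP`
for the depth test (`filter_homozygous(..., depth =)`), and disagreements
between the two are reported; this matches a workflow in which coverage is
computed once from the alignments rather than trusted per caller.

The *consensus* set is the intersection of the three filtered call sets,
keyed on (chromosome, position, ref, alt) — allele-aware, because the
downstream concordance analysis distinguishes positional agreement from
allelic agreement. The intersection can never exceed the smallest filtered
set, and raising either threshold can only shrink it; both facts are
asserted as properties in the test suite.

Rationale: the filters remove heterozygous-looking and low-confidence
calls (the accessions are inbred, so a true SNP should be near-fixed in
the reads), and the three-way intersection removes caller-specific
artifacts, which dominate the disagreement between callers.

## 2. Concordance classification

When the same accession has been assayed by a second technology, each
consensus SNP is classified against the second technology's call
hierarchy into five disjoint categories, evaluated in precedence order:

1. `identical_A` — same (chrom, pos, alt) in the second technology's own
   three-caller consensus;
2. `identical_B` — present, filter-passing, in one or two of its callers
   but not all three;
3. `identical_C` — present only in its raw (pre-filter) call union;
4. `different_call` — a positional hit with a different alternative
   allele anywhere in the raw union;
5. `rnaseq_only` — no call at the position at all.

The categories are reported as percentages that sum to 100; the
precedence order enforces disjointness where the definitions could
overlap. "Raw" means the union of the three callers' unfiltered outputs.
`different_call` uses the broadest reading — any allele mismatch at the
position, anywhere in the raw union. An optional `min_exome_depth` gate
can require the second technology to be covered at a position before the
position counts as assayed; the default applies no gate, so
`rnaseq_only` includes positions the second technology simply failed to
cover.

## 3. The bi-allelic genotype matrix

Sites for the panel-wide matrix are the union of all consensus SNP
positions, kept when three criteria hold: (i) at least one accession
carries a call; (ii) read depth ≥ `min_depth` in *every* accession at the
position; (iii) fewer than `max_third_allele_frac` (default 10%) of
accessions call an allele other than the site's plurality alternative
allele.

Criterion (ii) is what makes "no missing data" a theorem rather than an
aspiration: an accession without a call at a retained site is covered at
≥ 5x and carries no alternative allele there, so it can be coded as the
reference allele with confidence. Two open points were settled as
follows:

* **Third-allele carriers** are recoded to reference (the site's two
  alleles after recoding are exactly ref and the plurality alt). The
  alternative — dropping the site — is available via
  `third_allele = "drop_site"`. Recoding preserves the no-missing-data
  guarantee while honouring the tolerance; it treats a minority
  discordant allele as probable technical noise.
* **The site's alternative allele** is the plurality alt among calling
  accessions, ties broken alphabetically (A < C < G < T) for determinism.

A reference accession row of all zeros is appended (`reference_name`),
since the reference genotype is definitionally the reference allele at
every site. Pairwise identity — the fraction of matrix sites at which two
accessions agree — complements the p-distance exactly
(`identity = 1 - p_distance`), which the tests assert to 1e-12.

## 4. Tree, PCA

**Neighbour joining** is implemented directly (Saitou–Nei Q-criterion,
standard branch-length formulas) rather than delegated, for two
guarantees the delegate does not make: deterministic tie-breaking (ties
in Q are resolved toward the lexicographically smallest label pair) and
explicit handling of negative branch lengths (clamped to zero, deficit
moved to the sister branch, preserving path lengths). On additive inputs
NJ provably recovers the generating topology and branch lengths exactly;
the tests verify this on random 4–7-taxon trees against both an
exhaustive least-squares topology oracle (4 taxa) and `ape::nj` as an
independent implementation.

**PCA** centres each site column and, by default, normalises it by
sqrt(p(1-p)) with p = (1 + Σg)/(2 + n) — the shrunken frequency estimate
in the haploid analogue of the usual genotype-PCA normalisation (the
denominator is 2 + n, not 2 + 2n, because inbred accessions contribute
one allele, not two). Monomorphic columns are dropped. Scores are
eigenvectors of the accession covariance scaled by the square roots of
their eigenvalues, so score columns are orthogonal and their squared
norms are the eigenvalues; raw-genotype PCA is available with
`patterson_normalize = FALSE`.

## 5. Bayesian admixture and Evanno ΔK

The admixture model is the STRUCTURE model specialised to haploid data:
accession a draws its allele at site s from cluster z with probability
p[z, s], with z ~ Categorical(q[a, ]) per site. The Gibbs sampler
(compiled code, driven by R's RNG so a seed fixes the whole chain)
updates in turn:

* z | Q, P — per accession-site categorical draw;
* P | z — Beta(λ + alt, λ + ref) per cluster-site, λ = 1
  ("uncorrelated frequencies" default);
* Q | z — Dirichlet(α + origin counts) per accession;
* α — random-walk Metropolis (proposal sd 0.05) under a uniform prior on
  (0, 10], as in STRUCTURE's default α inference.

`reps` counts post-burn-in sweeps; Q and P are posterior means over those
sweeps and L is the mean data log-likelihood. K = 1 degenerates to a
Beta-binomial frequency model, which gives a closed-form oracle for L
used in the tests. Label switching is handled at comparison time only:
`match_clusters()` finds the cluster permutation minimising the mean
absolute ancestry error.

Model selection uses Evanno's ΔK as implemented by Structure Harvester:
ΔK = mean over replicate runs of |L(K-1) - 2L(K) + L(K+1)|, divided by
the standard deviation of L(K) across replicates. Replicate-wise second
differences are taken before averaging. A zero replicate standard
deviation yields an infinity marker when curvature is present and 0 (with
a warning) when the likelihoods are entirely flat.

The package's working MCMC profile is burn-in 500 and 2000 retained
sweeps on panels of ≲ 500 sites, which the tests show recovers planted
ancestry to within 0.02–0.1 mean absolute error and selects the planted
K; a full-study profile (burn-in 30000, 60000 sweeps) is the documented
parameter change for real analyses.

## 6. Windowed haplotype diversity and Hudson F_ST

Chromosomes are tiled into half-open 5-Mb windows (`make_windows`; the
step equals the width by default — published "sliding window" genome
tracks are most often tiled, and a smaller step is a parameter away).
Within a window:

* **Haplotype diversity** treats each accession's window-restricted
  genotype string as a haplotype: Hd = n/(n-1) (1 - Σ p_i²) (Nei).
  Windows with sites but no polymorphism give 0; windows with no sites
  give NA, and NA windows are excluded from genome-wide averages rather
  than zero-filled (zero-filling would conflate "no data" with "no
  diversity").
* **F_ST** uses Hudson's estimator 1 - Hw/Hb with Hw the mean pairwise
  difference count within groups (averaged over the two groups, with the
  n/(n-1) sample correction) and Hb the mean pairwise difference count
  between groups, both summed over the window's sites before the ratio is
  taken (ratio-of-sums, not mean-of-ratios). Values are clamped to
  [0, 1]; Hb = 0 marks the window undefined. Hudson's estimator was
  chosen over Weir–Cockerham because it is simple, nearly unbiased for
  the ratio-of-sums form, and cleanly defined for haploid data; under the
  Balding-Nichols generator its genome-wide expectation equals the
  simulated per-group F, which the acceptance checks exploit (estimates
  within ±0.05 of F = 0.2 at n = 50 per group, 2000 sites).

## 7. Linkage disequilibrium

For site pairs within `max_dist` (500 kb default) and minor-allele
frequency ≥ 0.05 — the conventional defaults of the standard haplotype
LD tool — the package computes r² = D²/(p_A q_A p_B q_B) and
D' = |D|/D_max directly from observed haplotype frequencies. No phasing
is needed: inbred accessions *are* haplotypes, a major simplification
this data type affords.

The decay curve bins pairs by distance (1-kb bins) and reports the
midpoint of the first bin whose mean r² falls to half the first bin's
mean as the half-decay distance — a deliberately simple, monotone
summary; it is NA when the curve never halves within range.

Block detection follows the Gabriel confidence-interval method: per pair,
a two-sided 90% CI on |D'| is obtained by normalising the multinomial
likelihood of the observed two-locus haplotype counts over a |D'| grid
(step 0.001); a pair is "strong LD" if CI_low ≥ 0.70 and CI_high ≥ 0.98
and "strong recombination" if CI_high < 0.90; a run of sites is a
candidate block when ≥ 95% of its informative pairs are strong LD; and
maximal non-overlapping blocks are chosen greedily, longest span first.
The ≥ 10 kb span restriction sometimes applied when drawing genome
tracks is an output filter (`min_span_bp`), not part of detection.

## 8. The synthetic-data generator

Every stage above is exercised on data from `simulate_populations()` /
`simulate_caller_outputs()`, which emulate the *products* of an
RNA-seq-based SNP study (call sets and depth tracks), not its reads.

**Population model.** Per site, an ancestral frequency
p ~ Uniform(0.05, 0.95) (bounded away from 0/1 so simulated sites are
plausibly polymorphic) and per-group frequencies from Balding-Nichols
Beta(p(1-F)/F, (1-p)(1-F)/F). This was chosen over a coalescent because
it gives direct, O(sites) control of the quantity the downstream
statistics estimate: the expected Hudson F_ST between two groups with
parameters F₁, F₂ is (F₁+F₂)/2. Accessions are haploid-equivalent —
the panel's accessions are inbred lines and the calling pipeline keeps
only homozygous SNPs — and assumed fully homozygous (no residual
heterozygosity). Linkage comes from a mosaic-donor walk: an accession's
allele at each site is drawn from its current donor group's frequency,
and the donor is re-drawn from the accession's ancestry proportions with
probability 1 - exp(-c·Δbp) between adjacent sites. Pure accessions
always draw from their own group, so *within-group* linkage is absent by
construction; admixed accessions carry ancestry mosaics whose r² decays
with distance at scale 1/c.

**Caller model.** One depth track per accession (Poisson depths, constant
over 200-bp tiles, mean equal to the average of the three profiles'
`depth_lambda`) is shared by its three callers — the three lambdas are
averaged because coverage is a property of the library, not the caller.
Each caller misses a true alt site independently with probability
`fn_rate`; reported sites get alt_reads ~ Binomial(depth, 1-ε) with
sequencing-error rate ε = 0.01 (configurable). False positives arrive at
`fp_rate` per Mb, uniformly over covered non-SNP positions, *with the
same confident alt-read model*: an emitted false call looks exactly like
a real one to the per-caller filters, and it is the cross-caller
intersection — independent callers rarely invent the same error — that
removes it. Modelling false calls as sequencing-error-like (alt fraction
≈ ε) would make them vanish in the alt-fraction filter and render
`fp_rate` inert. A guard refuses profiles whose expected false calls
exceed half the true calls, since such fixtures stop being informative.

**What passing tests do and do not show.** The generator reproduces the
features the statistics respond to — group divergence with a known F_ST,
admixture gradients, distance-decaying LD, caller dropout and artifacts,
depth variation. It does not reproduce gene-density-correlated SNP
density, shared error modes between callers (its callers err
independently), residual heterozygosity, allele-specific expression, or
within-group IBD sharing. The last point has a visible consequence:
within a pure group, sites are independent draws, so window haplotypes
repeat only when windows carry few segregating sites. The three-group
demonstration design (`demo_three_group_model()`: 7 chromosomes × 30 Mb,
60 sites each, i.e. ~10 sites per 5-Mb window) was therefore chosen
sparse, which is the regime where haplotype diversity discriminates
groups for this generator; with dense windows every haplotype is unique
and Hd saturates at 1 for all groups. Passing the Hd-ordering check shows
the estimator ranks admixed above pure groups where haplotype sharing
exists — not that any site density would show it.

**Study-condition sizes.** The bundled analyses and checks use: F_ST
recovery at n = 50 per group and 2000 sites over 20 replicates;
the three-group pattern on the demo design over 20 replicates; admixture
recovery at 15 + 15 accessions, 200 sites, burn-in 500 / 2000 sweeps,
with Evanno over K = 1..4 × 3 runs × 10 replicates; LD decay at 200
admixed accessions, 2000 sites on 1 Mb, switch distance 5 kb. These sizes
give stable statistics for each property while keeping any single check
in the seconds-to-a-minute range.

## 9. Numerical and degenerate-input choices

* F = 1 is rejected (degenerate Beta); F = 0 is the point mass at p.
* Duplicate accession names and ancestry rows not summing to 1 (±1e-9)
  are rejected.
* `evanno_delta_k` requires consecutive K and ≥ 2 replicates per K.
* Monomorphic sites: dropped by PCA; excluded by the LD MAF filter;
  contribute zero to both Hw and Hb in F_ST.
* Window statistics distinguish "no sites" (NA) from "no variation" (0).
* NJ with negative branch estimates clamps to 0 and moves the deficit to
  the sister branch (split evenly in the terminal three-node resolution).
* The D' CI grid clips haplotype frequencies at 1e-12 before taking logs.
* All stochastic entry points take an explicit seed; the pipeline
  (`run_pipeline`) derives stage seeds from the single config seed and is
  byte-reproducible, which the tests assert via artifact checksums.

## 10. The pipeline and repository shape

The package is organised as an analysis workflow: numbered drivers under
`analysis/` (simulate panel → consensus → concordance → matrix →
tree/PCA → admixture → windowed diversity/F_ST → LD) each call package
functions and write plain-text tables under `results/`. `run_pipeline()`
runs the same chain from one configuration (R list or YAML) and records
every artifact's MD5 in a JSON manifest; there is deliberately no shell
subcommand layer — the R functions and the numbered scripts are the
interface.

## 11. Known limitations

* Caller behaviour is simulated at the call-set level; nothing upstream
  of calling (trimming, mapping, the callers themselves) is modelled.
* The admixture sampler implements the haploid/uncorrelated-frequency
  model only — no linkage model, no LOCPRIOR, no diploid path.
* Hudson F_ST estimates from *noisy* call sets attenuate toward 0
  relative to truth-genotype estimates (false negatives recode alt
  carriers to reference, inflating within-group mismatch); the
  acceptance checks therefore measure estimator recovery on emitted
  genotypes, and the pipeline's matrix-based values should be read as
  conservative.
* Absolute haplotype-diversity and F_ST levels depend on the estimator
  and the window site density; between-group *orderings* are the robust,
  tested quantity.
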