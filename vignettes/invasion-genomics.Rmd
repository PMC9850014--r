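---
title: "Reconstructing the demographic and spatial history of an introduced population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the demographic and spatial history of an introduced population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`invadepop` analyses diploid biallelic SNP genotypes from a recently
introduced population sampled at two epochs (a small historical sample and a
large contemporary one) along a one-dimensional river network. It asks three
questions: did the population pass through a founding bottleneck; how large is
its contemporary effective size; and how connected is it across the invaded
range. This vignette documents the models, the tunable parameters, and the
design decisions behind the implementation; the README shows a worked example.

## The genotype container and the filtering cascade

Genotypes are held as an individuals x SNPs matrix of alternate-allele counts
(0/1/2, `NA` missing) with optional per-genotype read depths and a RAD-style
locus tag per SNP (`geno_matrix`). The standard filtering cascade
(`filter_cascade`) applies, in order:

1. **Iterative missingness filter.** Loci then individuals above the current
   missingness cut-off are dropped alternately while the cut-off tightens
   along a schedule (default 0.9, 0.7, 0.5, 0.3), finishing when the final
   30% locus and individual rules hold simultaneously. The gradual schedule
   prevents a few terrible samples from dragging down otherwise good loci and
   vice versa. The schedule itself is a free design choice (only the final
   thresholds and the alternating strategy are fixed by the protocol we
   follow); it is configurable and every removal is logged with its reason.
2. **Minor-allele-count filter.** Loci with minor allele count below 2 are
   removed (`min-mac 2` semantics, i.e. MAC >= 2 is kept; monomorphic loci
   always go). We follow the tool semantics rather than the looser phrase
   "greater than two" because the command line is the operational record of
   such pipelines.
3. **HDplot paralog screen.** Per locus, H is the heterozygote proportion and
   D = (A - B) / sqrt(A + B) the z-score of total reference (A) versus
   alternate (B) read counts over heterozygous individuals, against the
   binomial(0.5) expectation for a true heterozygous site. Collapsed
   paralogous loci inflate H and |D|. Defaults H <= 0.55 and |D| <= 7. The
   sign convention (D positive when reference-biased) is cosmetic since only
   |D| is thresholded, but it is fixed for reproducibility.
4. **One SNP per locus.** Within each locus tag the SNP with the highest
   minor allele frequency is kept; ties break to the lowest site position.

A method-of-moments relatedness screen (`pairwise_relatedness`, a
VanRaden-style kinship scaled so parent-offspring pairs sit near 0.5) is
provided for flagging close kin. It deliberately replaces maximum-likelihood
relatedness: the screening use case (detecting full/half sibs) does not need
the extra machinery, and the method-of-moments estimator is self-contained
and oracle-testable against pedigree simulations.

## The coalescent simulator and what it does (and does not) emulate

`simulate_snp_dataset` draws one genealogy per locus under a serial-sampling
n-coalescent with piecewise-constant diploid size N(t): among k active
lineages coalescence occurs at rate k(k-1)/(4N(t)); lineages sampled at a
historical time tb enter the process only at tb. A single mutation per locus
is placed on a branch chosen proportionally to branch length ("fixed-S"
ascertainment with S = 1), so every locus is polymorphic in the pooled
haploid sample — matching how SNP matrices are ascertained from the study
sample itself.

Two consequences of this ascertainment are worth understanding because they
are easy to get backwards:

* The per-site frequency spectrum is E[l_i / L] (the expected *share* of
  branch length subtending i tips), not the infinite-sites 1/i law; it has a
  slightly heavier singleton class. Our tests check the simulator against
  frozen expectations computed with an independent coalescent implementation
  (msprime), not against 1/i.
* Conditional on ascertainment, a bottleneck *raises* per-SNP gene diversity:
  rare variants are the ones lost, so surviving polymorphisms sit at
  intermediate frequencies. Genome-wide absolute diversity falls, but a
  fixed-size SNP panel cannot see that. The scenario classifier exploits this
  shifted spectrum (plus the historical/contemporary contrast); tests assert
  the direction the generative model actually produces.

The generator does not model recombination within loci, selection,
multi-allelic sites, mutation-rate variation, or spatial structure within the
coalescent; all loci are exchangeable and unlinked. Consequently, passing
tests demonstrate correctness of the inference machinery under the stated
model, not robustness to linked selection, allele-calling error beyond the
synthetic paralog class, or spatially heterogeneous demography.

Time is measured in generations throughout; conversion to years (about 3
years per generation for a fish maturing at age three) is left to reporting.

## The forward stepping-stone simulator

`simulate_river_population` is a forward-time diploid Wright-Fisher
simulation of demes on a line founded from a common pool, with symmetric
nearest-neighbour migration (edge mass reflecting home). It serves two
purposes the coalescent cannot:

* **Drift linkage disequilibrium.** Independent-locus coalescent simulations
  share no pedigree across loci and therefore generate *no* LD signal for the
  effective-size estimator. The forward simulation shares one realized
  pedigree across all loci, so LD-based Ne recovery can be validated against
  a known truth (the single-deme case).
* **Isolation by distance.** With small migration rates it produces spatial
  autocorrelation decaying along the river axis, the substrate for the
  spatial analyses. The IBD test fixture (20 demes of 25 diploids, 20 km
  spacing, migration rate 0.25, 150 generations) was constructed once so
  that its Mantel-correlogram autocorrelation range sits at ~100 km
  (5 demes); replicate simulations recover that range within +/- 2 distance
  classes.

Loci monomorphic in the final pooled sample are dropped (SNP ascertainment
again), so a dataset can carry slightly fewer loci than requested. Founder
allele frequencies are uniform on [0.05, 0.95] — a generic standing-variation
pool, not a fitted quantity.

Synthetic read depths (`add_read_depths`) are negative binomial around a
configurable mean (default 100, with dispersion giving realistic spread);
heterozygote reads split binomial(depth, 0.5). An injected paralog class
emulates two collapsed duplicated copies: individuals appear heterozygous
with probability 0.6 and their reads split at 0.65, producing the separable
H/D clusters the HDplot screen is designed to find. Rare true SNPs with a
handful of heterozygotes are intrinsically undetectable through D alone —
which is precisely why real paralog screens lean on H as well.

## Diversity statistics and temporal tests

Per locus with n non-missing genotypes: Ho is the heterozygote fraction; Hs
is Nei's unbiased gene diversity n/(n-1) (1 - sum p^2 - Ho/(2n));
Fis = 1 - Ho/Hs. Means over loci are unweighted (the behaviour of the
standard hierarchical-F-statistics implementations for a single population);
whether a weighted mean would better match any particular report is
unknowable from a printed mean, so the simpler convention was fixed.
Individual-level metrics are MLH (heterozygous SNPs over typed SNPs) and
internal relatedness IR = (2H - sum f) / (2N - sum f), where the allele
frequencies of *both* copies at each homozygous locus enter the sum
(2 f(allele) per locus) — the convention of the reference implementation this
index comes from, fixed here and brute-force tested.

Temporal change between eras uses a Wilcoxon signed-rank test paired by locus
(zero differences dropped; exact distribution when n < 50 and no ties), and,
for the individual-level metrics where group sizes are badly unbalanced
(8 vs 195), a randomization test of the mean difference with 5000 label
permutations and p = (1 + #{|perm| >= |obs|}) / (n_perm + 1).

Differentiation uses multi-locus Weir-Cockerham theta (ratio of summed
variance components) with a percentile bootstrap over loci (1000 resamples;
the resample count is our choice — reports rarely state it).

## Effective population size from linkage disequilibrium

For every locus pair passing the allele-frequency screen (MAF >= Pcrit),
the composite Burrows disequilibrium is estimated from unphased genotypes as
Delta = cov(X, Y)/2 using the S/(S-1) sample covariance, and
r^2 = Delta^2 / (pA qA pB qB), clipped to [0, 1]. The mean r^2 is
bias-corrected by the published sample-size regressions (random mating:
E[r^2|S] = 1/S + 3.19/S^2 for S >= 30; 0.0018 + 0.907/S + 4.44/S^2 below)
and inverted through the published quadratic drift relation; a non-positive
drift residual returns Ne = infinity, the correct reading of "no resolvable
drift signal" (expected for tiny samples from large populations, as with an
8-individual historical sample). Confidence intervals are a delete-one-locus
jackknife on mean r^2 mapped through the same inversion — the recommended
interval for SNP data, since locus pairs sharing a locus are not independent.
The published constants are used verbatim; correctness is referenced not to
the constants but to recovery of known truths in forward simulations
(medians within 25% at true sizes 50-500). The Pcrit sweep (0, 0.1, 0.2,
0.5 by default) reports a max-relative-spread diagnostic: stable Ne across
Pcrit suggests an isolated stable population, large spread an excess of rare
alleles (immigration or expansion). Overlapping generations, which bias
LD-Ne downward when cohorts are mixed, are acknowledged but not corrected.

## ABC random-forest demographic inference

Eight single-population scenarios in two groups are compared: group 1 (ids
1-4) without and group 2 (ids 5-8) with a founding bottleneck of size
Nbottleneck starting td generations back. Published schematics rarely pin
down every within-group variant, so the four variants per group are defined
as the 2x2 combinations of {size change at ta} x {change/recovery at tc},
with scenario 5 = bottleneck followed by establishment-size recovery and no
later change; the scenario list is an ordinary R structure users can replace
(`default_scenarios()`), making the within-group assumptions explicit and
overridable. Priors are integer-uniform (sizes 2-10,000; bottleneck 2-100;
t0 0-5, ta/tb 2-15, tc 2-50, td 1-100) with t0 < ta < tb < tc < td enforced
by rejection; rejection resolves the joint-support question (e.g. how t0 in
[0,5] interacts with ta >= 2) in the simplest defensible way, and the
realized marginals are chi-square-tested against an independent rejection
oracle.

Each reference-table row is a simulated dataset reduced to a 36-value
summary vector: per era and pooled, the proportion of monomorphic loci,
mean/variance of MAF, of Ho, of Hs, and mean Fis; between eras,
Weir-Cockerham Fst, Nei's standard distance and mean |allele-frequency
difference|; plus pooled MAF-spectrum deciles. The exact summary set used by
the original GUI tool is not printed anywhere, so this set was designed to
span the same moment families and is recorded in output metadata.

Scenario choice trains a 1000-tree random forest on the summaries; the
*prior error rate* is its out-of-bag misclassification, votes are trees
voting per class at the observed summary, and the posterior probability of
the selected class is estimated by a second regression forest trained on
out-of-bag correctness — the standard two-forest construction. A linear
discriminant projection of the reference rows is returned for overlap
inspection. Parameter estimation uses quantile regression forests (median
and 2.5/97.5% quantiles) trained on a *dedicated* single-scenario table,
twice the per-scenario size of the choice table at our desk scale —
mirroring the two-stage protocol of the original analysis — with NMAE
(mean |OOB prediction - truth|/truth) as the accuracy diagnostic.

Desk-scale defaults are 500 draws per scenario and 300 loci (about two
minutes of simulation on one core), chosen so the whole inference loop runs
comfortably inside a test suite while preserving the qualitative structure:
group-level discrimination far better than scenario-level, and bottleneck
size/timing estimated far more accurately than ancestral size. The
`paper_scale` flag of `default_config()` restores 5000 draws per scenario
and 1898 loci for a full run (hours on one core).

## Clustering without spatial information

`geno_pca` centres genotypes per locus, mean-imputes missing values for the
decomposition only, and eigendecomposes. `kmeans_bic_scan` runs seeded
K-means for K = 1..10 on all retained PCs and scores each K by
BIC = n log(WSS/n) + K log(n) — the BIC family used by the standard genetic
clustering tools; since published analyses name the criterion but not the
formula, acceptance is cluster-count recovery rather than BIC values. Two
selection rules are reported: "min" (smallest BIC) and "diffNgroup"
(smallest K whose BIC decrease to K+1 falls below one third of the maximal
successive decrease — a documented, configurable reading of the
sharpest-elbow heuristic). `dapc` performs linear discriminant analysis on
the retained PCs, choosing how many by repeated stratified 90/10
cross-validation minimizing the mean squared assignment error.

## Spatially explicit analyses

River distances are consumed, not derived: a square matrix keyed by sample
id, or a haversine fallback from lon/lat with a warning (straight-line
distance understates river distance). `nmds_project` re-embeds the distance
matrix in the plane by nonmetric MDS (seeded restarts, best stress kept) so
that graph-based methods can operate on Cartesian coordinates.

**sPCA.** The connection network is the minimum-distance neighbour graph,
implemented as: join every pair closer than the smallest threshold that
makes the graph connected. That phrase is underspecified in common usage;
this definition is reproducible, parameter-free and guarantees a connected
operator. The analysis eigendecomposes (1/n) X' M X with X the centred
allele matrix and M the symmetrized row-normalized adjacency: positive
eigenvalues are global (neighbours alike), negative local (neighbours
contrasting) structure. Monte Carlo tests permute genotype rows across
locations with the largest positive (most negative) eigenvalue as the
global (local) statistic — the exact test statistic of the original method
is not recoverable from its printed output, so this variant is calibrated by
simulation (type-I error at the nominal level on null fixtures). The two
largest positive and three smallest negative axes are the conventional set
to inspect.

**Moran eigenvector maps.** The MEM basis comes from principal coordinates
of the truncated distance matrix (classic PCNM construction); the response
is the principal coordinates of the shared-allele genetic distance
(1 - proportion of shared alleles); forward selection uses the
double-stopping rule (permutation p and adjusted-R2 ceiling) on a redundancy
analysis, reporting the selected vectors and the adjusted R2. An empty
selection with R2adj = 0 is a legitimate no-structure outcome, not an error.

**Mantel correlogram and neighbourhood size.** For distance classes of 10 km
up to 300 km (defaults), the Mantel correlation between genetic distance and
class membership is computed with the sign oriented so that positive values
mean "more similar than average within this class"; the first class is
closed at zero so same-site pairs belong to it. Permutation p-values (999,
seeded) are corrected by progressive Holm (class k corrected within the
first k classes — the convention of the ecological correlogram literature);
raw p-values are also reported. The genetic neighbourhood is the upper bound
of the last class in the initial unbroken run of significant positive
correlations. Published phrasings of this rule conflict ("first class no
longer significant" vs "largest significant class"); both readings coincide
when significance is an unbroken prefix, and both numbers are returned.
Because a neighbourhood of 220 km as a *distance class* corresponds to a
~110 km eradication *radius*, `neighborhood_diversity` takes a radius
argument the user can set to either reading.

**Neighbourhood diversity.** For each focal individual, all individuals
within the radius (inclusive) form its neighbourhood; neighbourhoods of at
least 20 members get Ho, He (Nei unbiased, so the infinite-radius case
equals the global gene diversity exactly), Fis, and allelic richness
rarefied to 2 x (smallest qualifying neighbourhood size) gene copies —
rarefaction depth must be common across neighbourhoods for comparability,
and twice the minimum qualifying n is the largest depth every qualifying
neighbourhood supports. Isolated samples are reported as not computed with
the reason, never silently dropped.

**Distance decay.** Ordinary least squares of a diversity metric on distance
from the introduction point, direction (north/south), and their interaction,
with backward elimination by likelihood-ratio tests at alpha = 0.05 starting
from the interaction; slopes are reported per 100 km. An optional leverage
rule excludes points beyond 4 x the mean distance (off by default and logged
when applied) — the automated analogue of removing a single far-outlying
sample whose leverage would otherwise dominate the fit.

## Numerical and testing conventions

Every stochastic routine takes a seed and is bit-reproducible under it (the
C++ engines draw from R's RNG). Degenerate inputs fail loudly with the
reason (empty locus sets, single populations, disconnected graphs,
insufficient samples for LD-Ne at S < 10) except where a quiet NA row with a
warning is the more useful behaviour (a Pcrit level leaving fewer than two
loci mid-sweep). Permutation p-values are never zero (the +1 convention).
Monte-Carlo tests in the suite use three-standard-error tolerances around
analytically or independently computed expectations; problem sizes in the
suite (hundreds of individuals, hundreds of loci, hundreds of replicates)
were chosen as the smallest at which the checked contrasts are decisively
resolved.

## Known limitations

Pcrit values of 0.1-0.5 are unusually aggressive for SNP data (conventional
screens use 0.01-0.05); they are implemented as specified and configurable.
LD-Ne assumes discrete generations and an isolated population; both
violations bias it downward. The ABC scenario space is single-population by
construction — a multiple-introduction scenario with admixture is outside
it, so "group 1 selected" must not be read as evidence for multiple
introductions. The spatial analyses assume the river distance matrix is the
relevant connectivity metric; no least-cost or resistance-surface modelling
is provided.
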