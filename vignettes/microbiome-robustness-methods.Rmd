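---
title: "Methods: quantifying gut-microbiome robustness to an acute stressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gut-microbiome robustness to an acute stressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

robustbiome asks one scientific question of a longitudinal microbiome study:
when a cohort is hit by an acute stressor, how much does each arm's
community composition, diversity and functional repertoire move — and does a
dietary intervention damp that movement? The package grew out of equine
work (two treatment arms of horses, fecal shotgun metagenomics before and
after a transport-stress challenge), but every step only assumes a
taxon-by-sample count table, per-sample design factors (subject, treatment
arm, ordered timepoint, pre/post-stress phase), and optionally a
taxon-by-CAZy-family annotation table.

## Compositional footing

Sequencing counts are compositional: only relative information is
meaningful, and analyses must be invariant to per-sample depth. All core
analyses therefore run on centered log-ratio (CLR) values,
$\operatorname{clr}(x)_j = \ln x_j - \tfrac1D\sum_k \ln x_k$, with Euclidean
distance between CLR rows (the Aitchison distance) as the sample metric.
Because the log requires positive parts, zeros are first replaced by the
Bayesian-multiplicative rule: in a sample with total $n$, a zero cell
becomes $r_j = t_j s/(n+s)$ and observed cells are shrunk by
$1-\sum_{\text{zeros}} r_k$, which preserves the ratios among observed
parts exactly. The default prior is the uniform Bayes–Laplace choice
($t_j = 1/D$, $s = D$) because it is deterministic and transparent; an
empirical prior weighted by overall taxon frequency is available when taxa
span many orders of magnitude.

Species enter the statistical analyses through a deliberately strict
filter: within each stress phase a species must be present in at least 75%
of that phase's samples and exceed a mean relative abundance of $10^{-5}$;
the union (superset) of the pre- and post-phase passing sets is analyzed.
Prevalence is evaluated per phase by default — a species that blooms only
after stress should not be discarded for being absent before it — with an
all-samples option; the abundance rule can likewise be switched from the
phase mean to the phase maximum. Shannon diversity
($H=-\sum p_i\ln p_i$, natural log throughout) is computed on counts
rarefied without replacement to the minimum sample depth, so that richness
differences are not driven by depth.

## Diversity models and PERMANOVA

Alpha diversity is modelled as
$H \sim \text{treatment} \times \text{timepoint} + (1\,|\,\text{subject})$
by REML, the standard repeated-measures formulation with the host animal as
a random intercept. Two contrast families mirror the two scientific
questions: all 21 timepoint pairs within each arm (is an arm internally
stable?), Bonferroni-adjusted within the arm, and treated-vs-control at
each timepoint (do the arms differ now?). Degrees of freedom use the
Satterthwaite approximation. Because the stressor is nested within
timepoint, a stress-only variant replaces the timepoint factor with the
binary phase factor (`time_term = "phase"`).

Beta diversity is tested by a permutational MANOVA implemented from first
principles: the distance matrix is Gower-centered
($G = -\tfrac12 J D^{(2)} J$), sequential (Type-I) sums of squares are
traces of projections of $G$ onto the nested design subspaces, and each
term's pseudo-F is referred to its permutation distribution with
$p = (1+\#\{F^\ast \ge F\})/(1+n_{\text{perm}})$, so $p$ is never zero.
Free permutation of samples is the default, matching common practice; since
samples are repeated measures within subject, a within-subject strata mode
is provided and reported alongside in the analysis drivers. Term order is
user-visible because Type-I sums of squares depend on it.

## Bias-corrected differential abundance

Per-species linear mixed models on CLR values share the alpha-model design.
The CLR constraint (rows sum to zero) means a genuine shift in a few
species induces an equal-and-opposite artefactual shift spread across all
species. Assuming most species are null for a covariate, that common bias
is the mode of the covariate's coefficient distribution across species,
estimated by a Gaussian kernel density (Silverman bandwidth, argmax over a
512-point grid) and subtracted from every species' coefficient.
Treated-vs-control fold changes anchored at each animal's day-0 sample are
then exactly the corrected treatment-by-timepoint interaction coefficients,
reported as log2 fold changes with BH-FDR across species within each
timepoint (a pooled family is available). The reported sign convention is
treated-minus-control, with a flip option for the opposite convention.

One finite-sample choice deserves emphasis: with only a few dozen species,
the mode estimate is itself noisy, and ignoring that noise produces
anti-conservative intervals. The package therefore adds the bootstrap
variance of the mode (200 resamples on a private RNG stream) to each model
variance and uses t rather than normal quantiles
(df = observations − fixed-effect parameters). In simulations at the
package's default scale (30 species, 20 subjects), interval coverage for a
planted unit effect moves from roughly 0.88–0.90 to about 0.94 at the
nominal 0.95.

## Consensus correlation networks

Species interaction structure is summarized by an ensemble network on CLR
values within each treatment-arm-by-phase stratum (a per-timepoint mode
exists): Pearson, Spearman and Kendall coefficients for every species pair,
analytic two-sided p-values (t approximation for Pearson/Spearman, normal
approximation for Kendall), BH-FDR per measure across pairs, and an edge
retained only when at least two measures are individually significant *and
agree in sign*; sign-conflicted edges are uninterpretable and discarded.
The summary statistic of interest is the count and positive share of edges
per stratum — a leaner, more positively connected post-stress network is
the signature of a stabilized community.

## Delta-CLR clustering and the gap statistic

Robustness is most directly visible in each animal's displacement from its
own baseline: the delta-CLR row for (subject, timepoint) is the CLR row
minus that subject's day-0 row, exactly zero at day 0 by construction.
Species (and CAZy families) are clustered with the Spearman dissimilarity
$1-\rho$ between their delta profiles; samples with the Aitchison
(Euclidean) distance between delta rows. The number of clusters comes from
the gap statistic with $W_k=\sum_c \frac{1}{2n_c}\sum_{i,j\in c} d_{ij}^2$,
reference sets drawn uniformly over each feature's observed range, and the
standard selection rule (smallest $k$ with
$\mathrm{Gap}(k)\ge\mathrm{Gap}(k+1)-s_{k+1}$). The partitioner is
k-medoids (PAM: greedy build plus swap steps, seeded random restarts),
chosen because neither $1-\rho$ nor an arbitrary dissimilarity supports
Euclidean centroids; on small problems it provably reaches the exhaustive
medoid optimum (tested against full enumeration at $n=8$). Arm-by-timepoint
cluster occupancy fractions then trace each arm's trajectory through the
cluster space.

## CAZy functional potential

Functional robustness uses the Carbohydrate-Active enZyme (CAZy) families
(AA, CBM, CE, GH, GT, PL). Given a taxon-by-family annotation table
(produced upstream by genome annotation; consumed here as a plain TSV), the
per-sample accumulated potential sums the family counts of every taxon
detected in the sample. Presence-weighting is the default — the quantity is
the community's repertoire, and it is invariant to abundance noise — with
abundance-weighted accumulation as a first-class alternative (invariant to
sequencing depth instead). The resulting sample-by-family table feeds the
identical CLR → delta → clustering machinery.

## The synthetic-study generator

Because the motivating study's raw data requires a heavyweight
classification pipeline, the package carries a generator that emulates the
design: 10 subjects per arm, timepoints d0/d28/d56 (pre) and
h0/h12/h24/h72 (post), 30 species, lognormal depths around 389,680 reads
per sample with CV 0.30 (matching the reported depth dispersion).
Log-abundances are baseline ramp (4 to −4, a ~3,000-fold dynamic range) +
subject random intercept (SD 0.3) + stress shift + shared latent factors +
i.i.d. noise (SD 0.5); probabilities are the softmax, counts multinomial.
The stressor raises 18 species and lowers 9 by 2 CLR-scale units
(mirroring the two observed response regimes), the treated arm receives
the shift damped by the attenuation parameter (default 0.8; 1 gives a
control-only effect), and 10 positive plus 2 negative latent couplings
(loading 0.8) plant a predominantly positive interaction structure. Since
CLR of a softmax is the centered log-abundance, every planted effect has an
exact expected CLR shift, recorded in the returned truth object. The
companion CAZy-profile generator draws sparse per-taxon family counts with
the six class prefixes; when given the species clusters it enriches each
group in its own family block (`group_enrichment`, default 4x) so that the
planted compositional regimes carry a matching functional signature.

What the generator does *not* emulate: taxonomic misclassification,
host-read contamination, overdispersion beyond the logistic-normal layer,
taxa appearing or vanishing entirely, and per-timepoint effect decay unless
configured. Passing tests therefore demonstrate that the machinery recovers
known effects under a faithful compositional sampling model — not that any
particular real dataset will show them.

## Numerical choices and limitations

* Ties in PAM and in the permutation count are broken deterministically
  (first index; `>=` with a 1e-12 slack), and all stochastic stages take
  explicit seeds; the pipeline derives per-stage seeds from one master seed
  and reruns byte-identically.
* Degenerate inputs fail loudly and early: all-zero samples, constant
  features under Spearman, single-level design factors, missing baselines
  (subjects dropped with a warning), all-identical items (gap returns
  k = 1 with a warning).
* Default problem sizes in the analysis drivers — 999 permutations, 50 gap
  references, k up to 7 — keep a full study analysis around a minute or two
  on a laptop core while leaving Monte-Carlo error well below the decision
  margins involved; all are config fields, not constants.
* The free-permutation PERMANOVA ignores the repeated-measures dependence;
  the within-subject mode is the honest sensitivity check and both are
  written by the analysis driver.
* With ~30 features the consensus network's Kendall normal approximation
  and the Spearman t approximation are accurate at the sample sizes used
  (>= 5 per stratum enforced, >= 20 typical); for very small strata a
  permutation-p extension would be preferable.
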