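---
title: "Classifying metacommunity structure from incidence matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metacommunity structure from incidence matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

A metacommunity is a set of local communities (sites) linked by potential
dispersal. Given a binary site-by-species incidence matrix, the elements of
metacommunity structure (EMS) framework asks three ordered questions about
the dominant compositional gradient: do species occurrences *cohere* along
one axis (few embedded absences)? do species *replace* one another along it
(turnover)? and are species range *boundaries clumped*, random, or
hyperdispersed? The combination of the three answers assigns one of ten
metacommunity types — checkerboard, random, nested, evenly spaced,
Gleasonian, Clementsian, and the quasi- variants of the latter four.
`emscomp` implements this classification with permutation null models, the
Baselga multiple-site beta-diversity partition, and a comparative stage
that relates the per-metacommunity outcomes to metacommunity-level traits.

## Ordination

All three statistics are defined on the *ordinated* matrix: rows and
columns sorted by their scores on the first non-trivial axis of reciprocal
averaging (correspondence analysis). `ca_axis1()` computes the SVD of the
standardized correspondence residuals
$S = D_r^{-1/2}(P - r c^\top)D_c^{-1/2}$ and returns standard coordinates;
these satisfy the reciprocal-averaging fixed point (each site's score is
proportional to the mean score of its species, and vice versa), which the
test suite asserts directly. Only axis 1 is consumed downstream; further
axes are exposed for diagnostics.

Two conventions make results reproducible:

* the axis sign is arbitrary, so it is fixed by requiring the first site's
  score to be non-positive;
* ordering treats scores equal to 12 significant digits as ties and breaks
  them by input order (a stable sort). Exactly duplicated site compositions
  receive identical scores in exact arithmetic, but eigenvector routines
  return last-bit noise; without the rounding, tie-breaking would be
  platform-dependent.

A matrix whose first correspondence eigenvalue is zero (for instance the
all-ones matrix) has no compositional gradient and is rejected.

`validate_for_ems()` removes empty rows and columns (they carry no
ordination information), warns below 15 sites — a dataset-selection rule in
comparative EMS work, not an algorithmic requirement — and rejects matrices
smaller than 3 sites or species. Rare species are deliberately retained.

## The three elements

**Coherence** counts *embedded absences* (`Abs`): zeros lying strictly
inside a species' range (its first to last occupied site) and, by default,
inside each site's range across the species ordering (`coherence_scope =
"both"`, the Leibold–Mikkelson convention; `"species_only"` is available
for sensitivity analysis). *Fewer* embedded absences than expected by
chance is positive coherence.

**Turnover** counts *replacements* (`Rep`) on the range-filled matrix
(every species range made contiguous first — the "range perspective"): over
all unordered site pairs and species pairs, configurations where one
species occupies only the first site and the other only the second. For a
site pair this equals $b_{ij} b_{ji}$, the product of the one-sided
compositional differences.

**Boundary clumping** collects both range endpoints of every species
(single-site species contribute both boundaries at that site) and measures
their aggregation with Morisita's index
$I = n \sum_i f_i(f_i - 1) / (F(F-1))$. Significance against $I = 1$ uses
the classical Morisita chi-square $\chi^2 = I(F-1) + n - F$ on $n - 1$
degrees of freedom, reported two-sided. The degrees of freedom follow the
multinomial goodness-of-fit null of uniformly placed boundaries; the df
convention is recorded in the result object.

## Null models and significance

`Abs` and `Rep` are tested against two permutation null models:

* **r1 (fixed-proportional)** — row sums (site richness) preserved
  exactly; within each row, occupied columns drawn without replacement with
  weights proportional to the observed species frequencies. Draws use
  sequential weighted sampling with renormalization (the semantics of
  `sample()`), which the test suite pins against an exhaustive
  subset-probability enumeration.
* **quasiswap (fixed-fixed)** — both margins preserved exactly. Each
  ensemble starts from an independent Gale–Ryser fill of the observed
  margins and runs a 2×2 checkerboard swap chain, whose stationary
  distribution is uniform over the margin class. Burn-in and thinning count
  *attempted* updates (defaults: 100× and 10× the number of presences).
  Counting accepted swaps instead would make the walk periodic on bipartite
  swap graphs — a 2×2 checkerboard would alternate deterministically — so
  attempts, which include aperiodicity-restoring self-loops, are the sound
  choice. Uniformity is verified against exhaustive enumeration of a 4×4
  margin class.

Each simulated matrix is independently re-ordinated before `Abs` and `Rep`
are measured (the standard EMS convention; a flag allows the fixed-ordering
alternative). Empty species columns arising inside r1 replicates are
dropped before re-ordination: a species observed nowhere has no range, and
dropping it also keeps it from inflating site-range gap counts.

Standardized effect sizes follow
$z = (\mathrm{obs} - \bar{x}_{\mathrm{null}}) / s_{\mathrm{null}}$, and
p-values are two-tailed add-one permutation probabilities
$p = 2\min(\#\{sim \le obs\}+1, \#\{sim \ge obs\}+1)/(n_{sim}+1)$, capped
at 1. With 999 simulations the $|z| > 1.96$ rule and the $p < 0.05$ rule
agree in well over 95% of draws, which the acceptance suite measures. A
degenerate null (zero spread) is flagged; its z is 0 when the observed
value equals the null mean and undefined otherwise. 999 simulations is the
default; 99 is a configuration choice for very large matrices, never
automatic.

**Sign convention.** z is computed on the raw `Abs` count, so *significant
positive coherence corresponds to z < −1.96* (fewer embedded absences than
null). Results store the raw z; the classifier encapsulates the inversion.

## The decision tree

With two-tailed tests at `alpha` (default 0.05):

1. Coherence nonsignificant → **random**.
2. Significantly *more* embedded absences → **checkerboard**.
3. Otherwise (positive coherence), examine turnover:
   * significantly negative (`Rep` below null) → **nested** (treated as a
     single type; the Morisita value is exposed for users who want nested
     subtypes);
   * significantly positive → **evenly spaced** ($I$ significantly < 1),
     **Gleasonian** ($I$ not distinguishable from 1) or **Clementsian**
     ($I$ significantly > 1);
   * nonsignificant → the **quasi-** analogues, with quasi-nested when the
     observed `Rep` falls below its null mean.

The classifier is a total function over the truth table of
(coherence sign/significance × turnover × clumping); the test suite
enumerates all cells.

## Multiple-site beta diversity

`multisite_beta()` implements the multiple-site (not averaged-pairwise)
Sørensen partition: $\beta_{SOR} = \beta_{SIM} + \beta_{SNE}$, with
$\beta_{SIM}$ the turnover (Simpson) component and $\beta_{SNE}$ the
nestedness-resultant component. The implementation is checked against
closed-form two-site limits and against vegan's independent
`nestedbetasor()`. Because $\beta_{SIM}$ and $\beta_{SNE}$ are strongly
negatively correlated by construction, only $\beta_{SIM}$ enters the
comparative models by default. One caveat worth knowing: adding a duplicate
of an existing site can *increase* $\beta_{SIM}$ (whenever the duplicated
site's summed pairwise minima are large relative to its richness), so the
statistic is not monotone under site duplication.

## The comparative stage

`run_comparative()` reproduces the two-level design: per-metacommunity EMS
plus beta diversity first, then cross-metacommunity models. Mixed traits
(continuous body size; categorical trophic group, ecosystem type, life
form, dispersal mode) are summarized by Gower distance
(`cluster::daisy()`) and principal coordinates (`stats::cmdscale()`;
negative-eigenvalue axes dropped without correction, variance normalized
over the positive axes). Body size enters the Gower computation as log10 —
across metacommunities it spans bacteria to fish, and an untransformed
range would concentrate the variable's resolution in the largest organisms.

The predictor set is the nine-variable design: number of sites, matrix
fill, multiple-site Simpson index, PCoA1–4, basin area, latitude. On it the
stage fits:

* Gaussian GLMs for the coherence z, turnover z and Morisita index, with
  VIFs ($1/(1-R^2_j)$) for collinearity screening;
* linear discriminant analysis of metacommunity type (`MASS::lda()`), with
  **equal priors by default**: group sizes are heavily unbalanced in
  comparative datasets and proportional priors would let the prior dominate
  the resubstitution table (both options exposed). Classification success
  is resubstitution; a leave-one-out flag is available. No claim is made of
  matching any particular published success rate, which depends on data we
  do not have;
* greedy forward selection on Wilks' lambda (partial-F admission at
  `p_enter = 0.05`), followed by an LDA on the selected predictors;
* MANOVA (Wilks' lambda with Rao's F; the univariate case reduces exactly
  to one-way ANOVA);
* when taxon labels are present, a permutation chi-square of taxon against
  type (Pearson statistic; both margins held fixed via `r2dtable`; add-one
  p) and Kruskal–Wallis checks of the three elements across taxa.

Outlier exclusion is a manual id list (`exclude =`), never automatic.

## What the synthetic generators emulate

`simulate_metacommunity()` builds the six canonical structures along a
latent gradient equal to the site index, so that CA ordination can in
principle recover it, and `simulate_trait_table()` mimics the statistical
shape of boreal freshwater comparative data (15–60 sites, fill 0.15–0.35,
latitudes 59–70°N, log-uniform basin areas, one continuous plus four
categorical traits). Generator choices worth explaining:

* **nested** — ranges share the first site as common endpoint; lengths are
  power-law quantiles with mean `fill × n_sites` spanning the whole
  gradient, so no site is empty and the realized fill is tight around the
  target. Uniformly distributed lengths would concentrate the community
  into the first `2 × fill × n_sites` sites.
* **clementsian** — enough equal blocks to tile the gradient; all species
  of a block share an identical contiguous range.
* **gleasonian** — one range endpoint uniform over sites; the other is the
  first plus a random-direction offset *reflected at the gradient edges*.
  The reflection keeps each boundary's marginal distribution exactly
  uniform (so Morisita's index is centred at 1, which the tests verify
  against a Monte-Carlo uniform-placement oracle), while stratified offsets
  control fill. Drawing both endpoints independently uniform would fix the
  expected fill at ~1/3 regardless of target.
* **evenly spaced** — equal-length ranges on a deterministic start
  lattice: boundary hyperdispersion is the defining property, so it is not
  randomized.
* **checkerboard** — mutually exclusive species pairs on complementary
  halves of a shared random site set (the pairs-based definition), rather
  than global exclusivity.
* **random** — independent Bernoulli(fill) cells.

Noise flips each cell independently. At `noise = 0` each structure
satisfies its defining property exactly, which the tests assert. Fill
targets are met per matrix for the deterministic generators and in
expectation (within ±0.03) for the stochastic ones, whose single-draw fill
has sampling spread by construction.

What the generators do *not* emulate: spatially autocorrelated sampling,
abundance structure, correlated trait syndromes (real pelagic organisms
are mostly lentic, for example), colonization–extinction dynamics, and the
huge species counts of microbial datasets. Passing recovery tests therefore
show that the chain of ordination, counting, null models and decision tree
works as specified on clean gradients — not that field data of any
particular taxon will classify cleanly.

## Known limitations, measured honestly

Two behaviours of the *method itself* (not of this implementation — both
reproduce with vegan's CA and both nulls) surface in the recovery tests and
are worth stating plainly:

* **Ordination-induced boundary clumping.** Wherever adjacent sites have
  nearly tied axis-1 scores — typically at the compressed ends of a long
  gradient — any ordering choice merges both sites' range-boundary mass
  onto whichever sorts later. For Gleasonian matrices this inflates
  Morisita's index (about +0.16 on average at 30×60, fill 0.25) and pushes
  a substantial fraction of noise-free Gleasonian replicates across the
  clumping significance boundary into Clementsian. The true-gradient-order
  boundaries are uniform (the acceptance script reports their mean index),
  so the inflation is a property of re-ordination, not of the generator.
* **Liberality of the fixed-proportional null.** On structureless
  Bernoulli matrices, r1 nulls are *more* coherent than the data (mean
  coherence z ≈ +1.5), so the nominal 5% two-sided test rejects roughly a
  quarter of random matrices. This liberality of proportional-column null
  models is well documented in the co-occurrence literature; under the
  fixed-fixed quasiswap null the same test is correctly calibrated, which
  the unit suite asserts.

Both phenomena are reported as measured rates by the acceptance suite
rather than smoothed over.

## Problem sizes used by the tests

The unit suite works on matrices up to ~30×60 with 49–199 null
simulations; oracle-equivalence checks use 500 random matrices up to
10×12 (exact equality) and 100 matrices for the ordination oracle (1e-8).
The acceptance suite runs the recovery study at 30 sites × 60 species,
fill 0.25, 999 simulations and 25 seeds per structure, 50,000 quasiswap
draws for the uniformity check, and 1,000 replicates for calibration
rates. These sizes are the package's chosen reference conditions for a
desk-scale, fully reproducible study.
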