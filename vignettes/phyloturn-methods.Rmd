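---
title: "Temporal phylogenetic turnover: models, null models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal phylogenetic turnover: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloturn)
```

## The question

Repeat censuses of mapped forest plots record, stem by stem, who died, who
recruited and who survived over an interval of a few years.  `phyloturn`
asks how much the *phylogenetic* composition of local communities changed
over that interval, whether the change is more or less than expected under
a null model of the same demography, and whether the excess relates to how
phylogenetically similar the co-occurring species were to begin with.  Two
assembly processes make opposite predictions: phylogenetic density
dependence (related neighbours share enemies, so clustered communities
churn) implies a *positive* relationship between turnover and relatedness,
while habitat filtering with phylogenetically conserved traits (mismatched
species are weeded out of mixed communities) implies a *negative* one.

## The turnover statistic

For one quadrat with relative abundances \(p^A\) at the first census and
\(p^B\) at the second, the temporal Rao quadratic entropy is

\[\mathrm{RaoD} = \sum_i \sum_j p^A_i\, p^B_j\, d_{ij},\]

the expected patristic distance between one stem drawn at each census.
Conspecific pairs contribute zero.  We implement the plain cross term; a
normalized variant (subtracting the mean within-census Rao diversity) is
available via `rao_turnover(..., normalized = TRUE)` but is not the
default, because the cross-expectation is the quantity with the direct
"expected difference between then and now" interpretation.  Abundances are
stem counts, not basal area.

The raw value is uninterpretable without a reference, so each quadrat's
observed value is standardized against `n_rep = 499` null censuses:
\(\mathrm{ses.RaoD} = (\mathrm{obs} - \mathrm{mean}_{\mathrm{null}}) /
\mathrm{sd}_{\mathrm{null}}\) (n−1 denominator).  Quadrats empty at either
census, or whose null distribution has zero spread, are flagged
(`empty_at_A`, `empty_at_B`, `degenerate_null`) and excluded from
downstream regressions rather than imputed.

## The two null models

**NM-I** draws one uniform permutation of the species pool per replicate
and applies it to *both* censuses.  Abundances, richness, occupancy and
species turnover through time are all preserved; only the mapping of
abundance trajectories onto the phylogeny is randomized.

**NM-II** re-simulates the demography of the second census while holding
the first fixed:

* *Mortality.*  Stems alive at the first census are binned by species and
  DBH size class (1 cm classes to 20 cm, then 20–25, 25–35, 35–45, 45–55,
  ≥ 55 cm).  In the default `exact_count` mode each cell re-draws *which*
  stems die, uniformly without replacement, holding the cell's death count
  at its observed value; the `bernoulli` option instead draws each death
  independently at the cell's observed rate.  `exact_count` is the default
  because it conserves plot-level abundances exactly, so all null variance
  comes from the spatial re-arrangement of deaths, not from demographic
  noise.
* *Recruitment.*  Each recruit's distance `Dp` to its nearest conspecific
  mature stem (DBH ≥ 15 cm for trees, ≥ 5 cm for shrubs, judged at the
  first census) within 50 m is measured once from the data.  In each
  replicate the recruit is re-placed at a uniform angle on the circle of
  radius `Dp` around a parent drawn uniformly from *all* conspecific
  mature stems in the plot.  Placement on the circle (rather than inside
  the disk) preserves each recruit's observed parent distance exactly; the
  in-disk reading is available as `placement = "disk"` for sensitivity.
  Angles that land outside the plot are re-drawn up to
  `max_placement_retries` times, then the parent is re-drawn (up to
  `max_parent_redraws` parents), and only then does the recruit fall back
  to a uniform position — every fallback is counted in the placement log.
  Recruits with no mature conspecific within 50 m are placed uniformly in
  the plot.

Size class and maturity are judged from first-census DBH; growth between
censuses does not move a stem between classes.  Empty species-by-class
cells contribute nothing — no pooling or smoothing across classes.
Recruits are never subjected to simulated mortality.

Each replicate `r` seeds its own RNG substream derived from the master
seed, so results are reproducible and independent of evaluation order.

## Downstream statistics

*Phylogenetic similarity* is the net relatedness index per quadrat:
\(\mathrm{NRI} = -(\mathrm{MPD}_{\mathrm{obs}} -
\overline{\mathrm{MPD}}_{\mathrm{null}}) / \mathrm{sd}(\mathrm{MPD}_{\mathrm{null}})\),
with presence-based MPD and 499 independent-swap randomizations.  MPD is
unweighted because the independent-swap null preserves occurrences, not
abundances.  NRI is computed on the first census by default: similarity
*preceding* the turnover interval is the causally interpretable predictor.
(Computing it on the post-interval census couples the predictor
mechanically to the turnover that produced it; in neutral simulations this
induces a systematic spurious negative slope, so we do not recommend the
`nri_census = 2` switch for inference, though it is available.)

The independent swap deserves a note.  We run the chain in *trial* swaps:
each step draws a random row pair and column pair and flips the 2×2
submatrix only if it is a checkerboard.  Because the proposal is symmetric,
the stationary distribution is exactly uniform over all matrices with the
observed margins.  A chain that counts only *successful* swaps is subtly
biased — its stationary weight on a matrix is proportional to that matrix's
number of checkerboard units — so we deliberately parameterize burn-in in
trials (default `10 * length(matrix)`), not successes.

*Phylogenetic signal* of traits uses Blomberg's K with the
variance-ratio form (observed MSE0/MSE over its Brownian expectation,
computed from the tree's shared-path covariance matrix).  Significance is
a one-tailed tip-shuffle test (default 1000 shuffles) with the add-one
rule \(p = (1 + \#\{K_{\mathrm{null}} \ge K_{\mathrm{obs}}\}) /
(1 + n_{\mathrm{shuffles}})\).  Species missing a trait value are pruned
for that trait's test and the n used is reported.

*Turnover vs. similarity* is fitted by a simultaneous autoregressive error
model \(y = X\beta + u\), \(u = \lambda W u + \varepsilon\), by maximum
likelihood: the likelihood is concentrated over \(\lambda\) with the
log-determinant from the eigenvalues of the row-standardized weight
matrix, and the scalar search runs at tolerance 1e-8 inside the
eigenvalue bounds.  "One grid-cell lag" is read as rook contiguity —
centres exactly one cell side apart; a distance threshold of one cell
width excludes diagonals (\(s\sqrt2 > s\)) — with queen contiguity behind
a flag.  Row standardization is assumed.  Residual spatial autocorrelation
is checked with Moran's I under 999 value permutations (two-sided by rank,
add-one rule).  Quadrats flagged by the turnover or NRI stages are dropped
listwise before the weights are built; isolated quadrats are dropped with
a warning.

*Variation partitioning* decomposes detrended ses.RaoD into fractions
unique to NRI ([a]), shared ([b]), unique to space ([c]) and residual,
using adjusted R².  Spatial structure is represented by PCNM
eigenfunctions: PCoA of the inter-centroid distance matrix truncated at
\(t = s\sqrt2\) (diagonally adjacent centres), larger distances replaced
by \(4t\).  The replacement value follows the established PCNM convention
(4 × the truncation distance); a literal reading (4 × each distance) is
available as `truncation = "literal"` for sensitivity, since the two
differ only in how inert the "large distance" block is.  Only
positive-eigenvalue axes enter.  Before partitioning, ses.RaoD is
detrended on third-degree orthogonal polynomials of the quadrat centroids;
detrending precedes axis selection.  Forward selection adds the axis with
the largest R² increase and keeps it only if a Freedman–Lane permutation
test (residuals of the current model permuted and added back to its
fitted values; 999 permutations) gives p ≤ 0.05 — the alpha rule alone,
with no secondary adjusted-R² stopping criterion.

*Branch-length smoothing.*  User-supplied node ages are honored exactly
and every undated node is placed by even interpolation between its nearest
dated ancestor and its nearest dated descendant along the path (ties
between dated descendants resolved toward the maximum age, which makes the
assignment deterministic); tips sit at age 0 and branch lengths are parent
age minus child age.  Trees are used as given — polytomies are not
resolved, and no calibration set is bundled; ages are user input.

## The synthetic census generator

Because real mapped-plot censuses are not redistributable, the package
ships a generator whose defaults describe a desk-scale plot chosen to be
demographically realistic for a five-year remeasurement interval: 40
species on 200 m × 100 m (divisible by all five analysis scales), lognormal
abundances (meanlog log 150, sdlog 1; about 5–10 thousand stems), ~15%
mortality and ~15% recruitment, 30% shrub species, and per-species
dispersal scales lognormal around 8 m.  Stems are placed by a Thomas-type
cluster process (cluster scale = the species' dispersal scale,
torus-wrapped), DBH is lognormal (meanlog log 3 cm, sdlog 0.9, truncated
to 1–90 cm), survival is logistic in log DBH around a per-species baseline
(mean 0.85, logit sd 0.5), and recruits arise around surviving mature
conspecifics at exponential-kernel distances, with a 20% immigrant
fraction placed uniformly (echoing the substantial share of real recruits
with no mapped parent nearby).  Coordinates and DBH are recorded to 0.1,
the usual census precision.

Two optional forcings act on the logit of survival: habitat filtering
(penalty φ·|trait − env(x, y)| with the trait rank-scaled to [0, 1] and a
linear-gradient or Gaussian-patch environment; an option additionally
seeds the first census pre-sorted by habitat) and phylogenetic density
dependence (penalty δ scaled by the relatedness-weighted neighbour density
within a radius, weight 1 − d/d_max).  Filtering acts on mortality, not on
initial placement, so the first census is filter-neutral unless
pre-sorting is requested.  Every realized survival probability, parent
assignment and dispersal distance is kept in a truth record, which is what
the parameter-recovery tests check against.

What the generator does *not* emulate: growth (DBH is static between
censuses), multi-stem individuals, habitat-dependent recruitment, realistic
allometry, and the deep, unbalanced phylogenies of real floras (trees are
pure-birth).  Tests passing on synthetic data therefore demonstrate the
statistical machinery, not ecological realism.

## What the self-tests do and do not show

The distributional checks calibrate the machinery: K averages 1 under
Brownian motion (200 trees of 128 tips) and the tip-shuffle test rejects
at the nominal 5% on white noise; a census generated by NM-II's own
process standardizes to near-z-scores (|mean| < 0.15, sd in [0.8, 1.2]
over ≥ 150 quadrats, 499 replicates); the swap chain's long-run state
frequencies are uniform on an enumerable 4×4 state space; the SAR fit
recovers λ = 0.6 and β = −0.5 on a 20×20 lattice with correct interval
coverage, and its residuals pass the Moran permutation test that OLS
residuals fail.

The end-to-end direction checks are harder, and one is honest about them.
With strong density dependence (δ = 10 within 5 m), the SAR slope of
ses.RaoD on NRI at the finest scale is positive in roughly three-quarters
of replicates — the mechanism's direction, though short of the strict
80% bar the packaged check asserts.  With strong filtering the expected
negative slope does *not* emerge reliably at this desk scale: the mediating
correlations are present and stable (quadrat mismatch raises ses.RaoD;
quadrat mismatch lowers NRI), but they are weak, and idiosyncratic
clade-level variation between simulated floras dominates the slope.
Scaling experiments (up to 100 species on 400 m × 200 m) did not change
this, and the apparent fix — measuring NRI on the post-interval census —
is rejected for the neutrality-control reason given above.  We report the
filtering-direction check as it stands rather than weaken it; detecting
the filtering signature evidently needs the species richness, plot area
and trait conservatism of real forests rather than a desk-scale synthetic
flora.

## Problem sizes and numerics

Defaults follow the study design (499 turnover and NRI randomizations,
1000 tip shuffles, 999 Moran and selection permutations, scales 10–50 m).
The packaged self-tests scale some simulations down (199 shuffles in the
type-I study, 199 randomizations and 50 replicates in the direction
study, 200 SAR replicates) — sizes chosen so the whole suite runs in
minutes while keeping Monte-Carlo error well inside the asserted bands.
Numerical tie-breaks worth knowing: quadrat cells are half-open with the
plot's maximal boundaries clamped inward; partial edge strips are dropped,
not analyzed; SES denominators of exactly zero flag the quadrat rather
than producing infinities; the SAR λ search is bounded strictly inside
the reciprocal extreme eigenvalues of W; and PCNM axes are kept when
their eigenvalue exceeds 1e-8 of the spectral radius.
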