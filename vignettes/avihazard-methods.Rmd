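---
title: "Models and design choices in avihazard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in avihazard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`avihazard` analyses transect-based bird surveys around airports. This
vignette is the package's account of the science it implements: the
estimators and indices, the null model, the risk score, the synthetic-data
generator, and the places where the design was genuinely open and a choice
had to be made.

## Data model

The unit of observation is the *detection event*: one row per encounter,
so a flock of *k* birds is a single row with `count = k`. This granularity
is load-bearing — the flock-size index of the risk assessment divides a
species' individuals by its number of encounters, which is unrecoverable
from aggregated counts. Aggregation happens only when
`build_community_matrix()` sums counts into a species × assemblage matrix
(assemblage = transect, habitat, season, habitat × season, or
transect × season). Closed vocabularies (four habitats, four seasons, five
flight-height bands partitioning altitude as [0,5), [5,30), [30,50),
[50,100), [100,∞) m, inside/outside zone) are validated at read time with
the offending row named in the error.

Phylogenies are single rooted Newick trees with non-negative branch
lengths; polytomies and zero-length branches are legal, negative lengths
are not. Pruning keeps the requested tips and collapses degree-2 nodes,
summing merged branch lengths, so patristic distances among retained tips
are invariant (a property the tests check against brute-force path sums).

## Sampling adequacy

Richness comparisons are meaningless if assemblages were unequally
sampled, so the first stage asks how complete each sample is.

* Rarefaction uses the hypergeometric expectation
  $S(m) = S_{obs} - \sum_i \binom{n-x_i}{m}\big/\binom{n}{m}$, evaluated
  through `lchoose` so abundances in the thousands neither overflow nor
  lose precision. Exhaustive enumeration of subsamples (feasible for
  $n \le 12$) is the test oracle.
* Chao1 is $S_{obs} + f_1^2/(2 f_2)$, switching to the bias-corrected
  $S_{obs} + f_1(f_1-1)/2$ when doubletons are absent. Chao2 is the
  incidence analogue and carries the standard $(R-1)/R$ small-sample
  factor on the rarity term; users comparing against software without
  that factor should expect slightly smaller estimates here.
* Extrapolation beyond the observed sample size is anchored to Chao1:
  $S(n+m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n\hat f_0 + f_1))^{m^*}]$,
  continuous at $m = n$, flat when $f_1 = 0$, asymptoting to Chao1.
* Coverage is the Good–Turing estimate
  $\hat C = 1 - (f_1/n)\,(n-1)f_1/((n-1)f_1 + 2f_2)$. The abundance-based
  form is computed per assemblage column; an incidence-based variant is
  not provided.
* Accumulation curves enumerate all unit orderings exhaustively when a
  grouping has ≤ 7 sampling units (the mean is then exact and the sd band
  is the true permutation sd); above that, `n_perm` seeded random
  orderings are used.

## Dominance

$Y_i = 100\,N_i/N$; species with $Y \ge 10$ are dominant, boundary
inclusive. Because shares sum to 100, at most ten species can ever be
dominant — a useful sanity check on any report. Dominance is computed per
habitat community by default (a species × habitat matrix); any community
matrix works, so per-season dominance is one argument away.

## Functional and phylogenetic diversity

Four traits enter the functional space: body mass, hand-wing index (HWI, a
flight-ability proxy), diet, and vertical foraging stratum. Gower
dissimilarity averages range-normalized absolute differences (continuous)
and 0/1 mismatches (categorical). **Body mass is log-transformed before
the range normalization.** Bird masses span orders of magnitude; on the
raw scale the heaviest pair of species would absorb essentially the whole
mass component and all small-bird contrasts would vanish — log mass is the
standard choice throughout avian functional ecology and is treated here as
part of the metric, not an option. A continuous trait with zero observed
range contributes zero to every pair and triggers a warning rather than an
error, since degenerate synthetic inputs are legitimate.

Principal coordinates analysis is classical metric scaling: eigendecompose
the double-centred squared-distance matrix, keep axes with positive
eigenvalues. For exactly Euclidean inputs the embedding reproduces the
input distances to 1e-8 (a tested invariant). MFD uses Euclidean distances
in the full positive-eigenvalue PCoA space. The functional dendrogram is
UPGMA; by default it is built directly on the Gower matrix (the classic
Petchey–Gaston recipe), with `fd_space = "pcoa"` exposing the alternative
of clustering the PCoA-Euclidean distances. Merge heights are half the
average-linkage distance, so the dendrogram is ultrametric and its
cophenetic distances equal the average-linkage distances; ties merge the
lexicographically smallest label pair first, making output deterministic.

FD and PD share one spanning-subtree convention: the total branch length
of the minimal subtree connecting the community's tips, rooted at their
most recent common ancestor, with the path above the MRCA excluded.
Implementations in the wild differ on the root path and on singletons;
here the convention is explicit: singleton communities have FD = PD = 0,
and MFD/MPD (which divide by $n(n-1)$) are undefined for $n < 2$ and
returned as missing with a warning — never silently zero. Internally both
metrics reduce to one edge–tip incidence matrix per tree, so a community
(or a batch of null communities) is scored with a single matrix product.

## Null models and standardized effect sizes

The randomization holds species richness constant and draws communities
uniformly without replacement from the regional pool — equivalent to
shuffling species labels across the distance matrices. The pool is the
full study species list (every species observed in any assemblage); this
is the default because the shuffle is defined on the whole distance
matrix, and a restricted (e.g. per-season) pool can be passed explicitly.
The same subset-resampling null serves FD, PD, MFD and MPD, so the four
SES values are comparable. With
$SES = (M_{obs} - M_{exp})/SD_{exp}$, negative values indicate clustering
(environmental filtering), positive overdispersion (competitive
exclusion). Degenerate nulls — $SD_{exp} = 0$, as on a star phylogeny or
when the community equals the pool — yield an explicit "indeterminate"
result instead of an infinite or zero SES. Assemblages with fewer than two
species are skipped for MFD/MPD, with a logged message.

Each assemblage × metric combination gets its own seed derived from the
master seed, so results are independent of execution order and
reproducible one assemblage at a time. Small pools (≤ 8 species) are
checked against complete enumeration of all richness-matched subsets.

## The bird-strike risk index

Per species: $IV = (N + G + S + W)/4$ and $F = (H + D)/2$, $R = IV \cdot F$.

* $N$: individuals / individuals of the most abundant species × 100.
* $G$: average flock size (individuals per encounter) / maximum average
  flock size × 100. "Encounter frequency" is the number of detection
  records of the species — the reason the reader never merges rows.
* $S$: summed area of the habitat types the species was recorded in /
  total survey area × 100. Habitat-type areas, not per-species occupancy
  polygons, are used; with a GIS-free input format that is the only
  well-defined reading.
* $W$: body mass / maximum body mass × 100.
* $H$: the coefficient of the species' modal height band (0.1, 0.5, 1.0,
  0.5, 0.1 from lowest to highest band — peaking where approach and
  departure paths sit). When band frequencies tie, the larger coefficient
  wins: aggregation ambiguity is resolved toward higher risk.
* $D$: 0.5 with any inside-airport record, 0.1 otherwise.

$N$ is computed on year-round totals (no seasonal stratification), so one
assessment covers the survey. Tiers cut at 25/15/5 with the boundary
belonging to the higher tier. $R$ is bounded by 75 ($IV \le 100$,
$F \le 0.75$) and is monotone in every component. Report shares are
rounded half-up to two decimals (base R's round-half-to-even would
misreproduce printed report tables); unrounded values stay in the
per-species output.

Species present in the survey but missing from the trait table, or with no
height-band record at all, abort the assessment by default; an explicit
`allow_drop = TRUE` removes them with a logged message. Silent dropping
would corrupt both the risk normalizations and the null-model pools, so it
is never the default.

## Group comparisons

Kruskal–Wallis (via `stats::kruskal.test`, tie-corrected) on per-transect
or per-transect-season diversity values, grouped by habitat or season.
For pooled $n \le 8$ the chi-squared approximation is replaced by an exact
permutation p: every distinct assignment of the pooled values to the group
sizes is enumerated and scored. Complete ties (all values equal) return
$H = 0$, $p = 1$ rather than NaN. Post hoc pairwise Wilcoxon rank-sum
tests run only when the omnibus $p < 0.05$ (an override exists), use the
normal approximation with tie correction, report the standardized $z$
alongside $p$, and apply Bonferroni ($p_{adj} = \min(1, p \cdot
\#pairs)$) with flags at 0.05 and 0.01.

## The synthetic-data generator

The generator exists so that every stage — especially the null models —
can be tested against known ground truth. Its defaults describe one fixed
study design: a 148-species regional pool, 17 transects (urban 3,
farmland 5, forest 6, wetland 3), four seasonal visits.

* **Phylogeny**: Yule process, waiting time Exp(birth_rate · k) at k
  lineages, uniformly chosen splitter, cut at the moment the next
  speciation would occur — ultrametric with positive pendant edges, and
  an exact depth expectation ($\sum_{k=2}^{n} 1/(bk)$) the tests verify.
* **Traits**: log body mass and log HWI evolve by correlated Brownian
  motion (evolutionary correlation 0.7, mimicking avian allometry) with
  variance `trait_signal` per unit branch length; root states 80 g and
  HWI 25. Diet and stratum evolve by a slow symmetric 4-state Markov
  process (~0.75 expected changes per root-to-tip path), giving the
  phylogenetically conserved categorical traits real bird communities
  show.
* **Assembly**: species suitability for a habitat decays as
  $\exp(-F (z - opt_h)^2)$ on the standardized composite trait axis
  $z$ (the standardized sum of the two scaled continuous traits).
  Optima sit at the 15/38/62/85 % quantiles of the *realized* axis, so
  every niche window is populated no matter how the simulated traits fall.
  Suitabilities are normalized within each habitat to a constant expected
  occupancy (40 % of the pool, capped at 1) and realized as one Bernoulli
  inclusion draw per species × habitat: a habitat has a fixed species
  capacity, and filtering redistributes membership toward suited species
  instead of emptying the habitat. This keeps community richness roughly
  constant across filtering strengths, which is what makes the SES
  response to `filtering_strength` monotone rather than
  power-confounded. At `filtering_strength = 0` inclusion is uniform and
  independent of traits — the neutral case used for calibration.
* **Abundance and detection**: per-species lognormal abundance scale
  (meanlog −1.2, sdlog 2: strongly right-skewed, a few very common
  species), independent of traits. Encounters are Poisson with mean
  scaled by the species' mean flock size; flock sizes are zero-truncated
  geometric with a lognormal across-species tendency (most species
  near-solitary, a few strongly flocking); each encounter is detected
  whole with probability `detection_rate` (0.8). At detection 1 the
  survey total equals the drawn abundance exactly.
* **Risk attributes**: preferred height bands follow body-mass rank with
  ~70 % of species in the lowest band; 20 % of species use the airport
  interior, and such a species' first record is forced inside so the zone
  flag determines its coefficient deterministically.

These defaults were chosen once to reproduce the scale of a real
year-round airport survey — several thousand individuals, per-habitat
coverage above 0.95, habitat richness well below the pool, and a risk-tier
profile dominated by low-risk species — and are not tuning knobs.

What the generator deliberately does *not* emulate: migration phenology
(seasons are exchangeable replicates, not a winter influx), spatial
autocorrelation among transects, observer error and double counting,
interannual variation, and any real species list. Passing calibration on
these simulations therefore demonstrates that the estimators and null
models behave correctly under their assumptions — not that any particular
field system satisfies those assumptions.

## Calibration properties

Under neutral assembly (filtering 0; 100-species pools, 20 transects, 199
null draws, 100 habitat communities) the SES distributions of FD, PD, MFD
and MPD are centred near 0 with standard deviation near 1. Under strong
filtering (strength 10) SES.MFD is negative in over 90 % of habitat
communities, and its median decreases monotonically across strengths
{0, 2, 10}. The test suite recomputes all of this at exactly those sizes;
they were chosen as the smallest design at which the neutral-calibration
standard error is comfortably inside the tolerance bands.

## Numerical choices and degenerate inputs

Log-gamma binomial coefficients throughout rarefaction; symmetric
eigendecomposition with an eigenvalue tolerance of 1e-9 × the spectral
radius in PCoA; UPGMA tie-breaks by label order; SES undefined (not 0)
when $SD_{exp} = 0$; coverage returns its formula limit 1 with a warning
for $n = 1$; empty assemblages, all-zero abundance vectors, vocabulary
violations and duplicated species are errors that name the offender.

## Limitations

The risk index is ordinal, not probabilistic — it ranks species by
plausible hazard, it does not estimate strike probability. The spatial
index inherits the coarseness of habitat-type areas. The null model holds
richness but not abundance structure; abundance-weighted MPD variants and
alternative swap algorithms are out of scope. MFD/MPD for
single-species assemblages are undefined by construction, so sparse
habitats contribute fewer SES values than rich ones.
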