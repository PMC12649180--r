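# avihazard

Avian community diversity and airport bird-strike hazard assessment.

Bird collisions with aircraft cluster at take-off and landing altitudes, and
the species that matter — large, flocking, mid-altitude birds active inside
the airfield — are rarely the most abundant ones. `avihazard` implements the
full analysis chain used in transect-based airport bird surveys: it reads
detection-event records (species, transect, habitat, season, flock size,
flight-height band, inside/outside-airport zone), checks sampling adequacy,
characterises community structure taxonomically, functionally and
phylogenetically, tests whether that structure departs from random assembly,
and scores every species on a composite strike-risk index with a four-tier
classification. A synthetic-data generator with known ground truth (Yule
phylogenies, Brownian traits, habitat-filtered occurrences) makes every
stage testable end to end.

It is written for ecologists and airport wildlife managers who work in R;
the API follows the conventions of `vegan`, `picante` and `ape` (plain data
frames, matrices, and `phylo` objects).

## The methods at the core

**Sampling adequacy.** Species accumulation curves (exhaustive ordering
enumeration for ≤ 7 units, permutation means otherwise), rarefaction
S(m) = S_obs − Σᵢ C(n−xᵢ, m)/C(n, m) computed via log-gamma,
Chao1 = S_obs + f₁²/(2f₂) (bias-corrected form when f₂ = 0), Chao2 with the
(R−1)/R small-sample factor, Chao1-anchored extrapolation, and the
Good–Turing sample coverage Ĉ = 1 − (f₁/n)·(n−1)f₁/((n−1)f₁ + 2f₂).

**Dominance.** Y = 100·Nᵢ/N per species; Y ≥ 10 % defines a dominant
species (boundary inclusive).

**Diversity.** Gower distances over four functional traits (log body mass,
hand-wing index, diet, vertical stratum) → principal coordinates analysis →
UPGMA functional dendrogram; FD is the dendrogram subtree length spanning a
community (Petchey–Gaston), PD is Faith's phylogenetic diversity (same
MRCA-rooted spanning-subtree convention), and MFD/MPD are abundance-unweighted
mean pairwise distances, MFD or MPD = Σ_{i≠j} δ(i,j) / (n(n−1)), with δ
Euclidean in PCoA trait space (MFD) or patristic on the tree (MPD).

**Null models.** Richness-constrained randomization: each community is
compared with communities of identical richness drawn uniformly from the
regional pool (999 draws by default), and
SES = (M_obs − M_exp)/SD_exp; SES < 0 indicates functional or phylogenetic
clustering (environmental filtering), SES > 0 overdispersion.

**Risk index.** Per species, R = IV × F with
IV = (N + G + S + W)/4 — normalized abundance, flock-size, spatial
distribution, and body-mass indices (0–100) — and F = (H + D)/2, where H is
the flight-height coefficient (0.1/0.5/1.0/0.5/0.1 for bands 0–5, 5–30,
30–50, 50–100, > 100 m) and D the activity-zone coefficient (0.5 if ever
recorded inside the airport, 0.1 otherwise). Tiers: R ≥ 25 extremely high,
15 ≤ R < 25 high, 5 ≤ R < 15 moderate, R < 5 low.

**Comparisons.** Kruskal–Wallis across habitats/seasons on per-transect
diversity values (exact permutation p for pooled n ≤ 8), gated pairwise
Wilcoxon rank-sum post hocs with Bonferroni correction.

## Worked example

```r
library(avihazard)

cfg <- sim_config(n_species = 40,
                  n_transects = c(urban = 2, farmland = 2,
                                  forest = 2, wetland = 2),
                  seed = 42)
ds <- simulate_dataset(cfg)          # tree, traits, survey, areas

comm <- build_community_matrix(ds$survey, "habitat")
adequacy_table(comm)
#>   assemblage species abundance  coverage chao1
#> 1   farmland      10       311 0.9968052  10.5
#> 2     forest      12       560 1.0000000  12.0
#> 3      urban      10       618 1.0000000  10.0
#> 4    wetland       4       249 1.0000000   4.0
```

Coverage near 1 says the (simulated) survey detected essentially every
species present; Chao1 barely exceeds the observed richness, so little
remains unseen. Risk assessment:

```r
risk <- assess_risk(ds$survey, ds$traits, ds$areas)
head(risk, 3)
#>    species_id       N    G     S     W   IV    F    R           tier
#> 15      sp026   1.473 30.6  9.95 100.0 35.5 0.75 26.6 extremely_high
#> 12      sp022 100.000 62.2 70.15  22.4 63.7 0.30 19.1           high
#> 21      sp038   0.268 44.4 46.77  46.3 34.4 0.55 18.9           high
risk_report(risk)
#>             tier count share
#> 1 extremely_high     1  4.76
#> 2           high     3 14.29
#> 3       moderate     6 28.57
#> 4            low    11 52.38
```

The top-risk species is rare (N = 1.5) but is the heaviest in the community
(W = 100), flies in the 30–50 m band and uses the airport interior
(F = 0.75) — exactly the profile that a pure abundance ranking would miss.
Community assembly:

```r
st <- community_structures(ds$traits, ds$tree, rownames(comm))
ses_table(comm, st, metrics = "MPD", n_iter = 999, seed = 1)
#>   assemblage metric M_obs M_exp SD_exp    SES interpretation
#> 1   farmland    MPD  4.21  4.52  0.184 -1.697      clustered
#> 2     forest    MPD  4.55  4.52  0.142  0.172  overdispersed
#> 3      urban    MPD  4.45  4.52  0.183 -0.359      clustered
#> 4    wetland    MPD  4.26  4.52  0.466 -0.555      clustered
```

Negative SES: those habitat communities hold species more closely related
than richness-matched random draws from the regional pool — the signature
of environmental filtering.

`run_pipeline()` chains all stages (adequacy → dominance → diversity →
SES → risk → comparisons) and writes one CSV per stage plus a run manifest;
outputs are byte-identical under the same configuration and seed.

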