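---
title: "Probabilistic functional connectivity in amphibian pondscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic functional connectivity in amphibian pondscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondscape)
```

## The problem

Pond-breeding amphibians live as metapopulations spread over networks of
small breeding ponds ("pondscapes"). Their persistence depends on functional
connectivity — the actual movement of individuals among ponds — yet
amphibian dispersal is infrequent, hard to observe, and highly variable both
between and within species: most individuals move short distances while a
small fraction performs rare long-distance dispersal. Binary connectivity
models built from a single maximum-dispersal threshold discard exactly this
variability. This package implements the probabilistic alternative: each
pond pair is connected with a probability taken from a species-specific
dispersal kernel fitted to systematically recorded capture–recapture
movements, and every pond's contribution to network-wide connectivity is
quantified on the resulting weighted graph.

The workflow has four stages, each usable on its own:

1. **Encounters** — raw field records (individual, species, sex, date,
   coordinates) are associated with ponds, compiled into capture histories,
   and scanned for movements between consecutive captures.
2. **Abundance** — per-pond population sizes are estimated with
   open-population Jolly–Seber models in the POPAN (superpopulation)
   formulation, with stepwise AICc model selection and model averaging.
3. **Kernels** — movement distances are fitted with lognormal and Weibull
   distributions; the lower-AIC family provides the dispersal kernel.
4. **Graphs** — a saturated probabilistic graph over all ponds yields the
   probability of connectivity (PC), per-pond importance (dPC and its
   fractions), betweenness, walktrap clusters, spanning trees and a
   community-level importance index.

## The POPAN model

Let a species' superpopulation at a pond (or in the study area) contain $N$
individuals. Individual presence is governed by three sets of parameters
over sampling occasions $t = 1, \dots, T$:

* $pent_b$ — probability of entering the sampled population just before
  occasion $b$, with $\sum_b pent_b = 1$;
* $\phi_t$ — apparent survival across the interval $(t, t+1)$;
* $p_t$ — detection probability at occasion $t$ while present.

The probability of an observed capture history $\omega$ sums over all
feasible entry occasions $b \le f(\omega)$ and departure occasions
$d \ge l(\omega)$ (first and last detections):

$$P(\omega) = \sum_{b \le f} \sum_{d \ge l} pent_b
  \prod_{t=b}^{d-1} \phi_t \; \delta_d
  \prod_{t=b}^{d} p_t^{\omega_t} (1 - p_t)^{1 - \omega_t},$$

where $\delta_d = 1 - \phi_d$ for $d < T$ and $1$ for $d = T$. The
$N - n$ never-detected animals contribute the all-zero history probability,
and the full likelihood carries the multinomial coefficient over distinct
histories. The test suite verifies this likelihood against exhaustive
enumeration of every latent (entry, departure, detection) configuration on
small problems ($T \le 3$, $N \le 5$) to $10^{-10}$.

Each of $\phi$, $p$ and $pent$ can be constant, time-, sex-, additively or
interactively structured; $\phi$ and $p$ use logit links, $pent$ a
multinomial-logit link with the first occasion as reference, and each
group's $N$ is estimated as $n + e^\theta$. A time-constant $pent$ is
excluded a priori: breeding amphibians enter ponds in seasonal pulses, not
at a flat rate. Stepwise selection fixes the best-AICc structure for
$\phi$, then $p$, then $pent$, and abundance is the AICc-weighted model
average of $N$ (the best model alone when its weight reaches 0.99 — the
"close to one" cut-off is configurable since no canonical value exists).

Numerical choices worth knowing:

* Optimization is quasi-Newton (BFGS) from three deterministic starting
  points plus a restart polish; `reltol` is $10^{-12}$.
* Log-probability terms are clamped at $-745$ (the smallest representable
  magnitude) so boundary values like $p = 1$ stay in finite arithmetic;
  with perfect detection the estimate collapses to $\hat N = n$ as it
  should.
* The AICc effective sample size is the number of distinct individuals, a
  common mark–recapture convention that must be stated because it is not
  universal.
* Multiplicity invariance ("doubling every history leaves rate estimates
  unchanged") holds only to first order for the unconditional likelihood
  with continuous $N$: the combinatorial term is not homogeneous in $n$.
  The test suite asserts it at 2%.

**The proxy rule.** Ponds where fewer than 8% of individuals were ever
recaptured do not support capture–recapture estimation; there the count of
distinct (photoidentified) individuals stands in as a conservative but
internally comparable abundance. Pond-level model fits default to
`{constant, time}` structures: pond-level histories rarely identify sex- or
interaction-structured models, and a failed saturated fit would silently
push ponds back to the proxy count.

## Dispersal kernels and edge probabilities

Distances of detected movements (consecutive captures of the same
individual at different locations) are fitted by maximum likelihood with
lognormal and Weibull distributions — two fat-tailed families that
accommodate the rare long-distance tail. The family with the lower AIC is
selected; a difference below 2 is flagged inconclusive, and an exact tie
resolves deterministically to lognormal. Fewer than three positive
distances mean no kernel: the species is reported with summaries only.

The kernel enters the graph through its survival function
$S(d) = 1 - F(d)$: the probability that a displacement reaches at least
distance $d$. The transform from kernel to edge probability is a genuine
design choice — the density and the binned interval mass are also offered
behind a switch — but the survival function is the default because it is
bounded in $[0,1]$, equals 1 at $d = 0$, decreases monotonically, and is
standard in probabilistic connectivity analysis.

## The pond graph and its metrics

Every pond pair is connected (a saturated graph) with probability
$p_{ij} = S(d^{\mathrm{eff}}_{ij})$. The effective distance is Euclidean,
**doubled** when the straight segment between the ponds crosses the road an
odd number of times — a barrier resistance expressed as a length
multiplier. The crossing test is odd-parity segment–polyline intersection;
a segment touching a road vertex exactly counts once per adjacent road
segment, a measure-zero ambiguity documented rather than special-cased.

Path "length" is the product of edge probabilities, maximized over paths;
computation uses additive shortest paths under $-\log p$, an exact algebraic
equivalence. Edges with $p < 10^{-12}$ are treated as absent to avoid
infinite lengths. The product metric penalizes stepping-stones: two hops of
0.6 (product 0.36) lose to a direct 0.5.

With node attributes $a_k$ (estimated population sizes) and
$A_L = \sum_k a_k$:

$$PC = \frac{\sum_i \sum_j a_i a_j \, p^*_{ij}}{A_L^2},$$

over all ordered pairs including $i = j$ with $p^*_{ii} = 1$. Removing node
$k$ and recomputing with $A_L$ **held fixed** gives
$dPC_k = 100\,(PC - PC^{-k})/PC$, which decomposes additively into

* $dPCintra_k = 100\, a_k^2 / (A_L^2 PC)$ — the pond's own population mass;
* $dPCflux_k = 100 \cdot 2 \sum_{j \ne k} a_k a_j p^*_{kj} / (A_L^2 PC)$ —
  attribute-weighted dispersal flux through its connections;
* $dPCconnector_k$ — the remainder: the pond's stepping-stone role inside
  other pairs' best paths.

Holding $A_L$ fixed during removal is what keeps the three fractions
summing exactly to $dPC_k$ (verified to $10^{-9}$ on random graphs in the
tests). Stepping-stone importance is additionally measured by weighted
betweenness with edge length $1/p_{ij}$ (fractional counting over tied
shortest paths, relative tolerance $10^{-12}$), network fragmentation by
walktrap clustering on the probability-weighted graph (random-walk length 4,
the algorithm's conventional default; partition cut at maximum weighted
modularity), and the most probable acyclic backbone by the spanning tree
minimizing total $-\log p$. Shortest paths, betweenness, walktrap and MST
are delegated to igraph and are cross-checked in the test suite against
hand-written exhaustive-enumeration oracles on all graphs with up to 7
nodes.

The community index scales each species' pond abundances by the species'
global maximum (an everywhere-absent species contributes zero) and sums the
scaled values per pond, giving a richness-and-abundance prioritization score
between 0 and the number of species. Max-scaling is the default; min–max
and z-score variants are available because "scaled" is convention-dependent.

## The synthetic pondscape

Because systematically collected amphibian movement datasets are rare, the
package ships a generative counterpart of the whole estimation chain, used
by every downstream test:

* ~64 ponds placed uniformly on a 3000 × 2500 m extent split by a
  north–south road into western and eastern sectors;
* per-species superpopulations entering over sessions under known
  $(pent, \phi, p, N)$ — defaults of $\phi = 0.85$, $p = 0.4$ for the
  aquatic-frog archetype and $\phi = 0.75$, $p = 0.3$ for the terrestrial
  toad, with pulsed entry;
* relocations between consecutive sessions with per-interval probability
  `move_prob` (0.14 and 0.39 for the two archetypes, matching the
  contrast between aquatic and terrestrial species); the destination is the
  pond nearest to a point at a kernel-drawn distance along a uniform random
  bearing. Default kernels are lognormal with medians of about 130 m and
  45 m.

One global seed drives everything; per-species substreams are derived
deterministically so adding a species does not perturb the others.

What the simulator does **not** emulate — and hence what green tests do not
certify about field data: terrestrial (off-pond) encounters, natal
(juvenile) dispersal, road mortality, within-season migration versus true
dispersal (every inter-pond relocation counts as a movement event, matching
the operational definition used in the field), detection heterogeneity
between individuals, and hydroperiod dynamics. One consequence visible in
the walkthrough: displacements shorter than the pond spacing snap back to
the origin pond, so observed movement medians exceed the kernel medians and
short-moving species lose proportionally more movements — a coarsening that
real pond networks impose on pond-associated records too.

## Problem sizes and runtime choices

The validation suite favours many small exactly-checkable problems over few
large ones: likelihood oracles run at $T \le 3$ and $N \le 5$ where
exhaustive enumeration is exact; parameter recovery uses 100 replicates of
an 8-session, $N = 600$ design; graph oracles enumerate all simple paths
and spanning trees on graphs of 4–7 nodes (100 seeds); walktrap recovery
uses 20 planted 3-block graphs. The analysis walkthrough
(`analysis/01_simulate.R` … `06_community.R`) runs the full pipeline on the
default 64-pond, two-species, 8-session pondscape; its pooled model table
uses main-effect structures, leaving the time-by-sex interaction models to
users with a reason to fit them.

## Known limitations

* POPAN confounding of first/last $pent \cdot p$ in fully time-dependent
  models is accepted, as in standard practice; only $N$ is reported from
  such models.
* Goodness-of-fit testing (transience/trap-dependence contingency tests) is
  out of scope; on real data it should precede model selection.
* Pond polygons, resistance rasters and least-cost paths are out of scope;
  the road rule is the only landscape resistance.
* The movement-frequency denominator follows the stated operational
  definition (movements / recaptures); alternative conventions are exposed
  via `freq_denominator` because published tables are not always
  reconstructible from a single convention.
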