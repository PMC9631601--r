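# pondscape

Probabilistic functional-connectivity analysis for pond-breeding amphibian
metapopulations, from raw capture–recapture field records to per-pond
conservation priorities.

Amphibians persist in landscapes as networks of breeding ponds connected by
infrequent, highly variable dispersal. Classical graph models connect two
ponds whenever their distance falls below a single maximum-dispersal
threshold, discarding that variability. `pondscape` instead treats dispersal
as a probability: each pond pair is connected with the probability that an
individual's displacement — drawn from a species-specific kernel fitted to
observed movements — covers the distance between them, with road barriers
expressed as doubled effective distance. On the resulting weighted graph the
package quantifies what every pond contributes to metapopulation
connectivity.

## What it computes

* **Encounter handling** — pond assignment within a 10 m association
  radius, capture-history construction, movement detection from consecutive
  captures, and survey-style per-species summaries
  (`assign_to_ponds`, `build_capture_histories`, `detect_movements`,
  `summarize_species`).
* **Abundance** — open-population Jolly–Seber (POPAN / superpopulation)
  estimation written from the likelihood up: structures over time and sex
  for survival Φ, capture probability p and entry probability pent, stepwise
  AICc selection, model averaging, and the 8%-recaptured proxy rule for
  sparse ponds (`fit_popan`, `stepwise_select`, `model_average_N`,
  `choose_abundance`).
* **Dispersal kernels** — maximum-likelihood lognormal and Weibull fits,
  AIC family selection with the ΔAIC < 2 inconclusiveness rule, and the
  survival-function edge-probability transform
  (`fit_kernel`, `select_kernel`, `dispersal_probability`, `tukey_hsd`).
* **Connectivity graphs** — saturated probabilistic graphs; probability of
  connectivity PC = Σᵢⱼ aᵢaⱼp*ᵢⱼ / A_L²; per-pond importance
  dPC_k = dPCintra_k + dPCflux_k + dPCconnector_k; maximum-product shortest
  paths; inverse-probability betweenness; walktrap clusters;
  maximum-probability spanning trees; movement graphs
  (`build_graph`, `node_importance`, `betweenness_centrality`,
  `walktrap_clusters`, `minimum_spanning_tree`, `movement_graph`).
* **Community index** — per-species abundances scaled globally and summed
  per pond (`community_index`), and an end-to-end driver (`run_pipeline`).
* **Synthetic pondscapes** — a generative counterpart of the whole chain
  (ponds, road, POPAN population dynamics, kernel-drawn relocations) with
  retained ground truth, so every estimator is tested against the values
  that generated its data (`simulate_dataset` and friends).

## A worked example

```r
library(pondscape)

# a 12-pond synthetic pondscape split by a road, one frog-like species
spec <- pondscape_spec(n_ponds = 12, extent = c(0, 1500, 0, 1200),
                       road = cbind(c(750, 750), c(-50, 1250)), seed = 42)
scape <- generate_pondscape(spec)
pars <- list(species_sim_params(
  "frog", setNames(rep(40, 12), scape$ponds$id),
  phi = 0.85, p_capture = 0.5, pent = c(0.5, 0.3, 0.2, 0, 0, 0),
  kernel_params = c(meanlog = log(250), sdlog = 0.6), move_prob = 0.3))
ds <- simulate_dataset(spec, pars, n_sessions = 6, seed = 42)

records <- assign_to_ponds(ds$records, ds$ponds, radius = 10)
moves <- detect_movements(records)
summarize_species(records, moves, n_monitored_ponds = 12)[
  , c("n_individuals", "n_recaptures", "n_movements", "median_movement_m")]
#>   n_individuals n_recaptures n_movements median_movement_m
#> 1           406          463          91          280.1134

# abundance at the best-sampled pond: enough recaptures for POPAN
pid <- names(sort(table(records$pond_id), decreasing = TRUE))[1]
choose_abundance(records[records$pond_id == pid, ])[c("a", "method")]
#> $a
#> [1] 60.64167
#> $method
#> [1] "popan"

# dispersal kernel and the probabilistic graph
sel <- select_kernel(moves$distance)
sel
#> Selected weibull kernel (delta AIC = 1.06, inconclusive)
a <- sapply(split(records$individual_id, records$pond_id),
            function(x) length(unique(x)))[ds$ponds$id]
g <- build_graph(ds$ponds, sel$best, road = ds$road, a = unname(a))
ni <- node_importance(g)
ni$betweenness <- betweenness_centrality(g)[ni$id]
head(ni[order(-ni$dPC), c("id", "a", "dPC", "dPCintra", "dPCflux",
                          "dPCconnector", "betweenness")], 3)
#>     id  a      dPC dPCintra  dPCflux dPCconnector betweenness
#> 9  P09 50 28.04507 3.959409 23.44568    0.6399846          28
#> 12 P12 42 27.31333 2.793759 20.96918    3.5503884           0
#> 4  P04 43 25.35211 2.928379 19.56850    2.8552271           9
attr(ni, "PC")
#> [1] 0.256653
walktrap_clusters(g)$n_clusters
#> [1] 3
```

Reading the output: removing pond P09 would cost the network 28% of its
probability of connectivity — mostly through lost dispersal flux
(`dPCflux`), since it is both populous and well connected, while its
stepping-stone role (`dPCconnector`) is small; its betweenness of 28 marks
it as lying on many of the most probable movement routes. With only 91
observed movements the Weibull/lognormal choice is inconclusive (ΔAIC
1.06 < 2), which the selection object reports rather than hides.

## The analysis walkthrough

`analysis/01_simulate.R` … `analysis/06_community.R` run the full study on
the default 64-pond, two-species pondscape: simulation with ground truth,
survey summaries and Tukey distance comparisons, per-pond POPAN/proxy
abundances with model tables, kernel fitting with exported survival curves,
per-species connectivity graphs (dPC decomposition, betweenness, clusters,
spanning trees), and the community importance index. Each step prints what
it found and writes its tables under `results/`.

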