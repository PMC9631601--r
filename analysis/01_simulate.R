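#!/usr/bin/env Rscript
# Step 1: generate the synthetic study pondscape and encounter dataset.
#
# 64 temporary ponds on a 3000 x 2500 m dehesa-like extent split by a
# north-south road; two contrasting species (an aquatic frog with long,
# infrequent movements and a terrestrial toad with short, frequent ones)
# monitored over 8 sampling sessions. Ground truth (superpopulations,
# kernels, relocation ledger) is kept as sidecar files so later steps can be
# judged against the generating values.

library(pondscape)

seed <- 20190313
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- default_pondscape_spec(seed = seed)
scape <- generate_pondscape(spec)
pars <- default_species_params(scape$ponds$id, n_sessions = 8, mean_n = 30,
                               seed = seed)
ds <- simulate_dataset(spec, pars, n_sessions = 8, seed = seed)

write_encounters_csv(ds$records, file.path(out, "encounters.csv"))
write_ponds_geojson(ds$ponds, file.path(out, "ponds.geojson"))
writeLines(sprintf("LINESTRING (%s)",
                   paste(sprintf("%g %g", spec$road[, 1], spec$road[, 2]),
                         collapse = ", ")),
           file.path(out, "road.wkt"))

truth_n <- do.call(rbind, lapply(names(ds$truth), function(sp) {
  npp <- ds$truth[[sp]]$params$superpopulation_per_pond
  data.frame(species = sp, pond_id = names(npp), true_N = as.integer(npp))
}))
write.csv(truth_n, file.path(out, "truth_abundance.csv"), row.names = FALSE)
truth_mv <- do.call(rbind, lapply(names(ds$truth), function(sp) {
  led <- ds$truth[[sp]]$relocations
  if (nrow(led)) cbind(species = sp, led) else NULL
}))
write.csv(truth_mv, file.path(out, "truth_relocations.csv"), row.names = FALSE)

cat(sprintf("Simulated %d encounter records of %d species across %d ponds\n",
            nrow(ds$records), length(pars), nrow(ds$ponds)))
cat(sprintf("Sector split: %s\n",
            paste(sprintf("%s=%d", names(table(ds$ponds$sector)),
                          table(ds$ponds$sector)), collapse = ", ")))
for (sp in names(ds$truth)) {
  cat(sprintf("  %s: true superpopulation %d, %d true relocations\n", sp,
              sum(ds$truth[[sp]]$params$superpopulation_per_pond),
              nrow(ds$truth[[sp]]$relocations)))
}
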