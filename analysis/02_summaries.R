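#!/usr/bin/env Rscript
# Step 2: capture and movement summaries per species (survey-table style),
# movement detection from consecutive captures, and a Tukey comparison of
# movement distances between species.

library(pondscape)

dat <- "results/data"
records <- read_encounters_csv(file.path(dat, "encounters.csv"))
ponds <- read_ponds_geojson(file.path(dat, "ponds.geojson"))

records <- assign_to_ponds(records, ponds, radius = 10)
records$sector <- ponds$sector[match(records$pond_id, ponds$id)]

summaries <- list()
all_moves <- list()
for (sp in sort(unique(records$species))) {
  rec <- records[records$species == sp, ]
  mv <- detect_movements(rec)
  all_moves[[sp]] <- mv
  summaries[[sp]] <- summarize_species(rec, mv, nrow(ponds))
}
summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))
write.csv(summaries, "results/species_summaries.csv", row.names = FALSE)
moves <- do.call(rbind, c(all_moves, make.row.names = FALSE))
write.csv(moves, "results/movements.csv", row.names = FALSE)

cat("Per-species capture and movement summary:\n")
print(summaries, row.names = FALSE)

# do the two species differ in mean movement distance?
tk <- tukey_hsd(moves$distance, moves$species)
cat("\nTukey comparison of raw movement distances:\n")
print(tk, row.names = FALSE)
cat(sprintf("\n%d movement events detected in total. Observed distances are\n",
            nrow(moves)))
cat("coarsened by the pond network: displacements shorter than the typical\n")
cat("pond spacing snap back to the origin pond and go undetected, so\n")
cat("realized medians sit above the kernel medians and the short-moving\n")
cat("species loses proportionally more of its movements.\n")
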