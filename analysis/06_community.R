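#!/usr/bin/env Rscript
# Step 6: community importance index. Per-species pond abundances are scaled
# by their global maximum and summed per pond, combining species richness and
# relative population size into a single prioritization score.

library(pondscape)

abund <- read.csv("results/pond_abundances.csv")
species <- sort(unique(abund$species))
ponds <- sort(unique(abund$pond_id))
m <- matrix(0, length(species), length(ponds),
            dimnames = list(species, ponds))
for (i in seq_len(nrow(abund))) {
  m[abund$species[i], abund$pond_id[i]] <- abund$a[i]
}
ci <- community_index(m)
ci <- ci[order(-ci$index), ]
write.csv(ci, "results/community_index.csv", row.names = FALSE)

cat(sprintf("Community index over %d ponds and %d species (range 0..%d):\n",
            length(ponds), length(species), length(species)))
print(head(ci, 8), row.names = FALSE)
cat("\nPonds scoring high host large populations of several species at once;\n")
cat("they are the natural priorities for protection or restoration.\n")
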