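#!/usr/bin/env Rscript
# Step 3: per-pond abundance estimates. Ponds with at least 8% of individuals
# recaptured get a POPAN (Jolly-Seber superpopulation) estimate with stepwise
# AICc selection and model averaging; sparser ponds fall back to the count of
# photoidentified individuals as a comparable proxy. A pooled-population
# stepwise selection per species illustrates the model table.

library(pondscape)

dat <- "results/data"
records <- read_encounters_csv(file.path(dat, "encounters.csv"))
ponds <- read_ponds_geojson(file.path(dat, "ponds.geojson"))
records <- assign_to_ponds(records, ponds, radius = 10)
truth <- read.csv(file.path(dat, "truth_abundance.csv"))

abund <- list()
model_tables <- list()
for (sp in sort(unique(records$species))) {
  rec <- records[records$species == sp, ]
  # pooled stepwise selection for the model table; main effects only here —
  # the time-by-sex interaction models are supported but add dozens of
  # parameters for no narrative gain on this walkthrough dataset
  ch <- build_capture_histories(rec, min_captures = 1)
  sel <- stepwise_select(ch, structures = c("constant", "time", "sex"))
  model_tables[[sp]] <- cbind(species = sp, sel$table)
  avg <- model_average_N(sel)
  true_total <- sum(truth$true_N[truth$species == sp])
  cat(sprintf("%s: pooled model-averaged N = %.0f (true %d); best model %s\n",
              sp, avg$N_total, true_total, format(sel$best$spec)))
  # per-pond abundances under the proxy rule
  a <- setNames(rep(0, nrow(ponds)), ponds$id)
  methods <- character(0)
  for (pid in unique(rec$pond_id[!is.na(rec$pond_id)])) {
    est <- choose_abundance(rec[!is.na(rec$pond_id) & rec$pond_id == pid, ])
    a[pid] <- est$a
    methods[pid] <- est$method
  }
  cat(sprintf("  pond-level: %d POPAN estimates, %d count proxies\n",
              sum(methods == "popan"), sum(methods == "count")))
  abund[[sp]] <- data.frame(species = sp, pond_id = names(a),
                            a = as.numeric(a),
                            method = methods[names(a)] ,
                            stringsAsFactors = FALSE)
}
abund <- do.call(rbind, c(abund, make.row.names = FALSE))
abund$method[is.na(abund$method)] <- "none"
write.csv(abund, "results/pond_abundances.csv", row.names = FALSE)
mt <- do.call(rbind, c(model_tables, make.row.names = FALSE))
write.csv(mt, "results/popan_model_tables.csv", row.names = FALSE)

merged <- merge(abund, truth, by = c("species", "pond_id"))
r <- cor(merged$a, merged$true_N)
cat(sprintf("\nPond-level abundance vs truth: r = %.2f over %d species-ponds\n",
            r, nrow(merged)))
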