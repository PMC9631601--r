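# Shared fixture builders (all data generated in code).

# A 64-pond registry: 32 western ponds on x = 100, 32 eastern on x = 2900,
# spread vertically; sector labels explicit.
fixture_ponds_64 <- function() {
  data.frame(
    id = sprintf("P%02d", 1:64),
    x = rep(c(100, 2900), each = 32),
    y = rep(seq(50, 2450, length.out = 32), times = 2),
    sector = rep(c("W", "E"), each = 32),
    stringsAsFactors = FALSE)
}

# Survey-style records for one species: n_ind individuals, the first n_west
# first-captured on the western sector, occupying the first n_used ponds
# round-robin.
fixture_species_records <- function(species, n_ind, n_west, n_used,
                                    ponds = fixture_ponds_64()) {
  used <- ponds$id[seq_len(n_used)]
  pond_id <- rep(used, length.out = n_ind)
  sector <- c(rep("W", n_west), rep("E", n_ind - n_west))
  data.frame(
    individual_id = sprintf("%s_%04d", species, seq_len(n_ind)),
    species = species,
    sex = rep(c("M", "F"), length.out = n_ind),
    date = as.Date("2019-04-01") + seq_len(n_ind) %% 20,
    session = 1L + seq_len(n_ind) %% 4,
    x = ponds$x[match(pond_id, ponds$id)],
    y = ponds$y[match(pond_id, ponds$id)],
    pond_id = pond_id,
    sector = sector,
    stringsAsFactors = FALSE)
}

# Dense pond grid where a kernel-scale displacement almost surely lands
# nearer another pond: used for relocation-rate checks.
fixture_grid_spec <- function(seed = 1L) {
  pondscape_spec(n_ponds = 100, extent = c(0, 2000, 0, 2000),
                 road = NULL, seed = seed)
}

# One-pond closed-population simulation + constant-model POPAN fit.
sim_popan_dataset <- function(seed, N = 600, phi = 0.85, p = 0.4,
                              n_sessions = 8, pent = NULL) {
  if (is.null(pent)) pent <- rep(1 / n_sessions, n_sessions)
  par <- species_sim_params("sp", c(A = N), phi = phi, p_capture = p,
                            pent = pent, move_prob = 0)
  pop <- simulate_population(par, n_sessions, seed = seed)
  det <- pop$detections
  data.frame(
    individual_id = det$individual_id,
    species = "sp",
    sex = pop$individuals$sex[match(det$individual_id, pop$individuals$id)],
    date = as.Date("2019-03-01") + 14 * (det$session - 1),
    session = det$session,
    stringsAsFactors = FALSE)
}
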