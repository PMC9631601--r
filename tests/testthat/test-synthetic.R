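# Synthetic pondscape and population simulator.

test_that("pondscape generation places ponds deterministically and partitions by road", {
  spec <- default_pondscape_spec(seed = 11)
  a <- generate_pondscape(spec)
  b <- generate_pondscape(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$ponds), 64)
  expect_true(all(a$ponds$sector %in% c("W", "E")))
  expect_equal(sum(table(a$ponds$sector)), 64)
  expect_true(all(a$ponds$x >= 0 & a$ponds$x <= 3000))
  # single pond, any road: one sector
  one <- generate_pondscape(pondscape_spec(1, c(0, 10, 0, 10),
                                           road = cbind(c(5, 5), c(-1, 11))))
  expect_equal(nrow(one$ponds), 1)
  expect_true(one$ponds$sector %in% c("W", "E"))
  # vertical road splits a wide extent into two non-empty sectors
  split <- generate_pondscape(pondscape_spec(64, c(0, 1000, 0, 1000),
                                             road = cbind(c(500, 500), c(-10, 1010)),
                                             seed = 3))
  tab <- table(split$ponds$sector)
  expect_equal(sum(tab), 64)
  expect_true(all(c("W", "E") %in% names(tab)))
  expect_true(all(split$ponds$x[split$ponds$sector == "W"] < 500))
})

test_that("degenerate pondscape specs are rejected", {
  expect_error(pondscape_spec(1, c(0, 0, 0, 10)), "positive area")
  expect_error(pondscape_spec(1, c(0, 10, 5, 5)), "positive area")
  expect_error(species_sim_params("s", c(A = 5), phi = 1.2, p_capture = 0.5,
                                  pent = c(1, 0)), "probabilities")
  expect_error(species_sim_params("s", c(A = 5), phi = 0.5, p_capture = 0.5,
                                  pent = c(0.5, 0.4)), "sum to 1")
  expect_error(species_sim_params("s", c(A = 5), phi = 0.5, p_capture = 0.5,
                                  pent = c(1, 0), kernel_family = "weibull",
                                  kernel_params = c(shape = -1, scale = 10)),
               "shape")
})

test_that("population simulation honours perfect and null detection", {
  par <- species_sim_params("sp", c(A = 40), phi = 1, p_capture = 1,
                            pent = c(1, 0, 0, 0), move_prob = 0)
  pop <- simulate_population(par, 4, seed = 5)
  expect_equal(length(unique(pop$detections$individual_id)), 40)
  expect_equal(nrow(pop$detections), 40 * 4)  # everyone, every session
  par0 <- species_sim_params("sp", c(A = 40), phi = 0.8, p_capture = 0,
                             pent = c(1, 0, 0, 0))
  expect_equal(nrow(simulate_population(par0, 4, seed = 5)$detections), 0)
  expect_error(simulate_population(par, 5), "pent")
})

test_that("detection of alive individuals is Bernoulli(p) and entries follow pent", {
  pent <- c(0.5, 0.2, 0.2, 0.05, 0.05, 0)
  par <- species_sim_params("sp", c(A = 3000), phi = 0.8, p_capture = 0.5,
                            pent = pent, move_prob = 0)
  pop <- simulate_population(par, 6, seed = 21)
  ind <- pop$individuals
  alive_sessions <- sum(ind$departure - ind$entry + 1)
  expect_equal(nrow(pop$detections) / alive_sessions, 0.5, tolerance = 0.05)
  expect_equal(as.numeric(prop.table(table(factor(ind$entry, levels = 1:6)))),
               pent, tolerance = 0.05)
  # survival: fraction surviving each interval ~ phi
  surv <- mean(ind$departure[ind$entry < 6] > ind$entry[ind$entry < 6])
  expect_equal(surv, 0.8, tolerance = 0.05)
})

test_that("kernel draws match closed-form summaries", {
  expect_length(simulate_movements("lognormal", c(meanlog = 5, sdlog = 1), 0), 0)
  d <- simulate_movements("lognormal", c(meanlog = 5, sdlog = 1), 1e5, seed = 2)
  expect_true(all(d > 0))
  expect_equal(median(d), exp(5), tolerance = 0.02)
  w <- simulate_movements("weibull", c(shape = 1, scale = 100), 1e5, seed = 3)
  expect_equal(mean(w), 100, tolerance = 0.02)
  expect_error(simulate_movements("weibull", c(shape = 0, scale = 100), 10),
               "shape")
})

test_that("full dataset simulation is reproducible with coherent movement ledger", {
  spec <- pondscape_spec(12, c(0, 1000, 0, 1000), road = NULL, seed = 4)
  pars <- list(species_sim_params("sp", setNames(rep(20, 12), sprintf("P%02d", 1:12)),
                                  phi = 0.9, p_capture = 0.6, pent = c(0.6, 0.2, 0.2, 0),
                                  kernel_params = c(meanlog = log(300), sdlog = 0.5),
                                  move_prob = 0.25))
  a <- simulate_dataset(spec, pars, n_sessions = 4, seed = 9)
  b <- simulate_dataset(spec, pars, n_sessions = 4, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$sp$relocations, b$truth$sp$relocations)
  led <- a$truth$sp$relocations
  expect_true(all(led$from_pond != led$to_pond))
  expect_true(all(led$realized_distance > 0))
})

test_that("relocation is suppressed with move_prob 0 or a single pond", {
  spec1 <- pondscape_spec(10, c(0, 500, 0, 500), seed = 2)
  par_fixed <- species_sim_params("sp", setNames(rep(15, 10), sprintf("P%02d", 1:10)),
                                  phi = 0.9, p_capture = 0.8,
                                  pent = c(1, 0, 0, 0), move_prob = 0)
  ds <- simulate_dataset(spec1, list(par_fixed), n_sessions = 4, seed = 1)
  expect_equal(nrow(ds$truth$sp$relocations), 0)
  per_ind <- tapply(ds$records$pond_id, ds$records$individual_id,
                    function(p) length(unique(p)))
  expect_true(all(per_ind == 1))
  spec2 <- pondscape_spec(1, c(0, 500, 0, 500), seed = 2)
  par_move <- species_sim_params("sp", c(P01 = 30), phi = 0.9, p_capture = 0.8,
                                 pent = c(1, 0, 0, 0), move_prob = 0.5)
  ds2 <- simulate_dataset(spec2, list(par_move), n_sessions = 4, seed = 1)
  expect_equal(nrow(ds2$truth$sp$relocations), 0)
})

test_that("relocation rate matches move_prob on a dense pond grid", {
  # 100 ponds ~200 m apart; lognormal displacements with median 450 m land
  # nearer a different pond essentially always, so the per-interval
  # relocation fraction estimates move_prob
  spec <- fixture_grid_spec(seed = 6)
  par <- species_sim_params("sp",
                            setNames(rep(30, 100), sprintf("P%03d", 1:100)),
                            phi = 0.95, p_capture = 1,
                            pent = c(1, 0, 0, 0, 0, 0),
                            kernel_params = c(meanlog = log(450), sdlog = 0.4),
                            move_prob = 0.3)
  # pond ids in the registry are P01..P100-style from generate_pondscape:
  # rename superpopulation to match
  scape <- generate_pondscape(spec)
  names(par$superpopulation_per_pond) <- scape$ponds$id[1:100]
  ds <- simulate_dataset(spec, list(par), n_sessions = 6, seed = 13)
  ind <- ds$truth$sp$individuals
  n_intervals <- sum(ind$departure - ind$entry)
  rate <- nrow(ds$truth$sp$relocations) / n_intervals
  expect_equal(rate, 0.3, tolerance = 0.1)
})
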