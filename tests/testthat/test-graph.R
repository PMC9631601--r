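# Probabilistic pond graphs: road rule, paths, PC/dPC, betweenness,
# clustering, spanning trees, movement graphs.

road_vertical <- cbind(c(500, 500), c(-100, 1100))

test_that("effective distance doubles across the road and only there", {
  expect_equal(effective_distance(c(0, 0), c(300, 0), road = NULL), 300)
  expect_equal(effective_distance(c(100, 500), c(400, 500), road_vertical), 300)
  expect_equal(effective_distance(c(350, 500), c(650, 500), road_vertical), 600)
  expect_equal(effective_distance(c(100, 100), c(100, 100), road_vertical), 0)
  # U-shaped road crossed twice: same side again, no doubling
  ushape <- cbind(c(400, 400, 600, 600), c(1100, 200, 200, 1100))
  expect_equal(count_road_crossings(c(300, 300), c(900, 300), ushape), 2L)
  expect_equal(effective_distance(c(300, 300), c(900, 300), ushape), 600)
})

test_that("saturated graphs carry kernel survival probabilities on all pairs", {
  k <- fit_kernel(simulate_movements("lognormal", c(meanlog = 5.5, sdlog = 0.8),
                                     1000, seed = 1), "lognormal")
  ponds <- data.frame(id = c("A", "B", "C"),
                      x = c(100, 400, 900), y = c(500, 500, 500),
                      stringsAsFactors = FALSE)
  g <- build_graph(ponds, k, road = road_vertical, a = c(5, 2, 1))
  expect_equal(sum(upper.tri(g$p) & g$p > 0), 3)  # n(n-1)/2 edges
  expect_equal(g$A_L, 8)
  # A and B sit west of the road, C east: only A-C and B-C double
  expect_equal(g$p["A", "B"], dispersal_probability(k, 300))
  expect_equal(g$p["B", "C"], dispersal_probability(k, 2 * 500))
  expect_lt(g$p["B", "C"], dispersal_probability(k, 500))
  expect_equal(g$p["A", "C"], dispersal_probability(k, 2 * 800))
  # coincident ponds connect with probability one
  g2 <- build_graph(data.frame(id = c("A", "B"), x = c(0, 0), y = c(0, 0)), k)
  expect_equal(g2$p["A", "B"], 1)
})

test_that("maximum product paths beat direct edges only when the product wins", {
  g2 <- pond_graph_from_p(matrix(c(0, 0.4, 0.4, 0), 2, 2))
  expect_equal(max_product_paths(g2)[1, 2], 0.4)
  # stepping-stone penalty: direct 0.5 beats 0.6 * 0.6
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 0.6
  p3[2, 3] <- p3[3, 2] <- 0.6
  p3[1, 3] <- p3[3, 1] <- 0.5
  ps <- max_product_paths(pond_graph_from_p(p3))
  expect_equal(ps[1, 3], 0.5)
  # ...and the stepping-stone wins when the direct edge is weak enough
  p3[1, 3] <- p3[3, 1] <- 0.3
  expect_equal(max_product_paths(pond_graph_from_p(p3))[1, 3], 0.36)
})

test_that("path and tree computations match exhaustive enumeration", {
  for (s in 1:15) {
    n <- 4 + (s %% 4)
    g <- random_prob_graph(n, seed = s, edge_keep = 0.85)
    ps <- max_product_paths(g)
    expect_true(all(ps >= g$p - 1e-12))
    expect_true(all(diag(ps) == 1))
    expect_equal(ps, t(ps))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(ps[i, j], oracle_max_product(g$p, i, j), tolerance = 1e-10)
    }
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(g$p),
                 tolerance = 1e-8)
    ow <- oracle_mst_weight(g$p)
    if (is.finite(ow)) {
      expect_equal(sum(minimum_spanning_tree(g)$weight), ow, tolerance = 1e-9)
    }
  }
})

test_that("adding an edge never decreases any best-path probability", {
  g <- random_prob_graph(7, seed = 77, edge_keep = 0.5)
  ps0 <- max_product_paths(g)
  p2 <- g$p
  off <- which(p2 == 0 & upper.tri(p2), arr.ind = TRUE)
  p2[off[1, 1], off[1, 2]] <- p2[off[1, 2], off[1, 1]] <- 0.5
  ps1 <- max_product_paths(pond_graph_from_p(p2, a = g$nodes$a))
  expect_true(all(ps1 >= ps0 - 1e-12))
})

test_that("probability of connectivity follows its closed form", {
  one <- pond_graph_from_p(matrix(0, 1, 1), a = 5)
  expect_equal(probability_of_connectivity(one), 1)
  two1 <- pond_graph_from_p(matrix(c(0, 1, 1, 0), 2, 2), a = c(1, 1))
  expect_equal(probability_of_connectivity(two1), 1)
  two <- pond_graph_from_p(matrix(c(0, 0.5, 0.5, 0), 2, 2), a = c(1, 1))
  expect_equal(probability_of_connectivity(two), 0.75)
  # invariant to uniform rescaling of the attributes
  g <- random_prob_graph(8, seed = 5)
  pc1 <- probability_of_connectivity(g)
  g2 <- pond_graph_from_p(g$p, a = g$nodes$a * 7.3)
  expect_equal(probability_of_connectivity(g2), pc1, tolerance = 1e-12)
  expect_error(probability_of_connectivity(pond_graph_from_p(matrix(0, 2, 2),
                                                             a = c(0, 0))),
               "positive")
})

test_that("dPC decomposes exactly and matches a from-scratch removal", {
  for (s in 1:20) {
    g <- random_prob_graph(4 + (s %% 9), seed = 300 + s)
    ni <- node_importance(g)
    expect_true(all(abs(ni$dPC - ni$dPCintra - ni$dPCflux - ni$dPCconnector)
                    < 1e-9))
    expect_true(all(ni$dPCconnector > -1e-9))
    # independent removal recomputation for one node
    k <- 1 + (s %% nrow(ni))
    PC <- attr(ni, "PC")
    sub <- pond_graph_from_p(g$p[-k, -k, drop = FALSE], a = g$nodes$a[-k])
    num <- as.numeric(g$nodes$a[-k] %*% max_product_paths(sub) %*% g$nodes$a[-k])
    dPC_k <- 100 * (PC - num / g$A_L^2) / PC
    expect_equal(ni$dPC[k], dPC_k, tolerance = 1e-9)
  }
})

test_that("attribute-free isolated nodes and pure endpoints contribute nothing", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.8
  g <- pond_graph_from_p(p, a = c(3, 2, 0))  # node 3 isolated with a = 0
  ni <- node_importance(g)
  expect_equal(ni$dPC[3], 0, tolerance = 1e-9)
  expect_equal(ni$dPCintra[3], 0)
  expect_equal(ni$dPCflux[3], 0)
  # complete equal-probability graph: nobody is an interior stepping-stone
  geq <- pond_graph_from_p(matrix(0.6, 4, 4) - diag(0.6, 4), a = rep(2, 4))
  nieq <- node_importance(geq)
  expect_true(all(abs(nieq$dPCconnector) < 1e-9))
  # single node: total importance
  expect_equal(node_importance(pond_graph_from_p(matrix(0, 1, 1), a = 2))$dPC,
               100)
})

test_that("betweenness concentrates on the bridging node", {
  # inverse-probability lengths AB = 2, BC = 2, AC = 10
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.5
  p[2, 3] <- p[3, 2] <- 0.5
  p[1, 3] <- p[3, 1] <- 0.1
  b <- betweenness_centrality(pond_graph_from_p(p))
  expect_equal(unname(b), c(0, 1, 0))
  # complete equal-probability graph: direct edges always shortest
  beq <- betweenness_centrality(pond_graph_from_p(matrix(0.7, 5, 5) -
                                                    diag(0.7, 5)))
  expect_true(all(beq == 0))
  # graph with no usable edges
  b0 <- betweenness_centrality(pond_graph_from_p(matrix(0, 3, 3)))
  expect_true(all(b0 == 0))
})

test_that("walktrap separates planted communities and merges uniform graphs", {
  # two 4-cliques joined by one weak edge
  p <- matrix(0, 8, 8)
  p[1:4, 1:4] <- 0.9
  p[5:8, 5:8] <- 0.9
  diag(p) <- 0
  p[4, 5] <- p[5, 4] <- 0.01
  cl <- walktrap_clusters(pond_graph_from_p(p))
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$membership[1:4])), 1)
  expect_equal(length(unique(cl$membership[5:8])), 1)
  expect_gt(cl$modularity, 0.3)
  # fully connected equal-weight graph: single community at the optimum
  cl1 <- walktrap_clusters(pond_graph_from_p(matrix(0.5, 6, 6) - diag(0.5, 6)))
  expect_equal(cl1$n_clusters, 1)
  expect_equal(walktrap_clusters(pond_graph_from_p(matrix(0, 1, 1)))$n_clusters, 1)
})

test_that("the spanning tree keeps the most probable edges without cycles", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.9
  p[2, 3] <- p[3, 2] <- 0.8
  p[1, 3] <- p[3, 1] <- 0.1
  tr <- minimum_spanning_tree(pond_graph_from_p(p))
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$p, c(0.9, 0.8))
  g <- random_prob_graph(9, seed = 41)
  tr9 <- minimum_spanning_tree(g)
  expect_equal(nrow(tr9), 8)  # n - 1 edges
  ig <- igraph::graph_from_data_frame(tr9[, c("from", "to")], directed = FALSE)
  expect_false(any(igraph::which_loop(ig)))
  expect_true(igraph::is_acyclic(ig))
  # disconnected: spanning forest with a warning
  pdis <- matrix(0, 4, 4)
  pdis[1, 2] <- pdis[2, 1] <- 0.5
  pdis[3, 4] <- pdis[4, 3] <- 0.5
  expect_warning(fr <- minimum_spanning_tree(pond_graph_from_p(pdis)),
                 "disconnected")
  expect_equal(nrow(fr), 2)
})

test_that("movement graphs count events per unordered pond pair", {
  mv <- data.frame(from_location = c("A", "A", "B"),
                   to_location = c("B", "B", "A"),
                   stringsAsFactors = FALSE)
  mg <- movement_graph(mv)
  expect_equal(nrow(mg), 1)
  expect_equal(mg$n_movements, 3)
  expect_equal(nrow(movement_graph(mv[0, ])), 0)
})

test_that("movement graph weights equal ground-truth relocation counts under perfect detection", {
  spec <- fixture_grid_spec(seed = 21)
  scape <- generate_pondscape(spec)
  par <- species_sim_params("sp", setNames(rep(8, 100), scape$ponds$id),
                            phi = 0.9, p_capture = 1, pent = c(1, 0, 0, 0),
                            kernel_params = c(meanlog = log(450), sdlog = 0.4),
                            move_prob = 0.25)
  ds <- simulate_dataset(spec, list(par), n_sessions = 4, seed = 2)
  mv <- detect_movements(assign_to_ponds(ds$records, ds$ponds))
  mg <- movement_graph(mv)
  led <- ds$truth$sp$relocations
  led_mg <- movement_graph(data.frame(from_location = led$from_pond,
                                      to_location = led$to_pond))
  expect_equal(mg, led_mg)
})
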