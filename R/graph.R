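## Probabilistic pond graphs: road-resistance effective distances, saturated
## graphs with kernel-derived edge probabilities, maximum-product shortest
## paths, probability of connectivity (PC) and its per-node decomposition
## (dPC = dPCintra + dPCflux + dPCconnector), weighted betweenness, walktrap
## clusters, maximum-probability spanning trees and observed movement graphs.
##
## Maximum product probability over a path is computed as a minimum additive
## length under the -log(p) transform (exact algebraic equivalence); edges
## with p below `p_floor` are dropped from path computations to avoid
## infinite lengths.

P_FLOOR <- 1e-12

## Orientation of the triple (a, b, c); 0 within eps means collinear.
.orient <- function(ax, ay, bx, by, cx, cy, eps = 1e-9) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  if (abs(v) <= eps) 0 else sign(v)
}

.on_segment <- function(ax, ay, bx, by, px, py, eps = 1e-9) {
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

## Does segment p1-p2 intersect segment q1-q2? Touching counts.
.segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- .orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- .orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
  (d1 == 0 && .on_segment(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])) ||
    (d2 == 0 && .on_segment(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])) ||
    (d3 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])) ||
    (d4 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2]))
}

#' Count crossings between a segment and a road polyline
#'
#' Odd-parity crossing counts decide whether two points lie on opposite sides
#' of the road. A segment touching a road-segment endpoint counts as one
#' crossing for that road segment; pond pairs in general position (the usual
#' case) are unaffected by this convention.
#'
#' @param p1,p2 numeric length-2 endpoints of the segment.
#' @param road two-column matrix of polyline vertices, or `NULL` (0
#'   crossings).
#' @return integer number of road segments intersected.
#' @export
count_road_crossings <- function(p1, p2, road) {
  if (is.null(road)) return(0L)
  road <- as.matrix(road)
  k <- 0L
  for (s in seq_len(nrow(road) - 1L)) {
    if (.segments_intersect(p1, p2, road[s, ], road[s + 1L, ])) k <- k + 1L
  }
  k
}

#' Effective inter-pond distance with road resistance
#'
#' Euclidean distance between the two points, doubled when the straight
#' segment between them crosses the road polyline an odd number of times
#' (road resistance as a length multiplier for a barrier to amphibian
#' movement).
#'
#' @param p1,p2 numeric length-2 coordinates in metres.
#' @param road road polyline (two-column matrix) or `NULL`.
#' @return effective distance in metres (0 for identical coordinates).
#' @export
effective_distance <- function(p1, p2, road = NULL) {
  d <- .edist(p1[1], p1[2], p2[1], p2[2])
  if (d == 0) return(0)
  if (count_road_crossings(p1, p2, road) %% 2 == 1) 2 * d else d
}

#' Build a saturated probabilistic pond graph
#'
#' Every pond pair gets an edge whose probability is the dispersal kernel's
#' survival function evaluated at the effective (road-resisted) distance.
#' Node attributes `a` are the estimated population sizes; the landscape
#' attribute `A_L` is their sum.
#'
#' @param ponds pond registry data.frame (`id`, `x`, `y`, optional `sector`,
#'   optional `a`).
#' @param kernel a `dispersal_kernel`.
#' @param road road polyline or `NULL` (no resistance applied).
#' @param a node attributes (estimated population sizes); defaults to
#'   `ponds$a`, else 1 for every pond.
#' @param method edge-probability transform, see [dispersal_probability()].
#' @return object of class `pond_graph`: `nodes`, `dist`, `eff_dist`, `p`
#'   (symmetric matrices, empty diagonal for `p`), `A_L`.
#' @export
build_graph <- function(ponds, kernel, road = NULL, a = NULL,
                        method = "survival") {
  stopifnot(nrow(ponds) >= 1)
  n <- nrow(ponds)
  if (is.null(a)) a <- ponds$a %||% rep(1, n)
  stopifnot(length(a) == n, all(a >= 0))
  ids <- ponds$id
  D <- as.matrix(dist(cbind(ponds$x, ponds$y)))
  E <- D
  if (!is.null(road) && n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (count_road_crossings(c(ponds$x[i], ponds$y[i]),
                                 c(ponds$x[j], ponds$y[j]), road) %% 2 == 1) {
          E[i, j] <- E[j, i] <- 2 * D[i, j]
        }
      }
    }
  }
  P <- matrix(0, n, n)
  if (n > 1) {
    ut <- upper.tri(E)
    P[ut] <- dispersal_probability(kernel, E[ut], method = method)
    P <- P + t(P)
  }
  dimnames(D) <- dimnames(E) <- dimnames(P) <- list(ids, ids)
  structure(list(nodes = cbind(ponds[, intersect(c("id", "x", "y", "sector"),
                                                 names(ponds)), drop = FALSE],
                               a = a),
                 dist = D, eff_dist = E, p = P, A_L = sum(a)),
            class = "pond_graph")
}

#' Construct a `pond_graph` from an explicit probability matrix
#'
#' Lower-level constructor used for testing and for graphs whose edge
#' probabilities do not come from a kernel.
#'
#' @param p symmetric probability matrix (diagonal ignored).
#' @param a node attributes (default 1).
#' @param ids node ids (default `V1..Vn`).
#' @return a `pond_graph` (without coordinates).
#' @export
pond_graph_from_p <- function(p, a = rep(1, nrow(p)), ids = NULL) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p),
            max(abs(p - t(p))) < 1e-12, all(p >= 0 & p <= 1),
            length(a) == nrow(p), all(a >= 0))
  n <- nrow(p)
  if (is.null(ids)) ids <- sprintf("V%02d", seq_len(n))
  diag(p) <- 0
  dimnames(p) <- list(ids, ids)
  structure(list(nodes = data.frame(id = ids, a = a, stringsAsFactors = FALSE),
                 dist = NULL, eff_dist = NULL, p = p, A_L = sum(a)),
            class = "pond_graph")
}

#' @export
print.pond_graph <- function(x, ...) {
  cat("Probabilistic pond graph:", nrow(x$nodes), "nodes, A_L =", x$A_L, "\n")
  invisible(x)
}

## igraph view of the probability matrix; edges below p_floor omitted.
## weight_mode: "neglog" (-log p), "inverse" (1/p) or "p".
.as_igraph <- function(g, weight_mode = "neglog", p_floor = P_FLOOR) {
  p <- g$p
  n <- nrow(p)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes$id)
  if (n > 1) {
    idx <- which(upper.tri(p) & p >= p_floor, arr.ind = TRUE)
    if (nrow(idx)) {
      ## lexicographic edge order (ids are sorted with the node order of the
      ## registry); deterministic tie-breaking downstream
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      pv <- p[idx]
      w <- switch(weight_mode, neglog = -log(pv), inverse = 1 / pv, p = pv)
      ig <- igraph::add_edges(ig, t(idx), weight = w, p = pv)
    }
  }
  ig
}

#' All-pairs maximum product-probability paths
#'
#' The "shortest" path between two ponds is the path with the maximum product
#' of edge probabilities (a multiplicative method that penalizes
#' stepping-stones: stepping through an intermediate only wins when the
#' direct probability is smaller than the product). Computed as additive
#' shortest paths under the `-log p` transform.
#'
#' @param graph a `pond_graph`.
#' @param p_floor edges below this probability are treated as absent.
#' @return matrix `pstar` of maximum product probabilities; diagonal 1,
#'   unreachable pairs 0.
#' @export
max_product_paths <- function(graph, p_floor = P_FLOOR) {
  ig <- .as_igraph(graph, "neglog", p_floor)
  D <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  pstar <- exp(-D)
  pstar[is.infinite(D)] <- 0
  diag(pstar) <- 1
  dimnames(pstar) <- dimnames(graph$p)
  pstar
}

#' Probability of connectivity (PC)
#'
#' `PC = sum_ij a_i a_j pstar_ij / A_L^2` over all ordered pond pairs
#' (including i = j with `pstar_ii = 1`): the probability that two points
#' placed at random into the landscape's attribute mass fall into ponds that
#' are mutually reachable, weighted by the best path probability.
#'
#' @param graph a `pond_graph` with `A_L > 0`.
#' @param pstar optional precomputed [max_product_paths()] matrix.
#' @return PC in `(0, 1]`.
#' @export
probability_of_connectivity <- function(graph, pstar = NULL) {
  if (graph$A_L <= 0) stop("A_L must be positive")
  if (is.null(pstar)) pstar <- max_product_paths(graph)
  a <- graph$nodes$a
  as.numeric(a %*% pstar %*% a) / graph$A_L^2
}

#' Per-node connectivity importance (dPC and its fractions)
#'
#' `dPC_k = 100 (PC - PC^-k) / PC`, where `PC^-k` is recomputed on the graph
#' without node k but with `A_L` held at its full-landscape value (keeping
#' the three fractions additive). `dPCintra_k` is the node's own attribute
#' contribution, `dPCflux_k` its attribute-weighted dispersal flux to all
#' other nodes, and `dPCconnector_k = dPC_k - dPCintra_k - dPCflux_k` its
#' stepping-stone role inside other pairs' best paths.
#'
#' @param graph a `pond_graph`.
#' @param p_floor see [max_product_paths()].
#' @return data.frame: `id`, `a`, `dPC`, `dPCintra`, `dPCflux`,
#'   `dPCconnector`, plus the graph-level `PC` as an attribute.
#' @export
node_importance <- function(graph, p_floor = P_FLOOR) {
  n <- nrow(graph$nodes)
  a <- graph$nodes$a
  AL2 <- graph$A_L^2
  pstar <- max_product_paths(graph, p_floor)
  PC <- probability_of_connectivity(graph, pstar)
  if (n == 1L) {
    out <- data.frame(id = graph$nodes$id, a = a, dPC = 100, dPCintra = 100,
                      dPCflux = 0, dPCconnector = 0, stringsAsFactors = FALSE)
    attr(out, "PC") <- PC
    return(out)
  }
  dPC <- dPCintra <- dPCflux <- numeric(n)
  for (k in seq_len(n)) {
    sub <- pond_graph_from_p(graph$p[-k, -k, drop = FALSE],
                             a = a[-k], ids = graph$nodes$id[-k])
    pstar_k <- max_product_paths(sub, p_floor)
    num_k <- as.numeric(a[-k] %*% pstar_k %*% a[-k])
    PC_k <- num_k / AL2  # full-landscape A_L kept fixed
    dPC[k] <- 100 * (PC - PC_k) / PC
    dPCintra[k] <- 100 * a[k]^2 / (AL2 * PC)
    dPCflux[k] <- 100 * 2 * sum(a[k] * a[-k] * pstar[k, -k]) / (AL2 * PC)
  }
  out <- data.frame(id = graph$nodes$id, a = a, dPC = dPC,
                    dPCintra = dPCintra, dPCflux = dPCflux,
                    dPCconnector = dPC - dPCintra - dPCflux,
                    stringsAsFactors = FALSE)
  attr(out, "PC") <- PC
  out
}

#' Weighted betweenness centrality
#'
#' Shortest-path betweenness with edge length `1 / p_ij` (path length is the
#' sum of inverse connection probabilities); multiple equally short paths are
#' counted fractionally and endpoints are excluded. Identifies ponds
#' condensing the most likely movement routes (stepping-stones).
#'
#' @param graph a `pond_graph`.
#' @param p_floor edges below this probability are ignored.
#' @return named numeric vector of betweenness values per pond.
#' @export
betweenness_centrality <- function(graph, p_floor = P_FLOOR) {
  ig <- .as_igraph(graph, "inverse", p_floor)
  if (igraph::ecount(ig) == 0) {
    return(setNames(rep(0, nrow(graph$nodes)), graph$nodes$id))
  }
  b <- igraph::betweenness(ig, directed = FALSE,
                           weights = igraph::E(ig)$weight)
  setNames(as.numeric(b), graph$nodes$id)
}

#' Walktrap community detection
#'
#' Random-walk (walktrap) clustering on the probability-weighted graph,
#' merging nodes by t-step random-walk similarity and cutting the dendrogram
#' at maximum weighted modularity. Cluster counts quantify network
#' fragmentation: many clusters mean tightly connected pond groups joined by
#' weak links.
#'
#' @param graph a `pond_graph`.
#' @param steps random-walk length (default 4, the algorithm's conventional
#'   default).
#' @param p_floor edges below this probability are ignored.
#' @return list with `membership` (named integer vector), `n_clusters`,
#'   `modularity`.
#' @export
walktrap_clusters <- function(graph, steps = 4, p_floor = P_FLOOR) {
  n <- nrow(graph$nodes)
  if (n == 1L) {
    return(list(membership = setNames(1L, graph$nodes$id),
                n_clusters = 1L, modularity = 0))
  }
  ig <- .as_igraph(graph, "p", p_floor)
  wt <- igraph::cluster_walktrap(ig, weights = igraph::E(ig)$weight,
                                 steps = steps)
  memb <- igraph::membership(wt)
  list(membership = setNames(as.integer(memb), graph$nodes$id),
       n_clusters = length(unique(memb)),
       modularity = igraph::modularity(ig, memb,
                                       weights = igraph::E(ig)$weight))
}

#' Maximum-probability spanning tree
#'
#' The spanning tree minimizing the total `-log p` edge weight, i.e.
#' maximizing the product of edge probabilities: the most likely acyclic
#' backbone connecting all ponds. On a disconnected graph a spanning forest
#' is returned with a warning.
#'
#' @param graph a `pond_graph`.
#' @param p_floor edges below this probability are ignored.
#' @return data.frame of tree edges: `from`, `to`, `p`, `weight` (`-log p`).
#' @export
minimum_spanning_tree <- function(graph, p_floor = P_FLOOR) {
  ig <- .as_igraph(graph, "neglog", p_floor)
  comps <- igraph::components(ig)
  if (comps$no > 1L) {
    warning("graph is disconnected; returning a spanning forest with ",
            comps$no, " components")
  }
  tree <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  el <- igraph::as_edgelist(tree)
  if (nrow(el) == 0) {
    return(data.frame(from = character(), to = character(), p = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  w <- igraph::E(tree)$weight
  out <- data.frame(from = pmin(el[, 1], el[, 2]),
                    to = pmax(el[, 1], el[, 2]),
                    p = exp(-w), weight = w, stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Observed movement graph
#'
#' Edge weights are the numbers of detected movement events between pond
#' pairs, direction ignored.
#'
#' @param movements movement events with pond-assigned endpoints (columns
#'   `from_location`, `to_location`).
#' @return data.frame of undirected edges: `from`, `to`, `n_movements`.
#' @export
movement_graph <- function(movements) {
  if (is.null(movements) || nrow(movements) == 0) {
    return(data.frame(from = character(), to = character(),
                      n_movements = integer(), stringsAsFactors = FALSE))
  }
  from <- pmin(movements$from_location, movements$to_location)
  to <- pmax(movements$from_location, movements$to_location)
  agg <- aggregate(list(n_movements = rep(1L, length(from))),
                   by = list(from = from, to = to), FUN = sum)
  agg[order(agg$from, agg$to), , drop = FALSE]
}
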