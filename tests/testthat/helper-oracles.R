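# Independent brute-force oracles used across the test files.

# POPAN oracle: per-individual probability of every observable history by
# exhaustive enumeration of latent (entry b, last-alive d, detection vector)
# configurations, assembled as a multinomial over history categories.
oracle_popan_loglik <- function(H, cnt, phi, p, pent, N) {
  T <- ncol(H)
  keys <- apply(H, 1L, paste, collapse = "")
  q <- setNames(numeric(2^T), vapply(0:(2^T - 1), function(k) {
    paste(rev(as.integer(intToBits(k)[1:T])), collapse = "")
  }, character(1)))
  for (b in 1:T) {
    for (d in b:T) {
      pr_bd <- pent[b]
      if (d > b) pr_bd <- pr_bd * prod(phi[b:(d - 1)])
      if (d < T) pr_bd <- pr_bd * (1 - phi[d])
      len <- d - b + 1
      for (k in 0:(2^len - 1)) {
        v <- as.integer(intToBits(k)[1:len])
        h <- integer(T)
        h[b:d] <- v
        pdet <- prod(ifelse(v == 1, p[b:d], 1 - p[b:d]))
        key <- paste(h, collapse = "")
        q[key] <- q[key] + pr_bd * pdet
      }
    }
  }
  zero <- paste(rep(0L, T), collapse = "")
  n <- sum(cnt)
  ll <- lgamma(N + 1) - lgamma(N - n + 1) + (N - n) * log(q[zero])
  for (i in seq_len(nrow(H))) {
    ll <- ll + cnt[i] * log(q[keys[i]]) - lgamma(cnt[i] + 1)
  }
  unname(ll)
}

# Link-scale coefficient vector for a constant-phi, constant-p, time-pent
# single-group model at given real-scale values.
beta_for_constant_model <- function(phi, p, pent, N, n) {
  c(qlogis(phi), qlogis(p), log(pent[-1] / pent[1]), log(N - n))
}

# All simple paths between two nodes of a probability matrix; returns the
# maximum product probability (0 if unreachable).
oracle_max_product <- function(p, from, to, p_floor = 1e-12) {
  n <- nrow(p)
  best <- 0
  rec <- function(cur, visited, prob) {
    if (cur == to) {
      best <<- max(best, prob)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && p[cur, nxt] >= p_floor) {
        visited[nxt] <- TRUE
        rec(nxt, visited, prob * p[cur, nxt])
        visited[nxt] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  rec(from, visited, 1)
  best
}

# Exhaustive weighted betweenness with edge length 1/p: enumerate all simple
# paths per pair, find the minimum total length, and split the count
# fractionally over co-minimal paths; endpoints excluded.
oracle_betweenness <- function(p, p_floor = 1e-12, tol = 1e-12) {
  n <- nrow(p)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      rec <- function(cur, visited, len, path) {
        if (cur == t) {
          paths[[length(paths) + 1]] <<- list(len = len, path = path)
          return(invisible())
        }
        for (nxt in seq_len(n)) {
          if (!visited[nxt] && p[cur, nxt] >= p_floor) {
            visited[nxt] <- TRUE
            rec(nxt, visited, len + 1 / p[cur, nxt], c(path, nxt))
            visited[nxt] <- FALSE
          }
        }
      }
      visited <- rep(FALSE, n); visited[s] <- TRUE
      rec(s, visited, 0, s)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      mins <- which(lens <= min(lens) * (1 + tol))
      for (m in mins) {
        inner <- setdiff(paths[[m]]$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(mins)
      }
    }
  }
  btw
}

# Minimum total -log(p) weight over all spanning trees: exhaustive over all
# edge subsets of size n-1, acyclicity/connectivity checked with union-find.
oracle_mst_weight <- function(p, p_floor = 1e-12) {
  n <- nrow(p)
  idx <- which(upper.tri(p) & p >= p_floor, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < n - 1) return(NA_real_)
  w <- -log(p[idx])
  find <- function(parent, x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  best <- Inf
  combs <- utils::combn(m, n - 1)
  for (ci in seq_len(ncol(combs))) {
    parent <- seq_len(n)
    ok <- TRUE
    for (e in combs[, ci]) {
      ra <- find(parent, idx[e, 1]); rb <- find(parent, idx[e, 2])
      if (ra == rb) { ok <- FALSE; break }  # cycle
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(w[combs[, ci]]))  # n-1 acyclic edges = tree
  }
  best
}

# Random symmetric probability matrix with a given attribute range.
random_prob_graph <- function(n, seed, p_range = c(0.05, 0.95),
                              a_range = c(0, 10), edge_keep = 1) {
  set.seed(seed)
  p <- matrix(0, n, n)
  ut <- upper.tri(p)
  vals <- runif(sum(ut), p_range[1], p_range[2])
  keep <- runif(sum(ut)) < edge_keep
  vals[!keep] <- 0
  p[ut] <- vals
  p <- p + t(p)
  a <- runif(n, a_range[1], a_range[2])
  pond_graph_from_p(p, a = a)
}
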