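## Open-population Jolly-Seber abundance estimation (POPAN / Schwarz-Arnason
## superpopulation formulation).
##
## An individual from the superpopulation N enters the sampled population
## before occasion b with probability pent_b (sum_b pent_b = 1), survives each
## inter-occasion interval with probability phi_t, and while present is
## detected at occasion t with probability p_t. The likelihood of an observed
## capture history sums over all feasible (entry, departure) occasion pairs;
## never-detected animals contribute the corresponding all-zero probability,
## assembled with the multinomial coefficient over distinct histories.
## Parameters are estimated by maximum likelihood with logit links for phi and
## p, a multinomial-logit link (first occasion as reference) for pent, and
## N_g = n_g + exp(theta_g) per group on the log scale.

POPAN_STRUCTURES <- c("constant", "time", "sex", "time+sex", "time*sex")

#' Specify a POPAN model structure
#'
#' Each of phi (apparent survival), p (capture probability) and pent (entry
#' probability) can be constant, time-dependent, sex-dependent, additive or
#' fully interacted. A pent constant through time is discarded a priori:
#' pond-breeding amphibians enter the breeding population in pulses, not at a
#' flat rate.
#'
#' @param phi,p,pent structure strings from
#'   `c("constant", "time", "sex", "time+sex", "time*sex")`; `"constant"` is
#'   disallowed for `pent`.
#' @return object of class `popan_spec`.
#' @export
popan_spec <- function(phi = "constant", p = "constant", pent = "time") {
  phi <- match.arg(phi, POPAN_STRUCTURES)
  p <- match.arg(p, POPAN_STRUCTURES)
  pent <- match.arg(pent, POPAN_STRUCTURES)
  if (pent == "constant") stop("a time-constant pent is disallowed a priori")
  structure(list(phi = phi, p = p, pent = pent), class = "popan_spec")
}

## With a single group, sex terms are void: collapse to the nested structure.
canonical_structure <- function(s, G) {
  if (G > 1L) return(s)
  switch(s, sex = "constant", `time+sex` = "time", `time*sex` = "time", s)
}

canonical_spec <- function(spec, G) {
  out <- popan_spec_unchecked(canonical_structure(spec$phi, G),
                              canonical_structure(spec$p, G),
                              canonical_structure(spec$pent, G))
  if (out$pent == "constant") {
    stop("pent structure collapses to constant for single-group data")
  }
  out
}

popan_spec_unchecked <- function(phi, p, pent) {
  structure(list(phi = phi, p = p, pent = pent), class = "popan_spec")
}

#' @export
format.popan_spec <- function(x, ...) {
  sprintf("phi(%s) p(%s) pent(%s)", x$phi, x$p, x$pent)
}

#' @export
print.popan_spec <- function(x, ...) {
  cat("POPAN model:", format(x), "\n")
  invisible(x)
}

## Cell design matrix for a structure over occasions `tt` and groups `gg`
## (rows = expand.grid(t = tt, g = gg), t varying fastest). Indicator columns
## are built directly so single-level factors (e.g. two-session pent) work.
cell_design <- function(structure, tt, gg) {
  cells <- expand.grid(t = factor(tt), g = factor(gg))
  ind <- function(f) {
    m <- outer(as.character(f), levels(f), `==`) * 1
    colnames(m) <- levels(f)
    m
  }
  switch(structure,
    constant = matrix(1, nrow(cells), 1),
    time = ind(cells$t),
    sex = ind(cells$g),
    `time+sex` = cbind(1, ind(cells$t)[, -1, drop = FALSE],
                       ind(cells$g)[, -1, drop = FALSE]),
    `time*sex` = ind(interaction(cells$t, cells$g)),
    stop("unknown structure: ", structure))
}

## Design bundle for a (spec, T, groups) combination.
popan_designs <- function(spec, n_sessions, groups) {
  G <- length(groups)
  spec <- canonical_spec(spec, G)
  X_phi <- cell_design(spec$phi, seq_len(n_sessions - 1L), groups)
  X_p <- cell_design(spec$p, seq_len(n_sessions), groups)
  ## pent: occasions 2..T, reference eta = 0 at occasion 1
  X_pent <- cell_design(spec$pent, seq(2L, n_sessions), groups)
  list(spec = spec, X_phi = X_phi, X_p = X_p, X_pent = X_pent,
       n_sessions = n_sessions, groups = groups,
       n_beta = ncol(X_phi) + ncol(X_p) + ncol(X_pent),
       K = ncol(X_phi) + ncol(X_p) + ncol(X_pent) + G)
}

## Real-scale cell values from the link-scale coefficient vector.
## beta = c(beta_phi, beta_p, beta_pent, theta_N[1..G]).
popan_cells <- function(designs, beta) {
  T <- designs$n_sessions
  G <- length(designs$groups)
  k1 <- ncol(designs$X_phi); k2 <- ncol(designs$X_p); k3 <- ncol(designs$X_pent)
  if (length(beta) != k1 + k2 + k3 + G) {
    stop("beta has length ", length(beta), ", expected ", k1 + k2 + k3 + G)
  }
  b_phi <- beta[seq_len(k1)]
  b_p <- beta[k1 + seq_len(k2)]
  b_pent <- beta[k1 + k2 + seq_len(k3)]
  theta <- beta[k1 + k2 + k3 + seq_len(G)]
  phi <- matrix(plogis(designs$X_phi %*% b_phi), T - 1L, G)
  p <- matrix(plogis(designs$X_p %*% b_p), T, G)
  eta <- rbind(0, matrix(designs$X_pent %*% b_pent, T - 1L, G))
  ex <- exp(eta - rep(apply(eta, 2L, max), each = T))
  pent <- ex / rep(colSums(ex), each = T)
  list(phi = phi, p = p, pent = pent, theta = theta)
}

## Per-group data preprocessing: everything that does not depend on the
## parameters (first/last captures, feasible (entry, departure) index sets,
## multinomial constants) is computed once per fit.
popan_group_prep <- function(H, cnt) {
  m <- nrow(H); T <- ncol(H)
  f <- apply(H, 1L, function(r) which(r == 1L)[1])
  l <- apply(H, 1L, function(r) max(which(r == 1L)))
  pb <- integer(0); pd <- integer(0)
  for (b in seq_len(T)) {
    pb <- c(pb, rep(b, T - b + 1L))
    pd <- c(pd, b:T)
  }
  ## mask[i, k]: history i is compatible with entry pb[k], departure pd[k]
  mask <- outer(f, pb, `>=`) & outer(l, pd, `<=`)
  UT <- outer(seq_len(T), seq_len(T), `<=`) * 1  # column j: occasions <= j
  list(H = H, cnt = cnt, m = m, T = T, n = sum(cnt),
       pair_b = pb, pair_d = pd, mask = mask * 1, UT = UT,
       lgam_cnt = sum(lgamma(cnt + 1)))
}

## Log-likelihood of one preprocessed group at real-scale cell values.
popan_eval_group <- function(prep, phi, p, pent, N) {
  if (N < prep$n) return(-Inf)
  T <- prep$T
  ## log terms clamped at the smallest representable magnitude so that
  ## boundary parameter values (p or phi of exactly 0/1, pent of 0) stay in
  ## ordinary (finite) arithmetic
  lfloor <- -745
  clamp <- function(x) { x[x < lfloor] <- lfloor; x }
  lp <- clamp(log(p)); lq <- clamp(log1p(-p))
  ls <- c(0, cumsum(clamp(log(phi))))         # ls[d] - ls[b]: survival b..d
  ldeath <- c(clamp(log1p(-phi)), 0)          # death after d (0 at d = T)
  lpent <- clamp(log(pent))
  cq <- cumsum(lq)
  C0 <- c(0, cq)                          # never-detected detection term
  b <- prep$pair_b; d <- prep$pair_d
  base <- lpent[b] + ls[d] - ls[b] + ldeath[d]   # one value per (b, d) pair
  P0 <- sum(exp(base + C0[d + 1L] - C0[b]))
  if (prep$m > 0) {
    ## C[i, j] = sum_{t <= j} H_it lp_t + (1 - H_it) lq_t, via one matmul
    W <- prep$H %*% (prep$UT * (lp - lq))
    Cm <- cbind(0, W + rep(cq, each = prep$m))
    ## per-history sums over compatible (entry, departure) pairs, vectorized
    Term <- Cm[, d + 1L, drop = FALSE] - Cm[, b, drop = FALSE] +
      rep(base, each = prep$m)
    P <- as.numeric((exp(Term) * prep$mask) %*% rep(1, length(b)))
  }
  ll <- lgamma(N + 1) - lgamma(N - prep$n + 1) +
    (N - prep$n) * log(max(P0, 1e-300))
  if (prep$m > 0) {
    if (any(P <= 0)) return(-Inf)
    ll <- ll + sum(prep$cnt * log(P)) - prep$lgam_cnt
  }
  ll
}

## Log-likelihood of one group of histories given real-scale cells.
## H: 0/1 matrix of distinct histories, cnt: multiplicities, N: superpopulation.
popan_loglik_group <- function(H, cnt, phi, p, pent, N) {
  popan_eval_group(popan_group_prep(H, cnt), phi, p, pent, N)
}

## Collapse a capture-history object to distinct histories with counts, split
## by group. Groups: sex levels present among {M, F} plus "U"; a single group
## "all" when no sexed individuals exist.
popan_group_data <- function(history) {
  m <- history$matrix
  sex <- history$sex
  groups <- sort(unique(sex))
  if (!any(groups %in% c("M", "F"))) groups <- "all"
  dat <- lapply(groups, function(g) {
    rows <- if (identical(groups, "all")) seq_len(nrow(m)) else which(sex == g)
    sub <- m[rows, , drop = FALSE]
    key <- apply(sub, 1L, paste, collapse = "")
    tab <- table(key)
    H <- do.call(rbind, lapply(names(tab), function(k) {
      as.integer(strsplit(k, "")[[1]])
    }))
    list(H = H, cnt = as.numeric(tab), n = nrow(sub))
  })
  names(dat) <- groups
  list(groups = groups, data = dat)
}

#' POPAN log-likelihood at given link-scale coefficients
#'
#' @param history a `capture_history` (see [build_capture_histories()]).
#' @param spec a [popan_spec()].
#' @param beta link-scale coefficient vector: phi block, p block, pent block
#'   (multinomial-logit, occasion 1 reference), then one `log(N_g - n_g)` per
#'   group.
#' @return the log-likelihood value (finite for interior beta).
#' @export
popan_loglik <- function(history, spec, beta) {
  if (nrow(history$matrix) == 0) stop("empty capture history")
  if (any(!is.finite(beta))) stop("beta must be finite")
  gd <- popan_group_data(history)
  designs <- popan_designs(spec, ncol(history$matrix), gd$groups)
  cells <- popan_cells(designs, beta)
  ll <- 0
  for (gi in seq_along(gd$groups)) {
    d <- gd$data[[gi]]
    N <- d$n + exp(cells$theta[gi])
    ll <- ll + popan_loglik_group(d$H, d$cnt, cells$phi[, gi], cells$p[, gi],
                                  cells$pent[, gi], N)
  }
  ll
}

#' Fit a POPAN model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization from three deterministic starting points;
#' the best converged solution is kept. Standard errors of N come from the
#' observed information via the delta method on the log scale.
#'
#' @param history a `capture_history` with at least one recapture.
#' @param spec a [popan_spec()].
#' @param control passed to [stats::optim()] (default `maxit = 500`).
#' @return object of class `popan_fit`: real-scale estimates per session and
#'   group (`phi_hat`, `p_hat`, `pent_hat`), `N_hat` and `N_se` per group,
#'   `N_total`, `loglik`, `K`, `n_eff`, `aicc`, `converged`.
#' @export
fit_popan <- function(history, spec, control = list(maxit = 500)) {
  if (nrow(history$matrix) == 0) stop("empty capture history")
  if (ncol(history$matrix) < 2) stop("need at least two sessions")
  gd <- popan_group_data(history)
  designs <- popan_designs(spec, ncol(history$matrix), gd$groups)
  G <- length(gd$groups)
  n_g <- vapply(gd$data, `[[`, numeric(1), "n")
  preps <- lapply(gd$data, function(d) popan_group_prep(d$H, d$cnt))
  ## Fully time-dependent models have a known confounded direction (last
  ## pent x p) along which N can diverge at near-flat likelihood; keep the
  ## search inside a generous but finite region and flag fits that press
  ## against it as non-identifiable.
  N_cap <- 1e3 * pmax(n_g, 1)
  nll <- function(par) {
    cells <- tryCatch(popan_cells(designs, par), error = function(e) NULL)
    if (is.null(cells)) return(1e10)
    ll <- 0
    for (gi in seq_len(G)) {
      extra <- exp(cells$theta[gi])
      if (!is.finite(extra) || extra > N_cap[gi]) return(1e10)
      ll <- ll + popan_eval_group(preps[[gi]], cells$phi[, gi],
                                  cells$p[, gi], cells$pent[, gi],
                                  n_g[gi] + extra)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  theta0 <- log(pmax(n_g, 1))
  starts <- lapply(c(0, qlogis(0.25), qlogis(0.75)), function(v) {
    c(rep(v, ncol(designs$X_phi)), rep(v, ncol(designs$X_p)),
      rep(0, ncol(designs$X_pent)), theta0)
  })
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(optim(s, nll, method = "BFGS", control = control),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) stop("POPAN optimization failed")
  ## polish: a restart resets the Hessian approximation and tightens the
  ## solution when BFGS stopped on a shallow direction
  polish <- tryCatch(optim(best$par, nll, method = "BFGS", control = control),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  cells <- popan_cells(designs, best$par)
  N_hat <- n_g + exp(cells$theta)
  N_se <- rep(NA_real_, G)
  hess <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      idx <- length(best$par) - G + seq_len(G)
      vtheta <- diag(vc)[idx]
      vtheta[vtheta < 0] <- NA_real_
      N_se <- exp(cells$theta) * sqrt(vtheta)
    }
  }
  n_eff <- sum(n_g)
  ll <- -best$value
  K <- designs$K
  aicc_val <- tryCatch(aicc(ll, K, n_eff), error = function(e) NA_real_)
  structure(
    list(spec = designs$spec, beta = best$par,
         phi_hat = cells$phi, p_hat = cells$p, pent_hat = cells$pent,
         N_hat = setNames(N_hat, gd$groups),
         N_se = setNames(N_se, gd$groups),
         N_total = sum(N_hat),
         loglik = ll, K = K, n_eff = n_eff, aicc = aicc_val,
         converged = best$convergence == 0 && is.finite(aicc_val) &&
           all(N_hat <= 100 * pmax(n_g, 1)),
         groups = gd$groups),
    class = "popan_fit")
}

#' @export
print.popan_fit <- function(x, ...) {
  cat("POPAN fit:", format(x$spec), "\n")
  cat("  loglik:", format(x$loglik), " K:", x$K, " AICc:", format(x$aicc), "\n")
  cat("  N_hat:", paste(sprintf("%s=%.1f", names(x$N_hat), x$N_hat),
                        collapse = ", "),
      sprintf("(total %.1f)", x$N_total), "\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `-2 loglik + 2K + 2K(K+1)/(n_eff - K - 1)`; the effective sample size is
#' the number of animals (distinct individuals).
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n_eff effective sample size (must exceed `K + 1`).
#' @return the AICc value.
#' @export
aicc <- function(loglik, K, n_eff) {
  if (n_eff <= K + 1) stop("n_eff must exceed K + 1 (model saturated)")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

## AICc weights over a set of fits.
aicc_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Stepwise POPAN model selection
#'
#' Stage 1 varies the phi structure over the candidate set while p and pent
#' stay saturated; the best-AICc phi is fixed. Stage 2 repeats for p, stage 3
#' for pent (constant excluded a priori). All evaluated fits are returned
#' with AICc weights `w_i = exp(-delta_i / 2) / sum exp(-delta_j / 2)`.
#'
#' @param history a `capture_history`.
#' @param structures candidate structures for phi and p (default: saturated,
#'   constant, time, sex).
#' @param pent_structures candidates for pent (default: the same minus
#'   constant).
#' @param control passed to [fit_popan()].
#' @return object of class `popan_selection`: `fits` (all evaluated, AICc
#'   order), `best`, `table` (model, K, loglik, AICc, weight, N).
#' @export
stepwise_select <- function(history,
                            structures = c("time*sex", "constant", "time", "sex"),
                            pent_structures = setdiff(structures, "constant"),
                            control = list(maxit = 500)) {
  gd <- popan_group_data(history)
  G <- length(gd$groups)
  saturated <- if (G > 1L && "time*sex" %in% structures) "time*sex" else "time"
  sat_pent <- if (G > 1L && "time*sex" %in% pent_structures) "time*sex" else "time"
  cache <- new.env(parent = emptyenv())
  eval_spec <- function(phi, p, pent) {
    spec <- tryCatch(canonical_spec(popan_spec_unchecked(phi, p, pent), G),
                     error = function(e) NULL)
    if (is.null(spec)) return(NULL)
    key <- format(spec)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- tryCatch(fit_popan(history, spec, control = control),
                    error = function(e) NULL)
    if (!is.null(fit) && !fit$converged) fit <- NULL
    cache[[key]] <- if (is.null(fit)) "failed" else fit
    cache[[key]]
  }
  best_of <- function(fits) {
    fits <- Filter(function(f) inherits(f, "popan_fit"), fits)
    if (!length(fits)) return(NULL)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]]
  }
  s1 <- lapply(structures, function(s) eval_spec(s, saturated, sat_pent))
  b1 <- best_of(s1)
  if (is.null(b1)) stop("all stage-1 POPAN fits failed")
  phi_fix <- b1$spec$phi
  s2 <- lapply(structures, function(s) eval_spec(phi_fix, s, sat_pent))
  b2 <- best_of(s2)
  p_fix <- if (is.null(b2)) saturated else b2$spec$p
  s3 <- lapply(pent_structures, function(s) eval_spec(phi_fix, p_fix, s))
  fits <- Filter(function(f) inherits(f, "popan_fit"), as.list(cache))
  if (!length(fits)) stop("all POPAN fits failed")
  ord <- order(vapply(fits, `[[`, numeric(1), "aicc"))
  fits <- fits[ord]
  w <- aicc_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  for (i in seq_along(fits)) fits[[i]]$aicc_weight <- w[i]
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), character(1)),
    K = vapply(fits, `[[`, numeric(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    weight = w,
    N_total = vapply(fits, `[[`, numeric(1), "N_total"),
    stringsAsFactors = FALSE)
  structure(list(fits = fits, best = fits[[1]], table = tab),
            class = "popan_selection")
}

#' @export
print.popan_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Model-averaged superpopulation estimate
#'
#' AICc-weighted average of N over the converged fits; when the top model's
#' weight is at least `top_threshold` (close to one), its estimate is used
#' alone.
#'
#' @param fits a `popan_selection` or list of `popan_fit` objects.
#' @param top_threshold weight above which the best model is used alone
#'   (default 0.99).
#' @return list with `N_total`, `N_by_group`, `weights`, `method`
#'   (`"averaged"` or `"best"`).
#' @export
model_average_N <- function(fits, top_threshold = 0.99) {
  if (inherits(fits, "popan_selection")) fits <- fits$fits
  fits <- Filter(function(f) inherits(f, "popan_fit") && f$converged, fits)
  if (!length(fits)) stop("no converged fits to average")
  w <- aicc_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  top <- which.max(w)
  if (w[top] >= top_threshold || length(fits) == 1L) {
    return(list(N_total = fits[[top]]$N_total,
                N_by_group = fits[[top]]$N_hat,
                weights = w, method = "best"))
  }
  groups <- names(fits[[1]]$N_hat)
  byg <- Reduce(`+`, lapply(seq_along(fits), function(i) {
    v <- fits[[i]]$N_hat[groups]
    v[is.na(v)] <- 0
    w[i] * v
  }))
  list(N_total = sum(vapply(seq_along(fits),
                            function(i) w[i] * fits[[i]]$N_total, numeric(1))),
       N_by_group = byg, weights = w, method = "averaged")
}

#' Choose a pond abundance estimate
#'
#' Implements the proxy rule for sparse data: when the proportion of
#' individuals recaptured at least once reaches `threshold` (default 0.08)
#' and POPAN fitting succeeds, the model-averaged superpopulation estimate is
#' used; otherwise the count of distinct individuals stands in as a
#' comparable (if conservative) abundance proxy.
#'
#' @param records encounter records of one species at one pond (or any unit
#'   for which an abundance is wanted).
#' @param sessions session vector defining history columns (default observed).
#' @param threshold minimum proportion recaptured for model-based estimation.
#' @param structures candidate structures for [stepwise_select()]; the
#'   default for pond-level data omits sex terms, which are rarely
#'   identifiable at that scale.
#' @param min_captures sessions with fewer captures are dropped from the
#'   history before fitting.
#' @return list with `a` (the abundance), `method` (`"popan"` or `"count"`),
#'   `n_individuals`, `prop_recaptured`, and `selection` when model-based.
#' @export
choose_abundance <- function(records, sessions = NULL, threshold = 0.08,
                             structures = c("constant", "time"),
                             min_captures = 1L) {
  ids <- unique(records$individual_id)
  n <- length(ids)
  if (n == 0) {
    return(list(a = 0, method = "count", n_individuals = 0,
                prop_recaptured = 0))
  }
  tab <- table(records$individual_id)
  prop_recap <- sum(tab >= 2) / n
  out <- list(a = n, method = "count", n_individuals = n,
              prop_recaptured = prop_recap)
  if (prop_recap < threshold || sum(tab) - n < 1) return(out)
  est <- tryCatch({
    ch <- build_capture_histories(records, sessions = sessions,
                                  min_captures = min_captures)
    if (ncol(ch$matrix) < 2 || nrow(ch$matrix) < 3) stop("too sparse")
    sel <- stepwise_select(ch, structures = structures,
                           pent_structures = setdiff(structures, "constant"))
    avg <- model_average_N(sel)
    list(a = avg$N_total, selection = sel, avg = avg)
  }, error = function(e) NULL)
  if (is.null(est) || !is.finite(est$a)) return(out)
  list(a = est$a, method = "popan", n_individuals = n,
       prop_recaptured = prop_recap, selection = est$selection,
       N_by_group = est$avg$N_by_group)
}
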