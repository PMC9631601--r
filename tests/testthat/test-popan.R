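# POPAN likelihood, fitting, model selection and abundance choice.

make_history <- function(H, sex = NULL) {
  if (is.null(sex)) sex <- rep("U", nrow(H))
  structure(list(matrix = H, sex = sex, sessions = seq_len(ncol(H))),
            class = "capture_history")
}

test_that("degenerate all-detected history has log-likelihood zero at N = n", {
  n <- 7
  H <- matrix(1L, n, 2)
  ll <- pondscape:::popan_loglik_group(unique(H), n, phi = 1, p = c(1, 1),
                                       pent = c(1, 0), N = n)
  expect_equal(ll, 0, tolerance = 1e-10)
})

test_that("likelihood equals exhaustive latent-state enumeration on toy data", {
  set.seed(42)
  for (rep in 1:20) {
    T <- sample(2:3, 1)
    phi <- runif(T - 1, 0.3, 0.95)
    p <- runif(T, 0.2, 0.9)
    pent <- as.numeric(prop.table(runif(T, 0.1, 1)))
    m <- sample(1:3, 1)
    H <- matrix(rbinom(m * T, 1, 0.6), m, T)
    H <- H[rowSums(H) > 0, , drop = FALSE]
    if (nrow(H) == 0) next
    H <- unique(H)
    cnt <- sample(1:2, nrow(H), replace = TRUE)
    N <- sum(cnt) + runif(1, 0.5, 5)
    expect_equal(
      pondscape:::popan_loglik_group(H, cnt, phi, p, pent, N),
      oracle_popan_loglik(H, cnt, phi, p, pent, N),
      tolerance = 1e-10)
  }
})

test_that("public log-likelihood matches the oracle and ignores row order", {
  H <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 1), c(0, 0, 1), c(0, 1, 0))
  ch <- make_history(H)
  pent <- c(0.5, 0.3, 0.2)
  beta <- beta_for_constant_model(0.7, 0.5, pent, N = nrow(H) + 2.5, n = nrow(H))
  spec <- popan_spec("constant", "constant", "time")
  ll <- popan_loglik(ch, spec, beta)
  Hu <- unique(H)
  cnt <- as.numeric(table(apply(H, 1, paste, collapse = ""))[
    apply(Hu, 1, paste, collapse = "")])
  expect_equal(ll, oracle_popan_loglik(Hu, cnt, rep(0.7, 2), rep(0.5, 3),
                                       pent, nrow(H) + 2.5),
               tolerance = 1e-10)
  set.seed(9)
  ch_perm <- make_history(H[sample(nrow(H)), ])
  expect_equal(popan_loglik(ch_perm, spec, beta), ll, tolerance = 1e-12)
  expect_error(popan_loglik(ch, spec, c(beta[-1], Inf)), "finite")
  expect_error(popan_loglik(make_history(H[0, , drop = FALSE]), spec, beta),
               "empty")
})

test_that("a priori constant pent is rejected", {
  expect_error(popan_spec("time", "time", "constant"), "disallowed")
})

test_that("perfect detection forces N_hat to the observed count", {
  rec <- sim_popan_dataset(seed = 3, N = 60, phi = 1, p = 1, n_sessions = 3,
                           pent = c(1, 0, 0))
  ch <- build_capture_histories(rec)
  fit <- fit_popan(ch, popan_spec("constant", "constant", "time"))
  expect_equal(fit$N_total, nrow(ch$matrix), tolerance = 1e-3)
})

test_that("estimates depend on the data only through history multiplicities", {
  # Doubling every multiplicity leaves the rate estimates essentially
  # unchanged. The match is not exact: in the unconditional superpopulation
  # likelihood the continuous-N combinatorial term is not homogeneous in n,
  # so the identity holds only to first order at finite sample size.
  rec <- sim_popan_dataset(seed = 8, N = 150, phi = 0.8, p = 0.5, n_sessions = 4)
  ch <- build_capture_histories(rec)
  fit1 <- fit_popan(ch, popan_spec("constant", "constant", "time"))
  doubled <- make_history(rbind(ch$matrix, ch$matrix),
                          sex = c(ch$sex, ch$sex))
  fit2 <- fit_popan(doubled, popan_spec("constant", "constant", "time"))
  expect_equal(fit1$phi_hat, fit2$phi_hat, tolerance = 0.02)
  expect_equal(fit1$p_hat, fit2$p_hat, tolerance = 0.02)
  expect_equal(fit1$pent_hat, fit2$pent_hat, tolerance = 0.02)
  expect_equal(fit2$N_total, 2 * fit1$N_total, tolerance = 0.02)
})

test_that("pent estimates sum to one and probabilities stay in range", {
  rec <- sim_popan_dataset(seed = 12, N = 300, n_sessions = 5,
                           pent = c(0.4, 0.3, 0.2, 0.1, 0))
  fit <- fit_popan(build_capture_histories(rec),
                   popan_spec("constant", "constant", "time"))
  expect_equal(unname(colSums(fit$pent_hat)), rep(1, ncol(fit$pent_hat)),
               tolerance = 1e-9)
  expect_true(all(fit$phi_hat >= 0 & fit$phi_hat <= 1))
  expect_true(all(fit$p_hat >= 0 & fit$p_hat <= 1))
  expect_true(fit$K >= 4)
})

test_that("AICc follows its closed form, limit and monotonicity", {
  expect_equal(aicc(0, 4, 100), 8 + 40 / 95)
  expect_equal(aicc(-10, 3, 1e9), 20 + 6, tolerance = 1e-6)  # AIC limit
  expect_true(aicc(-10, 5, 50) > aicc(-10, 4, 50))
  expect_error(aicc(0, 10, 11), "n_eff")
  # weights are invariant to a constant shift of all log-likelihoods
  a1 <- c(100, 102, 105)
  w1 <- pondscape:::aicc_weights(a1)
  expect_equal(w1, pondscape:::aicc_weights(a1 + 50))
  expect_equal(sum(w1), 1)
})

test_that("stepwise selection is deterministic, weights normalized, and favours the generating structure", {
  rec <- sim_popan_dataset(seed = 5, N = 400, phi = 0.8, p = 0.5, n_sessions = 5)
  ch <- build_capture_histories(rec)
  sel1 <- stepwise_select(ch, structures = c("constant", "time"))
  sel2 <- stepwise_select(ch, structures = c("constant", "time"))
  expect_identical(sel1$table, sel2$table)
  expect_equal(sum(sel1$table$weight), 1)
  # constant-phi data: selection should prefer constant phi in most replicates
  picks <- vapply(1:10, function(s) {
    reci <- sim_popan_dataset(seed = 100 + s, N = 400, phi = 0.8, p = 0.5,
                              n_sessions = 5)
    sel <- stepwise_select(build_capture_histories(reci),
                           structures = c("constant", "time"))
    sel$best$spec$phi
  }, character(1))
  expect_gt(mean(picks == "constant"), 0.5)
})

test_that("model averaging follows AICc weights with the top-model shortcut", {
  mk <- function(aicc, N) structure(list(aicc = aicc, N_total = N,
                                         N_hat = c(all = N), converged = TRUE),
                                    class = "popan_fit")
  # equal weights: plain average
  avg <- model_average_N(list(mk(100, 100), mk(100, 200)))
  expect_equal(avg$N_total, 150)
  expect_equal(avg$method, "averaged")
  # single fit: identity
  expect_equal(model_average_N(list(mk(50, 123)))$N_total, 123)
  # dominant top weight: best model used alone
  avg2 <- model_average_N(list(mk(100, 100), mk(100 + 2 * log(0.995 / 0.005), 1e6)))
  expect_equal(avg2$N_total, 100)
  expect_equal(avg2$method, "best")
})

test_that("abundance choice applies the recapture-proportion proxy rule", {
  # 100 individuals, 5 recaptured once: 0.05 < 0.08 -> photoidentified count
  rec <- data.frame(
    individual_id = c(sprintf("i%03d", 1:100), sprintf("i%03d", 1:5)),
    species = "sp", sex = "U",
    date = as.Date("2019-03-01") + c(rep(0, 100), rep(14, 5)),
    session = c(rep(1L, 100), rep(2L, 5)),
    stringsAsFactors = FALSE)
  est <- choose_abundance(rec)
  expect_equal(est$a, 100)
  expect_equal(est$method, "count")
  # no individuals
  expect_equal(choose_abundance(rec[0, ])$a, 0)
  # perfect detection: POPAN recovers the true superpopulation
  rec2 <- sim_popan_dataset(seed = 7, N = 80, phi = 1, p = 1, n_sessions = 3,
                            pent = c(1, 0, 0))
  est2 <- choose_abundance(rec2)
  expect_equal(est2$method, "popan")
  expect_equal(est2$a, 80, tolerance = 0.01)
})
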