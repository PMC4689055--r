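test_that("expected fitted markers per iteration follows (1 - pi) p", {
  expect_equal(expected_markers_per_iteration(0.95, 50000), 2500)
  expect_equal(expected_markers_per_iteration(0.996, 50000), 200)
  expect_equal(expected_markers_per_iteration(0, 1234), 1234)
  expect_error(expected_markers_per_iteration(1.2, 10), "pi")
})

test_that("prior scale derivation matches the implied-variance identity", {
  expect_equal(derive_scale_beta(1, 0, 4, mean_2pq = 0.5, n_markers = 2), 0.5)
  s1 <- derive_scale_beta(1, 0.5, 4.2, 0.3, 100)
  expect_equal(derive_scale_beta(2, 0.5, 4.2, 0.3, 100), 2 * s1)
  expect_gt(derive_scale_beta(1, 0.9, 4.2, 0.3, 100), s1)
  expect_error(derive_scale_beta(1, 1, 4.2, 0.3, 100), "pi")
  expect_error(derive_scale_beta(1, 0, 2, 0.3, 100), "nu_beta")
})

test_that("prior_spec enforces the family's constraints", {
  expect_equal(prior_spec("BayesA")$pi, 0)
  expect_error(prior_spec("BayesC0", pi = 0.5), "pi = 0")
  expect_error(prior_spec("BayesC", pi = 1), "degenerate")
  expect_error(prior_spec("BayesC", nu_beta = 2), "nu_beta")
  expect_error(chain_config(100, 100), "burn_in")
})

test_that("BayesC0 with fixed variances matches the ridge closed form", {
  set.seed(60)
  for (s in 1:3) {
    n <- 80
    p <- 120
    X <- matrix(rbinom(n * p, 2, 0.3), n, p)
    y <- drop(X %*% rnorm(p, 0, 0.1) + rnorm(n))
    pr <- prior_spec("BayesC0", fixed_sigma2_beta = 0.05, fixed_sigma2_e = 1)
    fit <- run_chain(X, y, pr, chain_config(2000, 200, seed = 60 + s))
    expect_gt(cor(fit$effect, ridge_effects(X, y, 1 / 0.05)), 0.98)
  }
})

test_that("a single perfectly informative marker recovers its effect", {
  set.seed(61)
  z <- rbinom(120, 2, 0.4)
  y <- z - mean(z)
  fit <- run_chain(matrix(z, ncol = 1), y, prior_spec("BayesC0"),
                   chain_config(2000, 500, seed = 62))
  expect_equal(fit$effect, 1, tolerance = 0.02)
  expect_equal(fit$inclusion, 1)
})

test_that("pi = 0 methods include every marker; chains are seed-deterministic", {
  g <- toy_geno(n = 60, p = 40, seed = 63)
  y <- drop(g$dosage %*% rnorm(40, 0, 0.3))
  for (m in c("BayesA", "BayesC0")) {
    fit <- run_chain(g, y, prior_spec(m), chain_config(500, 100, seed = 64))
    expect_true(all(fit$inclusion == 1))
  }
  f1 <- run_chain(g, y, prior_spec("BayesB", pi = 0.8),
                  chain_config(800, 200, seed = 65))
  f2 <- run_chain(g, y, prior_spec("BayesB", pi = 0.8),
                  chain_config(800, 200, seed = 65))
  expect_identical(f1$effect, f2$effect)
  expect_identical(f1$inclusion, f2$inclusion)
  f3 <- run_chain(g, y, prior_spec("BayesB", pi = 0.8),
                  chain_config(800, 200, seed = 66))
  expect_false(identical(f1$effect, f3$effect))
})

test_that("posterior means are exchangeable under marker permutation", {
  set.seed(67)
  n <- 80
  p <- 40
  X <- matrix(rbinom(n * p, 2, 0.35), n, p)
  colnames(X) <- sprintf("m%02d", 1:p)
  y <- drop(X %*% c(rep(1, 3), rep(0, p - 3)) + rnorm(n, 0, 0.3))
  pr <- prior_spec("BayesC0", fixed_sigma2_beta = 0.1, fixed_sigma2_e = 0.1)
  fit <- run_chain(X, y, pr, chain_config(4000, 500, seed = 68))
  perm <- sample(p)
  fit_p <- run_chain(X[, perm], y, pr, chain_config(4000, 500, seed = 69))
  back <- fit_p$effect[order(perm)]
  expect_gt(cor(fit$effect, back), 0.98)
})

test_that("inclusion counts on null data are calibrated to the prior", {
  set.seed(70)
  n <- 100
  p <- 200
  pi0 <- 0.9
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- rnorm(n)
  pr <- prior_spec("BayesC", pi = pi0, fixed_sigma2_beta = 0.01,
                   fixed_sigma2_e = 1)
  fit <- run_chain(X, y, pr, chain_config(2000, 500, seed = 71))
  mean_included <- sum(fit$inclusion)
  expect_lt(abs(mean_included - (1 - pi0) * p),
            3 * sqrt(p * pi0 * (1 - pi0)))
})

test_that("BayesCpi recovers strong sparsity", {
  set.seed(72)
  n <- 300
  p <- 600
  X <- matrix(rbinom(n * p, 2, rep(runif(p, 0.1, 0.5), each = n)), n, p)
  causal <- sample(p, 6)
  y <- drop(X[, causal] %*% rep(1, 6))
  fit <- run_chain(X, y, prior_spec("BayesCpi", pi = 0.95),
                   chain_config(1500, 400, seed = 73))
  expect_gt(fit$pi, 0.9)
  expect_lt(fit$pi, 1.0)
  expect_length(fit$pi_samples, 1100)
})

test_that("run_chain rejects degenerate inputs", {
  g <- toy_geno(n = 20, p = 10, seed = 74)
  expect_error(run_chain(g, rep(1, 20), prior_spec("BayesC0")), "constant")
  expect_error(run_chain(g, rnorm(5), prior_spec("BayesC0")), "length")
})

test_that("convergence monitor reproduces the full-chain correlation", {
  sim <- simulate_qtl_dataset(n_chromosomes = 2, markers_per_chromosome = 150,
                              n_founders = 80, n_generations = 1,
                              qtl_spacing = 20, seed = 75)
  y <- simulate_phenotype(sim$geno, sim$qtl, "summed")
  predictors <- setdiff(seq_len(300), sim$qtl$indices)
  sub <- subset_markers(sim$geno, predictors)
  fit <- run_chain(sub, y, prior_spec("BayesC", pi = 0.95),
                   chain_config(2500, 500, seed = 76, store_samples = TRUE))
  traj <- monitor_convergence(fit, sub, y, c(100, 500, 1500, 2000))
  full <- accuracy(y, dgv(sub, fit))
  expect_equal(traj$correlation[4], full, tolerance = 1e-12)
  # plateau: predictive ability stops improving well before the chain ends
  expect_lt(abs(traj$correlation[4] - traj$correlation[3]), 0.005)
  expect_error(monitor_convergence(fit, sub, y, 5000), "beyond")
  fit2 <- run_chain(sub, y, prior_spec("BayesC0"), chain_config(300, 100,
                                                                seed = 77))
  expect_error(monitor_convergence(fit2, sub, y, 10), "store_samples")
})
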