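# Conjugate-oracle, enumeration-oracle and reduction tests for the MCMC
# engine. All tests run the installed sampler in constrained modes (fixed
# variances, fixed mean, no markers) so the closed forms apply to the exact
# code path used in real fits.

fixed_opts <- function(se2, sb2 = 1, mu0 = TRUE) {
  list(update_mu = !mu0, mu_init = 0,
       fix_sigma2_e = TRUE, sigma2_e_init = se2,
       fix_sigma2_beta = TRUE, sigma2_beta_init = sb2)
}

test_that("the mean's full conditional matches its closed form", {
  set.seed(31)
  n <- 40; se2 <- 2.5
  y <- rnorm(n, 3, 2)
  fit <- gs_fit(y, NULL, "blup", prior_spec(S = 1),
                chain_config(11000, 1000, seed = 32),
                options = list(fix_sigma2_e = TRUE, sigma2_e_init = se2))
  # with no markers the draws are iid N(mean(y), se2/n)
  expect_lt(abs(fit$mu - mean(y)),
            3 * bm_se(fit$batch_means$mu) + 1e-8)
  expect_lt(abs(fit$mu_var - se2 / n) / (se2 / n), 0.12)
})

test_that("a single SNP effect matches the conjugate normal posterior", {
  set.seed(33)
  n <- 30; se2 <- 1.8; sb2 <- 0.7
  x <- rbinom(n, 2, 0.4)
  y <- 0.9 * x + rnorm(n, 0, sqrt(se2))
  fit <- gs_fit(y, matrix(x, ncol = 1), "bayesA", prior_spec(S = 1),
                chain_config(12000, 2000, seed = 34),
                options = fixed_opts(se2, sb2))
  a <- sum(x^2); b <- sum(x * y)
  denom <- a + se2 / sb2
  expect_lt(abs(fit$beta[1] - b / denom),
            3 * bm_se(fit$batch_means$beta[, 1]) + 1e-8)
  expect_lt(abs(fit$beta_var[1] - se2 / denom) / (se2 / denom), 0.12)
})

test_that("vanishing and infinite prior variance give the ridge limits", {
  set.seed(35)
  n <- 50
  x <- rbinom(n, 2, 0.5)
  y <- 1.2 * x + rnorm(n, 0, 0.5)
  se2 <- 0.25
  # prior variance -> infinity: posterior mean -> least squares
  f1 <- gs_fit(y, matrix(x, ncol = 1), "bayesA", prior_spec(S = 1),
               chain_config(6000, 1000, seed = 36),
               options = fixed_opts(se2, 1e9))
  expect_lt(abs(f1$beta[1] - sum(x * y) / sum(x^2)), 0.02)
  # prior variance -> 0: effect shrunk to zero
  f0 <- gs_fit(y, matrix(x, ncol = 1), "bayesA", prior_spec(S = 1),
               chain_config(6000, 1000, seed = 37),
               options = fixed_opts(se2, 1e-10))
  expect_lt(abs(f0$beta[1]), 1e-3)
})

test_that("the flat-prior variance update matches ScInvChi2(n-2, SSE)", {
  set.seed(38)
  n <- 25
  y <- rnorm(n, 0, 1.5)
  fit <- gs_fit(y, NULL, "blup", prior_spec(S = 1),
                chain_config(21000, 1000, seed = 39),
                options = list(update_mu = FALSE, mu_init = 0))
  ss <- sum(y^2)
  m_true <- ss / (n - 2 - 2)
  v_true <- 2 * ss^2 / ((n - 4)^2 * (n - 6))
  expect_lt(abs(fit$sigma2_e - m_true), 3 * sqrt(v_true / fit$n_samples))
})

test_that("polygenic effects match the closed-form GLS conditional mean", {
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  A <- build_A(ped)
  ainv <- pedigree_ainverse(ped, A)
  se2 <- 0.5; su2 <- 1.2
  y <- c(1.1, -0.4, 2.0)
  fit <- gs_fit(y, NULL, "blup", prior_spec(S = 1),
                chain_config(42000, 2000, seed = 40),
                ainv = ainv, obs_ped = 1:3,
                options = list(update_mu = FALSE, mu_init = 0,
                               fix_sigma2_e = TRUE, sigma2_e_init = se2,
                               fix_sigma2_u = TRUE, sigma2_u_init = su2))
  C <- solve(diag(3) / se2 + solve(A) / su2)
  u_true <- as.numeric(C %*% y / se2)
  for (i in 1:3)
    expect_lt(abs(fit$u[i] - u_true[i]),
              3 * bm_se(fit$batch_means$u[, i]) + 0.02)
})

test_that("with A = I the polygenic update is an independent ridge", {
  set.seed(41)
  n <- 6
  ped <- data.frame(id = 1:n, sire = 0, dam = 0) # unrelated: A = I
  ainv <- pedigree_ainverse(ped)
  expect_equal(as.matrix(ainv), diag(n), ignore_attr = TRUE)
  se2 <- 0.4; su2 <- 2
  y <- rnorm(n)
  fit <- gs_fit(y, NULL, "blup", prior_spec(S = 1),
                chain_config(30000, 2000, seed = 42),
                ainv = ainv, obs_ped = 1:n,
                options = list(update_mu = FALSE, mu_init = 0,
                               fix_sigma2_e = TRUE, sigma2_e_init = se2,
                               fix_sigma2_u = TRUE, sigma2_u_init = su2))
  shrink <- (1 / se2) / (1 / se2 + 1 / su2)
  for (i in 1:n)
    expect_lt(abs(fit$u[i] - shrink * y[i]),
              3 * bm_se(fit$batch_means$u[, i]) + 0.02)
})

test_that("Bayes C inclusion probabilities match exhaustive enumeration", {
  set.seed(43)
  n <- 35; p <- 3
  X <- matrix(rbinom(n * p, 2, 0.45), n, p)
  se2 <- 1; sb2 <- 0.5; cc <- 0.02; pi <- 0.3
  beta_true <- c(0.8, 0, -0.4)
  y <- as.numeric(X %*% beta_true) + rnorm(n, 0, sqrt(se2))
  truth <- enumerate_inclusion(y, X, se2, v_in = sb2, v_out = cc * sb2, pi)
  pr <- prior_spec(S = 1, pi = pi, c = cc)
  fit <- gs_fit(y, X, "bayesC", pr, chain_config(42000, 2000, seed = 44),
                options = fixed_opts(se2, sb2))
  for (j in 1:p)
    expect_lt(abs(fit$inclusion[j] - truth[j]),
              3 * bm_se(fit$batch_means$gamma[, j]) + 0.02)
})

test_that("Bayes A/B reversible jump matches exhaustive enumeration", {
  set.seed(45)
  n <- 30; p <- 2
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  se2 <- 1; sb2 <- 0.6; pi <- 0.25
  y <- as.numeric(X %*% c(0.7, 0)) + rnorm(n, 0, sqrt(se2))
  truth <- enumerate_inclusion(y, X, se2, v_in = sb2, v_out = 0, pi)
  pr <- prior_spec(S = 1, pi = pi, k = 1, m = 3)
  fit <- gs_fit(y, X, "bayesAB", pr, chain_config(42000, 2000, seed = 46),
                options = fixed_opts(se2, sb2))
  for (j in 1:p)
    expect_lt(abs(fit$inclusion[j] - truth[j]),
              3 * bm_se(fit$batch_means$gamma[, j]) + 0.02)
  # excluded SNPs are held at exactly zero between sweeps: with the SNP
  # out, its posterior-mean effect comes only from "in" phases
  expect_true(all(abs(fit$beta) < 1))
})

test_that("degenerate mixtures reduce to their parent samplers", {
  ds <- sim_dataset(tiny_config(), seed = 47)
  ai <- pedigree_ainverse(ds$pedigree)
  ch <- chain_config(1500, 500, seed = 48)
  fa <- fit_timepoint(ds, 397, "bayesA", prior_spec(), ch, ainv = ai)
  fab <- fit_timepoint(ds, 397, "bayesAB", prior_spec(pi = 1), ch, ainv = ai)
  # pi = 1: the hybrid IS Bayes A, trajectory-identical under a shared seed
  expect_equal(fab$beta, fa$beta, tolerance = 1e-12)
  expect_equal(fab$sigma2_e, fa$sigma2_e, tolerance = 1e-12)
  expect_true(all(fab$inclusion == 1))
  # c = 1: identical components, the indicator stays at its prior
  fc <- fit_timepoint(ds, 397, "bayesC", prior_spec(pi = 0.3, c = 1), ch,
                      ainv = ai)
  n_draws <- fc$n_samples * length(fc$inclusion)
  expect_lt(abs(mean(fc$inclusion) - 0.3), 4 / sqrt(n_draws) + 0.01)
})

test_that("the residual cache stays consistent over a long realistic chain", {
  ds <- sim_dataset(tiny_config(), seed = 49)
  ai <- pedigree_ainverse(ds$pedigree)
  fit <- fit_timepoint(ds, 397, "bayesC", prior_spec(),
                       chain_config(4000, 500, seed = 50), ainv = ai)
  expect_lt(fit$max_resid_dev, 1e-6)
})

test_that("column order does not matter beyond Monte-Carlo noise", {
  ds <- sim_dataset(tiny_config(), seed = 51)
  obs <- which(ds$pedigree$phenotyped)
  y <- ds$phenotypes$t397[obs]
  X <- ds$genotypes[obs, ]
  perm <- sample(ncol(X))
  f1 <- gs_fit(y, X, "bayesA", prior_spec(), chain_config(4000, 1000, seed = 52))
  f2 <- gs_fit(y, X[, perm], "bayesA", prior_spec(),
               chain_config(4000, 1000, seed = 53))
  beta_back <- f2$beta[order(perm)]
  g1 <- as.numeric(ds$genotypes %*% f1$beta)
  g2 <- as.numeric(ds$genotypes %*% beta_back)
  expect_gt(cor(g1, g2), 0.98)
})

test_that("monomorphic markers are skipped with a zero effect", {
  set.seed(54)
  n <- 40
  X <- cbind(rbinom(n, 2, 0.5), rep(2, n))
  y <- X[, 1] + rnorm(n)
  fit <- gs_fit(y, X, "bayesA", prior_spec(), chain_config(800, 200, seed = 55),
                center = TRUE)
  expect_identical(fit$beta[2], 0)
  expect_gt(fit$beta[1], 0.5)
})

test_that("marker effects are recovered on data with a few large QTL", {
  set.seed(56)
  n <- 1000; p <- 100
  freq <- runif(p, 0.1, 0.9)
  X <- sapply(freq, function(f) rbinom(n, 2, f))
  beta_true <- numeric(p)
  beta_true[sample(p, 5)] <- rnorm(5, 0, 1)
  g <- as.numeric(X %*% beta_true)
  y <- g + rnorm(n, 0, sd(g)) # h2 = 0.5
  fit <- gs_fit(y, X, "bayesA", prior_spec(),
                chain_config(1500, 500, seed = 57))
  expect_gt(cor(fit$beta, beta_true), 0.6)
})
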