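test_that("zero-truncated Poisson draws have the conditioned law", {
  set.seed(2)
  for (rate in c(1e-8, 0.5, 2, 50)) {
    expect_true(all(rtruncpois(2000, rate) >= 1))
  }
  # tiny rate: essentially all mass at 1
  expect_true(all(rtruncpois(5000, 1e-8) == 1))
  # closed-form truncated mean at rate 2
  n <- 1e5
  draws <- rtruncpois(n, 2)
  mu <- 2 / (1 - exp(-2))
  v <- mu * (1 + 2 - mu)                       # truncated-Poisson variance
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / n))
  expect_error(rtruncpois(5, 0), "positive")
  expect_error(rtruncpois(5, Inf), "positive")
})

test_that("latent counts respect the outcome constraint", {
  set.seed(3)
  X <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  X[rowSums(X) == 0, 4] <- 1L
  y <- rbinom(30, 1, 0.5)
  d <- make_dataset(X, sex = y, z = sample(1:4, 30, replace = TRUE))
  pars <- model_parameters(rgamma(12, 1, 1) + 0.05, c(1.3, 0.8, 1))
  for (i in 1:25) {
    W <- sample_latent_counts(pars, d)
    expect_true(all(W[y == 1, ] == 0))          # female: no counts
    expect_true(all(rowSums(W[y == 0, , drop = FALSE]) >= 1))
    expect_true(all(W[X == 0] == 0))            # only on intercourse days
  }
  # all-female dataset: identically zero
  df <- make_dataset(X, sex = rep(1L, 30), z = rep(1L, 30))
  expect_true(all(sample_latent_counts(pars, df) == 0))
})

test_that("male-cycle counts land on intercourse days as a multinomial", {
  # one intercourse day: the whole truncated total lands there
  x1 <- integer(12)
  x1[6] <- 1L
  d1 <- make_dataset(matrix(x1, 1), sex = 0L, z = 1L)
  pars <- model_parameters(rep(0.5, 12))
  set.seed(14)
  W <- sample_latent_counts(pars, d1)
  expect_true(W[1, 6] >= 1 && sum(W[1, -6]) == 0)
  # two days with lambda ratio 3:1 -> expected allocation share 0.75/0.25
  lam <- rep(0.5, 12)
  lam[2] <- 0.6
  lam[7] <- 0.2
  x2 <- integer(12)
  x2[c(2, 7)] <- 1L
  n <- 20000
  d2 <- make_dataset(matrix(rep(x2, each = n), n), sex = rep(0L, n),
                     z = rep(1L, n))
  W2 <- sample_latent_counts(model_parameters(lam), d2)
  tot <- sum(W2)
  share <- sum(W2[, 2]) / tot
  expect_lt(abs(share - 0.75), 4 * sqrt(0.75 * 0.25 / tot))
})

test_that("lambda update is the stated conjugate gamma draw", {
  # prior-only day: day 12 has no intercourse anywhere
  set.seed(6)
  X <- matrix(0L, 50, 12)
  X[, 1] <- 1L
  X[, 2] <- rbinom(50, 1, 0.5)
  d <- make_dataset(X, sex = rbinom(50, 1, 0.6), z = rep(1L, 50))
  pars <- model_parameters(rep(0.5, 12))
  pr <- prior_spec(a0k = 2, b0k = 3)
  W <- sample_latent_counts(pars, d)
  draws <- replicate(4000, update_lambda(W, pars, d, pr))
  # day with no data: prior Gamma(2, 3), mean 2/3
  expect_lt(abs(mean(draws[12, ]) - 2 / 3),
            4 * sqrt(2 / 9 / 4000))
  # day with data: Gamma(a + sum W, b + sum X xi)
  shp <- 2 + sum(W[, 1])
  rte <- 3 + sum(X[, 1])
  expect_lt(abs(mean(draws[1, ]) - shp / rte),
            4 * sqrt(shp / rte^2 / 4000))
})

test_that("point-mass weight matches 1-D quadrature and never overflows", {
  set.seed(17)
  for (i in 1:100) {
    A <- sample(0:50, 1)
    B <- runif(1, 0.01, 30)
    a <- runif(1, 0.05, 3)
    b <- runif(1, 0.05, 3)
    pi_h <- runif(1, 0.05, 0.95)
    got <- cyclesex:::gamma_pointmass_prob(pi_h, a, b, A, B)
    want <- oracle_pointmass_prob(pi_h, a, b, A, B)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # no-information case: posterior point mass equals the prior weight
  expect_equal(cyclesex:::gamma_pointmass_prob(0.7, 0.1, 0.1, 0, 0), 0.7)
  # huge latent totals stay finite in log space
  for (A in c(1e3, 1e4)) {
    p <- cyclesex:::gamma_pointmass_prob(0.5, 0.1, 0.1, A, A / 2)
    expect_true(is.finite(p) && p >= 0 && p <= 1)
    expect_equal(p, oracle_pointmass_prob(0.5, 0.1, 0.1, A, A / 2),
                 tolerance = 1e-6)
  }
})

test_that("gamma update falls back to the prior without informative cycles", {
  set.seed(23)
  X <- matrix(rbinom(40 * 12, 1, 0.5), 40, 12)
  X[rowSums(X) == 0, 1] <- 1L
  d <- make_dataset(X, sex = rbinom(40, 1, 0.5), z = rep(1L, 40))
  pars <- model_parameters(rep(0.5, 12))
  pr <- prior_spec()
  W <- sample_latent_counts(pars, d)
  g <- replicate(4000, update_gamma(W, pars, d, pr))
  for (h in 1:3) {
    frac <- mean(g[h, ] == 1)
    expect_lt(abs(frac - pr$pi_h[h]),
              4 * sqrt(pr$pi_h[h] * (1 - pr$pi_h[h]) / 4000))
  }
})

test_that("the chain runner is deterministic and honors the point mass", {
  set.seed(51)
  cfg <- generator_config(n_cycles = 40, seed = 77)
  d <- generate_cycles(cfg)
  mc <- mcmc_config(burn_in = 50, iterations = 200, chains = 2, seed = 5)
  f1 <- run_chain(d, prior_spec(), mc)
  f2 <- run_chain(d, prior_spec(), mc)
  expect_identical(f1$chains, f2$chains)
  expect_identical(dim(f1$chains[[1]]), c(200L, 15L))
  # pi = 1: gamma pinned at the point mass forever
  f3 <- run_chain(d, prior_spec(pi_h = 1), mc)
  g <- do.call(rbind, f3$chains)[, c("gamma_1", "gamma_2", "gamma_3")]
  expect_true(all(g == 1))
  # covariate off: gamma columns absent
  f4 <- run_chain(d, prior_spec(), mc, covariate = FALSE)
  expect_identical(colnames(f4$chains[[1]]), cyclesex:::lambda_names())
  # thinning bookkeeping
  mc2 <- mcmc_config(burn_in = 50, iterations = 200, chains = 1, thin = 4,
                     seed = 5)
  expect_identical(nrow(run_chain(d, prior_spec(), mc2)$chains[[1]]), 50L)
  expect_error(mcmc_config(iterations = 10, thin = 3), "multiple")
})

test_that("samples round-trip through the long-format CSV", {
  set.seed(52)
  d <- generate_cycles(generator_config(n_cycles = 25, seed = 12))
  fit <- run_chain(d, prior_spec(),
                   mcmc_config(burn_in = 20, iterations = 60, chains = 2,
                               seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(fit, path)
  back <- read_samples(path)
  expect_equal(length(back$chains), 2)
  for (ch in 1:2) {
    expect_equal(unname(back$chains[[ch]]), unname(fit$chains[[ch]]),
                 tolerance = 1e-12)
  }
  long <- read.csv(path)
  expect_identical(nrow(long), 2L * 60L * 15L)
  expect_true(all(c("lambda_-8", "gamma_3") %in% long$parameter))
})

test_that("brute-force posterior is exact where closed forms exist", {
  pr <- prior_spec(a0k = 1.5, b0k = 2)
  # no data: prior means and prior point mass
  b0 <- brute_force_posterior(NULL, pr, active_days = -8,
                              gamma_active = TRUE, n_grid = 400)
  expect_equal(unname(b0$mean["lambda_-8"]), 1.5 / 2, tolerance = 0.005)
  expect_equal(b0$p_gamma1, pr$pi_h[1], tolerance = 1e-12)
  # conjugate case: all-female cycles with one intercourse day
  n <- 18
  X <- matrix(0L, n, 12)
  X[, 1] <- 1L
  d <- make_dataset(X, sex = rep(1L, n), z = rep(1L, n))
  bf <- brute_force_posterior(d, pr, active_days = -8, n_grid = 400)
  expect_lt(abs(bf$mean["lambda_-8"] - 1.5 / (2 + n)), 5e-4)
  expect_lt(abs(bf$sd["lambda_-8"] - sqrt(1.5) / (2 + n)), 5e-4)
  # refinement: halving the grid spacing shrinks the error
  exact <- 1.5 / (2 + n)
  errs <- sapply(c(25, 50, 100, 200), function(m) {
    abs(brute_force_posterior(d, pr, -8, n_grid = m)$mean["lambda_-8"] -
          exact)
  })
  expect_true(all(diff(errs) < 0))
  expect_error(brute_force_posterior(d, pr, active_days = c(-8, -7, -6),
                                     gamma_active = TRUE), "3 free")
})

test_that("Gibbs posterior agrees with quadrature on a reduced model", {
  set.seed(61)
  d <- make_reduced_dataset(20, active_days = -8, lambda_active = 0.7)
  pr <- prior_spec()
  bf <- brute_force_posterior(d, pr, active_days = -8, n_grid = 300)
  fit <- run_chain(d, pr,
                   mcmc_config(burn_in = 500, iterations = 6000, chains = 2,
                               seed = 19))
  est <- chain_mcse(fit, "lambda_-8")
  expect_lt(abs(est$mean - bf$mean["lambda_-8"]), 4 * est$mcse)
})
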