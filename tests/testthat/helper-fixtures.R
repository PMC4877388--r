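# Fixture builders used across the test files.

# cycle_dataset from an intercourse matrix, outcomes and follicular classes
make_dataset <- function(X, sex, z = rep(1L, nrow(X)), study = "SYN") {
  X <- as.matrix(X)
  colnames(X) <- cyclesex:::ic_columns()
  df <- data.frame(sex = sex,
                   foll_len = c(12L, 15L, 18L, 22L)[z],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X))
  df$study <- study
  cycle_dataset(df)
}

# reduced dataset: intercourse only on the given relative days
make_reduced_dataset <- function(n, active_days, p_ic = 0.7,
                                 lambda_active, gamma1 = NULL) {
  k <- relative_day_to_index(active_days)
  X <- matrix(0L, n, 12)
  X[, k] <- matrix(rbinom(n * length(k), 1, p_ic), n)
  none <- rowSums(X) == 0
  X[none, k[1]] <- 1L
  z <- if (is.null(gamma1)) rep(1L, n) else sample(1:2, n, replace = TRUE)
  lambda <- rep(0.5, 12)
  lambda[k] <- lambda_active
  gam <- c(if (is.null(gamma1)) 1 else gamma1, 1, 1)
  pf <- prob_female(model_parameters(lambda, gam), X, z)
  make_dataset(X, sex = rbinom(n, 1, pf), z = z)
}

# posterior_samples object from explicit chain matrices
make_samples <- function(..., covariate = TRUE) {
  chains <- list(...)
  structure(list(chains = chains, config = NULL, covariate = covariate,
                 n_cycles = NA_integer_),
            class = "posterior_samples")
}

# Monte-Carlo standard error of a chain mean, via effective sample size
chain_mcse <- function(samples, parameter, transform = identity) {
  draws <- lapply(samples$chains, function(m) transform(m[, parameter]))
  pooled <- unlist(draws)
  ess <- sum(vapply(draws, effective_sample_size, numeric(1)))
  list(mean = mean(pooled), mcse = stats::sd(pooled) / sqrt(ess))
}

# independent log-space quadrature of the gamma-branch marginal likelihood
# integral((1 - pi) * gamma^A * exp(-gamma * B) * dgamma(gamma; a, b)):
# integrand rescaled by its maximum so large A cannot overflow
oracle_pointmass_prob <- function(pi_h, a, b, A, B) {
  logf <- function(g) A * log(g) - g * B + dgamma(g, a, b, log = TRUE)
  mode <- max((A + a - 1) / (B + b), 1e-12)
  m <- logf(mode)
  val <- integrate(function(g) exp(logf(g) - m), 0, Inf,
                   rel.tol = 1e-10)$value
  log_alt <- log1p(-pi_h) + m + log(val)
  log_null <- log(pi_h) - B
  1 / (1 + exp(log_alt - log_null))
}
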