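# Gibbs sampler with Poisson latent-count augmentation.
#
# Augmentation: attach independent latent counts W_ik ~ Poisson(lambda_k *
# xi_i * X_ik) to every cycle/day and identify the outcome with the event
# "no count anywhere": a cycle conceives a female iff sum_k W_ik = 0, which
# reproduces P(female) = exp(-xi_i sum_k X_ik lambda_k) exactly.  Conditional
# on the outcome, female cycles have all counts zero and male cycles carry a
# truncated-Poisson total allocated multinomially across their intercourse
# days.  Given the counts, every lambda_k update is conjugate gamma and each
# gamma_h has an exact two-branch (point mass at 1 vs gamma) conditional.

#' MCMC configuration
#'
#' @param burn_in Discarded initial iterations (default 5000).
#' @param iterations Retained iterations per chain after burn-in
#'   (default 40000).
#' @param chains Number of independent chains (default 2).
#' @param thin Thinning interval (default 1; every `thin`-th retained draw is
#'   stored).
#' @param seed Integer base seed; chain `c` uses `seed + c` with the
#'   Mersenne-Twister generator, so runs are reproducible across platforms.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 5000, iterations = 40000, chains = 2,
                        thin = 1, seed = 1) {
  vals <- c(burn_in = burn_in, iterations = iterations, chains = chains,
            thin = thin)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 1) ||
      burn_in < 0) {
    stop("MCMC settings must be positive integers", call. = FALSE)
  }
  if (iterations %% thin != 0) {
    stop("`iterations` must be a multiple of `thin`", call. = FALSE)
  }
  if (!is.numeric(seed) || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  structure(list(burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 chains = as.integer(chains), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Draw from a zero-truncated Poisson distribution
#'
#' Samples `N >= 1` with `P(N = n) = exp(-rate) rate^n / (n! (1 -
#' exp(-rate)))` by inverse-CDF on the conditioned law (exact; no rejection
#' loop, so small rates cannot stall).
#'
#' @param n Number of draws.
#' @param rate Positive finite Poisson rate(s), recycled to length `n`.
#' @return Integer vector of draws, all at least 1.
#' @export
rtruncpois <- function(n, rate) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be strictly positive and finite", call. = FALSE)
  }
  rate <- rep_len(rate, n)
  p0 <- exp(-rate)
  u <- p0 + stats::runif(n) * (1 - p0)
  pmax(stats::qpois(pmin(u, 1 - 1e-16), rate), 1L)
}

# cycle multipliers for current gamma (vector over the dataset)
cycle_xi <- function(gamma, z) c(1, cumprod(gamma))[z]

#' Sample the latent Poisson counts given parameters and outcomes
#'
#' Female cycles get all-zero counts.  For each male cycle the total count is
#' zero-truncated Poisson with rate `eta_i = xi_i * sum_k X_ik lambda_k`, then
#' allocated across the cycle's intercourse days with multinomial
#' probabilities proportional to `lambda_k` (drawn by exact sequential
#' binomial thinning, vectorized over cycles).
#'
#' @param params A [model_parameters()].
#' @param data A `cycle_dataset` (follicular classes required).
#' @return Integer n x 12 matrix of latent counts `W`.
#' @export
sample_latent_counts <- function(params, data) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(data, "cycle_dataset"))
  X <- intercourse_matrix(data)
  z <- data$foll_class
  if (anyNA(z)) stop("cycles with missing follicular class", call. = FALSE)
  n <- nrow(X)
  W <- matrix(0L, n, 12, dimnames = list(NULL, colnames(X)))
  males <- which(data$sex == 0)
  if (length(males) == 0) return(W)
  xi <- cycle_xi(params$gamma, z)
  Xm <- X[males, , drop = FALSE]
  s <- as.vector(Xm %*% params$lambda)          # sum_k X_ik lambda_k
  if (any(s * xi[males] <= 0)) {
    stop("male cycle with zero total rate", call. = FALSE)
  }
  N <- rtruncpois(length(males), xi[males] * s)
  rem <- N
  remp <- s
  for (k in 1:12) {
    pk <- ifelse(Xm[, k] == 1, params$lambda[k] / remp, 0)
    wk <- stats::rbinom(length(males), rem, pmin(pk, 1))
    W[males, k] <- wk
    rem <- rem - wk
    remp <- remp - Xm[, k] * params$lambda[k]
  }
  W
}

#' Conjugate gamma update of the day parameters
#'
#' Given the latent counts, each `lambda_k` is conditionally
#' Gamma(`a0k + sum_i W_ik`, `b0k + sum_i X_ik xi_i`), independently.
#'
#' @param latent Latent-count matrix from [sample_latent_counts()].
#' @param params Current [model_parameters()] (supplies `gamma`).
#' @param data The `cycle_dataset`.
#' @param priors A [prior_spec()].
#' @return New lambda vector (length 12).
#' @export
update_lambda <- function(latent, params, data, priors) {
  X <- intercourse_matrix(data)
  xi <- cycle_xi(params$gamma, data$foll_class)
  stats::rgamma(12, shape = priors$a0k + colSums(latent),
                rate = priors$b0k + colSums(X * xi))
}

# log mixture weight of the point-mass branch for one gamma_h given
# sufficient statistics A (count sum) and B (exposure sum); log-space so
# large A cannot overflow
gamma_pointmass_prob <- function(pi_h, a0h, b0h, A, B) {
  if (pi_h >= 1) return(1)
  if (pi_h <= 0) return(0)
  la <- log(pi_h) - B
  lb <- log1p(-pi_h) + a0h * log(b0h) - lgamma(a0h) +
    lgamma(a0h + A) - (a0h + A) * log(b0h + B)
  1 / (1 + exp(lb - la))
}

#' Point-mass mixture update of the follicular-class multipliers
#'
#' Systematic scan over `h = 1, 2, 3`.  For each `h`, with
#' `A_h = sum_{i: z_i > h} sum_k W_ik` and
#' `B_h = sum_{i: z_i > h} sum_k X_ik lambda_k prod_{h' < z_i, h' != h}
#' gamma_{h'}`, the conditional sets `gamma_h = 1` with probability
#' `pi_h e^{-B_h} / [pi_h e^{-B_h} + (1 - pi_h) (b0h^a0h / Gamma(a0h))
#' Gamma(a0h + A_h) / (b0h + B_h)^{a0h + A_h}]` (evaluated in log space) and
#' otherwise draws Gamma(`a0h + A_h`, `b0h + B_h`).
#'
#' @inheritParams update_lambda
#' @return New gamma vector (length 3).
#' @export
update_gamma <- function(latent, params, data, priors) {
  X <- intercourse_matrix(data)
  z <- data$foll_class
  gamma <- params$gamma
  s <- as.vector(X %*% params$lambda)
  sW <- rowSums(latent)
  for (h in 1:3) {
    idx <- z > h
    if (any(idx)) {
      xim <- rep(1, length(z))
      for (hp in 1:3) {
        if (hp != h) xim <- xim * ifelse(z > hp, gamma[hp], 1)
      }
      A <- sum(sW[idx])
      B <- sum(s[idx] * xim[idx])
    } else {
      A <- 0
      B <- 0
    }
    p1 <- gamma_pointmass_prob(priors$pi_h[h], priors$a0h[h], priors$b0h[h],
                               A, B)
    gamma[h] <- if (stats::runif(1) < p1) 1 else {
      stats::rgamma(1, shape = priors$a0h[h] + A, rate = priors$b0h[h] + B)
    }
  }
  gamma
}

#' Run the Gibbs sampler
#'
#' Alternates latent-count sampling, the conjugate lambda updates and the
#' point-mass gamma updates in a fixed scan order.  Initialization draws
#' `lambda` from its prior and starts every `gamma_h` at 1 (inside the
#' point-mass state).  Chain `c` is seeded with `config$seed + c`
#' (Mersenne-Twister), so results are fully reproducible.
#'
#' @param data A validated `cycle_dataset`; when `covariate = TRUE` cycles
#'   with a missing follicular class are excluded with a message.
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param covariate Include the follicular-class multipliers?  When `FALSE`
#'   the gammas are fixed at 1 and absent from the output.
#' @param verbose Report progress every 1000 iterations.
#' @return A `posterior_samples` object: list with `chains` (one
#'   iterations/thin x P matrix per chain, named columns
#'   `lambda_-8 .. lambda_3[, gamma_1 .. gamma_3]`), the `config`, the
#'   `covariate` flag and `n_cycles` actually fitted.
#' @export
run_chain <- function(data, priors = prior_spec(), config = mcmc_config(),
                      covariate = TRUE, verbose = FALSE) {
  stopifnot(inherits(data, "cycle_dataset"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (covariate && anyNA(data$foll_class)) {
    n_drop <- sum(is.na(data$foll_class))
    message("excluding ", n_drop, " cycle(s) with missing follicular class")
    data <- data[!is.na(data$foll_class), , drop = FALSE]
    class(data) <- c("cycle_dataset", "data.frame")
    if (nrow(data) == 0) stop("no cycles left to fit", call. = FALSE)
  }
  if (!covariate) {
    # gamma plays no role: force class 1 so xi = 1 throughout
    data$foll_class <- 1L
  }
  pnames <- c(lambda_names(), if (covariate) gamma_names())
  n_keep <- config$iterations %/% config$thin
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch, kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    lambda <- stats::rgamma(12, priors$a0k, priors$b0k)
    gamma <- c(1, 1, 1)
    params <- model_parameters(lambda, gamma)
    draws <- matrix(NA_real_, n_keep, length(pnames),
                    dimnames = list(NULL, pnames))
    total <- config$burn_in + config$iterations
    kept <- 0L
    for (it in seq_len(total)) {
      W <- sample_latent_counts(params, data)
      params$lambda <- update_lambda(W, params, data, priors)
      if (covariate) {
        params$gamma <- update_gamma(W, params, data, priors)
      }
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- c(params$lambda, if (covariate) params$gamma)
      }
      if (verbose && it %% 1000 == 0) {
        message("chain ", ch, ": iteration ", it, "/", total)
      }
    }
    chains[[ch]] <- draws
  }
  structure(list(chains = chains, config = config, covariate = covariate,
                 n_cycles = nrow(data)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " retained draws, ", ncol(x$chains[[1]]),
      " parameters (", x$n_cycles, " cycles)\n", sep = "")
  invisible(x)
}

#' Export posterior samples to long-format CSV
#'
#' Columns `chain,iteration,parameter,value` with parameter names
#' `lambda_-8 .. lambda_3, gamma_1 .. gamma_3`.
#'
#' @param samples A `posterior_samples` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  long <- do.call(rbind, lapply(seq_along(samples$chains), function(ch) {
    m <- samples$chains[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior samples from long-format CSV
#'
#' @param path Path written by [write_samples()].
#' @return A `posterior_samples` object (configuration metadata other than
#'   chain/iteration structure is not stored in the CSV).
#' @export
read_samples <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "iteration", "parameter", "value")
  if (!all(need %in% names(long))) {
    stop("samples file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  pnames <- unique(long$parameter)
  chains <- lapply(sort(unique(long$chain)), function(ch) {
    sub <- long[long$chain == ch, ]
    m <- sapply(pnames, function(p) {
      v <- sub[sub$parameter == p, ]
      v$value[order(v$iteration)]
    })
    colnames(m) <- pnames
    m
  })
  structure(list(chains = chains, config = NULL,
                 covariate = any(grepl("^gamma_", pnames)),
                 n_cycles = NA_integer_),
            class = "posterior_samples")
}
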