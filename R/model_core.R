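# Model parameters, priors, likelihood and prior simulation.
#
# Each intercourse act on fertile-window day k contributes an independent
# complementary log-log hazard of conceiving a male: the day-specific
# probability of a male from intercourse on day k alone is
# q_k = 1 - exp(-lambda_k * xi), with xi the cycle-level multiplier built
# from the follicular-length class effects.  A conception cycle yields a
# female only if no intercourse day "produces a male", so
# P(female) = prod_k (1 - q_k)^{X_k} = exp(-xi * sum_k X_k lambda_k).

#' Day-specific and follicular-length model parameters
#'
#' @param lambda Numeric vector of 12 strictly positive day-specific baseline
#'   hazard parameters, ordered by relative day -8..+3.
#' @param gamma Numeric vector of 3 strictly positive multipliers; `gamma[h]`
#'   is the multiplicative change associated with moving from follicular
#'   class `h` to `h + 1` (exactly 1 encodes "no effect").
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(lambda, gamma = c(1, 1, 1)) {
  if (!is.numeric(lambda) || length(lambda) != 12 || anyNA(lambda) ||
      any(lambda <= 0) || any(!is.finite(lambda))) {
    stop("`lambda` must be 12 strictly positive finite values", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 3 || anyNA(gamma) ||
      any(gamma <= 0) || any(!is.finite(gamma))) {
    stop("`gamma` must be 3 strictly positive finite values", call. = FALSE)
  }
  structure(list(lambda = as.numeric(lambda), gamma = as.numeric(gamma)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n  lambda (day -8..+3):",
      paste(signif(x$lambda, 3), collapse = " "), "\n  gamma:",
      paste(signif(x$gamma, 3), collapse = " "), "\n")
  invisible(x)
}

#' Prior specification
#'
#' Independent Gamma(`a0k`, `b0k`) priors (shape/rate) for the 12 day
#' parameters and one-inflated gamma priors for the 3 follicular-class
#' multipliers: `gamma[h] = 1` with probability `pi_h`, otherwise
#' Gamma(`a0h`, `b0h`).  Defaults are the diffuse choices
#' `a0k = b0k = 1`, `pi_h = 0.5^(1/3)` (so the joint null
#' `gamma = (1, 1, 1)` has prior mass 0.5) and `a0h = b0h = 0.1`.
#'
#' @param a0k,b0k Gamma shape and rate for each day parameter (length 12 or
#'   scalar, recycled).
#' @param pi_h Point-mass weight at 1 for each multiplier (length 3 or
#'   scalar), in `[0, 1]`.
#' @param a0h,b0h Gamma shape and rate for the continuous branch of each
#'   multiplier prior (length 3 or scalar).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(a0k = 1, b0k = 1, pi_h = 0.5^(1 / 3),
                       a0h = 0.1, b0h = 0.1) {
  a0k <- rep_len(as.numeric(a0k), 12)
  b0k <- rep_len(as.numeric(b0k), 12)
  pi_h <- rep_len(as.numeric(pi_h), 3)
  a0h <- rep_len(as.numeric(a0h), 3)
  b0h <- rep_len(as.numeric(b0h), 3)
  if (anyNA(c(a0k, b0k, a0h, b0h, pi_h)) ||
      any(c(a0k, b0k, a0h, b0h) <= 0)) {
    stop("prior shapes and rates must be strictly positive", call. = FALSE)
  }
  if (any(pi_h < 0 | pi_h > 1)) {
    stop("`pi_h` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(a0k = a0k, b0k = b0k, pi_h = pi_h, a0h = a0h, b0h = b0h),
            class = "prior_spec")
}

#' Cycle-level covariate multiplier
#'
#' The multiplier for a cycle in follicular class `z` is the product of the
#' first `z - 1` class effects, `xi = prod_{h < z} gamma[h]`; the empty
#' product (class 1) is 1.
#'
#' @param gamma Numeric vector of 3 positive multipliers.
#' @param z Integer vector of follicular classes in `1..4`.
#' @return Numeric vector of multipliers, one per element of `z`.
#' @export
covariate_multiplier <- function(gamma, z) {
  if (!is.numeric(gamma) || length(gamma) != 3 || any(gamma <= 0)) {
    stop("`gamma` must be 3 strictly positive values", call. = FALSE)
  }
  if (anyNA(z) || !all(z %in% 1:4)) {
    stop("follicular class `z` must be in 1..4", call. = FALSE)
  }
  c(1, cumprod(gamma))[z]
}

#' Day-specific hazard of conceiving a male
#'
#' `q = 1 - exp(-lambda_k * xi)`: the probability that an intercourse act on
#' a given day, alone, results in a male conception.
#'
#' @param lambda_k Positive day parameter(s).
#' @param xi Positive cycle multiplier(s).
#' @return Probabilities in (0, 1); strictly increasing in both arguments.
#' @export
day_hazard <- function(lambda_k, xi) {
  if (any(!is.finite(lambda_k)) || any(lambda_k <= 0) ||
      any(!is.finite(xi)) || any(xi <= 0)) {
    stop("`lambda_k` and `xi` must be strictly positive and finite",
         call. = FALSE)
  }
  -expm1(-lambda_k * xi)
}

#' Probability that a conception cycle produces a female
#'
#' `P(female) = exp(-xi * sum_k X_k lambda_k)`: the product over intercourse
#' days of the per-day survival probabilities `1 - q_k`.
#'
#' @param params A [model_parameters()] object.
#' @param x Either a `cycle_dataset` or an intercourse indicator vector
#'   (length 12) / matrix (n x 12).
#' @param z Follicular class(es) in `1..4`; ignored (taken from the data)
#'   when `x` is a `cycle_dataset`.  Cycles with missing class are an error.
#' @return Numeric vector of probabilities in (0, 1], one per cycle.
#' @export
prob_female <- function(params, x, z = 1L) {
  stopifnot(inherits(params, "model_parameters"))
  if (inherits(x, "cycle_dataset")) {
    z <- x$foll_class
    if (anyNA(z)) stop("cycles with missing follicular class", call. = FALSE)
    x <- intercourse_matrix(x)
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != 12 || any(is.na(x)) || !all(x %in% c(0, 1))) {
    stop("`x` must hold 12 binary intercourse indicators per cycle",
         call. = FALSE)
  }
  if (any(rowSums(x) == 0)) {
    stop("cycle with no intercourse in the fertile window", call. = FALSE)
  }
  xi <- covariate_multiplier(params$gamma, rep_len(z, nrow(x)))
  exp(-xi * as.vector(x %*% params$lambda))
}

#' Log-likelihood of a conception-cycle dataset
#'
#' Independent Bernoulli log-mass summed over cycles:
#' `sum_i [ y_i log P_i + (1 - y_i) log(1 - P_i) ]` with `P_i` the
#' model probability that cycle `i` conceives a female.
#'
#' @param params A [model_parameters()] object.
#' @param data A non-empty `cycle_dataset` with follicular classes.
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(data, "cycle_dataset"), nrow(data) >= 1)
  p <- prob_female(params, data)
  sum(ifelse(data$sex == 1, log(p), log1p(-p)))
}

#' Draw parameters from the prior
#'
#' Each `lambda_k` is Gamma(`a0k`, `b0k`); each `gamma_h` equals 1 with
#' probability `pi_h` and is Gamma(`a0h`, `b0h`) otherwise, independently.
#'
#' @param priors A [prior_spec()].
#' @param n Number of independent draws.
#' @return A list with matrices `lambda` (`n` x 12) and `gamma` (`n` x 3).
#'   Uses the current RNG stream; call `set.seed()` first for
#'   reproducibility.
#' @export
sample_prior <- function(priors, n = 1) {
  stopifnot(inherits(priors, "prior_spec"), n >= 1)
  lambda <- matrix(stats::rgamma(n * 12, shape = rep(priors$a0k, each = n),
                                 rate = rep(priors$b0k, each = n)),
                   nrow = n, dimnames = list(NULL, lambda_names()))
  at_one <- matrix(stats::runif(n * 3) < rep(priors$pi_h, each = n), nrow = n)
  gam <- matrix(stats::rgamma(n * 3, shape = rep(priors$a0h, each = n),
                              rate = rep(priors$b0h, each = n)),
                nrow = n, dimnames = list(NULL, gamma_names()))
  gam[at_one] <- 1
  list(lambda = lambda, gamma = gam)
}

#' Female probability implied by a sex ratio at birth
#'
#' Converts a sex ratio expressed as males per 100 females into the implied
#' probability that a birth is female, `100 / (100 + ratio)`.  The commonly
#' cited ratio of about 106 gives 0.485.
#'
#' @param males_per_100_females Positive sex ratio.
#' @return Probability in (0, 1).
#' @export
implied_female_prob_from_sex_ratio <- function(males_per_100_females) {
  if (!is.numeric(males_per_100_females) || any(males_per_100_females <= 0) ||
      any(!is.finite(males_per_100_females))) {
    stop("sex ratio must be strictly positive and finite", call. = FALSE)
  }
  100 / (100 + males_per_100_females)
}

# parameter names used in sample objects and reports
lambda_names <- function() paste0("lambda_", fertile_window_days())
gamma_names <- function() paste0("gamma_", 1:3)
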