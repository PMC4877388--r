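# Posterior summaries and the standard convergence diagnostics.

#' Summarize posterior samples
#'
#' Pools post-burn-in draws across chains and reports, per parameter, the
#' mean, median, SD and 95% equal-tailed credible interval (2.5% and 97.5%
#' empirical quantiles, inverse-CDF with linear interpolation, i.e.
#' `stats::quantile()` type 7).  For the follicular-class multipliers the
#' posterior probability of "no effect" is the fraction of draws exactly
#' equal to 1 — exact equality is meaningful because the sampler sets the
#' point-mass state exactly.
#'
#' @param samples A `posterior_samples` object.
#' @return Data frame with columns `parameter`, `mean`, `median`, `sd`,
#'   `ci_lower`, `ci_upper`, `p_gamma_eq_1` (`NA` for day parameters).
#' @export
summarize_posterior <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  pooled <- do.call(rbind, samples$chains)
  if (is.null(pooled) || nrow(pooled) == 0) {
    stop("no retained samples to summarize", call. = FALSE)
  }
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 7, names = FALSE)
  is_gamma <- grepl("^gamma_", colnames(pooled))
  data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    median = qs[2, ],
    sd = apply(pooled, 2, stats::sd),
    ci_lower = qs[1, ],
    ci_upper = qs[3, ],
    p_gamma_eq_1 = ifelse(is_gamma, colMeans(pooled == 1), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}

# shared guards for the diagnostics
check_chain <- function(chain, min_len = 100) {
  if (!is.numeric(chain) || length(chain) < min_len) {
    stop("chain must be numeric with at least ", min_len, " draws",
         call. = FALSE)
  }
  if (stats::sd(chain) == 0) {
    stop("degenerate (constant) chain: diagnostic undefined", call. = FALSE)
  }
  invisible(chain)
}

#' Geweke convergence z-score
#'
#' Compares the means of an early and a late chain segment, standardized by
#' spectral-density-at-zero variance estimates; |z| well above 2-3 signals a
#' drifting chain.
#'
#' @param chain Numeric vector of one parameter's draws (length >= 100).
#' @param frac_a Fraction of the chain in the early window (default 0.1).
#' @param frac_b Fraction in the late window (default 0.5).
#' @return The z-score (scalar).
#' @export
geweke_z <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  check_chain(chain)
  d <- coda::geweke.diag(coda::mcmc(chain), frac1 = frac_a, frac2 = frac_b)
  z <- unname(d$z[1])
  if (!is.finite(z)) {
    stop("degenerate chain segments: Geweke z undefined", call. = FALSE)
  }
  z
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within variance ratio over two or more equal-length
#' chains: `sqrt(((n - 1)/n * W + B/n) / W)`, approaching 1 from below the
#' usual thresholds as chains mix over the same distribution.  With zero
#' between-chain variance it attains its minimum `sqrt((n - 1)/n)`.
#'
#' @param chains List of >= 2 numeric chains of equal length >= 100.
#' @return The PSRF (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least 2 chains", call. = FALSE)
  }
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  lapply(chains, check_chain)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  w <- mean(vars)
  b_over_n <- stats::var(means)           # B/n
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Effective sample size of one chain
#'
#' `n / (1 + 2 * sum(rho_t))` with the autocorrelation sum truncated by
#' Geyer's initial-positive-sequence rule: lag pairs `(rho_1 + rho_2),
#' (rho_3 + rho_4), ...` are accumulated while positive and the sum stops at
#' the first non-positive pair.
#'
#' @param chain Numeric vector of draws (length >= 100).
#' @return Estimated effective sample size (positive scalar).
#' @export
effective_sample_size <- function(chain) {
  check_chain(chain)
  n <- length(chain)
  lag_max <- min(n - 1, 2000L)
  rho <- as.vector(stats::acf(chain, lag.max = lag_max,
                              plot = FALSE)$acf)[-1]
  s <- 0
  j <- 1
  while (j + 1 <= length(rho)) {
    pair <- rho[j] + rho[j + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    j <- j + 2
  }
  n / (1 + 2 * s)
}

#' Diagnostics table for a set of posterior samples
#'
#' Per parameter: Geweke z (first chain), Gelman-Rubin PSRF (when >= 2
#' chains; otherwise `NA` with a warning), and total effective sample size
#' summed over chains.  Degenerate (constant) chains yield `NA` entries with
#' a warning rather than aborting the table.
#'
#' @param samples A `posterior_samples` object.
#' @return Data frame with columns `parameter`, `geweke_z`, `rhat`, `ess`.
#' @export
diagnose_posterior <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  pnames <- colnames(samples$chains[[1]])
  one_chain <- length(samples$chains) < 2
  if (one_chain) {
    warning("single chain: Gelman-Rubin statistic not computed")
  }
  rows <- lapply(pnames, function(p) {
    cols <- lapply(samples$chains, function(m) m[, p])
    gz <- tryCatch(geweke_z(cols[[1]]), error = function(e) {
      warning("parameter ", p, ": ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
    rh <- if (one_chain) NA_real_ else {
      tryCatch(gelman_rubin(cols), error = function(e) {
        warning("parameter ", p, ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
    }
    ess <- tryCatch(sum(vapply(cols, effective_sample_size, numeric(1))),
                    error = function(e) {
                      warning("parameter ", p, ": ", conditionMessage(e),
                              call. = FALSE)
                      NA_real_
                    })
    data.frame(parameter = p, geweke_z = gz, rhat = rh, ess = ess,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a posterior summary table to CSV
#'
#' Columns `parameter,mean,median,sd,ci_lower,ci_upper,p_gamma_eq_1`.
#'
#' @param summary Data frame from [summarize_posterior()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
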