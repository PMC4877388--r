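# Brute-force numerical posterior for reduced models.
#
# Independent check on the Gibbs sampler: evaluates prior x likelihood in its
# closed aggregated-Bernoulli form (no latent-variable augmentation) on a
# tensor grid and normalizes.  Each continuous dimension is discretized at
# midpoint prior quantiles ((j - 0.5)/m, j = 1..m), i.e. the quadrature is a
# midpoint rule in prior-probability space; this absorbs the integrable
# singularity of the Gamma(0.1, 0.1) density at zero and gives every node
# equal prior weight 1/m.  The point mass of a one-inflated gamma prior is an
# explicit atom at 1 with weight pi.  The discretization error shrinks as m
# grows (the likelihood is smooth and bounded); doubling m is the practical
# error check.

#' Brute-force posterior for a reduced model by quadrature
#'
#' Supports at most three free dimensions: one or two day parameters (all
#' other days must have no intercourse anywhere in `data`) and optionally the
#' first follicular-class multiplier (`gamma_1`; follicular classes must then
#' be in {1, 2}; without it all classes must be 1).  Intended as an
#' independent oracle for sampler validation on small datasets, not as a
#' fitting routine.
#'
#' @param data A `cycle_dataset`, or `NULL` for the no-data (pure prior)
#'   case.
#' @param priors A [prior_spec()]; entries for unused days are ignored.
#' @param active_days Integer vector (length 1 or 2) of relative days in
#'   `-8..3` whose parameters are free.
#' @param gamma_active Include `gamma_1` (with its point mass) as a free
#'   dimension?
#' @param n_grid Number of prior-quantile nodes per continuous dimension.
#' @return List with `mean` and `sd` (named over the free parameters),
#'   `p_gamma1` (posterior mass of `gamma_1 = 1`, `NA` when inactive),
#'   `n_grid`, and `log_z` (log normalizing constant over the grid).
#' @export
brute_force_posterior <- function(data, priors, active_days,
                                  gamma_active = FALSE, n_grid = 160) {
  stopifnot(inherits(priors, "prior_spec"))
  d_lam <- length(active_days)
  if (d_lam < 1 || d_lam > 2 || (d_lam + gamma_active) > 3) {
    stop("at most 3 free dimensions (<= 2 day parameters)", call. = FALSE)
  }
  k_act <- relative_day_to_index(active_days)

  # per-dimension prior-quantile nodes, lambda index varies fastest
  nodes_l <- lapply(k_act, function(k) {
    stats::qgamma((seq_len(n_grid) - 0.5) / n_grid,
                  shape = priors$a0k[k], rate = priors$b0k[k])
  })
  m_l <- n_grid^d_lam
  if (d_lam == 1) {
    lam_grid <- list(nodes_l[[1]])
  } else {
    lam_grid <- list(rep(nodes_l[[1]], times = n_grid),
                     rep(nodes_l[[2]], each = n_grid))
  }

  if (gamma_active) {
    g_nodes <- c(1, stats::qgamma((seq_len(n_grid) - 0.5) / n_grid,
                                  shape = priors$a0h[1], rate = priors$b0h[1]))
    logw_g <- c(log(priors$pi_h[1]),
                rep(log1p(-priors$pi_h[1]) - log(n_grid), n_grid))
    m_g <- n_grid + 1
  } else {
    g_nodes <- 1
    logw_g <- 0
    m_g <- 1
  }

  ll <- matrix(0, m_l, m_g)
  if (!is.null(data)) {
    stopifnot(inherits(data, "cycle_dataset"))
    X <- intercourse_matrix(data)
    if (any(X[, -k_act, drop = FALSE] != 0)) {
      stop("data has intercourse outside `active_days`", call. = FALSE)
    }
    z <- data$foll_class
    if (gamma_active) {
      if (!all(z %in% 1:2)) {
        stop("with `gamma_active`, follicular classes must be 1 or 2",
             call. = FALSE)
      }
    } else if (!all(z == 1)) {
      stop("without `gamma_active`, all follicular classes must be 1",
           call. = FALSE)
    }
    pat <- stats::aggregate(
      list(count = rep(1L, nrow(data))),
      by = c(lapply(seq_len(d_lam), function(j) X[, k_act[j]]),
             list(z = z, y = data$sex)),
      FUN = sum)
    names(pat)[seq_len(d_lam)] <- paste0("x", seq_len(d_lam))
    for (r in seq_len(nrow(pat))) {
      s <- rep(0, m_l)
      for (j in seq_len(d_lam)) s <- s + pat[[j]][r] * lam_grid[[j]]
      if (pat$z[r] == 1) {
        lr <- if (pat$y[r] == 1) -s else log1p(-exp(-s))
        ll <- ll + pat$count[r] * lr      # recycled across gamma columns
      } else {
        sx <- outer(s, g_nodes)           # xi = gamma_1 for class-2 cycles
        lr <- if (pat$y[r] == 1) -sx else log1p(-exp(-sx))
        ll <- ll + pat$count[r] * lr
      }
    }
  }

  logw_l <- rep(-d_lam * log(n_grid), m_l)
  lp <- ll + logw_l                       # column-wise recycle
  lp <- sweep(lp, 2, logw_g, "+")
  mx <- max(lp)
  log_z <- mx + log(sum(exp(lp - mx)))
  w <- exp(lp - log_z)

  pname <- paste0("lambda_", active_days)
  means <- vapply(seq_len(d_lam),
                  function(j) sum(w * lam_grid[[j]]), numeric(1))
  m2 <- vapply(seq_len(d_lam),
               function(j) sum(w * lam_grid[[j]]^2), numeric(1))
  if (gamma_active) {
    cg <- colSums(w)
    means <- c(means, sum(cg * g_nodes))
    m2 <- c(m2, sum(cg * g_nodes^2))
    pname <- c(pname, "gamma_1")
    p_g1 <- cg[1]
  } else {
    p_g1 <- NA_real_
  }
  list(mean = stats::setNames(means, pname),
       sd = stats::setNames(sqrt(pmax(m2 - means^2, 0)), pname),
       p_gamma1 = unname(p_g1), n_grid = n_grid, log_z = log_z)
}
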