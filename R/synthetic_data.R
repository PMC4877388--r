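# Synthetic conception-cycle generator.
#
# The published individual-level data are restricted-access, so the
# generator reproduces their reported structure: per-day intercourse
# marginals and follicular-class proportions matching the published
# frequency tables, and sex outcomes drawn from the aggregated-Bernoulli
# model at known true parameters.  Intercourse days are independent across
# days (the inference model conditions on the indicators, so their joint
# distribution does not affect model correctness, only the information
# content of a dataset).

# published per-day intercourse marginals (%) for days -8..+3 and
# follicular-class proportions (classes 1..4)
default_day_probs <- function() {
  c(20.34, 17.66, 23.80, 25.53, 29.37, 23.03,
    31.67, 29.56, 38.96, 24.57, 19.19, 18.62) / 100
}
default_class_probs <- function() c(0.2821, 0.2975, 0.2284, 0.1919)

# representative follicular length inside each class bin (midpoints; the
# open-ended class 4 uses 22).  Only the class enters the model.
class_representative_length <- function() c(12L, 15L, 18L, 22L)

#' Configuration for the synthetic-cycle generator
#'
#' Defaults emulate the joined fecundability studies: 521 cycles, per-day
#' intercourse probabilities equal to the published Table-1 marginals,
#' follicular-class probabilities equal to the published Table-2 relative
#' frequencies (renormalized to sum exactly to 1), and true parameters
#' `lambda = 0.5` on every day with `gamma = (1, 1, 1)` (no
#' follicular-length effect).
#'
#' @param n_cycles Number of conception cycles to generate.
#' @param intercourse_day_probs 12 per-day intercourse probabilities in
#'   (0, 1).
#' @param follicular_class_probs 4 class probabilities; must sum to 1 within
#'   0.005 and are renormalized to sum exactly to 1.
#' @param true_params A [model_parameters()] object used to draw the sex
#'   outcomes.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param min_one_intercourse Redraw cycles whose 12 indicators are all zero
#'   (default `TRUE`), so every generated cycle passes validation and `n` is
#'   exact; this slightly inflates the per-day marginals.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cycles = 521,
                             intercourse_day_probs = default_day_probs(),
                             follicular_class_probs = default_class_probs(),
                             true_params = model_parameters(rep(0.5, 12)),
                             seed = 1,
                             min_one_intercourse = TRUE) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  }
  if (length(intercourse_day_probs) != 12 ||
      any(intercourse_day_probs <= 0) || any(intercourse_day_probs >= 1)) {
    stop("`intercourse_day_probs` must be 12 probabilities in (0, 1)",
         call. = FALSE)
  }
  if (length(follicular_class_probs) != 4 ||
      any(follicular_class_probs < 0)) {
    stop("`follicular_class_probs` must be 4 non-negative values",
         call. = FALSE)
  }
  s <- sum(follicular_class_probs)
  if (abs(s - 1) > 0.005) {
    stop("`follicular_class_probs` must sum to 1 (within 0.005)",
         call. = FALSE)
  }
  follicular_class_probs <- follicular_class_probs / s
  stopifnot(inherits(true_params, "model_parameters"))
  if (!is.null(seed) && (!is.numeric(seed) || seed != round(seed))) {
    stop("`seed` must be an integer or NULL", call. = FALSE)
  }
  structure(list(n_cycles = as.integer(n_cycles),
                 intercourse_day_probs = as.numeric(intercourse_day_probs),
                 follicular_class_probs = follicular_class_probs,
                 true_params = true_params,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 min_one_intercourse = isTRUE(min_one_intercourse)),
            class = "generator_config")
}

#' Generate a synthetic conception-cycle dataset
#'
#' Per cycle: intercourse indicators are independent Bernoulli draws with
#' the configured per-day probabilities (all-zero cycles are redrawn when
#' `min_one_intercourse` is on); the follicular class is categorical with
#' the configured probabilities and receives a representative length inside
#' its bin; the sex is Bernoulli with `P(female)` computed from the true
#' parameters via [prob_female()].
#'
#' @param config A [generator_config()].
#' @return A validated `cycle_dataset` with `study = "SYN"`.
#' @export
generate_cycles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) {
    set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  n <- config$n_cycles
  p <- config$intercourse_day_probs
  X <- matrix(stats::rbinom(n * 12, 1, rep(p, each = n)), n, 12)
  if (config$min_one_intercourse) {
    bad <- rowSums(X) == 0
    while (any(bad)) {
      nb <- sum(bad)
      X[bad, ] <- matrix(stats::rbinom(nb * 12, 1, rep(p, each = nb)), nb, 12)
      bad[bad] <- rowSums(X[bad, , drop = FALSE]) == 0
    }
  }
  z <- sample.int(4, n, replace = TRUE, prob = config$follicular_class_probs)
  w <- class_representative_length()[z]
  pf <- prob_female(config$true_params, X, z)
  y <- stats::rbinom(n, 1, pf)
  df <- data.frame(woman_id = sprintf("W%05d", seq_len(n)),
                   cycle_id = sprintf("C%05d", seq_len(n)),
                   sex = y, foll_len = w, stringsAsFactors = FALSE)
  colnames(X) <- ic_columns()
  df <- cbind(df, as.data.frame(X))
  df$study <- "SYN"
  cycle_dataset(df)
}

#' Redraw the sex outcomes of a dataset at given parameters
#'
#' Keeps every cycle's intercourse pattern and follicular class, replacing
#' only the sex with a fresh Bernoulli draw from the model.  Uses the
#' current RNG stream (no internal seeding); used by prior-preservation
#' checks of the sampler and available for posterior predictive simulation.
#'
#' @param data A `cycle_dataset`.
#' @param params A [model_parameters()].
#' @return The dataset with new `sex` values.
#' @export
resimulate_sex <- function(data, params) {
  stopifnot(inherits(data, "cycle_dataset"))
  pf <- prob_female(params, data)
  data$sex <- stats::rbinom(nrow(data), 1, pf)
  data
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a dataset at the configured true parameters, fits
#' it with [run_chain()], and records for every parameter the truth, the
#' posterior mean, the 95% credible interval, whether it covers the truth,
#' and (for the multipliers) the posterior probability of "no effect".
#' Replicate `r` uses data seed `config$seed + r` and chain seed
#' `mcmc$seed + 100 * r`.
#'
#' @param config A [generator_config()].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param replicates Number of independent replicate datasets.
#' @return Data frame (class `recovery_report`) with one row per replicate
#'   and parameter: `replicate`, `parameter`, `truth`, `mean`, `ci_lower`,
#'   `ci_upper`, `covered`, `p_gamma_eq_1`.
#' @export
parameter_recovery_experiment <- function(config, priors = prior_spec(),
                                          mcmc = mcmc_config(),
                                          replicates = 10) {
  stopifnot(inherits(config, "generator_config"), replicates >= 1)
  truth <- stats::setNames(
    c(config$true_params$lambda, config$true_params$gamma),
    c(lambda_names(), gamma_names()))
  rows <- lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- (if (is.null(config$seed)) 0L else config$seed) + r
    dat <- generate_cycles(cfg)
    mc <- mcmc
    mc$seed <- mcmc$seed + 100L * r
    fit <- run_chain(dat, priors, mc)
    sm <- summarize_posterior(fit)
    data.frame(replicate = r, parameter = sm$parameter,
               truth = unname(truth[sm$parameter]), mean = sm$mean,
               ci_lower = sm$ci_lower, ci_upper = sm$ci_upper,
               covered = sm$ci_lower <= truth[sm$parameter] &
                 truth[sm$parameter] <= sm$ci_upper,
               p_gamma_eq_1 = sm$p_gamma_eq_1,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("recovery_report", "data.frame"))
}
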