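# Simulation of hypothetical two-arm non-inferiority trials and Bayesian
# updating of the PTS-incidence and relative-risk parameters -- the inner
# machinery of the EVSI computation.

#' Describe a two-arm trial design
#'
#' @param n_total total number of patients (>= 2), split 1:1 across arms
#'   (standard arm gets `floor(n/2)`).
#' @param fixed_cost fixed trial cost, EUR.
#' @param cost_per_patient variable trial cost per included patient, EUR.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_total, fixed_cost = 10000, cost_per_patient = 5000) {
  stopifnot(n_total >= 2, n_total == round(n_total))
  n_std <- as.integer(floor(n_total / 2))
  structure(list(n_total = as.integer(n_total), n_standard = n_std,
                 n_tailored = as.integer(n_total) - n_std,
                 fixed_cost = fixed_cost, cost_per_patient = cost_per_patient),
            class = "trial_design")
}

#' Total cost of running a trial
#' @param design a `trial_design`.
#' @param n optional total sample size(s) overriding the design's `n_total`.
#' @return cost in EUR.
#' @export
trial_cost <- function(design, n = design$n_total) {
  design$fixed_cost + design$cost_per_patient * n
}

#' Simulate one hypothetical trial outcome
#'
#' Each arm is a multinomial over \{onset in 0--6, 6--12, 12--24 months, no
#' onset by 24 months\}. The standard arm uses the interval-conditional
#' onset probabilities `(q1, q2, q3)`; the tailored arm multiplies the
#' post-6-month probabilities by the relative risk (clamped at 1 from
#' above by the censored prior, at 1 from below as a probability).
#'
#' @param design a `trial_design`.
#' @param theta_true named vector with elements `q1`, `q2`, `q3`, `rr` (the
#'   "true" state of the world for this simulation).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `trial_outcome`: list with `design` and `counts`,
#'   a 2 x 4 matrix (rows `standard`, `tailored`; columns `int1`, `int2`,
#'   `int3`, `free`).
#' @export
simulate_trial <- function(design, theta_true, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  cell_probs <- function(q1, q2, q3) {
    p <- c(q1, (1 - q1) * q2, (1 - q1) * (1 - q2) * q3)
    c(p, 1 - sum(p))
  }
  th <- as.list(theta_true[c("q1", "q2", "q3", "rr")])
  if (any(!vapply(th, is.finite, logical(1))))
    stop("theta_true must contain finite q1, q2, q3, rr", call. = FALSE)
  q <- c(th$q1, th$q2, th$q3)
  if (any(q < 0 | q > 1)) stop("onset probabilities must lie in [0, 1]", call. = FALSE)
  qt <- c(th$q1, pmin(th$rr * c(th$q2, th$q3), 1))
  counts <- rbind(
    standard = as.integer(stats::rmultinom(1, design$n_standard, cell_probs(q[1], q[2], q[3]))),
    tailored = as.integer(stats::rmultinom(1, design$n_tailored, cell_probs(qt[1], qt[2], qt[3]))))
  colnames(counts) <- c("int1", "int2", "int3", "free")
  structure(list(design = design, counts = counts), class = "trial_outcome")
}

#' Conjugate beta-binomial update of the interval onset probabilities
#'
#' Interval i contributes a binomial observation with `x_i` onsets among the
#' `m_i` patients still at risk (patients with onset in earlier intervals
#' are excluded from the risk set), giving the conjugate posterior
#' `Beta(alpha_i + x_i, beta_i + m_i - x_i)`. Only standard-arm counts are
#' used: the interval parameters describe standard therapy, and the tailored
#' arm informs the relative risk instead (see [update_rr_posterior()]).
#'
#' @param priors list of three numeric `c(alpha, beta)` pairs for
#'   `q1`, `q2`, `q3`.
#' @param counts standard-arm counts: numeric vector `c(int1, int2, int3,
#'   free)` or a `trial_outcome`.
#' @return list of three posterior `c(alpha, beta)` pairs.
#' @export
update_incidence_posterior <- function(priors, counts) {
  if (inherits(counts, "trial_outcome")) counts <- counts$counts["standard", ]
  stopifnot(length(priors) == 3, length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  at_risk <- c(n, n - counts[1], n - counts[1] - counts[2])
  x <- counts[1:3]
  if (any(x > at_risk)) stop("interval events exceed the at-risk set", call. = FALSE)
  out <- vector("list", 3)
  for (i in 1:3)
    out[[i]] <- c(alpha = unname(priors[[i]][1] + x[i]),
                  beta = unname(priors[[i]][2] + at_risk[i] - x[i]))
  names(out) <- names(priors)
  out
}

#' Normal update of the log relative risk from a simulated trial
#'
#' The relative-risk parameter multiplies the post-6-month onset
#' probabilities, so the natural data summary is the ratio of post-6-month
#' onset proportions among patients still PTS-free at month 6:
#' `r_hat = [(int2+int3)/m_new] / [(int2+int3)/m_std]` with `m` the 6-month
#' risk sets. `log(r_hat)` carries the delta-method standard error
#' `s^2 = (1-p_std)/(m_std p_std) + (1-p_new)/(m_new p_new)` and updates the
#' `Normal(mu0, sigma0^2)` prior on log RR by precision weighting:
#' `sigma1^2 = 1/(1/sigma0^2 + 1/s^2)`,
#' `mu1 = sigma1^2 (mu0/sigma0^2 + log(r_hat)/s^2)`. Posterior draws are
#' censored at 1 downstream, like the prior. If either arm has zero
#' post-6-month events or zero non-events (the normal approximation breaks
#' down), the prior is kept unchanged and flagged.
#'
#' @param prior numeric `c(mu, sigma)` for log RR (default `c(0, 0.612)`).
#' @param outcome a `trial_outcome`.
#' @return list with `mu`, `sigma`, logical `updated`, and when updated the
#'   data summaries `log_rhat` and `s`.
#' @export
update_rr_posterior <- function(prior = c(mu = 0, sigma = 0.612), outcome) {
  stopifnot(inherits(outcome, "trial_outcome"), length(prior) == 2, prior[2] > 0)
  cts <- outcome$counts
  m <- rowSums(cts[, c("int2", "int3", "free")])   # at risk at month 6
  e <- rowSums(cts[, c("int2", "int3")])           # onset after month 6
  if (any(e < 1) || any(m - e < 1))
    return(list(mu = unname(prior[1]), sigma = unname(prior[2]), updated = FALSE))
  p <- e / m
  log_rhat <- log(p[["tailored"]] / p[["standard"]])
  s <- sqrt(sum((1 - p) / (m * p)))
  post <- precision_weighted_update(prior[[1]], prior[[2]], log_rhat, s)
  list(mu = post$mu, sigma = post$sigma, updated = TRUE, log_rhat = log_rhat, s = s)
}

#' Precision-weighted normal-normal update
#'
#' Combines a `Normal(mu0, sigma0^2)` prior with a normal data summary
#' `estimate +/- se`: `sigma1^2 = 1/(1/sigma0^2 + 1/se^2)`,
#' `mu1 = sigma1^2 (mu0/sigma0^2 + estimate/se^2)`. As `se` grows the
#' posterior tends to the prior; with `se = sigma0` and `estimate = mu0` the
#' posterior sd is `sigma0/sqrt(2)`.
#'
#' @param mu0,sigma0 prior mean and sd (`sigma0 > 0`).
#' @param estimate,se data summary and its standard error (`se > 0`).
#' @return list with `mu` and `sigma`.
#' @export
precision_weighted_update <- function(mu0, sigma0, estimate, se) {
  stopifnot(sigma0 > 0, se > 0)
  prec <- 1 / sigma0^2 + 1 / se^2
  list(mu = (mu0 / sigma0^2 + estimate / se^2) / prec, sigma = sqrt(1 / prec))
}

#' Draw joint parameter vectors from a trial-updated posterior
#'
#' The incidence parameters are drawn from their posterior Betas, the
#' relative risk from the posterior lognormal censored at 1, and every other
#' parameter from its (unchanged) prior. Uses the current RNG state so EVSI
#' inner loops form one reproducible stream.
#'
#' @param config a `voi_config`.
#' @param post_inc posterior Beta pairs from [update_incidence_posterior()].
#' @param post_rr posterior `list(mu, sigma)` from [update_rr_posterior()].
#' @param K number of draws.
#' @return `K x P` matrix of class `param_draws`.
#' @export
sample_posterior_draws <- function(config, post_inc, post_rr, K) {
  draws <- vapply(names(config$specs), function(nm) {
    if (nm %in% c("q1", "q2", "q3")) {
      ab <- post_inc[[match(nm, c("q1", "q2", "q3"))]]
      stats::rbeta(K, ab[1], ab[2])
    } else if (nm == "rr") {
      pmax(exp(stats::rnorm(K, post_rr$mu, post_rr$sigma)), 1)
    } else draw_spec(config$specs[[nm]], K)
  }, numeric(K))
  if (K == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(config$specs)))
  structure(draws, class = c("param_draws", class(draws)))
}

#' Export a batch of simulated trial outcomes to CSV
#' @param outcomes list of `trial_outcome` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_trials <- function(outcomes, path) {
  rows <- lapply(seq_along(outcomes), function(i) {
    o <- outcomes[[i]]
    data.frame(trial = i, n_standard = o$design$n_standard,
               n_tailored = o$design$n_tailored,
               std_int1 = o$counts["standard", "int1"],
               std_int2 = o$counts["standard", "int2"],
               std_int3 = o$counts["standard", "int3"],
               tail_int1 = o$counts["tailored", "int1"],
               tail_int2 = o$counts["tailored", "int2"],
               tail_int3 = o$counts["tailored", "int3"])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
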