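# Value-of-information analysis: EVPI, population EVPI, EVPPI (nested Monte
# Carlo), EVSI (trial simulation + Bayesian updating) and the expected net
# benefit of sampling, whose argmax over the sample-size grid is the
# decision-theoretic optimal trial size.

#' Per-patient expected value of perfect information
#'
#' `EVPI = E_theta[max_j NMB(j, theta)] - max_j E_theta[NMB(j, theta)]`:
#' the expected opportunity loss of deciding under current uncertainty,
#' estimated from PSA draws.
#'
#' @param psa a `psa_result`, or a `K x J` matrix of per-draw NMB values.
#' @return list with `evpi` (EUR per patient), Monte Carlo `se`, and `K`.
#' @export
evpi <- function(psa) {
  m <- if (inherits(psa, "psa_result")) psa$nmb else as.matrix(psa)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  rowmax <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  jstar <- which.max(colMeans(m))
  loss <- rowmax - m[, jstar]
  list(evpi = mean(loss), se = stats::sd(loss) / sqrt(nrow(m)), K = nrow(m))
}

#' Discounted effective population
#'
#' Number of patients affected by the adoption decision over the remaining
#' lifetime of the technology: yearly incident cohorts accrued for
#' `tech_lifetime` years and discounted, i.e. the annuity
#' `incidence * (1 - (1+r)^-L) / r` (or `incidence * L` when `r = 0`).
#'
#' @param annual_incidence new patients per year.
#' @param tech_lifetime technology lifetime in years.
#' @param discount_rate annual discount rate in \[0, 1).
#' @return discounted person count.
#' @examples
#' effective_population(25000, 10, 0.04)  # ~202,772
#' @export
effective_population <- function(annual_incidence, tech_lifetime, discount_rate) {
  stopifnot(annual_incidence > 0, tech_lifetime > 0,
            discount_rate >= 0, discount_rate < 1)
  if (discount_rate == 0) return(annual_incidence * tech_lifetime)
  annual_incidence * (1 - (1 + discount_rate)^(-tech_lifetime)) / discount_rate
}

#' Population expected value of perfect information
#' @param evpi_per_patient per-patient EVPI, EUR.
#' @param population effective population (discounted person count).
#' @return population EVPI, EUR.
#' @export
population_evpi <- function(evpi_per_patient, population) {
  stopifnot(evpi_per_patient >= 0 || is.finite(evpi_per_patient), population >= 0)
  evpi_per_patient * population
}

#' Nested Monte Carlo EVPPI estimator (generic)
#'
#' Two-level estimator of
#' `E_phi[max_j E_psi[NMB]] - max_j E[NMB]` for an arbitrary model: the
#' outer loop draws the parameter subset phi, the inner loop draws the
#' complement psi and evaluates NMB. The baseline `max_j E[NMB]` is taken
#' over the pooled nested sample, which keeps the estimate nonnegative up
#' to Monte Carlo noise.
#'
#' Conditional expected NMB values are centred on the first (reference)
#' strategy before taking the maximum. Because the conditional expectation
#' of the reference strategy's NMB integrates back to its prior mean, this
#' leaves the estimand unchanged while removing the (large, common) NMB
#' level from the Monte Carlo variance -- the usual incremental-net-benefit
#' formulation.
#'
#' @param sample_phi function(k) returning k outer draws (matrix or vector).
#' @param nmb_fn function(phi_row, inner) returning an `inner x J` NMB
#'   matrix for one outer draw; it must draw psi internally from the
#'   current RNG stream.
#' @param outer,inner loop sizes.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `evppi` (per patient), `se` (outer-loop standard
#'   error), `outer`, `inner`.
#' @export
evppi_nested <- function(sample_phi, nmb_fn, outer, inner, seed = NULL) {
  stopifnot(outer >= 2, inner >= 2)
  if (!is.null(seed)) set.seed(seed)
  phi <- sample_phi(outer)
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 1)
  v <- numeric(outer)
  pooled <- NULL
  for (t in seq_len(outer)) {
    m <- nmb_fn(phi[t, , drop = TRUE], inner)
    cm <- colMeans(m)
    cm <- cm - cm[1]
    v[t] <- max(cm)
    pooled <- if (is.null(pooled)) cm else pooled + cm
  }
  baseline <- max(pooled / outer)
  list(evppi = mean(v) - baseline, se = stats::sd(v) / sqrt(outer),
       outer = outer, inner = inner)
}

#' EVPPI for a subset of the cohort-model parameters
#'
#' Applies [evppi_nested()] to the cohort model: the outer loop fixes the
#' named subset phi at prior draws, the inner loop redraws all remaining
#' parameters from their (independent) priors.
#'
#' @param config a `voi_config`.
#' @param subset character vector of parameter names (e.g.
#'   `c("q1","q2","q3","rr")`, the parameters describing PTS incidence under
#'   tailored therapy).
#' @param outer,inner nested loop sizes.
#' @param seed integer seed.
#' @return list as from [evppi_nested()], plus `subset` and
#'   `population_evppi` scaled by the discounted effective population.
#' @export
evppi <- function(config, subset, outer = config$voi$outer,
                  inner = config$voi$inner, seed = NULL) {
  unknown <- setdiff(subset, names(config$specs))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(length(subset) >= 1)
  psi_specs <- config$specs[setdiff(names(config$specs), subset)]
  res <- evppi_nested(
    sample_phi = function(k) {
      d <- sample_priors(config$specs[subset], k)
      matrix(unclass(d), nrow = k, dimnames = list(NULL, subset))
    },
    nmb_fn = function(phi_row, k) {
      draws <- matrix(NA_real_, k, length(config$specs),
                      dimnames = list(NULL, names(config$specs)))
      for (nm in subset) draws[, nm] <- phi_row[[nm]]
      if (length(psi_specs)) {
        psi <- sample_priors(psi_specs, k)
        draws[, names(psi_specs)] <- unclass(psi)
      }
      ce <- evaluate_strategies(draws, config)
      nmb(ce$cost, ce$effect, config$model$threshold)
    },
    outer = outer, inner = inner, seed = seed)
  pop <- effective_population(config$population$annual_incidence,
                              config$population$tech_lifetime,
                              config$population$discount_rate)
  res$subset <- subset
  res$population_evppi <- res$evppi * pop
  res
}

#' Monte Carlo EVSI estimator (generic)
#'
#' Estimates `E_X[max_j E_{theta|X}[NMB]] - max_j E_theta[NMB]` for an
#' arbitrary model: the outer loop draws a true state of the world from the
#' prior and simulates a study result X; the inner loop evaluates the
#' expected NMB of each strategy under the posterior given X.
#'
#' @param rtruth function() returning one prior draw of the parameters a
#'   study would inform.
#' @param rdata function(truth) simulating one study result.
#' @param posterior_value function(data, inner) returning the length-J
#'   vector of posterior expected NMB per strategy (typically by an inner
#'   Monte Carlo of size `inner`). Values may be centred on a reference
#'   strategy (incremental NMB) provided `baseline` uses the same centring;
#'   centring leaves the estimand unchanged and greatly reduces Monte Carlo
#'   variance.
#' @param baseline `max_j E_theta[NMB]` under the prior (same centring as
#'   `posterior_value`), computed once by the caller.
#' @param outer,inner loop sizes.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `evsi` (per patient), `se`, `outer`, `inner`.
#' @export
evsi_mc <- function(rtruth, rdata, posterior_value, baseline, outer, inner,
                    seed = NULL) {
  stopifnot(outer >= 2, inner >= 2)
  if (!is.null(seed)) set.seed(seed)
  v <- numeric(outer)
  for (t in seq_len(outer)) {
    truth <- rtruth()
    x <- rdata(truth)
    v[t] <- max(posterior_value(x, inner))
  }
  list(evsi = mean(v) - baseline, se = stats::sd(v) / sqrt(outer),
       outer = outer, inner = inner)
}

#' EVSI curve over a grid of trial sizes
#'
#' For each candidate total sample size n: draw a true parameter vector from
#' the priors, simulate a two-arm trial ([simulate_trial()]), update the
#' standard-arm interval incidences (conjugate beta-binomial) and the log
#' relative risk (precision-weighted normal), then evaluate the posterior
#' expected NMB of both strategies by an inner PSA
#' ([sample_posterior_draws()]); non-updated parameters are redrawn from
#' their priors. The per-patient EVSI is the outer-loop mean of the best
#' posterior expected NMB minus the best prior expected NMB (computed once
#' from a prior PSA of `outer * inner` draws shared across the grid).
#' Population EVSI multiplies by the discounted effective population minus
#' the trial patients themselves (subtracted from the first-year cohort
#' before discounting), since trial participants do not benefit from the
#' information. `n = 0` returns 0 exactly (no data, posterior = prior).
#'
#' @param config a `voi_config`.
#' @param grid integer vector of total sample sizes (default from config).
#' @param outer number of simulated trials per n.
#' @param inner posterior PSA draws per simulated trial.
#' @param seed master seed; per-n streams are derived deterministically.
#' @return object of class `evsi_curve`: data.frame with columns `n`,
#'   `evsi_pp`, `se_pp`, `population`, `pop_evsi`, `pop_se`,
#'   `skipped_rr_updates`; attributes `outer`, `inner`, `seed`, `baseline`,
#'   `eff_pop`.
#' @export
evsi <- function(config, grid = config$trial$sample_size_grid,
                 outer = config$voi$outer, inner = config$voi$inner,
                 seed = 1L) {
  stopifnot(length(grid) >= 1, all(grid >= 0), outer >= 2, inner >= 2)
  specs_inc <- config$specs[c("q1", "q2", "q3")]
  if (any(vapply(specs_inc, function(s) s$family, "") == "fixed") ||
      config$specs$rr$family == "fixed")
    stop("EVSI requires uncertain incidence and relative-risk priors; ",
         "with zero-variance priors a trial carries no information", call. = FALSE)
  prior_betas <- lapply(specs_inc, function(s) {
    ab <- beta_from_moments(s$mean, s$se); c(ab$alpha, ab$beta)
  })
  rr_prior <- c(mu = 0, sigma = config$specs$rr$sigma_log)

  # shared prior baseline: max_j E[NMB] under current evidence, centred on
  # the comparator (incremental form; see evsi_mc)
  psa0 <- run_psa(config, K = outer * inner, seed = derive_seed(seed, "evsi-baseline"))
  cm0 <- colMeans(psa0$nmb)
  baseline <- max(cm0 - cm0[1])

  pop0 <- effective_population(config$population$annual_incidence,
                               config$population$tech_lifetime,
                               config$population$discount_rate)
  r <- config$population$discount_rate

  rows <- lapply(grid, function(n) {
    if (n == 0)
      return(data.frame(n = 0L, evsi_pp = 0, se_pp = 0, population = pop0,
                        pop_evsi = 0, pop_se = 0, skipped_rr_updates = 0L))
    design <- trial_design(n, config$trial$fixed_cost, config$trial$cost_per_patient)
    skipped <- 0L
    res <- evsi_mc(
      rtruth = function() sample_priors(config$specs[c("q1", "q2", "q3", "rr")], 1)[1, ],
      rdata = function(truth) simulate_trial(design, truth),
      posterior_value = function(x, k) {
        post_inc <- update_incidence_posterior(prior_betas, x)
        post_rr <- update_rr_posterior(rr_prior, x)
        if (!post_rr$updated) skipped <<- skipped + 1L
        draws <- sample_posterior_draws(config, post_inc, post_rr, k)
        ce <- evaluate_strategies(draws, config)
        cm <- colMeans(nmb(ce$cost, ce$effect, config$model$threshold))
        cm - cm[1]
      },
      baseline = baseline, outer = outer, inner = inner,
      seed = derive_seed(seed, paste0("evsi-n", n)))
    pop_n <- max(pop0 - n / (1 + r), 0)
    data.frame(n = as.integer(n), evsi_pp = res$evsi, se_pp = res$se,
               population = pop_n, pop_evsi = res$evsi * pop_n,
               pop_se = res$se * pop_n, skipped_rr_updates = skipped)
  })
  out <- do.call(rbind, rows)
  structure(out, outer = outer, inner = inner, seed = seed,
            baseline = baseline, eff_pop = pop0,
            class = c("evsi_curve", class(out)))
}

#' Expected net benefit of sampling and optimal sample size
#'
#' `ENBS(n) = population EVSI(n) - (fixed cost + per-patient cost * n)`.
#' The optimal sample size is the grid argmax; ties resolve to the smallest
#' n.
#'
#' @param curve an `evsi_curve` from [evsi()].
#' @param fixed_cost,cost_per_patient trial cost components, EUR.
#' @return object of class `enbs_curve`: the input data.frame with added
#'   columns `trial_cost` and `enbs`, and attribute `optimal_n`.
#' @export
enbs <- function(curve, fixed_cost = 10000, cost_per_patient = 5000) {
  stopifnot(nrow(curve) >= 1)
  out <- as.data.frame(curve)
  out$trial_cost <- fixed_cost + cost_per_patient * out$n
  out$enbs <- out$pop_evsi - out$trial_cost
  best <- which(out$enbs == max(out$enbs))[1]
  structure(out, optimal_n = out$n[best],
            outer = attr(curve, "outer"), inner = attr(curve, "inner"),
            seed = attr(curve, "seed"), eff_pop = attr(curve, "eff_pop"),
            class = c("enbs_curve", "data.frame"))
}

#' @export
print.enbs_curve <- function(x, ...) {
  cat("<enbs_curve> expected net benefit of sampling\n")
  df <- as.data.frame(x)
  df$pop_evsi <- sprintf("%.2f M", df$pop_evsi / 1e6)
  df$enbs <- sprintf("%.2f M", df$enbs / 1e6)
  print(df[, c("n", "evsi_pp", "pop_evsi", "trial_cost", "enbs")], row.names = FALSE)
  cat(sprintf("optimal n = %d\n", attr(x, "optimal_n")))
  invisible(x)
}
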