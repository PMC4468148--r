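# Four-state cohort model of post-thrombotic syndrome (PTS) after deep vein
# thrombosis under two elastic-compression-stocking (ECS) strategies:
#   two_year  -- all patients wear stockings for 24 months (comparator)
#   tailored  -- all wear for 6 months, then a configurable proportion stops;
#                the rest continue to 24 months. A relative-risk parameter
#                (rr >= 1) multiplies the post-6-month onset probabilities in
#                this arm.

STRATEGIES <- c("two_year", "tailored")

#' Cycle plan of the cohort model
#'
#' Two 6-month cycles followed by 1-year cycles up to the horizon age
#' (lifetime implemented as a run-until-`horizon_age` cap).
#'
#' @param start_age age at model entry (years).
#' @param horizon_age age at which the model stops.
#' @return data.frame with one row per cycle: `cycle`, `length` (years),
#'   `age` and `time` at cycle start.
#' @export
cycle_plan <- function(start_age, horizon_age) {
  stopifnot(horizon_age > start_age + 1)
  len <- c(0.5, 0.5, rep(1, horizon_age - start_age - 1))
  start <- cumsum(c(0, len[-length(len)]))
  data.frame(cycle = seq_along(len), length = len,
             age = start_age + start, time = start)
}

#' Interval-conditional onset probabilities from cumulative incidence
#'
#' Converts cumulative PTS incidence at 6, 12 and 24 months into the
#' conditional probability of onset within each interval given no prior
#' onset: `q1 = c6`, `q2 = (c12-c6)/(1-c6)`, `q3 = (c24-c12)/(1-c12)`.
#' The recomposition `1 - (1-q1)(1-q2)(1-q3)` returns `c24` exactly.
#'
#' @param c6,c12,c24 cumulative incidences, `0 <= c6 <= c12 <= c24 < 1`.
#' @return named numeric vector `c(q1, q2, q3)`.
#' @examples
#' interval_probs_from_cumulative(0.211, 0.222, 0.245)
#' @export
interval_probs_from_cumulative <- function(c6, c12, c24) {
  if (any(!is.finite(c(c6, c12, c24))) || c6 < 0 || c24 >= 1 || c6 > c12 || c12 > c24)
    stop("cumulative incidences must satisfy 0 <= c6 <= c12 <= c24 < 1", call. = FALSE)
  c(q1 = c6, q2 = (c12 - c6) / (1 - c6), q3 = (c24 - c12) / (1 - c12))
}

#' Apply the relative-risk parameter to post-6-month onset probabilities
#'
#' The rr parameter expresses the uncertain loss of preventive effect when
#' stocking duration is individually tailored. It multiplies only the onset
#' probabilities after month 6 (tailoring starts at the 6-month visit); the
#' 0--6-month probability is common to both arms. Products above 1 clamp to 1.
#'
#' @param q2,q3 conditional onset probabilities for 6--12 and 12--24 months.
#' @param rr relative risk, `rr >= 1` (draws are censored upstream).
#' @return named numeric vector `c(q2, q3)` after multiplication.
#' @export
apply_rr <- function(q2, q3, rr) {
  if (any(rr < 1)) stop("rr must be >= 1; censor draws before applying", call. = FALSE)
  c(q2 = pmin(rr * q2, 1), q3 = pmin(rr * q3, 1))
}

# Annual Gompertz mortality hazard at a given age.
gompertz_hazard <- function(age, a, b) a * exp(b * age)

# Onset probability looked up for a cycle: onset is possible only in the
# cycles covering months 0-24 (the evidence window); rr_factor is 1 for the
# two-year arm and the rr draw for the tailored arm.
onset_prob <- function(theta, cycle, rr_factor) {
  q <- switch(as.character(cycle),
              "1" = theta[["q1"]],
              "2" = theta[["q2"]] * rr_factor,
              "3" = theta[["q3"]] * rr_factor,
              0)
  pmin(q, 1)
}

# Fraction of the (alive) cohort wearing stockings during a cycle.
wear_fraction <- function(strategy, cycle, stop_proportion) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (cycle > 3) return(0)
  if (strategy == "two_year") 1
  else if (cycle == 1) 1
  else 1 - stop_proportion
}

#' Transition matrix for one cycle
#'
#' Builds the 4x4 transition matrix over states NoPTS, MildModPTS, SeverePTS,
#' Death for a given parameter draw, strategy and cycle. Onset moves patients
#' from NoPTS into the two PTS states split by the configured severe
#' fraction; age-specific background mortality applies from every alive
#' state; Death is absorbing; PTS confers no excess mortality and no new
#' onset occurs after the cycle ending at month 24.
#'
#' @param theta named numeric vector with at least `q1`, `q2`, `q3`, `rr`.
#' @param strategy `"two_year"` or `"tailored"`.
#' @param cycle cycle index (1-based) within the plan.
#' @param config a `voi_config`.
#' @return 4x4 row-stochastic matrix with dimnames `STATES`.
#' @export
build_transitions <- function(theta, strategy, cycle, config) {
  strategy <- match.arg(strategy, STRATEGIES)
  plan <- cycle_plan(config$model$start_age, config$model$horizon_age)
  if (cycle < 1 || cycle > nrow(plan)) stop("cycle index outside the cycle plan", call. = FALSE)
  sev <- config$model$severe_fraction
  if (sev < 0 || sev > 1) stop("configuration error: severe_fraction outside [0,1]", call. = FALSE)
  len <- plan$length[cycle]
  age <- plan$age[cycle]
  mort <- config$model$mortality
  d <- 1 - exp(-gompertz_hazard(age, mort$gompertz_a, mort$gompertz_b) * len)
  rr_factor <- if (strategy == "tailored") theta[["rr"]] else 1
  q <- onset_prob(theta, cycle, rr_factor)
  P <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  P["NoPTS", ] <- c((1 - d) * (1 - q), (1 - d) * q * (1 - sev), (1 - d) * q * sev, d)
  P["MildModPTS", ] <- c(0, 1 - d, 0, d)
  P["SeverePTS", ] <- c(0, 0, 1 - d, d)
  P["Death", ] <- c(0, 0, 0, 1)
  P
}

#' Run the cohort simulation for one parameter draw
#'
#' Starts the full cohort in NoPTS and propagates it through every cycle of
#' the plan. Deterministic given its inputs.
#'
#' @inheritParams build_transitions
#' @param theta named numeric vector of parameter values (one draw).
#' @return matrix of class `cohort_trace`, `(n_cycles + 1) x 4`, of cohort
#'   occupancy at the start of each cycle (row 1 = model entry).
#' @export
run_cohort <- function(config, theta, strategy) {
  plan <- cycle_plan(config$model$start_age, config$model$horizon_age)
  trace <- matrix(NA_real_, nrow(plan) + 1, 4, dimnames = list(NULL, STATES))
  v <- c(1, 0, 0, 0)
  trace[1, ] <- v
  for (i in seq_len(nrow(plan))) {
    v <- as.numeric(v %*% build_transitions(theta, strategy, i, config))
    trace[i + 1, ] <- v
  }
  structure(trace, class = c("cohort_trace", class(trace)))
}

# Age-dependent population norm utility (placeholder linear decline).
utility_norm <- function(age, config) {
  config$model$utility_norm_at_start -
    config$model$utility_norm_slope * (age - config$model$start_age)
}

#' Discounted lifetime cost and QALYs from a cohort trace
#'
#' Accumulates, over cycles, discounted costs (PTS state costs plus
#' strategy-specific ECS costs while stockings are worn) and discounted
#' QALYs (age norm utility minus PTS and ECS disutilities). Rewards accrue
#' on the occupancy at cycle start; discount factors use annual compounding
#' evaluated at cycle start, without half-cycle correction. Utilities that
#' would become negative after subtracting disutilities are clamped at zero
#' with a warning.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param theta named numeric vector of parameter values (one draw).
#' @param config a `voi_config`.
#' @param strategy `"two_year"` or `"tailored"`.
#' @return object of class `ce_outcome`: list with `strategy`, `cost`
#'   (EUR), `effect` (QALYs).
#' @export
discounted_ce <- function(trace, theta, config, strategy) {
  strategy <- match.arg(strategy, STRATEGIES)
  plan <- cycle_plan(config$model$start_age, config$model$horizon_age)
  stopifnot(nrow(trace) == nrow(plan) + 1)
  m <- config$model
  cost <- 0; qaly <- 0; clamped <- FALSE
  for (i in seq_len(nrow(plan))) {
    occ <- trace[i, ]
    len <- plan$length[i]
    dfc <- (1 + m$discount_cost)^(-plan$time[i])
    dfe <- (1 + m$discount_effect)^(-plan$time[i])
    w <- wear_fraction(strategy, i, m$stop_proportion)
    ecs_rate <- (theta[["cost_stocking"]] +
                   theta[["homecare_fraction"]] * theta[["cost_homecare"]]) * w
    alive <- occ[["NoPTS"]] + occ[["MildModPTS"]] + occ[["SeverePTS"]]
    cost <- cost + dfc * len *
      (occ[["MildModPTS"]] * theta[["cost_pts_mild"]] +
       occ[["SeverePTS"]] * theta[["cost_pts_severe"]] + alive * ecs_rate)
    un <- utility_norm(plan$age[i], config)
    u <- c(un - w * theta[["disutility_ecs"]],
           un - theta[["disutility_mild"]] - w * theta[["disutility_ecs"]],
           un - theta[["disutility_severe"]] - w * theta[["disutility_ecs"]])
    if (any(u < 0)) { clamped <- TRUE; u <- pmax(u, 0) }
    qaly <- qaly + dfe * len * sum(occ[1:3] * u)
  }
  if (clamped) warning("utility clamped at 0 after disutility subtraction")
  structure(list(strategy = strategy, cost = cost, effect = qaly),
            class = "ce_outcome")
}

#' @export
print.ce_outcome <- function(x, ...) {
  cat(sprintf("<ce_outcome> %s: cost %.2f EUR, effect %.4f QALY\n",
              x$strategy, x$cost, x$effect))
  invisible(x)
}

#' Vectorised cost-effectiveness evaluation over parameter draws
#'
#' Evaluates the cohort model for every row of a parameter-draw matrix and
#' both strategies simultaneously, accumulating discounted costs and QALYs on
#' the fly. Identical (to machine precision) to running [run_cohort()] plus
#' [discounted_ce()] per draw, but vectorised over draws; this is the hot
#' path used by the PSA and all value-of-information loops.
#'
#' @param draws matrix of parameter draws (columns named as in
#'   `config$specs`).
#' @param config a `voi_config`.
#' @return list with `cost` and `effect`, each a `K x 2` matrix with columns
#'   `two_year`, `tailored`.
#' @export
evaluate_strategies <- function(draws, config) {
  draws <- unclass(draws)
  K <- nrow(draws)
  m <- config$model
  plan <- cycle_plan(m$start_age, m$horizon_age)
  mort <- m$mortality
  sev <- m$severe_fraction
  ecs_rate0 <- draws[, "cost_stocking"] + draws[, "homecare_fraction"] * draws[, "cost_homecare"]
  cost <- matrix(0, K, 2, dimnames = list(NULL, STRATEGIES))
  effect <- matrix(0, K, 2, dimnames = list(NULL, STRATEGIES))
  clamped <- FALSE
  for (s in 1:2) {
    strategy <- STRATEGIES[s]
    rr_factor <- if (strategy == "tailored") draws[, "rr"] else rep(1, K)
    nN <- rep(1, K); nM <- rep(0, K); nS <- rep(0, K)
    for (i in seq_len(nrow(plan))) {
      len <- plan$length[i]
      age <- plan$age[i]
      dfc <- (1 + m$discount_cost)^(-plan$time[i])
      dfe <- (1 + m$discount_effect)^(-plan$time[i])
      w <- wear_fraction(strategy, i, m$stop_proportion)
      alive <- nN + nM + nS
      cost[, s] <- cost[, s] + dfc * len *
        (nM * draws[, "cost_pts_mild"] + nS * draws[, "cost_pts_severe"] +
         alive * ecs_rate0 * w)
      un <- utility_norm(age, config)
      uN <- un - w * draws[, "disutility_ecs"]
      uM <- uN - draws[, "disutility_mild"]
      uS <- uN - draws[, "disutility_severe"]
      if (any(uS < 0) || any(uM < 0) || any(uN < 0)) {
        clamped <- TRUE
        uN <- pmax(uN, 0); uM <- pmax(uM, 0); uS <- pmax(uS, 0)
      }
      effect[, s] <- effect[, s] + dfe * len * (nN * uN + nM * uM + nS * uS)
      d <- 1 - exp(-gompertz_hazard(age, mort$gompertz_a, mort$gompertz_b) * len)
      q <- if (i == 1) draws[, "q1"]
           else if (i == 2) pmin(draws[, "q2"] * rr_factor, 1)
           else if (i == 3) pmin(draws[, "q3"] * rr_factor, 1)
           else 0
      onset <- nN * (1 - d) * q
      nM <- nM * (1 - d) + onset * (1 - sev)
      nS <- nS * (1 - d) + onset * sev
      nN <- nN * (1 - d) * (1 - q)
    }
  }
  if (clamped) warning("utility clamped at 0 after disutility subtraction")
  list(cost = cost, effect = effect)
}

#' Write a cohort trace to CSV
#' @param trace a `cohort_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  df <- data.frame(row = seq_len(nrow(trace)) - 1L, unclass(trace))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
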