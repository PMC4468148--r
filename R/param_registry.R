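# Ordered health states of the cohort model.
STATES <- c("NoPTS", "MildModPTS", "SeverePTS", "Death")

# Distribution families understood by the parameter registry.
PARAM_FAMILIES <- c("beta-by-moments", "gamma-by-moments", "lognormal-censored",
                    "normal", "fixed")

#' Specify one uncertain (or fixed) model parameter
#'
#' A `param_spec` describes a single entry of the parameter vector theta as a
#' distribution family plus a moment (mean/SE) specification in natural units.
#' Supported families are `beta-by-moments` (proportions), `gamma-by-moments`
#' (non-negative costs), `lognormal-censored` (a relative risk with draws
#' below `lower` rounded up to `lower`), `normal`, and `fixed`.
#'
#' @param name identifier, used as a column name in parameter draws.
#' @param family one of `"beta-by-moments"`, `"gamma-by-moments"`,
#'   `"lognormal-censored"`, `"normal"`, `"fixed"`.
#' @param mean mean in natural units (ignored for `lognormal-censored`, whose
#'   location is fixed at a log-scale mean of 0).
#' @param se standard error in natural units; must be 0 for `family = "fixed"`.
#' @param sigma_log log-scale standard deviation, required for
#'   `lognormal-censored`.
#' @param lower,upper optional bounds; `lower` is the censoring point of the
#'   censored lognormal (default 1).
#' @param units free-text unit annotation.
#' @param appendix_default logical; marks placeholder values standing in for
#'   quantities the primary evidence sources do not publish in full detail.
#' @return an object of class `param_spec`.
#' @export
param_spec <- function(name, family, mean = NA_real_, se = NA_real_,
                       sigma_log = NA_real_, lower = NA_real_, upper = NA_real_,
                       units = "", appendix_default = FALSE) {
  stopifnot(is.character(name), nzchar(name))
  family <- match.arg(family, PARAM_FAMILIES)
  if (family == "beta-by-moments") {
    if (!is.finite(mean) || mean <= 0 || mean >= 1)
      stop("parameter '", name, "': beta-by-moments requires 0 < mean < 1", call. = FALSE)
    if (!is.finite(se) || se < 0 || se^2 >= mean * (1 - mean))
      stop("parameter '", name, "': infeasible moments, need se^2 < mean*(1-mean)", call. = FALSE)
  } else if (family == "gamma-by-moments") {
    if (!is.finite(mean) || mean <= 0) stop("parameter '", name, "': gamma-by-moments requires mean > 0", call. = FALSE)
    if (!is.finite(se) || se <= 0) stop("parameter '", name, "': gamma-by-moments requires se > 0", call. = FALSE)
  } else if (family == "lognormal-censored") {
    if (!is.finite(sigma_log) || sigma_log <= 0)
      stop("parameter '", name, "': lognormal-censored requires sigma_log > 0", call. = FALSE)
    if (is.na(lower)) lower <- 1
  } else if (family == "normal") {
    if (!is.finite(mean) || !is.finite(se) || se < 0)
      stop("parameter '", name, "': normal requires finite mean and se >= 0", call. = FALSE)
  } else if (family == "fixed") {
    if (!is.finite(mean)) stop("parameter '", name, "': fixed requires a finite mean", call. = FALSE)
    if (is.na(se)) se <- 0
    if (se != 0) stop("parameter '", name, "': fixed requires se = 0", call. = FALSE)
  }
  structure(list(name = name, family = family, mean = mean, se = se,
                 sigma_log = sigma_log, lower = lower, upper = upper,
                 units = units, appendix_default = isTRUE(appendix_default)),
            class = "param_spec")
}

#' @export
print.param_spec <- function(x, ...) {
  extra <- if (x$family == "lognormal-censored")
    sprintf("sigma_log=%g, censored at %g", x$sigma_log, x$lower)
  else sprintf("mean=%g, se=%g", x$mean, x$se)
  flag <- if (x$appendix_default) " [appendix-default]" else ""
  cat(sprintf("<param_spec> %s: %s (%s)%s\n", x$name, x$family, extra, flag))
  invisible(x)
}

#' Beta distribution from mean and standard error
#'
#' Method-of-moments fit: with \eqn{v = m(1-m)/se^2 - 1}, the shapes
#' \eqn{\alpha = m v} and \eqn{\beta = (1-m) v} reproduce the requested mean
#' and SE exactly.
#'
#' @param mean proportion in (0, 1).
#' @param se standard error, with `se^2 < mean * (1 - mean)`.
#' @return list with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.211, 0.0429)
#' @export
beta_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(se) || se <= 0)
    stop("se must be positive; use family 'fixed' for known parameters", call. = FALSE)
  if (se^2 >= mean * (1 - mean))
    stop("infeasible moments: se^2 must be < mean*(1-mean)", call. = FALSE)
  v <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * v, beta = (1 - mean) * v)
}

#' Gamma distribution from mean and standard error
#'
#' Method-of-moments fit on the (shape, rate) parameterisation:
#' `shape = mean^2/se^2`, `rate = mean/se^2`.
#'
#' @param mean positive mean.
#' @param se positive standard error.
#' @return list with elements `shape` and `rate`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive", call. = FALSE)
  if (!is.finite(se) || se <= 0)
    stop("se must be positive; use family 'fixed' for known parameters", call. = FALSE)
  list(shape = mean^2 / se^2, rate = mean / se^2)
}

#' Censored lognormal relative-risk distribution
#'
#' The relative-risk prior has median 1 on the natural scale (log-scale mean
#' 0) and log-scale standard deviation `sigma_log`; draws below `censor_at`
#' are rounded up to `censor_at`, encoding the assumption that the new
#' therapy is at best equal to, and possibly worse than, the standard
#' therapy. The returned handle exposes `sample(k, seed)`, `quantile(q)` and
#' the closed-form `mean()`
#' \eqn{E[\max(e^Z, c)] = c\,\Phi(\log(c)/\sigma) +
#'      e^{\sigma^2/2}\,\Phi(\sigma - \log(c)/\sigma)}.
#'
#' @param sigma_log positive log-scale standard deviation.
#' @param censor_at censoring point, default 1.
#' @return an object of class `censored_lognormal` with function elements
#'   `sample`, `quantile`, `mean`.
#' @examples
#' rr <- censored_lognormal(0.612)
#' rr$quantile(0.975)  # upper end of the 95% interval, ~3.32
#' @export
censored_lognormal <- function(sigma_log, censor_at = 1) {
  if (!is.finite(sigma_log) || sigma_log <= 0)
    stop("sigma_log must be positive", call. = FALSE)
  lc <- log(censor_at)
  obj <- list(
    sigma_log = sigma_log,
    censor_at = censor_at,
    sample = function(k, seed = NULL) {
      if (!is.null(seed)) set.seed(seed)
      pmax(exp(stats::rnorm(k, 0, sigma_log)), censor_at)
    },
    quantile = function(q) {
      stopifnot(all(q >= 0 & q <= 1))
      pmax(exp(stats::qnorm(q) * sigma_log), censor_at)
    },
    mean = function() {
      censor_at * stats::pnorm(lc / sigma_log) +
        exp(sigma_log^2 / 2) * stats::pnorm(sigma_log - lc / sigma_log)
    })
  class(obj) <- "censored_lognormal"
  obj
}

#' Refit interval-conditional onset probabilities as independent Betas
#'
#' The evidence base reports cumulative PTS incidence at 6, 12 and 24 months
#' with standard errors, but not the joint distribution of the three
#' quantities. Sampling the three cumulative values independently would
#' produce non-monotone draws, so the registry instead samples the
#' per-interval conditional onset probabilities q1, q2, q3 (see
#' [interval_probs_from_cumulative()]) independently from moment-matched
#' Betas, which guarantees monotone cumulative incidence by construction.
#' Interval SEs are obtained by variance differencing on the cumulative
#' scale: `se(q1) = se(c6)`, `se(q2) = sqrt(se(c12)^2 - se(c6)^2)/(1 - c6)`,
#' and analogously for q3, so that recomposed cumulative draws have
#' approximately the reported spread.
#'
#' @param c6,c12,c24 lists with elements `mean` and `se` for the cumulative
#'   incidence at 6, 12 and 24 months.
#' @return list of three `param_spec` objects named `q1`, `q2`, `q3`.
#' @export
incidence_interval_specs <- function(c6, c12, c24) {
  m <- c(c6$mean, c12$mean, c24$mean)
  s <- c(c6$se, c12$se, c24$se)
  if (any(!is.finite(m)) || any(!is.finite(s)))
    stop("incidence entries need finite mean and se", call. = FALSE)
  if (is.unsorted(m)) stop("cumulative incidence means must be nondecreasing", call. = FALSE)
  if (is.unsorted(s))
    stop("cumulative incidence SEs must be nondecreasing for variance differencing", call. = FALSE)
  q <- interval_probs_from_cumulative(m[1], m[2], m[3])
  se_q <- c(s[1],
            sqrt(s[2]^2 - s[1]^2) / (1 - m[1]),
            sqrt(s[3]^2 - s[2]^2) / (1 - m[2]))
  mapply(function(nm, mean, se) {
    if (se == 0)  # degenerate evidence: a known interval probability
      param_spec(nm, "fixed", mean = mean, units = "probability per interval")
    else
      param_spec(nm, "beta-by-moments", mean = mean, se = se,
                 units = "probability per interval")
  }, c("q1", "q2", "q3"), q, se_q, SIMPLIFY = FALSE)
}

# Deterministic sub-seed for a named random stream, kept below 2^31 so it is
# a valid R integer seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

# ---- configuration ---------------------------------------------------------

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("configuration error: unknown key(s) in '", where, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(allowed, names(x))
  if (length(missing))
    stop("configuration error: missing key(s) in '", where, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(x)
}

check_rate <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x >= 1)
    stop("configuration error: '", key, "' must be a rate in [0, 1)", call. = FALSE)
  x
}

#' Path to the shipped case-study configuration
#' @return file path of the YAML configuration installed with the package.
#' @export
case_config_path <- function() {
  system.file("extdata", "case_study.yaml", package = "voidesign", mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads the hierarchical YAML configuration (sections `model`, `population`,
#' `trial`, `frequentist`, `voi`, `parameters`), validates every invariant
#' (rates in \[0,1), strictly increasing sample-size grid, feasible moment
#' specifications, monotone cumulative incidence) and rejects unknown keys.
#' Cumulative incidence entries are converted to interval-conditional Beta
#' specs via [incidence_interval_specs()]. Parameters marked
#' `appendix_default: true` in the file are placeholder values; they are
#' flagged as such in the returned specs.
#'
#' @param path path to a YAML configuration file; defaults to the shipped
#'   case study.
#' @return an object of class `voi_config`: a list with elements `model`,
#'   `population`, `trial`, `frequentist`, `voi` and `specs` (a named list of
#'   [param_spec()] objects).
#' @export
load_config <- function(path = case_config_path()) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("model", "population", "trial", "frequentist", "voi", "parameters"),
             "top level")

  m <- check_keys(raw$model,
                  c("threshold", "discount_cost", "discount_effect", "start_age",
                    "horizon_age", "severe_fraction", "stop_proportion",
                    "utility_norm_at_start", "utility_norm_slope", "mortality"),
                  "model")
  if (!is.numeric(m$threshold) || m$threshold < 0)
    stop("configuration error: 'threshold' must be a nonnegative amount per QALY", call. = FALSE)
  check_rate(m$discount_cost, "discount_cost")
  check_rate(m$discount_effect, "discount_effect")
  check_rate(m$severe_fraction, "severe_fraction")
  check_rate(m$stop_proportion, "stop_proportion")
  if (m$horizon_age <= m$start_age)
    stop("configuration error: 'horizon_age' must exceed 'start_age'", call. = FALSE)
  check_keys(m$mortality, c("gompertz_a", "gompertz_b"), "model.mortality")
  if (m$mortality$gompertz_a <= 0 || m$mortality$gompertz_b <= 0)
    stop("configuration error: Gompertz mortality parameters must be positive", call. = FALSE)

  pop <- check_keys(raw$population,
                    c("annual_incidence", "tech_lifetime", "discount_rate"),
                    "population")
  if (pop$annual_incidence <= 0 || pop$tech_lifetime <= 0)
    stop("configuration error: population size inputs must be positive", call. = FALSE)
  check_rate(pop$discount_rate, "population.discount_rate")

  tr <- check_keys(raw$trial,
                   c("fixed_cost", "cost_per_patient", "sample_size_grid"),
                   "trial")
  g <- tr$sample_size_grid
  if (!is.numeric(g) || any(g != round(g)) || any(g <= 0) || is.unsorted(g, strictly = TRUE))
    stop("configuration error: 'sample_size_grid' must be strictly increasing positive integers",
         call. = FALSE)
  tr$sample_size_grid <- as.integer(g)

  fr <- check_keys(raw$frequentist,
                   c("p_standard", "p_new", "margin", "alpha", "power"),
                   "frequentist")

  voi <- check_keys(raw$voi, c("psa_draws", "outer", "inner"), "voi")

  pars <- check_keys(raw$parameters,
                     c("incidence", "rr", "disutility_mild", "disutility_severe",
                       "disutility_ecs", "cost_pts_mild", "cost_pts_severe",
                       "cost_stocking", "homecare_fraction", "cost_homecare"),
                     "parameters")
  inc <- check_keys(pars$incidence, c("c6", "c12", "c24"), "parameters.incidence")
  for (k in names(inc)) check_keys(inc[[k]], c("mean", "se"), paste0("parameters.incidence.", k))
  specs <- incidence_interval_specs(inc$c6, inc$c12, inc$c24)

  rrp <- check_keys(pars$rr, c("sigma_log"), "parameters.rr")
  specs$rr <- if (rrp$sigma_log == 0)  # no uncertainty: rr known to be 1
    param_spec("rr", "fixed", mean = 1, units = "relative risk")
  else
    param_spec("rr", "lognormal-censored", sigma_log = rrp$sigma_log,
               units = "relative risk")

  scalar_par <- function(key) {
    p <- pars[[key]]
    ok <- c("family", "mean", "se")
    if (!is.null(p$appendix_default)) ok <- c(ok, "appendix_default")
    check_keys(p, ok, paste0("parameters.", key))
    param_spec(key, p$family, mean = p$mean, se = p$se,
               appendix_default = isTRUE(p$appendix_default))
  }
  for (key in c("disutility_mild", "disutility_severe", "disutility_ecs",
                "cost_pts_mild", "cost_pts_severe", "cost_stocking",
                "homecare_fraction", "cost_homecare"))
    specs[[key]] <- scalar_par(key)

  structure(list(model = m, population = pop, trial = tr, frequentist = fr,
                 voi = voi, specs = specs),
            class = "voi_config")
}

#' @export
print.voi_config <- function(x, ...) {
  cat("<voi_config>\n")
  cat(sprintf("  threshold: %s per QALY; discounting %g%% costs / %g%% effects\n",
              format(x$model$threshold, big.mark = ","),
              100 * x$model$discount_cost, 100 * x$model$discount_effect))
  cat(sprintf("  cohort: age %g to %g; %d uncertain/fixed parameters\n",
              x$model$start_age, x$model$horizon_age, length(x$specs)))
  cat(sprintf("  population: %s/yr over %g yr; trial cost %s + %s per patient\n",
              format(x$population$annual_incidence, big.mark = ","),
              x$population$tech_lifetime,
              format(x$trial$fixed_cost, big.mark = ","),
              format(x$trial$cost_per_patient, big.mark = ",")))
  invisible(x)
}

# Draw k values from one spec using the current RNG state.
draw_spec <- function(spec, k) {
  switch(spec$family,
    "beta-by-moments" = {
      ab <- beta_from_moments(spec$mean, spec$se)
      stats::rbeta(k, ab$alpha, ab$beta)
    },
    "gamma-by-moments" = {
      sr <- gamma_from_moments(spec$mean, spec$se)
      stats::rgamma(k, shape = sr$shape, rate = sr$rate)
    },
    "lognormal-censored" = pmax(exp(stats::rnorm(k, 0, spec$sigma_log)),
                                if (is.na(spec$lower)) 1 else spec$lower),
    "normal" = stats::rnorm(k, spec$mean, spec$se),
    "fixed" = rep(spec$mean, k))
}

#' Sample joint prior parameter draws
#'
#' Draws `K` joint realisations of the parameter vector theta. All parameters
#' are sampled independently; the three PTS onset probabilities are sampled
#' on the interval-conditional scale, so recomposed cumulative incidences are
#' monotone in every draw, and relative-risk draws are censored at 1.
#'
#' @param specs named list of [param_spec()] objects (e.g. `config$specs`).
#' @param K number of draws.
#' @param seed integer seed; if `NULL` the current RNG state is used, which
#'   lets callers embed sampling in a larger reproducible stream.
#' @return a `K x length(specs)` matrix of class `param_draws` with one named
#'   column per parameter and attribute `seed`.
#' @export
sample_priors <- function(specs, K, seed = NULL) {
  stopifnot(K >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(specs, draw_spec, numeric(K), k = K)
  if (K == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(specs)))
  colnames(draws) <- names(specs)
  structure(draws, seed = seed, class = c("param_draws", class(draws)))
}

#' Write parameter draws to CSV
#' @param draws a `param_draws` matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_draws <- function(draws, path) {
  utils::write.csv(as.data.frame(unclass(draws)), path, row.names = FALSE)
  invisible(path)
}
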