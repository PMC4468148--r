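# Probabilistic sensitivity analysis on the net monetary benefit scale.

#' Net monetary benefit
#'
#' `NMB = lambda * effect - cost`, per strategy. Differences between
#' strategies then reproduce the incremental form
#' `lambda * (H_new - H_std) - (C_new - C_std)`.
#'
#' @param cost cost in EUR (vector or matrix).
#' @param effect health outcome in QALYs, conformable with `cost`.
#' @param lambda willingness-to-pay threshold, EUR per QALY.
#' @return net monetary benefit in EUR, same shape as the inputs.
#' @examples
#' nmb(14400, 12.50, 20000)  # 235600
#' @export
nmb <- function(cost, effect, lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative", call. = FALSE)
  lambda * effect - cost
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `K` joint parameter vectors from the priors and evaluates the
#' cohort model for both strategies at the same draw (common random
#' parameters, so incremental quantities are estimated with maximal
#' precision and the EVPI is coherent).
#'
#' @param config a `voi_config`.
#' @param K number of draws (default from `config$voi$psa_draws`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `psa_result`: list with `draws` (K x P), `cost`,
#'   `effect`, `nmb` (each K x 2 with columns `two_year`, `tailored`),
#'   `lambda`, `K`, `seed`.
#' @export
run_psa <- function(config, K = config$voi$psa_draws, seed = NULL) {
  stopifnot(K >= 2)
  draws <- sample_priors(config$specs, K, seed)
  ce <- evaluate_strategies(draws, config)
  structure(list(draws = draws, cost = ce$cost, effect = ce$effect,
                 nmb = nmb(ce$cost, ce$effect, config$model$threshold),
                 lambda = config$model$threshold, K = K, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> K = %d draws, lambda = %s per QALY\n",
              x$K, format(x$lambda, big.mark = ",")))
  print(summarize_psa(x), digits = 4)
  invisible(x)
}

#' Summarise a PSA
#'
#' Mean and empirical 2.5/97.5 percentiles (linear interpolation) of cost,
#' effect and NMB per strategy, plus the probability that each strategy has
#' the highest NMB. Per-draw ties for the highest NMB are counted half to
#' each strategy.
#'
#' @param psa a `psa_result`.
#' @return data.frame with one row per strategy.
#' @export
summarize_psa <- function(psa) {
  stopifnot(inherits(psa, "psa_result"), psa$K >= 2)
  qs <- function(m) t(apply(m, 2, function(v)
    c(mean = mean(v), stats::quantile(v, c(0.025, 0.975), names = FALSE))))
  cm <- qs(psa$cost); em <- qs(psa$effect); nm <- qs(psa$nmb)
  best1 <- psa$nmb[, 1] > psa$nmb[, 2]
  tie <- psa$nmb[, 1] == psa$nmb[, 2]
  p_best <- c(mean(best1) + mean(tie) / 2, mean(!best1 & !tie) + mean(tie) / 2)
  data.frame(strategy = colnames(psa$nmb),
             cost_mean = cm[, 1], cost_lo = cm[, 2], cost_hi = cm[, 3],
             effect_mean = em[, 1], effect_lo = em[, 2], effect_hi = em[, 3],
             nmb_mean = nm[, 1], nmb_lo = nm[, 2], nmb_hi = nm[, 3],
             p_best = p_best, row.names = NULL)
}

#' Write PSA draws and outcomes to CSV
#'
#' One row per draw: the parameter values followed by per-strategy cost,
#' effect and NMB. This file is the interchange format for downstream
#' value-of-information analysis.
#'
#' @param psa a `psa_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_psa <- function(psa, path) {
  df <- data.frame(unclass(psa$draws),
                   cost_two_year = psa$cost[, 1], cost_tailored = psa$cost[, 2],
                   effect_two_year = psa$effect[, 1], effect_tailored = psa$effect[, 2],
                   nmb_two_year = psa$nmb[, 1], nmb_tailored = psa$nmb[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
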