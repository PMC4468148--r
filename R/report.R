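# End-to-end case-study driver: frequentist design, PSA, EVPI/EVPPI/EVSI/
# ENBS, CSV outputs, a plain-text report and a run manifest.

# All-zero EVSI curve used when the priors carry no uncertainty.
evsi_zero_curve <- function(grid, pop) {
  structure(data.frame(n = as.integer(grid), evsi_pp = 0, se_pp = 0,
                       population = pop, pop_evsi = 0, pop_se = 0,
                       skipped_rr_updates = 0L),
            class = c("evsi_curve", "data.frame"))
}

#' Run the full case study
#'
#' Drives every stage of the comparison on one configuration: the
#' frequentist non-inferiority sample size, the probabilistic sensitivity
#' analysis, EVPI and population EVPI, EVPPI for the PTS-incidence
#' parameters, the EVSI curve over the sample-size grid and the ENBS with
#' its optimal n. Writes CSV outputs, a markdown report juxtaposing the two
#' sample sizes, and a JSON manifest sufficient to re-run the analysis
#' bit-identically.
#'
#' @param config_path path to a YAML configuration (default: shipped case).
#' @param mode `"scaled-down"` (outer 50, inner 200, 4-point grid; minutes
#'   on one CPU) or `"full"` (outer and inner from the config, full grid).
#' @param seed master seed for all random streams.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with all computed objects and `outdir`.
#' @export
run_case_study <- function(config_path = case_config_path(),
                           mode = c("scaled-down", "full"),
                           seed = 1L, outdir = tempfile("case_study_")) {
  mode <- match.arg(mode)
  config <- load_config(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (mode == "scaled-down") {
    outer <- 50L; inner <- 200L
    grid <- config$trial$sample_size_grid
    grid <- grid[unique(round(seq(1, length(grid), length.out = min(4, length(grid)))))]
  } else {
    outer <- config$voi$outer; inner <- config$voi$inner
    grid <- config$trial$sample_size_grid
  }

  fr <- config$frequentist
  design_freq <- ni_sample_size(fr$p_standard, fr$p_new, fr$margin, fr$alpha, fr$power)
  freq_df <- data.frame(quantity = c("p_standard", "p_new", "margin", "alpha", "power",
                                     "z_alpha", "z_beta", "n_raw_per_group",
                                     "n_per_group", "n_total"),
                        value = c(fr$p_standard, fr$p_new, fr$margin, fr$alpha, fr$power,
                                  design_freq$z_alpha, design_freq$z_beta,
                                  design_freq$n_raw, design_freq$n_per_group,
                                  design_freq$n_total))
  utils::write.csv(freq_df, file.path(outdir, "frequentist.csv"), row.names = FALSE)

  psa <- run_psa(config, K = max(config$voi$psa_draws, 1000L),
                 seed = derive_seed(seed, "psa"))
  psa_sum <- summarize_psa(psa)
  utils::write.csv(psa_sum, file.path(outdir, "psa_summary.csv"), row.names = FALSE)

  ev <- evpi(psa)
  pop <- effective_population(config$population$annual_incidence,
                              config$population$tech_lifetime,
                              config$population$discount_rate)
  pop_ev <- population_evpi(ev$evpi, pop)
  evpi_df <- data.frame(quantity = c("evpi_per_patient", "evpi_mc_se",
                                     "effective_population", "population_evpi"),
                        value = c(ev$evpi, ev$se, pop, pop_ev))
  utils::write.csv(evpi_df, file.path(outdir, "evpi.csv"), row.names = FALSE)

  inc_subset <- c("q1", "q2", "q3", "rr")
  no_uncertainty <- ev$evpi <= 0
  if (no_uncertainty) {
    # zero-variance priors: no decision uncertainty, nothing to learn
    pev <- list(evppi = 0, se = 0, population_evppi = 0)
    curve <- evsi_zero_curve(grid, pop)
  } else {
    pev <- evppi(config, inc_subset, outer = outer, inner = inner,
                 seed = derive_seed(seed, "evppi"))
    curve <- evsi(config, grid = grid, outer = outer, inner = inner, seed = seed)
  }
  evppi_df <- data.frame(subset = paste(inc_subset, collapse = "+"),
                         evppi_per_patient = pev$evppi, mc_se = pev$se,
                         population_evppi = pev$population_evppi)
  utils::write.csv(evppi_df, file.path(outdir, "evppi.csv"), row.names = FALSE)

  nb <- enbs(curve, config$trial$fixed_cost, config$trial$cost_per_patient)
  utils::write.csv(as.data.frame(nb), file.path(outdir, "evsi_enbs.csv"),
                   row.names = FALSE)

  n_opt <- attr(nb, "optimal_n")
  meur <- function(x) sprintf("%.1f", x / 1e6)
  rpt <- c(
    "# Sample size for the non-inferiority trial: frequentist vs decision theory",
    "",
    sprintf("Frequentist (Blackwelder) total sample size: **%d** (%d per group; raw %.2f).",
            design_freq$n_total, design_freq$n_per_group, design_freq$n_raw),
    sprintf("Decision-theoretic optimal sample size (ENBS argmax): **%d**.", n_opt),
    "",
    "## Current evidence (PSA)",
    sprintf("Two-year ECS: cost %.0f (95%% CI %.0f-%.0f) EUR, %.2f (%.2f-%.2f) QALY.",
            psa_sum$cost_mean[1], psa_sum$cost_lo[1], psa_sum$cost_hi[1],
            psa_sum$effect_mean[1], psa_sum$effect_lo[1], psa_sum$effect_hi[1]),
    sprintf("Tailored ECS:  cost %.0f (95%% CI %.0f-%.0f) EUR, %.2f (%.2f-%.2f) QALY.",
            psa_sum$cost_mean[2], psa_sum$cost_lo[2], psa_sum$cost_hi[2],
            psa_sum$effect_mean[2], psa_sum$effect_lo[2], psa_sum$effect_hi[2]),
    "",
    "## Value of information",
    if (ev$evpi <= 0)
      "EVPI = 0: there is no decision uncertainty and no value in further research."
    else
      sprintf(paste0("EVPI %.0f EUR/patient; population EVPI %s M EUR ",
                     "(effective population %.0f). EVPPI(%s) %s M EUR."),
              ev$evpi, meur(pop_ev), pop, paste(inc_subset, collapse = ","),
              meur(pev$population_evppi)),
    "",
    "ENBS curve (EUR million):",
    paste(sprintf("  n = %5d: EVSI %s, ENBS %s", nb$n, meur(nb$pop_evsi), meur(nb$enbs)),
          collapse = "\n"),
    "",
    sprintf("Settings: mode %s, outer %d, inner %d, seed %d.", mode, outer, inner, seed))
  writeLines(rpt, file.path(outdir, "report.md"))

  outputs <- c("frequentist.csv", "psa_summary.csv", "evpi.csv", "evppi.csv",
               "evsi_enbs.csv", "report.md")
  manifest <- list(
    package = "voidesign",
    version = as.character(utils::packageVersion("voidesign")),
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    mode = mode, seed = seed, outer = outer, inner = inner,
    grid = grid, psa_draws = psa$K, outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, frequentist = design_freq, psa = psa,
                 psa_summary = psa_sum, evpi = ev, effective_population = pop,
                 population_evpi = pop_ev, evppi = pev, evsi = curve,
                 enbs = nb, optimal_n = n_opt, outdir = outdir))
}
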