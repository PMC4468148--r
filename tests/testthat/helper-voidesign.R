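# Shared fixtures, all built in code.

case_cfg <- function() load_config(case_config_path())

# Replace every uncertain parameter by a point mass at a chosen value
# (defaults: prior means; rr at 1). Zero-variance priors make the NMB
# columns constant across draws.
degenerate_config <- function(cfg = case_cfg(), rr = 1) {
  cfg$specs <- lapply(cfg$specs, function(s) {
    m <- if (s$name == "rr") rr else s$mean
    param_spec(s$name, "fixed", mean = m)
  })
  cfg
}

# Effectively switch off background mortality (validation requires a > 0).
no_mortality <- function(cfg) {
  cfg$model$mortality$gompertz_a <- 1e-300
  cfg
}

# One theta vector at the prior means (rr at the censored-lognormal mean
# unless overridden), usable by both the scalar and vectorised engines.
theta_at_means <- function(cfg = case_cfg(), rr = NULL) {
  if (is.null(rr)) rr <- censored_lognormal(cfg$specs$rr$sigma_log)$mean()
  th <- vapply(cfg$specs, function(s) if (s$name == "rr") rr else s$mean, numeric(1))
  names(th) <- names(cfg$specs)
  th
}

theta_as_draws <- function(theta) {
  matrix(theta, nrow = 1, dimnames = list(NULL, names(theta)))
}

# Write a modified copy of the shipped YAML config to a temp file.
config_variant <- function(transform) {
  lines <- readLines(case_config_path())
  lines <- transform(lines)
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}
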