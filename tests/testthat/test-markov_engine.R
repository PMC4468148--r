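test_that("interval probabilities recompose the cumulative incidence exactly", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  # independent arithmetic: q2 = (0.222-0.211)/(1-0.211), q3 = (0.245-0.222)/(1-0.222)
  expect_equal(q[["q1"]], 0.211)
  expect_equal(q[["q2"]], 0.011 / 0.789, tolerance = 1e-12)
  expect_equal(q[["q3"]], 0.023 / 0.778, tolerance = 1e-12)
  expect_equal(1 - (1 - q[1]) * (1 - q[2]) * (1 - q[3]), 0.245,
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_equal(interval_probs_from_cumulative(0, 0, 0), c(q1 = 0, q2 = 0, q3 = 0))
  expect_error(interval_probs_from_cumulative(0.3, 0.2, 0.4), "c6 <= c12 <= c24")
})

test_that("the relative risk scales only post-6-month onset and clamps at 1", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  expect_equal(apply_rr(q[["q2"]], q[["q3"]], 1), c(q2 = q[["q2"]], q3 = q[["q3"]]))
  expect_equal(apply_rr(0.9, 0.9, 3.316), c(q2 = 1, q3 = 1))
  expect_error(apply_rr(0.01, 0.01, 0.8), ">= 1")

  # at the prior's upper 95% limit the two-year incidence rises by ~7.5
  # percentage points: the design margin expressed on the incidence scale
  rr <- 3.316
  qq <- apply_rr(q[["q2"]], q[["q3"]], rr)
  c24_tailored <- 1 - (1 - q[["q1"]]) * (1 - qq[["q2"]]) * (1 - qq[["q3"]])
  expect_lt(abs(c24_tailored - 0.320), 0.005)
  expect_lt(abs((c24_tailored - 0.245) - 0.075), 0.005)
})

test_that("transition matrices are row-stochastic with absorbing death", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg, rr = 2)
  for (strategy in c("two_year", "tailored")) for (cy in c(1, 2, 3, 4, 20)) {
    P <- build_transitions(th, strategy, cy, cfg)
    expect_equal(rowSums(P), c(NoPTS = 1, MildModPTS = 1, SeverePTS = 1, Death = 1),
                 tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P["Death", ], c(NoPTS = 0, MildModPTS = 0, SeverePTS = 0, Death = 1))
    # PTS states never revert to NoPTS
    expect_equal(P["MildModPTS", "NoPTS"], 0)
    expect_equal(P["SeverePTS", "NoPTS"], 0)
  }
  expect_error(build_transitions(th, "two_year", 99, cfg), "cycle")
})

test_that("zero mortality and zero incidence give the identity matrix", {
  cfg <- no_mortality(case_cfg())
  th <- theta_at_means(cfg)
  th[c("q1", "q2", "q3")] <- 0
  P <- build_transitions(th, "two_year", 1, cfg)
  expect_equal(unname(P), diag(4), tolerance = 1e-15)
  tr <- run_cohort(cfg, th, "two_year")
  expect_true(all(tr[, "NoPTS"] == 1))
})

test_that("first-cycle onset equals q1 split by the severity fraction", {
  cfg <- no_mortality(case_cfg())
  th <- theta_at_means(cfg)
  P <- build_transitions(th, "two_year", 1, cfg)
  expect_equal(P["NoPTS", "MildModPTS"] + P["NoPTS", "SeverePTS"], 0.211,
               tolerance = 1e-12)
  expect_equal(P["NoPTS", "SeverePTS"] / 0.211, cfg$model$severe_fraction,
               tolerance = 1e-12)
})

test_that("cohort traces conserve mass and accumulate the 2-year incidence", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg, rr = 1.5)
  for (strategy in c("two_year", "tailored")) {
    tr <- run_cohort(cfg, th, strategy)
    expect_equal(rowSums(tr), rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr[, "Death"]) >= 0))
    expect_true(all(tr >= 0 & tr <= 1))
  }
  # without mortality, PTS occupancy after the cycle covering month 24 is
  # exactly the cumulative two-year incidence
  cfg0 <- no_mortality(cfg)
  tr <- run_cohort(cfg0, theta_at_means(cfg0, rr = 1), "two_year")
  expect_equal(unname(tr[4, "MildModPTS"] + tr[4, "SeverePTS"]), 0.245, tolerance = 1e-12)
  expect_equal(unname(tr[10, "MildModPTS"] + tr[10, "SeverePTS"]), 0.245, tolerance = 1e-12)
})

test_that("a 3-cycle truncation matches hand-computed matrix products", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg, rr = 1)
  # hand-rolled recursion with explicitly written formulas
  a <- cfg$model$mortality$gompertz_a; b <- cfg$model$mortality$gompertz_b
  sev <- cfg$model$severe_fraction
  ages <- c(60, 60.5, 61); lens <- c(0.5, 0.5, 1)
  qs <- c(th[["q1"]], th[["q2"]], th[["q3"]])
  v <- c(1, 0, 0, 0)
  hand <- matrix(NA_real_, 4, 4); hand[1, ] <- v
  for (i in 1:3) {
    d <- 1 - exp(-a * exp(b * ages[i]) * lens[i])
    v <- c(v[1] * (1 - d) * (1 - qs[i]),
           v[2] * (1 - d) + v[1] * (1 - d) * qs[i] * (1 - sev),
           v[3] * (1 - d) + v[1] * (1 - d) * qs[i] * sev,
           v[4] + (v[1] + v[2] + v[3]) * d)
    hand[i + 1, ] <- v
  }
  tr <- run_cohort(cfg, th, "two_year")
  expect_equal(unclass(tr)[1:4, ], hand, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("undiscounted QALYs equal the horizon when utility is 1 and nothing happens", {
  cfg <- no_mortality(case_cfg())
  cfg$model$discount_cost <- 0
  cfg$model$discount_effect <- 0
  cfg$model$horizon_age <- 70          # 10-year horizon
  cfg$model$utility_norm_at_start <- 1
  cfg$model$utility_norm_slope <- 0
  th <- theta_at_means(cfg, rr = 1)
  th[c("q1", "q2", "q3")] <- 0
  th[c("disutility_mild", "disutility_severe", "disutility_ecs")] <- 0
  th[c("cost_stocking", "homecare_fraction", "cost_homecare")] <- 0
  tr <- run_cohort(cfg, th, "two_year")
  ce <- discounted_ce(tr, th, cfg, "two_year")
  expect_equal(ce$effect, 10, tolerance = 1e-12)
  expect_equal(ce$cost, 0)
})

test_that("the vectorised engine agrees with the per-draw trace computation", {
  cfg <- case_cfg()
  d <- sample_priors(cfg$specs, 20, seed = 31)
  ce <- evaluate_strategies(d, cfg)
  for (k in c(1, 7, 20)) for (s in c("two_year", "tailored")) {
    tr <- run_cohort(cfg, d[k, ], s)
    one <- discounted_ce(tr, d[k, ], cfg, s)
    expect_equal(unname(ce$cost[k, s]), one$cost, tolerance = 1e-12)
    expect_equal(unname(ce$effect[k, s]), one$effect, tolerance = 1e-12)
  }
})

test_that("with rr = 1 and equal stocking exposure the strategies coincide", {
  cfg <- case_cfg()
  cfg$model$stop_proportion <- 0       # tailored arm keeps stockings 24 months
  th <- theta_at_means(cfg, rr = 1)
  a <- discounted_ce(run_cohort(cfg, th, "two_year"), th, cfg, "two_year")
  b <- discounted_ce(run_cohort(cfg, th, "tailored"), th, cfg, "tailored")
  expect_equal(a$cost, b$cost, tolerance = 1e-14)
  expect_equal(a$effect, b$effect, tolerance = 1e-14)
})

test_that("raising rr lowers tailored QALYs and raises tailored costs", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg)
  out <- t(vapply(c(1, 1.5, 2, 3, 3.316), function(rr) {
    th["rr"] <- rr
    ce <- discounted_ce(run_cohort(cfg, th, "tailored"), th, cfg, "tailored")
    c(ce$cost, ce$effect)
  }, numeric(2)))
  expect_true(all(diff(out[, 1]) > 0))
  expect_true(all(diff(out[, 2]) < 0))
})

test_that("at prior means the strategies differ only marginally", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg)           # rr at its censored-lognormal mean
  a <- discounted_ce(run_cohort(cfg, th, "two_year"), th, cfg, "two_year")
  b <- discounted_ce(run_cohort(cfg, th, "tailored"), th, cfg, "tailored")
  expect_lt(abs(a$cost - b$cost), 200)
  expect_lt(abs(a$effect - b$effect), 0.02)
})

test_that("negative utilities are clamped with a warning", {
  cfg <- case_cfg()
  th <- theta_at_means(cfg)
  th["disutility_severe"] <- 0.95
  expect_warning(discounted_ce(run_cohort(cfg, th, "two_year"), th, cfg, "two_year"),
                 "clamped")
})
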