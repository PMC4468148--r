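test_that("trial designs split totals across arms", {
  d <- trial_design(788)
  expect_equal(d$n_standard, 394L)
  expect_equal(d$n_tailored, 394L)
  d <- trial_design(501)
  expect_equal(d$n_standard + d$n_tailored, 501L)
  expect_equal(trial_cost(d), 10000 + 5000 * 501)
  expect_error(trial_design(1), "n_total")
})

test_that("simulated trials follow the generating multinomial", {
  d <- trial_design(100)
  # no onset risk: everyone PTS-free
  out <- simulate_trial(d, c(q1 = 0, q2 = 0, q3 = 0, rr = 1), seed = 1)
  expect_equal(unname(out$counts[, "free"]), c(50L, 50L))
  expect_equal(unname(rowSums(out$counts)), c(50L, 50L))

  # rr = 1: both arms share a generating law
  d2 <- trial_design(1e6)
  out2 <- simulate_trial(d2, c(q1 = 0.211, q2 = 0.0139, q3 = 0.0296, rr = 1), seed = 2)
  prop <- 1 - out2$counts[, "free"] / rowSums(out2$counts)
  expect_lt(abs(prop[1] - prop[2]), 0.002)

  # binomial expectation oracle: mean standard-arm 24-month event proportion
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  d3 <- trial_design(500)
  set.seed(33)
  props <- vapply(1:3000, function(i) {
    o <- simulate_trial(d3, c(q, rr = 1.4))
    1 - o$counts["standard", "free"] / 250
  }, numeric(1))
  se <- sqrt(0.245 * 0.755 / (250 * 3000))
  expect_lt(abs(mean(props) - 0.245), 3 * se)

  expect_error(simulate_trial(d, c(q1 = 1.2, q2 = 0, q3 = 0, rr = 1)), "\\[0, 1\\]")
})

test_that("conjugate incidence updates match Bayes' rule arithmetic", {
  priors <- list(q1 = c(2, 3), q2 = c(1, 1), q3 = c(1, 1))
  # 4 patients, 1 onset in interval 1
  post <- update_incidence_posterior(priors, c(1, 0, 0, 3))
  expect_equal(unname(post$q1), c(3, 6))
  # intervals with an empty risk set keep the prior
  expect_equal(unname(post$q2), c(1, 4))   # 3 at risk, 0 events
  post0 <- update_incidence_posterior(priors, c(0, 0, 0, 0))
  expect_equal(unname(post0$q1), c(2, 3))
  expect_equal(unname(post0$q2), c(1, 1))
  expect_equal(unname(post0$q3), c(1, 1))
})

test_that("conjugate posteriors match a brute-force grid posterior", {
  # Riemann-sum posterior over a fine grid for small counts
  grid_posterior <- function(alpha, beta, x, m) {
    p <- seq(1e-6, 1 - 1e-6, length.out = 20001)
    w <- dbeta(p, alpha, beta) * p^x * (1 - p)^(m - x)
    w <- w / sum(w)
    mu <- sum(p * w)
    c(mean = mu, sd = sqrt(sum((p - mu)^2 * w)))
  }
  for (case in list(c(2, 3, 1, 4), c(1, 1, 0, 5), c(5, 2, 3, 3))) {
    post <- c(case[1] + case[3], case[2] + case[4] - case[3])
    g <- grid_posterior(case[1], case[2], case[3], case[4])
    expect_equal(unname(post[1] / sum(post)), unname(g["mean"]), tolerance = 1e-3)
    a <- post[1]; b <- post[2]
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), unname(g["sd"]),
                 tolerance = 1e-3)
  }
})

test_that("posterior means interpolate prior mean and sample proportion", {
  priors <- list(q1 = c(3, 7), q2 = c(1, 1), q3 = c(1, 1))
  for (m in 1:6) for (x in 0:m) {
    post <- update_incidence_posterior(priors, c(x, 0, 0, m - x))
    pm <- post$q1[1] / sum(post$q1)
    lo <- min(0.3, x / m); hi <- max(0.3, x / m)
    expect_gte(pm, lo - 1e-12)
    expect_lte(pm, hi + 1e-12)
  }
})

test_that("the precision-weighted normal update has the right limits", {
  # uninformative data: posterior equals prior
  u <- precision_weighted_update(0, 0.612, estimate = 3, se = 1e9)
  expect_equal(u$mu, 0, tolerance = 1e-12)
  expect_equal(u$sigma, 0.612, tolerance = 1e-12)
  # equal precision, estimate at the prior mean: sd shrinks by sqrt(2)
  e <- precision_weighted_update(0, 0.612, estimate = 0, se = 0.612)
  expect_equal(e$mu, 0)
  expect_equal(e$sigma, 0.612 / sqrt(2), tolerance = 1e-12)
})

test_that("rr updates contract the posterior and skip degenerate trials", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  d <- trial_design(1000)
  out <- simulate_trial(d, c(q, rr = 2), seed = 7)
  post <- update_rr_posterior(c(0, 0.612), out)
  expect_true(post$updated)
  expect_lt(post$sigma, 0.612)

  # a trial with no onsets cannot update the rr parameter
  out0 <- simulate_trial(d, c(q1 = 0, q2 = 0, q3 = 0, rr = 1), seed = 8)
  post0 <- update_rr_posterior(c(0, 0.612), out0)
  expect_false(post0$updated)
  expect_equal(post0$sigma, 0.612)
})

test_that("expected posterior uncertainty decreases with sample size", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  cfg <- case_cfg()
  prior_betas <- lapply(cfg$specs[c("q1", "q2", "q3")], function(s) {
    ab <- beta_from_moments(s$mean, s$se); c(ab$alpha, ab$beta)
  })
  beta_var <- function(ab) ab[1] * ab[2] / ((ab[1] + ab[2])^2 * (ab[1] + ab[2] + 1))
  mean_post_sd <- function(n, reps = 40) {
    set.seed(100 + n)
    d <- trial_design(n)
    sds <- replicate(reps, {
      o <- simulate_trial(d, c(q, rr = 1.4))
      pi <- update_incidence_posterior(prior_betas, o)
      pr <- update_rr_posterior(c(0, 0.612), o)
      c(sqrt(beta_var(pi$q1)), pr$sigma)
    })
    rowMeans(sds)
  }
  s200 <- mean_post_sd(200); s1000 <- mean_post_sd(1000); s5000 <- mean_post_sd(5000)
  prior_sd_q1 <- sqrt(beta_var(prior_betas$q1))
  expect_true(all(s200 <= c(prior_sd_q1, 0.612) + 1e-12))
  expect_true(all(s1000 < s200))
  expect_true(all(s5000 < s1000))
})

test_that("the true relative risk is recovered from large trials", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  d <- trial_design(5000)
  set.seed(77)
  medians <- replicate(200, {
    o <- simulate_trial(d, c(q, rr = 2))
    p <- update_rr_posterior(c(0, 0.612), o)
    max(exp(p$mu), 1)   # posterior median of the censored rr
  })
  expect_lt(abs(mean(medians) - 2) / 2, 0.10)
})

test_that("posterior draws respect censoring and feed the engine", {
  cfg <- case_cfg()
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  prior_betas <- lapply(cfg$specs[c("q1", "q2", "q3")], function(s) {
    ab <- beta_from_moments(s$mean, s$se); c(ab$alpha, ab$beta)
  })
  o <- simulate_trial(trial_design(800), c(q, rr = 1.8), seed = 5)
  pi <- update_incidence_posterior(prior_betas, o)
  pr <- update_rr_posterior(c(0, 0.612), o)
  set.seed(9)
  dr <- sample_posterior_draws(cfg, pi, pr, 500)
  expect_true(all(dr[, "rr"] >= 1))
  expect_equal(colnames(dr), names(cfg$specs))
  ce <- evaluate_strategies(dr, cfg)
  expect_true(all(is.finite(ce$cost)) && all(is.finite(ce$effect)))
})

test_that("trial batches export to CSV", {
  q <- interval_probs_from_cumulative(0.211, 0.222, 0.245)
  d <- trial_design(100)
  set.seed(2)
  outs <- lapply(1:3, function(i) simulate_trial(d, c(q, rr = 1)))
  f <- tempfile(fileext = ".csv")
  export_trials(outs, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$n_standard, rep(50, 3))
})
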