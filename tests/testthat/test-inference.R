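test_that("an identity proposal is always accepted", {
  set.seed(1)
  lp <- function(x) -0.5 * x^2
  stp <- rw_mh_step(0.7, lp(0.7), lp, sd = 0)
  expect_true(stp$accepted)
  expect_equal(stp$value, 0.7)
})

test_that("the MH kernel reproduces a logistic toy posterior vs quadrature", {
  set.seed(20)
  x <- rnorm(20)
  y <- rbinom(20, 1, plogis(0.8 * x))
  loglik <- function(b) sum(y * plogis(b * x, log.p = TRUE) +
                              (1 - y) * plogis(-b * x, log.p = TRUE))
  logpost <- function(b) loglik(b)  # flat prior
  # quadrature oracle for the posterior mean
  grid <- seq(-10, 10, length.out = 4001)
  w <- exp(vapply(grid, logpost, numeric(1)))
  mean_quad <- sum(grid * w) / sum(w)
  set.seed(21)
  run <- mh_sample(logpost, init = 0, n_iter = 5e4, sd = 1.2)
  expect_lt(abs(mean(run$draws) - mean_quad) / abs(mean_quad), 0.02)

  # detailed-balance smoke test: ten quantiles of the draws agree with the
  # quadrature CDF to about a percent
  cdf <- cumsum(w) / sum(w)
  emp_q <- quantile(run$draws, probs = seq(0.05, 0.95, by = 0.1), names = FALSE)
  cdf_at <- approx(grid, cdf, xout = emp_q)$y
  expect_true(all(abs(cdf_at - seq(0.05, 0.95, by = 0.1)) < 0.015))
})

test_that("the variance Gibbs step matches the closed-form inverse gamma", {
  # prior draw (n = 0): mean of IG(3, 2) is b/(a-1) = 1
  set.seed(30)
  prior_draws <- replicate(1e5, draw_sigma2(0, 0, shape = 3, rate = 2))
  expect_lt(abs(mean(prior_draws) - 1), 0.03)
  # zero residuals shift only the shape: IG(a0 + n/2, b0)
  set.seed(31)
  a <- draw_sigma2(0, 10, shape = 3, rate = 2)
  set.seed(31)
  b <- 1 / rgamma(1, shape = 3 + 5, rate = 2)
  expect_identical(a, b)
  # concentration: sigma_true = 0.5, n = 1e4
  set.seed(32)
  r <- rnorm(1e4, 0, 0.5)
  draws <- replicate(2000, sqrt(draw_sigma2(sum(r^2), length(r))))
  expect_gt(mean(draws), 0.49)
  expect_lt(mean(draws), 0.51)
  # the 90% interval of the conjugate posterior matches closed-form quantiles
  q_emp <- quantile(draws^2, c(0.05, 0.95), names = FALSE)
  q_cf <- 1 / qgamma(c(0.95, 0.05), shape = 0.001 + 5000,
                     rate = 0.001 + sum(r^2) / 2)
  expect_equal(q_emp, q_cf, tolerance = 0.01)
})

test_that("chains are bit-reproducible under a fixed seed", {
  sim <- small_sim(n_trees = 120, seed = 4)
  cfg <- mcmc_config(n_chains = 1, n_iter_phase1 = 100, n_iter_phase2 = 150,
                     burn_in = 50, thinning = 5)
  f1 <- tv_fit(sim$census, sim$traits, config = cfg, seed = 99)
  f2 <- tv_fit(sim$census, sim$traits, config = cfg, seed = 99)
  expect_identical(f1$draws, f2$draws)
  # two chains with the same per-chain seeds give identical summaries
  cfg2 <- mcmc_config(n_chains = 2, n_iter_phase1 = 100, n_iter_phase2 = 150,
                      burn_in = 50, thinning = 5)
  g1 <- tv_fit(sim$census, sim$traits, config = cfg2, seed = 7)
  g2 <- tv_fit(sim$census, sim$traits, config = cfg2, seed = 7)
  expect_identical(summary(g1)$median, summary(g2)$median)
})

test_that("selection with zero candidates collapses to the plain sampler", {
  sim <- small_sim(n_trees = 120, seed = 4)
  cfg <- mcmc_config(n_chains = 1, n_iter_phase1 = 100, n_iter_phase2 = 150,
                     burn_in = 50, thinning = 5)
  plain <- tv_fit(sim$census, sim$traits, config = cfg, seed = 13)
  sel0 <- tv_fit(sim$census, sim$traits, config = cfg, seed = 13,
                 select = TRUE, candidates = character())
  expect_identical(plain$draws, sel0$draws)
})

test_that("phase-2 acceptance rates settle near the target band", {
  sim <- small_sim(n_trees = 400, seed = 6)
  cfg <- mcmc_config(n_chains = 1, n_iter_phase1 = 600, n_iter_phase2 = 400,
                     burn_in = 100, thinning = 5)
  fit <- tv_fit(sim$census, sim$traits, config = cfg, seed = 3)
  rates <- fit$acceptance[[1]]
  rates <- rates[!is.na(rates)]
  # the stochastic-approximation tuning aims at the middle of [0.2, 0.5];
  # allow slack around the band edges on a small community
  expect_true(all(rates > 0.1 & rates < 0.65))
})

test_that("a YAML configuration round-trips into mcmc_config", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("n_chains: 2", "n_iter_phase1: 50", "n_iter_phase2: 80",
               "burn_in: 20", "thinning: 4",
               "proposal_sd:", "  theta5: 0.02",
               "prior:", "  coef_sd: 5"), path)
  cfg <- read_mcmc_config(path)
  expect_equal(cfg$n_chains, 2)
  expect_equal(cfg$proposal_sd[["theta5"]], 0.02)
  expect_equal(cfg$prior$coef_sd, 5)
  expect_equal(cfg$thinning, 4)
})
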