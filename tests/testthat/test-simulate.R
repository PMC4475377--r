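test_that("species traits sample uniformly within their ranges", {
  # degenerate ranges collapse every species onto one trait vector
  r <- trait_ranges()
  r_pt <- lapply(r, function(z) c(mean(z), mean(z)))
  cfg <- sim_config(n_trees = 10, n_species = 5, ranges = r_pt, seed = 1)
  tt <- sample_species_traits(cfg)
  expect_true(all(vapply(tt[c("dbh95", "hmax", "wd", "tough", "d13c")],
                         function(col) all(col == col[1]), logical(1))))
  # default ranges respected, moments near the uniform law
  cfg2 <- sim_config(n_trees = 10, n_species = 1e4, seed = 2)
  tt2 <- sample_species_traits(cfg2)
  expect_true(all(tt2$wd >= 0.28 & tt2$wd <= 0.91))
  for (f in c("dbh95", "hmax", "wd", "tough", "d13c")) {
    rng <- r[[f]]
    expect_true(all(tt2[[f]] >= rng[1] & tt2[[f]] <= rng[2]))
    se <- diff(rng) / sqrt(12) / sqrt(1e4)
    expect_lt(abs(mean(tt2[[f]]) - mean(rng)), 5 * se)
  }
})

test_that("the immortal limit produces a full census with zero deaths", {
  # constant, strongly negative linear predictor via the injectable basis
  b <- ontogeny_basis(f1 = function(x) rep(-30, length(x)),
                      f2 = function(x) 0 * x)
  p <- default_params()
  p_immortal <- joint_params(theta = p$theta,
                             beta = c(0, 1, 0, 0, 0, 0, 0))
  cfg <- sim_config(n_trees = 500, n_species = 20, params = p_immortal,
                    basis = b, seed = 3)
  sim <- simulate_census(cfg)
  expect_true(all(is.na(sim$truth$death_interval)))
  expect_equal(nrow(sim$census), 500 * 3)
})

test_that("first-interval deaths follow the binomial oracle when eta = 0", {
  p0 <- joint_params(theta = default_params()$theta, beta = rep(0, 7))
  cfg <- sim_config(n_trees = 10000, n_species = 50, params = p0, seed = 4)
  sim <- simulate_census(cfg)
  deaths1 <- sum(sim$truth$death_interval == 1, na.rm = TRUE)
  expect_lt(abs(deaths1 - 5000), 4 * sqrt(10000 * 0.25))
})

test_that("noiseless growth reproduces the model prediction exactly", {
  p <- default_params()
  p$theta[["sigma"]] <- 0
  cfg <- sim_config(n_trees = 300, n_species = 10, params = p, seed = 5)
  sim <- simulate_census(cfg)
  obs <- compute_growth_observations(sim$census)
  expect_equal(attr(obs, "n_clamped"), 0L)
  tr_idx <- match(obs$species_id, sim$traits$species_id)
  pred <- predict_log_growth(obs$dbh_prev, sim$traits[tr_idx, ], p)
  expect_equal(obs$log_agr1, pred, tolerance = 1e-10)
  expect_true(all(abs(compute_vigor(obs$log_agr1, pred)) < 1e-10))
})

test_that("empirical residual spread recovers the generating sigma", {
  sim <- small_sim(n_trees = 5000, seed = 6)
  obs <- compute_growth_observations(sim$census)
  keep <- !obs$clamped
  tr_idx <- match(obs$species_id[keep], sim$traits$species_id)
  pred <- predict_log_growth(obs$dbh_prev[keep], sim$traits[tr_idx, ],
                             default_params())
  res <- obs$log_agr1[keep] - pred
  # sd of a sample sd is about sigma/sqrt(2n)
  expect_lt(abs(sd(res) - 0.5), 4 * 0.5 / sqrt(2 * length(res)))
})

test_that("trees dying in an interval had lower vigor than survivors", {
  sim <- small_sim(n_trees = 8000, seed = 7)
  died2 <- which(sim$truth$death_interval == 2)
  surv2 <- which(is.na(sim$truth$death_interval))
  # lagged vigor entering interval 2 is the first-interval growth error
  expect_lt(mean(sim$truth$eps[died2, 1]), mean(sim$truth$eps[surv2, 1]))
})

test_that("simulate-write-read round trip prefers the generating parameters", {
  better <- 0L
  n_rep <- 5L
  for (seed in seq_len(n_rep)) {
    sim <- small_sim(n_trees = 400, seed = 100 + seed)
    dir <- withr::local_tempdir()
    write_sim(sim, dir)
    cen <- read_census(file.path(dir, "census.csv"), interval_years = 10)
    tra <- read_traits(file.path(dir, "traits.csv"))
    md <- joint_model_data(cen, tra)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    p_true <- joint_params(theta = unlist(truth$theta),
                           beta = unlist(truth$beta))
    ll_true <- total_loglik(md, p_true)$total
    expect_true(is.finite(ll_true))
    p_pert <- p_true
    p_pert$theta[["theta1"]] <- p_pert$theta[["theta1"]] * 1.3
    p_pert$beta[["beta0"]] <- p_pert$beta[["beta0"]] - 0.5
    better <- better + (ll_true > total_loglik(md, p_pert)$total)
  }
  expect_gt(better, n_rep / 2)
})

test_that("alternative vigor modes run and keep the marginal error scale", {
  for (mode in c("per-tree", "ar1")) {
    sim <- simulate_census(sim_config(n_trees = 2000, n_species = 20,
                                      vigor_mode = mode, seed = 8))
    e1 <- sim$truth$eps[, 1]
    expect_lt(abs(sd(e1, na.rm = TRUE) - 0.5), 0.05)
    if (mode == "per-tree") {
      both <- stats::complete.cases(sim$truth$eps)
      expect_equal(sim$truth$eps[both, 1], sim$truth$eps[both, 2])
    }
  }
})
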