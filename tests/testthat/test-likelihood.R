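test_that("survivor and death branches match a from-scratch naive loop", {
  p <- default_params()
  tt <- ref_trait_table()
  # survivor over two intervals
  cen_s <- one_tree_census(c(15.0, 16.2, 17.0))
  traj <- trajectories(cen_s, tt)[[1]]
  expect_equal(tree_loglik(traj, p), naive_loglik(cen_s, tt, p),
               tolerance = 1e-12)
  # death in the second interval: growth factor for interval 1 only
  cen_d <- one_tree_census(c(15.0, 16.2), die = TRUE)
  traj_d <- trajectories(cen_d, tt)[[1]]
  expect_equal(tree_loglik(traj_d, p), naive_loglik(cen_d, tt, p),
               tolerance = 1e-12)
  # death in the first interval: a single death factor, no growth term
  cen_d1 <- one_tree_census(15.0, die = TRUE)
  traj_d1 <- trajectories(cen_d1, tt)[[1]]
  eta <- mortality_linear_predictor(0, 15, ref_traits(), p)
  expect_equal(tree_loglik(traj_d1, p), log(mortality_probability(eta)),
               tolerance = 1e-12)
})

test_that("a clamped interval contributes the mortality factor only", {
  p <- default_params()
  tt <- ref_trait_table()
  cen <- one_tree_census(c(15.0, 14.8, 15.5))
  traj <- trajectories(cen, tt)[[1]]
  expect_equal(tree_loglik(traj, p), naive_loglik(cen, tt, p),
               tolerance = 1e-12)
  # manual check: survival factors for both intervals, growth for the second
  tr <- ref_traits()
  eta1 <- mortality_linear_predictor(0, 15.0, tr, p)
  eta2 <- mortality_linear_predictor(0, 14.8, tr, p)  # vigor fell back to 0
  y2 <- log1p(10 * (15.5 - 14.8) / 10)
  manual <- log1p(-mortality_probability(eta1)) +
    log1p(-mortality_probability(eta2)) +
    growth_logdensity(y2, 14.8, tr, p)
  expect_equal(tree_loglik(traj, p), manual, tolerance = 1e-12)
})

test_that("an impossible outcome returns -Inf, never an error", {
  p <- default_params()
  tt <- ref_trait_table()
  cen_d <- one_tree_census(15.0, die = TRUE)
  traj <- trajectories(cen_d, tt)[[1]]
  # basis forcing eta = -Inf -> p = 0 while a death is observed
  b <- ontogeny_basis(f1 = function(x) rep(-Inf, length(x)),
                      f2 = function(x) 0 * x)
  pb <- joint_params(theta = p$theta, beta = c(0, 1, 0, 0, 0, 0, 0))
  expect_equal(tree_loglik(traj, pb, basis = b), -Inf)
})

test_that("the total likelihood is additive and exchangeable", {
  p <- default_params()
  sim <- small_sim(n_trees = 30, seed = 5)
  trs <- trajectories(sim$census, sim$traits)
  one <- vapply(trs, tree_loglik, numeric(1), params = p)
  expect_equal(total_loglik(trs, p)$total, sum(one), tolerance = 1e-12)
  expect_equal(total_loglik(rev(trs), p)$total, sum(one), tolerance = 1e-12)
  # duplicating a tree doubles its contribution
  expect_equal(total_loglik(c(trs[1], trs[1]), p)$total, unname(2 * one[1]),
               tolerance = 1e-12)
})

test_that("the vectorised engine matches the naive loop on a 50-tree fixture", {
  p <- default_params()
  sim <- small_sim(n_trees = 50, seed = 11)
  md <- joint_model_data(sim$census, sim$traits)
  fast <- total_loglik(md, p)
  slow <- naive_loglik(sim$census, sim$traits, p)
  expect_equal(fast$total, slow, tolerance = 1e-10)
  # and the per-trajectory path agrees too
  trs <- trajectories(sim$census, sim$traits)
  expect_equal(total_loglik(trs, p)$total, slow, tolerance = 1e-10)
})

test_that("component scoping: beta moves never touch the growth component", {
  sim <- small_sim(n_trees = 60, seed = 2)
  md <- joint_model_data(sim$census, sim$traits)
  p <- default_params()
  base <- total_loglik(md, p)
  for (j in paste0("beta", c(0, 1, 2, 3, 5, 6))) {
    p2 <- p
    p2$beta[[j]] <- p2$beta[[j]] + 0.37
    pert <- total_loglik(md, p2)
    expect_identical(pert$growth, base$growth)     # bit-identical
    expect_false(pert$mortality == base$mortality)
  }
  # any theta move changes both components (vigor propagates)
  for (j in paste0("theta", 1:6)) {
    p2 <- p
    p2$theta[[j]] <- p2$theta[[j]] * 1.1
    pert <- total_loglik(md, p2)
    expect_false(pert$growth == base$growth)
    expect_false(pert$mortality == base$mortality)
  }
})

test_that("deselected predictors contribute exactly zero", {
  sim <- small_sim(n_trees = 40, seed = 9)
  md <- joint_model_data(sim$census, sim$traits)
  p <- default_params()
  # zero coefficient vs deselected indicator give identical likelihoods
  p_zero <- p; p_zero$theta[["theta2"]] <- 0
  p_off <- p; p_off$gamma[["WD_growth"]] <- 0L
  expect_identical(total_loglik(md, p_off)$total,
                   total_loglik(md, p_zero)$total)
})
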