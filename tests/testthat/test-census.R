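test_that("a minimal two-record census reads and yields one growth interval", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tree_id,species_id,time_index,time_years,dbh_cm,status",
               "t1,s1,0,0,15.0,alive",
               "t1,s1,1,10,16.2,alive"), path)
  cen <- read_census(path, interval_years = 10)
  expect_s3_class(cen, "tv_census")
  expect_equal(nrow(cen), 2L)
  obs <- compute_growth_observations(cen)
  expect_equal(nrow(obs), 1L)
  # 1.2 cm over 10 yr = 1.2 mm/yr annualised
  expect_equal(obs$agr, 1.2)
  expect_equal(obs$log_agr1, log(2.2))
  expect_equal(attr(obs, "n_clamped"), 0L)
})

test_that("invalid census tables fail with messages naming the tree", {
  base <- data.frame(tree_id = "t9", species_id = "s1", time_index = 0:1,
                     time_years = c(0, 10), dbh_cm = c(15, NA),
                     status = c("alive", "dead"), stringsAsFactors = FALSE)
  # dbh on a dead record
  bad <- base; bad$dbh_cm[2] <- 14
  expect_error(as_census(bad), "dead record.*t9")
  # dbh missing on an alive record
  bad <- base; bad$dbh_cm[1] <- NA
  expect_error(as_census(bad), "alive record.*t9")
  # duplicate (tree, time)
  bad <- base; bad$time_index[2] <- 0; bad$status[2] <- "alive"; bad$dbh_cm[2] <- 15
  expect_error(as_census(bad), "duplicate.*t9")
  # non-increasing time
  bad <- base; bad$time_index <- c(1, 0)
  expect_error(as_census(bad), "t9")
  # record after death
  bad <- rbind(base, data.frame(tree_id = "t9", species_id = "s1",
                                time_index = 2, time_years = 20,
                                dbh_cm = 15, status = "alive"))
  expect_error(as_census(bad), "after death.*t9")
  # missing column
  expect_error(as_census(base[, -5]), "missing columns")
})

test_that("a simulated community round-trips through write/read identically", {
  sim <- small_sim(n_trees = 100, seed = 3)
  dir <- withr::local_tempdir()
  write_census(sim$census, file.path(dir, "census.csv"))
  write_traits(sim$traits, file.path(dir, "traits.csv"))
  cen2 <- read_census(file.path(dir, "census.csv"), interval_years = 10)
  tra2 <- read_traits(file.path(dir, "traits.csv"))
  expect_equal(as.data.frame(cen2), as.data.frame(sim$census),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tra2, sim$traits, tolerance = 1e-12, ignore_attr = TRUE)
  # and the likelihood is identical on both copies
  p <- default_params()
  ll1 <- total_loglik(joint_model_data(sim$census, sim$traits), p)
  ll2 <- total_loglik(joint_model_data(cen2, tra2), p)
  expect_equal(ll1$total, ll2$total, tolerance = 1e-10)
})

test_that("negative increments are clamped to zero and counted", {
  cen <- one_tree_census(c(15.0, 14.8, 14.8))
  obs <- compute_growth_observations(cen)
  expect_equal(obs$agr, c(0, 0))
  expect_equal(obs$log_agr1, c(0, 0))
  expect_identical(obs$clamped, c(TRUE, FALSE))
  expect_equal(attr(obs, "n_clamped"), 1L)
})

test_that("growth observations match a brute-force recount of alive pairs", {
  for (seed in 1:3) {
    sim <- small_sim(n_trees = 150, seed = seed)
    df <- as.data.frame(sim$census)
    n_pairs <- 0L
    for (id in unique(df$tree_id)) {
      sub <- df[df$tree_id == id, ]
      sub <- sub[order(sub$time_index), ]
      if (nrow(sub) < 2) next
      n_pairs <- n_pairs +
        sum(sub$status[-nrow(sub)] == "alive" & sub$status[-1] == "alive")
    }
    expect_equal(nrow(compute_growth_observations(sim$census)), n_pairs)
  }
})

test_that("trait reader validates units and ranges it owns", {
  tt <- ref_trait_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_traits(tt, path)
  back <- read_traits(path)
  expect_equal(back$dbh95, tt$dbh95)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species_id = "s1", dbh95_m = 0.5, hmax_dm = 3,
                              ortho = 2, wd = 0.6, tough = 5, d13c = -3),
                   path2, row.names = FALSE)
  expect_error(read_traits(path2), "ortho")
  utils::write.csv(data.frame(species_id = "s1", dbh95_m = 0.5, hmax_dm = 3,
                              ortho = 1, wd = -0.6, tough = 5, d13c = -3),
                   path2, row.names = FALSE)
  expect_error(read_traits(path2), "wd")
})
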