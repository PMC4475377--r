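# shared fixtures: everything generated in code, no files on disk

# reference single-species trait vector used in hand-computed examples
ref_traits <- function() {
  list(dbh95 = 0.5, hmax = 3.0, ortho = 0, wd = 0.6, tough = 5.0, d13c = -3.0)
}

# a small simulated community
small_sim <- function(n_trees = 200, seed = 1, ...) {
  simulate_census(sim_config(n_trees = n_trees, n_species = 20, seed = seed,
                             ...))
}

# census data frame for a single tree observed alive at the given diameters,
# optionally dying one census after the last diameter
one_tree_census <- function(dbh, die = FALSE, id = "t1", sp = "s1",
                            interval_years = 10) {
  k <- length(dbh)
  n <- k + die
  df <- data.frame(
    tree_id = id, species_id = sp,
    time_index = 0:(n - 1),
    time_years = (0:(n - 1)) * interval_years,
    dbh_cm = c(dbh, if (die) NA_real_),
    status = c(rep("alive", k), if (die) "dead"),
    stringsAsFactors = FALSE
  )
  as_census(df, interval_years = interval_years)
}

# single-species trait table matching ref_traits()
ref_trait_table <- function(sp = "s1") {
  tr <- ref_traits()
  data.frame(species_id = sp, dbh95 = tr$dbh95, hmax = tr$hmax,
             ortho = tr$ortho, wd = tr$wd, tough = tr$tough, d13c = tr$d13c,
             stringsAsFactors = FALSE)
}

# independent naive evaluation of the joint likelihood, written directly
# from the model formulas (loops + dnorm/plogis); deliberately shares no
# code with the package internals
naive_loglik <- function(census, traits, params, interval_years = 10) {
  df <- as.data.frame(census)
  total <- 0
  for (id in unique(df$tree_id)) {
    sub <- df[df$tree_id == id, ]
    sub <- sub[order(sub$time_index), ]
    tr <- traits[traits$species_id == sub$species_id[1], ]
    th <- params$theta; be <- params$beta; g <- params$gamma
    mu_of <- function(d) {
      gm <- th[["theta1"]] * g[["DBH95_growth"]] * tr$dbh95 +
        th[["theta2"]] * g[["WD_growth"]] * tr$wd +
        th[["theta3"]] * g[["Hmax_growth"]] * tr$hmax +
        th[["theta4"]] * g[["d13C_growth"]] * tr$d13c
      gm * exp(-0.5 * (log(d / (th[["theta5"]] * tr$dbh95 * 100)) /
                         (th[["theta6"]] * tr$wd))^2)
    }
    p_of <- function(v, d) {
      x <- d / (tr$dbh95 * 100)
      eta <- be[["beta0"]] * v + be[["beta1"]] * x + be[["beta2"]] / x +
        be[["beta3"]] * g[["Hmax_mort"]] * tr$hmax +
        be[["beta4"]] * g[["Ortho_mort"]] * tr$ortho +
        be[["beta5"]] * g[["WD_mort"]] * tr$wd +
        be[["beta6"]] * g[["Tough_mort"]] * tr$tough
      1 / (1 + exp(-eta))
    }
    v <- 0
    for (r in 2:nrow(sub)) {
      d_prev <- sub$dbh_cm[r - 1]
      p <- p_of(v, d_prev)
      if (sub$status[r] == "dead") {
        total <- total + log(p)
        break
      }
      total <- total + log(1 - p)
      agr <- 10 * (sub$dbh_cm[r] - d_prev) / interval_years
      if (agr >= 0) {
        y <- log(agr + 1)
        mu <- mu_of(d_prev)
        total <- total + dnorm(y, mu, th[["sigma"]], log = TRUE)
        v <- y - mu
      } else {
        v <- 0
      }
    }
  }
  total
}
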