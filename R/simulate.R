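#' Configuration of the forward census simulator
#'
#' Describes a Paracou-like community: 17,151 trees followed over three
#' censuses 10 years apart (the reference inventory design), species traits
#' drawn uniformly from the reference ranges ([trait_ranges()], Ortho
#' Bernoulli(0.5)), and demography generated from the joint model at a known
#' parameter vector (default: the community posterior medians of
#' [default_params()], Ortho effect zero, residual sd 0.5 on the modelled
#' scale). Initial diameters are lognormal with median 15 cm, truncated to
#' the inventory floor of 10 cm below and to the species maximum diameter
#' above.
#'
#' The individual growth error can be drawn independently at each interval
#' (`vigor_mode = "iid"`, the inference model's assumption), once per tree
#' (`"per-tree"`), or as a stationary AR(1) process across intervals
#' (`"ar1"` with coefficient `ar_rho`). The non-iid modes exist for
#' simulation experiments only; the inference model always assumes iid
#' errors.
#'
#' @param n_trees number of trees.
#' @param n_censuses number of censuses (>= 2).
#' @param interval_years census spacing, years.
#' @param n_species number of species.
#' @param ranges trait ranges, as [trait_ranges()].
#' @param ortho_prob probability a species is orthotropic.
#' @param params generating `tv_params`.
#' @param init_dbh list with `meanlog`, `sdlog` (log-cm) and `min_cm`.
#' @param vigor_mode growth-error structure (see Details).
#' @param ar_rho AR(1) coefficient for `vigor_mode = "ar1"`.
#' @param basis mortality [ontogeny_basis()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `tv_sim_config`.
#' @export
sim_config <- function(n_trees = 17151,
                       n_censuses = 3,
                       interval_years = 10,
                       n_species = 335,
                       ranges = trait_ranges(),
                       ortho_prob = 0.5,
                       params = default_params(),
                       init_dbh = list(meanlog = log(15), sdlog = 0.6,
                                       min_cm = 10),
                       vigor_mode = c("iid", "per-tree", "ar1"),
                       ar_rho = 0.6,
                       basis = ontogeny_basis(),
                       seed = NULL) {
  vigor_mode <- match.arg(vigor_mode)
  if (n_censuses < 2) stop("n_censuses must be at least 2")
  if (interval_years <= 0) stop("interval_years must be positive")
  stopifnot(all(vapply(ranges, length, 1L) == 2L))
  if (ranges$wd[1] <= 0 || ranges$dbh95[1] <= 0) {
    stop("wd and dbh95 ranges must be positive")
  }
  structure(list(
    n_trees = n_trees, n_censuses = n_censuses,
    interval_years = interval_years, n_species = n_species,
    ranges = ranges, ortho_prob = ortho_prob, params = params,
    init_dbh = init_dbh, vigor_mode = vigor_mode, ar_rho = ar_rho,
    basis = basis, seed = seed
  ), class = "tv_sim_config")
}

#' Sample a species trait table
#'
#' Each numeric trait uniform in its configured range; stem orientation
#' Bernoulli. Reproducible under the config seed.
#'
#' @param config a [sim_config()].
#' @return species trait data frame (columns `species_id`, `dbh95`, `hmax`,
#'   `ortho`, `wd`, `tough`, `d13c`).
#' @export
sample_species_traits <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  r <- config$ranges
  data.frame(
    species_id = sprintf("s%04d", seq_len(n)),
    dbh95 = stats::runif(n, r$dbh95[1], r$dbh95[2]),
    hmax = stats::runif(n, r$hmax[1], r$hmax[2]),
    ortho = stats::rbinom(n, 1, config$ortho_prob),
    wd = stats::runif(n, r$wd[1], r$wd[2]),
    tough = stats::runif(n, r$tough[1], r$tough[2]),
    d13c = stats::runif(n, r$d13c[1], r$d13c[2]),
    stringsAsFactors = FALSE
  )
}

# truncated-lognormal initial diameters in [min_cm, dbh95_cm] by rejection
.draw_init_dbh <- function(n, dbh95_cm, init) {
  out <- numeric(n)
  todo <- seq_len(n)
  upper <- pmax(dbh95_cm, init$min_cm + 1)  # degenerate species still usable
  for (rep_i in 1:1000) {
    d <- stats::rlnorm(length(todo), init$meanlog, init$sdlog)
    ok <- d >= init$min_cm & d <= upper[todo]
    out[todo[ok]] <- d[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  # pathological ranges: fall back to uniform in the window
  out[todo] <- stats::runif(length(todo), init$min_cm, upper[todo])
  out
}

#' Forward-simulate a census table from known parameters
#'
#' Generates a community census under the joint model: at each interval an
#' at-risk tree first faces death with the logistic interval probability
#' (using its lagged vigor; zero in its first interval, the same rule the
#' inference uses), and a survivor then grows by
#' `log(AGR+1) = mu(D) + eps` with `eps` drawn according to the configured
#' vigor mode, its diameter advancing by the annualised increment. Dead
#' trees produce a final `dead` record (no diameter) and nothing after.
#'
#' @param config a [sim_config()].
#' @return an object of class `tv_sim`: list with `census` (a `tv_census`),
#'   `traits` (species trait table) and `truth` (generating parameters,
#'   species assignment, per-interval growth errors, death intervals).
#' @export
simulate_census <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pars <- config$params
  n <- config$n_trees
  nc <- config$n_censuses
  dt <- config$interval_years

  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # the seed was consumed above; don't reset mid-run
  traits <- sample_species_traits(cfg_noseed)
  sp <- sample.int(config$n_species, n, replace = TRUE)
  tr <- traits[sp, , drop = FALSE]
  dbh95_cm <- m_to_cm(tr$dbh95)

  D <- matrix(NA_real_, n, nc)
  D[, 1] <- .draw_init_dbh(n, dbh95_cm, config$init_dbh)
  eps <- matrix(NA_real_, n, nc - 1)
  death_interval <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  vig_lag <- numeric(n)
  eps_tree <- if (config$vigor_mode == "per-tree") {
    stats::rnorm(n, 0, pars$theta[["sigma"]])
  }

  for (t in seq_len(nc - 1)) {
    idx <- which(alive)
    if (!length(idx)) break
    eta <- mortality_linear_predictor(vig_lag[idx], D[idx, t],
                                      tr[idx, , drop = FALSE], pars,
                                      config$basis)
    dies <- stats::rbinom(length(idx), 1, mortality_probability(eta)) == 1
    death_interval[idx[dies]] <- t
    alive[idx[dies]] <- FALSE
    s <- idx[!dies]
    if (!length(s)) next
    sigma <- pars$theta[["sigma"]]
    e <- switch(config$vigor_mode,
      "iid" = stats::rnorm(length(s), 0, sigma),
      "per-tree" = eps_tree[s],
      "ar1" = {
        if (t == 1) stats::rnorm(length(s), 0, sigma)
        else config$ar_rho * eps[s, t - 1] +
          stats::rnorm(length(s), 0, sigma * sqrt(1 - config$ar_rho^2))
      })
    mu <- predict_log_growth(D[s, t], tr[s, , drop = FALSE], pars)
    y <- mu + e
    eps[s, t] <- e
    agr <- expm1(y)                       # mm/yr, may be slightly negative
    D[s, t + 1] <- D[s, t] + mm_to_cm(agr) * dt
    vig_lag[s] <- e                       # lagged vigor for the next interval
  }

  # assemble the long census table
  last_alive <- ifelse(is.na(death_interval), nc - 1L, death_interval - 1L)
  n_rows <- last_alive + 1L + !is.na(death_interval)
  tree_ids <- sprintf("t%06d", seq_len(n))
  rows_tree <- rep.int(seq_len(n), n_rows)
  t_idx <- unlist(lapply(seq_len(n), function(i) 0:(n_rows[i] - 1L)),
                  use.names = FALSE)
  is_dead_row <- !is.na(death_interval[rows_tree]) &
    t_idx == death_interval[rows_tree]
  dbh <- D[cbind(rows_tree, t_idx + 1L)]
  dbh[is_dead_row] <- NA_real_
  census <- data.frame(
    tree_id = tree_ids[rows_tree],
    species_id = traits$species_id[sp[rows_tree]],
    time_index = t_idx,
    time_years = t_idx * dt,
    dbh_cm = dbh,
    status = ifelse(is_dead_row, "dead", "alive"),
    stringsAsFactors = FALSE
  )
  census <- as_census(census, interval_years = dt)
  structure(list(
    census = census,
    traits = traits,
    truth = list(params = pars, species = sp,
                 eps = eps, death_interval = death_interval,
                 config = config)
  ), class = "tv_sim")
}

#' @export
print.tv_sim <- function(x, ...) {
  n <- length(x$truth$death_interval)
  cat(sprintf("Simulated census: %d trees, %d censuses, %d deaths (%.1f%%)\n",
              n, x$truth$config$n_censuses,
              sum(!is.na(x$truth$death_interval)),
              100 * mean(!is.na(x$truth$death_interval))))
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Writes `census.csv` and `traits.csv` in the package's delimited formats
#' and the ground truth (generating parameters, seed, per-tree death
#' intervals) as `truth.json`.
#'
#' @param sim a `tv_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_census(sim$census, file.path(dir, "census.csv"))
  write_traits(sim$traits, file.path(dir, "traits.csv"))
  truth <- list(
    theta = as.list(sim$truth$params$theta),
    beta = as.list(sim$truth$params$beta),
    gamma = as.list(sim$truth$params$gamma),
    seed = sim$truth$config$seed,
    death_interval = as.vector(sim$truth$death_interval)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
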