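#' Per-tree trajectories from a census and a trait table
#'
#' Reshapes a validated census into one trajectory per usable tree: the
#' observed diameters while alive, the death interval (if any) and the
#' species trait vector. Trajectories are the unit over which the joint
#' likelihood factorises.
#'
#' @param census a `tv_census`.
#' @param traits species trait table (see [read_traits()]).
#' @return list of `tv_trajectory` objects, each a list with `tree_id`,
#'   `traits`, `diameters` (cm, while alive), `death_interval` (integer
#'   interval index `k` meaning death in `(k-1, k]`, or `NA`).
#' @export
trajectories <- function(census, traits) {
  df <- as.data.frame(census)
  tr_idx <- match(df$species_id, traits$species_id)
  if (anyNA(tr_idx)) {
    stop("species missing from trait table: ",
         df$species_id[which(is.na(tr_idx))[1]])
  }
  split_idx <- split(seq_len(nrow(df)), df$tree_id)
  lapply(split_idx, function(ii) {
    sub <- df[ii, , drop = FALSE]
    alive <- sub$status == "alive"
    dead_at <- if (any(!alive)) sub$time_index[!alive][1] else NA_integer_
    structure(list(
      tree_id = sub$tree_id[1],
      traits = as.list(traits[tr_idx[ii[1]], , drop = FALSE]),
      diameters = sub$dbh_cm[alive],
      first_index = sub$time_index[1],
      death_interval = if (is.na(dead_at)) NA_integer_ else
        as.integer(dead_at - sub$time_index[1])
    ), class = "tv_trajectory")
  })
}

#' Joint log-likelihood of one tree trajectory
#'
#' Reference (loop) evaluation of the per-tree factor of the joint
#' likelihood. A survivor observed at diameters `D_0..D_T` contributes
#' `sum_t [ log f(D_t | D_{t-1}) + log(1 - p_t) ]`; a tree dying in interval
#' `(k-1, k]` contributes the same factors up to `k-1` plus `log p_k` and no
#' growth factor for the death interval (it has no final diameter). The
#' vigor entering `p_t` is the growth residual of the preceding interval;
#' for each tree's first interval (no preceding growth) it is 0, its prior
#' mean. Growth intervals with a clamped (negative raw) increment contribute
#' the mortality factor only, and the following interval's vigor falls back
#' to 0. A survival or death probability of exactly 0 or 1 opposing the
#' observed outcome yields `-Inf`, never an error.
#'
#' @param traj a `tv_trajectory` (see [trajectories()]).
#' @param params a `tv_params`.
#' @param basis an [ontogeny_basis()].
#' @param interval_years census spacing, years.
#' @return the tree's joint log-likelihood.
#' @export
tree_loglik <- function(traj, params, basis = ontogeny_basis(),
                        interval_years = 10) {
  d <- traj$diameters
  k_death <- traj$death_interval
  n_alive <- length(d)
  ll <- 0
  vig <- 0                       # lagged vigor for the upcoming interval
  vig_next <- 0
  last_obs <- if (is.na(k_death)) n_alive - 1L else n_alive
  if (last_obs < 1L) return(0)
  for (t in seq_len(last_obs)) {
    dies_now <- !is.na(k_death) && t == n_alive  # death interval: no D_t
    eta <- mortality_linear_predictor(vig, d[t], traj$traits, params, basis)
    p <- mortality_probability(eta)
    if (dies_now) {
      ll <- ll + log(p)
      return(ll)
    }
    ll <- ll + log1p(-p)
    # growth factor for the interval (t-1, t] in 0-based census indices:
    # observed increment d[t] -> d[t+1]
    agr <- annual_increment(d[t], d[t + 1L], interval_years)
    if (agr >= 0) {
      y <- log1p(agr)
      mu <- predict_log_growth(d[t], traj$traits, params)
      ll <- ll + stats::dnorm(y, mu, params$theta[["sigma"]], log = TRUE)
      vig_next <- compute_vigor(y, mu)
    } else {
      vig_next <- 0              # clamped: growth factor omitted
    }
    vig <- vig_next
  }
  ll
}

#' Vectorised model data for the joint likelihood
#'
#' Precomputes the flat arrays the likelihood engine and the MCMC sampler
#' operate on: one row per usable growth observation (alive-to-alive,
#' unclamped) and one row per at-risk tree-interval, with the index linking
#' each mortality row to the growth residual of the preceding interval
#' (the lagged vigor covariate).
#'
#' @param census a `tv_census`.
#' @param traits species trait table.
#' @param basis an [ontogeny_basis()].
#' @return an environment of class `tv_model_data`.
#' @export
joint_model_data <- function(census, traits, basis = ontogeny_basis()) {
  df <- as.data.frame(census)
  dt <- attr(census, "interval_years")
  ti <- match(df$species_id, traits$species_id)
  if (anyNA(ti)) {
    stop("species missing from trait table: ", df$species_id[which(is.na(ti))[1]])
  }
  n <- nrow(df)
  i <- seq_len(n - 1L); j <- i + 1L
  pair <- df$tree_id[i] == df$tree_id[j] & df$time_index[j] == df$time_index[i] + 1L
  i <- i[pair]; j <- j[pair]
  died <- df$status[j] == "dead"

  # growth rows: both endpoints alive; clamped increments excluded from the
  # growth density (they contribute the mortality factor only)
  raw <- annual_increment(df$dbh_cm[i], df$dbh_cm[j], dt)
  is_growth <- !died & !is.na(raw) & raw >= 0
  gi <- i[is_growth]; gj <- j[is_growth]
  gsp <- ti[gi]

  md <- new.env(parent = emptyenv())
  md$interval_years <- dt
  md$n_clamped <- sum(!died & !is.na(raw) & raw < 0)
  md$g_tree <- df$tree_id[gi]
  md$g_end <- df$time_index[gj]
  md$g_y <- log1p(raw[is_growth])
  md$g_dbh95 <- traits$dbh95[gsp]
  md$g_wd <- traits$wd[gsp]
  md$g_hmax <- traits$hmax[gsp]
  md$g_d13c <- traits$d13c[gsp]
  md$g_lx <- log(df$dbh_cm[gi] / m_to_cm(md$g_dbh95))
  md$ng <- length(gi)

  # mortality rows: every at-risk interval (tree alive at the start)
  msp <- ti[i]
  x <- df$dbh_cm[i] / m_to_cm(traits$dbh95[msp])
  md$m_tree <- df$tree_id[i]
  md$m_end <- df$time_index[j]
  md$m_died <- as.numeric(died)
  md$m_f1 <- basis$f1(x)
  md$m_f2 <- basis$f2(x)
  md$m_x <- x
  md$m_hmax <- traits$hmax[msp]
  md$m_ortho <- traits$ortho[msp]
  md$m_wd <- traits$wd[msp]
  md$m_tough <- traits$tough[msp]
  md$nm <- length(i)

  # vigor link: mortality row (tree, end k) <- growth row (tree, end k-1)
  gkey <- paste(md$g_tree, md$g_end)
  mkey <- paste(md$m_tree, md$m_end - 1L)
  link <- match(mkey, gkey)
  md$m_has_vigor <- !is.na(link)
  md$m_gidx <- link[md$m_has_vigor]
  md$basis <- basis
  class(md) <- "tv_model_data"
  md
}

# growth mean/residual arrays at a parameter vector
.growth_state <- function(md, params) {
  th <- params$theta; g <- params$gamma
  gm <- th[["theta1"]] * g[["DBH95_growth"]] * md$g_dbh95 +
    th[["theta2"]] * g[["WD_growth"]] * md$g_wd +
    th[["theta3"]] * g[["Hmax_growth"]] * md$g_hmax +
    th[["theta4"]] * g[["d13C_growth"]] * md$g_d13c
  z <- (md$g_lx - log(th[["theta5"]])) / (th[["theta6"]] * md$g_wd)
  mu <- gm * exp(-0.5 * z * z)
  r <- md$g_y - mu
  list(mu = mu, r = r, ssr = sum(r * r))
}

.growth_loglik <- function(md, ssr, sigma) {
  -0.5 * md$ng * log(2 * pi * sigma * sigma) - ssr / (2 * sigma * sigma)
}

.vigor_vector <- function(md, r) {
  v <- numeric(md$nm)
  v[md$m_has_vigor] <- r[md$m_gidx]
  v
}

.mort_eta <- function(md, params, v) {
  be <- params$beta; g <- params$gamma
  be[["beta0"]] * v +
    be[["beta1"]] * md$m_f1 +
    be[["beta2"]] * md$m_f2 +
    be[["beta3"]] * g[["Hmax_mort"]] * md$m_hmax +
    be[["beta4"]] * g[["Ortho_mort"]] * md$m_ortho +
    be[["beta5"]] * g[["WD_mort"]] * md$m_wd +
    be[["beta6"]] * g[["Tough_mort"]] * md$m_tough
}

.mort_loglik <- function(md, eta) {
  lp_die <- stats::plogis(eta, log.p = TRUE)
  lp_live <- stats::plogis(eta, lower.tail = FALSE, log.p = TRUE)
  sum(md$m_died * lp_die + (1 - md$m_died) * lp_live)
}

#' Joint log-likelihood of a collection of trees
#'
#' Vectorised evaluation of the full joint likelihood, returned together
#' with its two components: the growth-density sum (the only part the
#' residual sd touches) and the mortality Bernoulli sum (the only part the
#' beta coefficients touch). The component split supports the samplers'
#' update-scoping rule — a mortality-only parameter never changes the growth
#' component — and the pseudo-R-squared of [pseudo_r2()].
#'
#' Accepts either precomputed model data (fast path) or a list of
#' trajectories (summed over [tree_loglik()]).
#'
#' @param trees a `tv_model_data` or a list of `tv_trajectory`.
#' @param params a `tv_params`.
#' @param basis an [ontogeny_basis()] (trajectory path only; model data
#'   carries its own).
#' @param interval_years census spacing (trajectory path only).
#' @return list with `total`, `growth`, `mortality`, `n_growth`, `n_mort`.
#'   A non-finite per-tree contribution propagates as `-Inf` with a warning
#'   naming the tree.
#' @export
total_loglik <- function(trees, params, basis = ontogeny_basis(),
                         interval_years = 10) {
  if (inherits(trees, "tv_model_data")) {
    md <- trees
    gs <- .growth_state(md, params)
    llg <- .growth_loglik(md, gs$ssr, params$theta[["sigma"]])
    v <- .vigor_vector(md, gs$r)
    eta <- .mort_eta(md, params, v)
    llm <- .mort_loglik(md, eta)
    if (!is.finite(llg) || !is.finite(llm)) {
      bad <- unique(c(md$g_tree[!is.finite(gs$r)], md$m_tree[!is.finite(eta)]))
      if (length(bad)) {
        warning("non-finite likelihood contribution for tree ", bad[1])
      }
      return(list(total = -Inf, growth = llg, mortality = llm,
                  n_growth = md$ng, n_mort = md$nm))
    }
    return(list(total = llg + llm, growth = llg, mortality = llm,
                n_growth = md$ng, n_mort = md$nm))
  }
  if (!length(trees)) stop("empty tree collection")
  per_tree <- vapply(trees, tree_loglik, numeric(1), params = params,
                     basis = basis, interval_years = interval_years)
  if (any(!is.finite(per_tree))) {
    bad <- which(!is.finite(per_tree))[1]
    if (is.nan(per_tree[bad])) {
      warning("non-finite likelihood contribution for tree ",
              trees[[bad]]$tree_id)
      per_tree[!is.finite(per_tree)] <- -Inf
    }
  }
  list(total = sum(per_tree), growth = NA_real_, mortality = NA_real_,
       n_growth = NA_integer_, n_mort = NA_integer_)
}
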