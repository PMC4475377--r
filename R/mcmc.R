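#' MCMC configuration
#'
#' Settings of the componentwise random-walk Metropolis-Hastings sampler
#' with its inverse-gamma Gibbs step. The reference schedule is 2000
#' adaptation iterations (phase 1, proposal scales tuned towards the target
#' acceptance band), then a rerun with frozen proposal scales (phase 2, 3500
#' iterations by default), a burn-in of 1000 and a thinning of 10 applied to
#' phase-2 draws; retained draws are pooled across chains. The desk default
#' is 4 chains (the community-scale reference analysis used 100).
#'
#' Priors are weakly informative and configurable: Normal(0, `coef_sd`^2) on
#' every growth and mortality coefficient (positivity of the optimum
#' diameter and curve width enforced by rejection), InverseGamma(
#' `sigma_shape`, `sigma_rate`) on the residual variance, and Bernoulli(
#' `inclusion_prob`) on each selection indicator.
#'
#' @param n_chains number of independent chains.
#' @param n_iter_phase1 adaptation iterations (proposal scales tuned).
#' @param n_iter_phase2 sampling iterations (proposal scales frozen).
#' @param burn_in phase-2 iterations discarded before retention.
#' @param thinning retain every `thinning`-th phase-2 draw.
#' @param proposal_sd named numeric of initial random-walk proposal sds;
#'   missing entries take the built-in defaults.
#' @param target_acceptance length-2 acceptance band; the stochastic-
#'   approximation adaptation steers each parameter's acceptance towards the
#'   middle of this band during phase 1.
#' @param adapt_every time constant (iterations) of the adaptation gain
#'   decay: the per-update gain is `1/sqrt(1 + iter/adapt_every)`, so the
#'   scales settle as phase 1 proceeds.
#' @param prior list with `coef_sd`, `sigma_shape`, `sigma_rate`,
#'   `inclusion_prob`.
#' @param seed integer seed for the first chain (chain c uses `seed + c - 1`);
#'   `NULL` leaves the RNG state alone.
#' @return an object of class `tv_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4,
                        n_iter_phase1 = 2000,
                        n_iter_phase2 = 3500,
                        burn_in = 1000,
                        thinning = 10,
                        proposal_sd = NULL,
                        target_acceptance = c(0.2, 0.5),
                        adapt_every = 50,
                        prior = list(),
                        seed = NULL) {
  psd <- c(theta1 = 0.1, theta2 = 0.1, theta3 = 0.1, theta4 = 0.1,
           theta5 = 0.05, theta6 = 0.5,
           beta0 = 0.1, beta1 = 0.1, beta2 = 0.1, beta3 = 0.1,
           beta4 = 0.1, beta5 = 0.1, beta6 = 0.1)
  if (!is.null(proposal_sd)) {
    if (is.null(names(proposal_sd))) stop("`proposal_sd` must be named")
    psd[names(proposal_sd)] <- proposal_sd
  }
  if (any(psd <= 0)) stop("proposal sds must be positive")
  pr <- list(coef_sd = 10, sigma_shape = 0.001, sigma_rate = 0.001,
             inclusion_prob = 0.5)
  pr[names(prior)] <- prior
  if (burn_in >= n_iter_phase2) stop("burn_in must be smaller than n_iter_phase2")
  if (thinning < 1) stop("thinning must be >= 1")
  structure(list(
    n_chains = n_chains, n_iter_phase1 = n_iter_phase1,
    n_iter_phase2 = n_iter_phase2, burn_in = burn_in, thinning = thinning,
    proposal_sd = psd,
    target_acceptance = target_acceptance, adapt_every = adapt_every,
    prior = pr, seed = seed
  ), class = "tv_mcmc_config")
}

#' Read an MCMC configuration from a YAML file
#'
#' Key/value hierarchy mirroring the arguments of [mcmc_config()];
#' `proposal_sd` and `prior` as nested maps.
#'
#' @param path YAML file path.
#' @return a `tv_mcmc_config`.
#' @export
read_mcmc_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(mcmc_config)))]
  if (!is.null(args$proposal_sd)) args$proposal_sd <- unlist(args$proposal_sd)
  if (!is.null(args$target_acceptance)) {
    args$target_acceptance <- as.numeric(unlist(args$target_acceptance))
  }
  do.call(mcmc_config, args)
}

#' One scalar random-walk Metropolis-Hastings step
#'
#' Gaussian random-walk proposal around the current value, accepted with
#' probability `min(1, exp(logpost(prop) - lp_current))`. A proposal with
#' non-finite log-posterior is rejected. This kernel is the building block
#' of the joint sampler and is exported so that reduced models (e.g. a
#' one-parameter logistic toy) can be sampled with the identical kernel.
#'
#' @param current current value.
#' @param lp_current log-posterior at `current`.
#' @param logpost function of one numeric argument.
#' @param sd proposal standard deviation.
#' @return list with `value`, `lp`, `accepted`.
#' @export
rw_mh_step <- function(current, lp_current, logpost, sd) {
  prop <- current + stats::rnorm(1, 0, sd)
  lp_prop <- logpost(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_current) {
    list(value = prop, lp = lp_prop, accepted = TRUE)
  } else {
    list(value = current, lp = lp_current, accepted = FALSE)
  }
}

#' Sample a univariate posterior by random-walk Metropolis-Hastings
#'
#' Thin convenience wrapper repeating [rw_mh_step()]; used for sampler
#' correctness checks against quadrature on toy posteriors.
#'
#' @param logpost log-posterior function of one numeric argument.
#' @param init initial value (must have finite log-posterior).
#' @param n_iter number of iterations.
#' @param sd proposal standard deviation.
#' @return list with `draws` (numeric vector) and `acceptance` rate.
#' @export
mh_sample <- function(logpost, init, n_iter, sd) {
  draws <- numeric(n_iter)
  cur <- init
  lp <- logpost(init)
  if (!is.finite(lp)) stop("initial value has non-finite log-posterior")
  acc <- 0L
  for (it in seq_len(n_iter)) {
    stp <- rw_mh_step(cur, lp, logpost, sd)
    cur <- stp$value; lp <- stp$lp
    acc <- acc + stp$accepted
    draws[it] <- cur
  }
  list(draws = draws, acceptance = acc / n_iter)
}

#' Conjugate Gibbs draw for the growth residual variance
#'
#' With a Normal growth likelihood and an InverseGamma(a0, b0) prior, the
#' residual variance has full conditional InverseGamma(a0 + n/2,
#' b0 + ssr/2), sampled as the reciprocal of a gamma variate. With `n = 0`
#' the draw is from the prior.
#'
#' @param ssr sum of squared growth residuals.
#' @param n number of growth observations.
#' @param shape,rate prior InverseGamma parameters.
#' @return one draw of the variance.
#' @export
draw_sigma2 <- function(ssr, n, shape = 0.001, rate = 0.001) {
  1 / stats::rgamma(1, shape = shape + n / 2, rate = rate + ssr / 2)
}

# ---- internal joint sampler -------------------------------------------------

# scalar coefficients and where they live
.theta_ids <- paste0("theta", 1:6)
.beta_ids <- paste0("beta", 0:6)

# log prior of a plain coefficient (constant dropped)
.lp_coef <- function(x, sd) -0.5 * (x / sd)^2

.init_state <- function(md, cfg, include_ortho, include_vigor, rng_try = 100) {
  pr <- cfg$prior
  for (try in seq_len(rng_try)) {
    th <- c(stats::runif(4, -2, 2), stats::runif(1, 0.3, 1.5),
            stats::runif(1, 1, 8), stats::runif(1, 0.2, 1.5))
    names(th) <- c(.theta_ids, "sigma")
    be <- stats::setNames(stats::runif(7, -2, 2), .beta_ids)
    if (!include_ortho) be[["beta4"]] <- 0
    if (!include_vigor) be[["beta0"]] <- 0
    gam <- stats::setNames(rep(1L, 8L), tv_candidates())
    if (!include_ortho) gam[["Ortho_mort"]] <- 0L
    p <- list(theta = th, beta = be, gamma = gam)
    gs <- .growth_state(md, p)
    llg <- .growth_loglik(md, gs$ssr, th[["sigma"]])
    v <- .vigor_vector(md, gs$r)
    eta <- .mort_eta(md, p, v)
    llm <- .mort_loglik(md, eta)
    if (is.finite(llg) && is.finite(llm)) {
      st <- new.env(parent = emptyenv())
      st$th <- th; st$be <- be; st$gam <- gam
      st$mu <- gs$mu; st$r <- gs$r; st$ssr <- gs$ssr
      st$llg <- llg; st$v <- v; st$eta <- eta; st$llm <- llm
      return(st)
    }
  }
  stop("could not find a finite-likelihood starting point after ", rng_try,
       " prior draws")
}

.params_of <- function(st) {
  structure(list(theta = st$th, beta = st$be, gamma = st$gam),
            class = "tv_params")
}

# full growth recompute for a candidate theta vector; returns NULL if the
# proposal lies outside the parameter domain
.try_theta <- function(md, st, th_new) {
  if (th_new[["theta5"]] <= 0 || th_new[["theta6"]] <= 0) return(NULL)
  p <- list(theta = th_new, beta = st$be, gamma = st$gam)
  gs <- .growth_state(md, p)
  llg <- .growth_loglik(md, gs$ssr, th_new[["sigma"]])
  v <- .vigor_vector(md, gs$r)
  eta <- st$eta + st$be[["beta0"]] * (v - st$v)
  llm <- .mort_loglik(md, eta)
  list(gs = gs, llg = llg, v = v, eta = eta, llm = llm)
}

.run_chain <- function(md, cfg, select, candidates, include_ortho,
                       include_vigor, chain_seed) {
  if (!is.null(chain_seed)) set.seed(chain_seed)
  pr <- cfg$prior
  st <- .init_state(md, cfg, include_ortho, include_vigor)
  psd <- cfg$proposal_sd
  band <- cfg$target_acceptance

  th_upd <- .theta_ids
  be_upd <- .beta_ids
  if (!include_ortho) be_upd <- setdiff(be_upd, "beta4")
  if (!include_vigor) be_upd <- setdiff(be_upd, "beta0")
  scalar_ids <- c(th_upd, be_upd)
  acc <- stats::setNames(numeric(length(scalar_ids)), scalar_ids)
  n_upd <- acc
  rm_target <- mean(band)  # aim for the middle of the acceptance band

  n1 <- cfg$n_iter_phase1; n2 <- cfg$n_iter_phase2
  keep_at <- which(seq_len(n2) > cfg$burn_in &
                     (seq_len(n2) - cfg$burn_in) %% cfg$thinning == 0)
  cols <- c(names(st$th), names(st$be), names(st$gam))
  draws <- matrix(NA_real_, length(keep_at), length(cols),
                  dimnames = list(NULL, cols))
  krow <- 0L
  # Robbins-Monro gain: aggressive early, settling as phase 1 proceeds
  rm_gain <- function(iter) 1 / sqrt(1 + iter / cfg$adapt_every)

  cand_coef <- .candidate_coef[candidates]

  for (iter in seq_len(n1 + n2)) {
    adapting <- iter <= n1

    # growth coefficients theta1..theta6
    for (id in th_upd) {
      j <- match(id, .theta_ids)
      is_cand <- id %in% c("theta1", "theta2", "theta3", "theta4")
      cand_id <- if (is_cand) tv_candidates()[j] else NA
      if (is_cand && st$gam[[cand_id]] == 0L) {
        # deselected: full conditional is the prior (Kuo-Mallick)
        st$th[[id]] <- stats::rnorm(1, 0, pr$coef_sd)
        next
      }
      prop <- st$th
      prop[[id]] <- prop[[id]] + stats::rnorm(1, 0, psd[[id]])
      cand <- .try_theta(md, st, prop)
      n_upd[[id]] <- n_upd[[id]] + 1
      accepted <- FALSE
      if (!is.null(cand) && is.finite(cand$llg) && is.finite(cand$llm)) {
        lr <- (cand$llg + cand$llm + .lp_coef(prop[[id]], pr$coef_sd)) -
          (st$llg + st$llm + .lp_coef(st$th[[id]], pr$coef_sd))
        if (log(stats::runif(1)) < lr) {
          st$th <- prop
          st$mu <- cand$gs$mu; st$r <- cand$gs$r; st$ssr <- cand$gs$ssr
          st$llg <- cand$llg; st$v <- cand$v; st$eta <- cand$eta
          st$llm <- cand$llm
          acc[[id]] <- acc[[id]] + 1
          accepted <- TRUE
        }
      }
      if (adapting) {
        psd[[id]] <- min(max(psd[[id]] *
          exp(rm_gain(iter) * (accepted - rm_target)), 1e-5), 50)
      }
    }

    # mode-jump kick for the curvature pair (theta5, theta6): an
    # independence proposal from broad lognormals. Componentwise walks can
    # strand on the flat-curve ridge (optimum below the data range, width
    # inflated); a joint proposal with likelihood-ratio acceptance restores
    # irreducibility across that ridge at the cost of one likelihood
    # evaluation per sweep.
    {
      p5 <- stats::rlnorm(1, log(0.7), 0.6)
      p6 <- stats::rlnorm(1, log(4), 0.6)
      th_new <- st$th
      th_new[["theta5"]] <- p5; th_new[["theta6"]] <- p6
      cand <- .try_theta(md, st, th_new)
      if (!is.null(cand) && is.finite(cand$llg) && is.finite(cand$llm)) {
        lq_new <- stats::dlnorm(p5, log(0.7), 0.6, log = TRUE) +
          stats::dlnorm(p6, log(4), 0.6, log = TRUE)
        lq_cur <- stats::dlnorm(st$th[["theta5"]], log(0.7), 0.6, log = TRUE) +
          stats::dlnorm(st$th[["theta6"]], log(4), 0.6, log = TRUE)
        lr <- (cand$llg + cand$llm +
                 .lp_coef(p5, pr$coef_sd) + .lp_coef(p6, pr$coef_sd) - lq_new) -
          (st$llg + st$llm + .lp_coef(st$th[["theta5"]], pr$coef_sd) +
             .lp_coef(st$th[["theta6"]], pr$coef_sd) - lq_cur)
        if (log(stats::runif(1)) < lr) {
          st$th <- th_new
          st$mu <- cand$gs$mu; st$r <- cand$gs$r; st$ssr <- cand$gs$ssr
          st$llg <- cand$llg; st$v <- cand$v; st$eta <- cand$eta
          st$llm <- cand$llm
        }
      }
    }

    # Gibbs step for the residual variance
    sig2 <- draw_sigma2(st$ssr, md$ng, pr$sigma_shape, pr$sigma_rate)
    st$th[["sigma"]] <- sqrt(sig2)
    st$llg <- .growth_loglik(md, st$ssr, st$th[["sigma"]])

    # mortality coefficients beta0..beta6 (mortality component only)
    for (id in be_upd) {
      j <- match(id, .beta_ids)
      cand_id <- switch(id, beta3 = "Hmax_mort", beta4 = "Ortho_mort",
                        beta5 = "WD_mort", beta6 = "Tough_mort", NA)
      if (!is.na(cand_id) && st$gam[[cand_id]] == 0L) {
        st$be[[id]] <- stats::rnorm(1, 0, pr$coef_sd)
        next
      }
      prop <- st$be
      prop[[id]] <- prop[[id]] + stats::rnorm(1, 0, psd[[id]])
      p <- list(theta = st$th, beta = prop, gamma = st$gam)
      eta_new <- .mort_eta(md, p, st$v)
      llm_new <- .mort_loglik(md, eta_new)
      n_upd[[id]] <- n_upd[[id]] + 1
      accepted <- FALSE
      if (is.finite(llm_new)) {
        lr <- (llm_new + .lp_coef(prop[[id]], pr$coef_sd)) -
          (st$llm + .lp_coef(st$be[[id]], pr$coef_sd))
        if (log(stats::runif(1)) < lr) {
          st$be <- prop; st$eta <- eta_new; st$llm <- llm_new
          acc[[id]] <- acc[[id]] + 1
          accepted <- TRUE
        }
      }
      if (adapting) {
        psd[[id]] <- min(max(psd[[id]] *
          exp(rm_gain(iter) * (accepted - rm_target)), 1e-5), 50)
      }
    }

    # Kuo-Mallick inclusion indicators
    for (cand_id in candidates) {
      coef_id <- cand_coef[[cand_id]]
      if (startsWith(coef_id, "beta")) {
        col <- switch(cand_id, Hmax_mort = md$m_hmax, Ortho_mort = md$m_ortho,
                      WD_mort = md$m_wd, Tough_mort = md$m_tough)
        delta <- st$be[[coef_id]] * col
        if (st$gam[[cand_id]] == 1L) {
          eta1 <- st$eta; eta0 <- st$eta - delta
          ll1 <- st$llm; ll0 <- .mort_loglik(md, eta0)
        } else {
          eta0 <- st$eta; eta1 <- st$eta + delta
          ll0 <- st$llm; ll1 <- .mort_loglik(md, eta1)
        }
        p1 <- stats::plogis((ll1 - ll0) +
                              log(pr$inclusion_prob / (1 - pr$inclusion_prob)))
        g_new <- as.integer(stats::runif(1) < p1)
        if (g_new != st$gam[[cand_id]]) {
          st$gam[[cand_id]] <- g_new
          if (g_new == 1L) { st$eta <- eta1; st$llm <- ll1 }
          else { st$eta <- eta0; st$llm <- ll0 }
        }
      } else {
        gam_flip <- st$gam
        gam_flip[[cand_id]] <- 1L - gam_flip[[cand_id]]
        p_flip <- list(theta = st$th, beta = st$be, gamma = gam_flip)
        gs_f <- .growth_state(md, p_flip)
        llg_f <- .growth_loglik(md, gs_f$ssr, st$th[["sigma"]])
        v_f <- .vigor_vector(md, gs_f$r)
        eta_f <- st$eta + st$be[["beta0"]] * (v_f - st$v)
        llm_f <- .mort_loglik(md, eta_f)
        ll_cur <- st$llg + st$llm
        ll_flip <- llg_f + llm_f
        if (st$gam[[cand_id]] == 1L) { ll1 <- ll_cur; ll0 <- ll_flip }
        else { ll1 <- ll_flip; ll0 <- ll_cur }
        p1 <- stats::plogis((ll1 - ll0) +
                              log(pr$inclusion_prob / (1 - pr$inclusion_prob)))
        g_new <- as.integer(stats::runif(1) < p1)
        if (g_new != st$gam[[cand_id]]) {
          st$gam <- gam_flip
          st$mu <- gs_f$mu; st$r <- gs_f$r; st$ssr <- gs_f$ssr
          st$llg <- llg_f; st$v <- v_f; st$eta <- eta_f; st$llm <- llm_f
        }
      }
    }

    if (iter == n1) { acc[] <- 0; n_upd[] <- 0 }  # report phase-2 rates

    # periodic cache refresh against floating-point drift of the
    # incremental eta updates
    if (iter %% 500 == 0) {
      p_cur <- list(theta = st$th, beta = st$be, gamma = st$gam)
      st$eta <- .mort_eta(md, p_cur, st$v)
      st$llm <- .mort_loglik(md, st$eta)
    }

    if (!adapting) {
      it2 <- iter - n1
      if (it2 > cfg$burn_in && (it2 - cfg$burn_in) %% cfg$thinning == 0) {
        krow <- krow + 1L
        draws[krow, ] <- c(st$th, st$be, st$gam)
      }
    }
  }

  list(draws = draws[seq_len(krow), , drop = FALSE],
       acceptance = ifelse(n_upd > 0, acc / n_upd, NA_real_),
       proposal_sd = psd,
       final_state = .params_of(st))
}

.run_chains <- function(md, cfg, select = FALSE,
                        candidates = if (select) tv_candidates() else character(),
                        include_ortho = select && "Ortho_mort" %in% candidates,
                        include_vigor = TRUE) {
  chains <- vector("list", cfg$n_chains)
  for (c_i in seq_len(cfg$n_chains)) {
    seed_c <- if (is.null(cfg$seed)) NULL else cfg$seed + c_i - 1L
    chains[[c_i]] <- .run_chain(md, cfg, select, candidates, include_ortho,
                                include_vigor, seed_c)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  list(draws = draws, chains = chains)
}

# posterior summary table from pooled draws
.summarise_draws <- function(draws, candidates) {
  param_cols <- setdiff(colnames(draws), tv_candidates())
  qs <- t(apply(draws[, param_cols, drop = FALSE], 2, stats::quantile,
                probs = c(0.05, 0.5, 0.95), names = FALSE))
  out <- data.frame(parameter = param_cols,
                    median = qs[, 2], q05 = qs[, 1], q95 = qs[, 3],
                    inclusion = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  incl <- colMeans(draws[, tv_candidates(), drop = FALSE])
  link <- .candidate_coef[names(incl)]
  sel <- names(incl) %in% candidates
  out$inclusion[match(link[sel], out$parameter)] <- incl[sel]
  attr(out, "inclusion_frequency") <- incl[sel]
  attr(out, "n_draws") <- nrow(draws)
  out
}
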