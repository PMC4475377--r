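#' McFadden pseudo-R-squared of a mortality model
#'
#' `1 - lnL/lnL0` (unadjusted) or, adjusted for the number of fitted
#' parameters, `1 - (lnL - k)/lnL0`. Both log-likelihoods are Bernoulli
#' mortality components; the adjusted variant can be read as the fraction of
#' the null model's information recovered by the fitted predictors, net of
#' parameter cost.
#'
#' @param model_loglik mortality Bernoulli log-likelihood of the model.
#' @param null_loglik mortality log-likelihood of the null (intercept-only)
#'   model; must be negative.
#' @param k_params number of fitted mortality parameters (0 for the
#'   unadjusted statistic).
#' @return the pseudo-R-squared.
#' @export
mcfadden_pseudo_r2 <- function(model_loglik, null_loglik, k_params = 0) {
  if (!is.finite(null_loglik) || null_loglik >= 0) {
    stop("null log-likelihood must be finite and negative")
  }
  1 - (model_loglik - k_params) / null_loglik
}

#' Adjusted pseudo-R-squared of a fitted joint model's mortality component
#'
#' Computes the Bernoulli mortality log-likelihood at the posterior medians,
#' compares it against the intercept-only null (a single empirical death
#' rate across all at-risk intervals), and adjusts by the number of sampled
#' mortality coefficients.
#'
#' @param fit a `tv_fit`.
#' @param adjusted penalise by the number of fitted mortality parameters.
#' @return the (adjusted) McFadden pseudo-R-squared.
#' @export
pseudo_r2 <- function(fit, adjusted = TRUE) {
  md <- fit$model_data
  p <- as_params(fit)
  gs <- .growth_state(md, p)
  v <- .vigor_vector(md, gs$r)
  eta <- .mort_eta(md, p, v)
  ll <- .mort_loglik(md, eta)
  rate <- mean(md$m_died)
  ll0 <- sum(md$m_died * log(rate) + (1 - md$m_died) * log1p(-rate))
  # sampled mortality coefficients: beta1..beta3, beta5, beta6 always,
  # beta0 and beta4 when included
  k <- if (adjusted) 5 + fit$include_vigor + fit$include_ortho else 0
  mcfadden_pseudo_r2(ll, ll0, k)
}

#' Vigor-binned mortality calibration
#'
#' Groups at-risk tree-intervals with an available vigor estimate into
#' equal-count bins by vigor, and compares the observed death rate per bin
#' with the rate predicted by the model. Because mortality is stochastic,
#' the predicted rate is the mean over `n_sims` Bernoulli resimulations of
#' every tree-interval, and a 90% simulation band (5% and 95% quantiles of
#' the per-simulation bin rates) accompanies it.
#'
#' @param fit a `tv_fit`, or a `tv_model_data`.
#' @param params parameter vector at which to predict; defaults to the
#'   posterior medians of `fit`.
#' @param n_bins number of vigor bins.
#' @param n_sims number of Bernoulli resimulations.
#' @param seed optional seed for the resimulations.
#' @return a `tv_calibration` data frame: per bin, mean vigor, number of
#'   tree-intervals, observed rate, predicted rate, `lo90`, `hi90`.
#' @export
vigor_calibration <- function(fit, params = NULL, n_bins = 10, n_sims = 100,
                              seed = NULL) {
  md <- if (inherits(fit, "tv_model_data")) fit else fit$model_data
  if (is.null(params)) {
    if (inherits(fit, "tv_model_data")) {
      stop("`params` must be supplied when calibrating raw model data")
    }
    params <- as_params(fit)
  }
  if (!is.null(seed)) set.seed(seed)
  gs <- .growth_state(md, params)
  v_all <- .vigor_vector(md, gs$r)
  keep <- md$m_has_vigor
  if (sum(keep) < n_bins) {
    stop("fewer tree-intervals with available vigor (", sum(keep),
         ") than bins (", n_bins, ")")
  }
  v <- v_all[keep]
  died <- md$m_died[keep]
  eta <- .mort_eta(md, params, v_all)[keep]
  p <- mortality_probability(eta)

  bin <- ceiling(rank(v, ties.method = "first") / (length(v) / n_bins))
  bin <- pmin(bin, n_bins)
  sims <- matrix(stats::rbinom(length(p) * n_sims, 1, rep(p, n_sims)),
                 ncol = n_sims)
  sim_rates <- apply(sims, 2, function(s) tapply(s, bin, mean))
  out <- data.frame(
    bin = seq_len(n_bins),
    mean_vigor = as.numeric(tapply(v, bin, mean)),
    n = as.integer(table(bin)),
    observed = as.numeric(tapply(died, bin, mean)),
    predicted = rowMeans(sim_rates),
    model_rate = as.numeric(tapply(p, bin, mean)),
    lo90 = apply(sim_rates, 1, stats::quantile, probs = 0.05),
    hi90 = apply(sim_rates, 1, stats::quantile, probs = 0.95),
    row.names = NULL
  )
  class(out) <- c("tv_calibration", "data.frame")
  out
}

#' @export
plot.tv_calibration <- function(x, ...) {
  graphics::plot(x$predicted, x$observed,
                 xlab = "predicted mortality rate",
                 ylab = "observed mortality rate",
                 cex = 1 + 2 * (x$mean_vigor - min(x$mean_vigor)) /
                   diff(range(x$mean_vigor)),
                 ...)
  graphics::segments(x$lo90, x$observed, x$hi90, x$observed)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Trait-effect response surfaces of the mortality model
#'
#' Probability of dying as a function of ontogenetic stage `x = DBH/DBH95`,
#' evaluated over a grid of trait profiles and vigor levels (-1, 0, +1 by
#' default). With a negative vigor coefficient the higher-vigor curve lies
#' strictly below the lower-vigor one at every stage.
#'
#' @param params a `tv_params`.
#' @param traits data frame of trait profiles, one row per curve (defaults
#'   to the range midpoints with each of Hmax, WD, Tough swept over its
#'   low/mid/high reference value).
#' @param vigor vigor levels.
#' @param x grid of ontogenetic stages (> 0).
#' @param basis an [ontogeny_basis()].
#' @param dbh95 reference species maximum diameter (m) used to convert
#'   stages to diameters.
#' @return long data frame with `profile`, `vigor`, `x`, `p`.
#' @export
mortality_response <- function(params, traits = NULL, vigor = c(-1, 0, 1),
                               x = seq(0.05, 1, length.out = 50),
                               basis = ontogeny_basis(), dbh95 = 0.62) {
  if (is.null(traits)) {
    r <- trait_ranges()
    mid <- function(z) mean(z)
    base <- data.frame(dbh95 = dbh95, hmax = mid(r$hmax), ortho = 0,
                       wd = mid(r$wd), tough = mid(r$tough),
                       d13c = mid(r$d13c))
    traits <- do.call(rbind, lapply(c("hmax", "wd", "tough"), function(tr) {
      lv <- c(r[[tr]][1], mid(r[[tr]]), r[[tr]][2])
      out <- base[rep(1, 3), ]
      out[[tr]] <- lv
      out$profile <- paste0(tr, "_", c("low", "mid", "high"))
      out
    }))
  }
  if (is.null(traits$profile)) traits$profile <- paste0("profile", seq_len(nrow(traits)))
  grid <- expand.grid(row = seq_len(nrow(traits)), vigor = vigor, x = x,
                      KEEP.OUT.ATTRS = FALSE)
  tr <- traits[grid$row, , drop = FALSE]
  dbh_cm <- grid$x * m_to_cm(tr$dbh95)
  eta <- mortality_linear_predictor(grid$vigor, dbh_cm, tr, params, basis)
  data.frame(profile = tr$profile, vigor = grid$vigor, x = grid$x,
             p = mortality_probability(eta), row.names = NULL)
}
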