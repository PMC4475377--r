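#' Fit the joint growth-mortality model
#'
#' Fits the coupled individual-based model to a census and a trait table by
#' MCMC: the hump-shaped trait-driven growth model and the logistic
#' discrete-time mortality model are inferred simultaneously from the joint
#' likelihood, with tree vigor (the lagged growth residual) as a mortality
#' covariate. Coefficients are updated one at a time by random-walk
#' Metropolis-Hastings — an update of a mortality coefficient recomputes the
#' mortality component only, while a growth-coefficient update recomputes
#' both components because vigor propagates — and the residual variance by a
#' conjugate inverse-gamma Gibbs step. With `select = TRUE` the eight
#' candidate predictors additionally carry Kuo-Mallick inclusion
#' indicators.
#'
#' @param census a `tv_census` (see [read_census()], [simulate_census()]).
#' @param traits species trait table (see [read_traits()]).
#' @param config a [mcmc_config()].
#' @param select run Kuo-Mallick indicator selection over `candidates`.
#' @param candidates candidate predictors (subset of [tv_candidates()]);
#'   only used when `select = TRUE`.
#' @param include_ortho sample the Ortho mortality coefficient. Defaults to
#'   `TRUE` only when Ortho is among the selection candidates, mirroring the
#'   reference analysis in which Ortho was dropped from the final model.
#' @param include_vigor sample the vigor coefficient beta0. Setting `FALSE`
#'   fixes beta0 at zero (the no-vigor comparator model used for
#'   pseudo-R-squared contrasts).
#' @param basis an [ontogeny_basis()].
#' @param seed convenience override of `config$seed`.
#' @return an object of class `tv_fit` with components `draws` (pooled
#'   retained draws, one column per coefficient plus one per inclusion
#'   indicator), `summary` (medians, 90% credibility intervals, inclusion
#'   frequencies), `acceptance` (phase-2 acceptance rates per chain),
#'   `model_data`, `config` and the model flags.
#' @export
tv_fit <- function(census, traits, config = mcmc_config(),
                   select = FALSE,
                   candidates = if (select) tv_candidates() else character(),
                   include_ortho = select && "Ortho_mort" %in% candidates,
                   include_vigor = TRUE,
                   basis = ontogeny_basis(),
                   seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  if (select && length(setdiff(candidates, tv_candidates()))) {
    stop("unknown candidate predictor(s): ",
         paste(setdiff(candidates, tv_candidates()), collapse = ", "))
  }
  if (!select) candidates <- character()
  md <- joint_model_data(census, traits, basis)
  res <- .run_chains(md, config, select = select, candidates = candidates,
                     include_ortho = include_ortho,
                     include_vigor = include_vigor)
  smry <- .summarise_draws(res$draws, candidates)
  structure(list(
    draws = res$draws,
    summary = smry,
    inclusion = attr(smry, "inclusion_frequency"),
    acceptance = lapply(res$chains, `[[`, "acceptance"),
    model_data = md,
    config = config,
    select = select,
    candidates = candidates,
    include_ortho = include_ortho,
    include_vigor = include_vigor,
    basis = basis,
    call = match.call()
  ), class = "tv_fit")
}

#' Posterior medians of a fitted joint model
#'
#' @param object a `tv_fit`.
#' @param ... unused.
#' @return named numeric vector of posterior medians (coefficients only).
#' @export
coef.tv_fit <- function(object, ...) {
  s <- object$summary
  stats::setNames(s$median, s$parameter)
}

# posterior-median tv_params of a fit (modal gamma for selection runs)
as_params <- function(fit) {
  med <- coef(fit)
  gam <- stats::setNames(rep(1L, 8L), tv_candidates())
  if (fit$select) {
    gam[names(fit$inclusion)] <- as.integer(fit$inclusion >= 0.5)
  } else if (!fit$include_ortho) {
    gam[["Ortho_mort"]] <- 0L
  }
  joint_params(
    theta = med[c(paste0("theta", 1:6), "sigma")],
    beta = med[paste0("beta", 0:6)],
    gamma = gam
  )
}

#' @export
print.tv_fit <- function(x, ...) {
  cat("Joint growth-mortality model fit (treevigor)\n")
  cat(sprintf("  trees-at-risk intervals: %d, growth observations: %d\n",
              x$model_data$nm, x$model_data$ng))
  cat(sprintf("  chains: %d, retained draws: %d%s\n",
              x$config$n_chains, nrow(x$draws),
              if (x$select) ", Kuo-Mallick selection on" else ""))
  cat("Posterior medians:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Summarise a fitted joint model
#'
#' @param object a `tv_fit`.
#' @param ... unused.
#' @return the posterior summary data frame (median, 5% and 95% quantiles,
#'   inclusion frequency for selectable predictors), with the retained draw
#'   count as attribute `n_draws`.
#' @export
summary.tv_fit <- function(object, ...) {
  s <- object$summary
  class(s) <- c("summary.tv_fit", "data.frame")
  s
}

#' @export
print.summary.tv_fit <- function(x, ...) {
  cat("Posterior summary (median and 90% credibility interval):\n")
  df <- as.data.frame(x)
  df$median <- signif(df$median, 4)
  df$q05 <- signif(df$q05, 4)
  df$q95 <- signif(df$q95, 4)
  df$inclusion <- ifelse(is.na(df$inclusion), "", signif(df$inclusion, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predictions from a fitted joint model
#'
#' At the posterior medians: `type = "growth"` returns the expected
#' log(AGR+1) for each growth observation, `type = "mortality"` the
#' per-interval death probability for each at-risk tree-interval, and
#' `type = "eta"` the mortality linear predictor.
#'
#' @param object a `tv_fit`.
#' @param type prediction scale.
#' @param ... unused.
#' @return numeric vector, one element per model-data row.
#' @export
predict.tv_fit <- function(object, type = c("mortality", "growth", "eta"), ...) {
  type <- match.arg(type)
  md <- object$model_data
  p <- as_params(object)
  gs <- .growth_state(md, p)
  if (type == "growth") return(gs$mu)
  v <- .vigor_vector(md, gs$r)
  eta <- .mort_eta(md, p, v)
  if (type == "eta") eta else mortality_probability(eta)
}

#' Vigor residuals of a fitted joint model
#'
#' The vigor estimator at the posterior medians: observed minus expected
#' log(AGR+1) for every usable growth observation. These residuals, lagged
#' by one interval, are the mortality covariate of the joint model.
#'
#' @param object a `tv_fit`.
#' @param ... unused.
#' @return data frame with `tree_id`, `interval_index` and `vigor`.
#' @export
residuals.tv_fit <- function(object, ...) {
  md <- object$model_data
  gs <- .growth_state(md, as_params(object))
  data.frame(tree_id = md$g_tree, interval_index = md$g_end,
             vigor = gs$r, stringsAsFactors = FALSE)
}

#' Forward-simulate a census from a fitted joint model
#'
#' Simulates new census tables at the posterior medians, using the fitted
#' community's species trait table and initial-diameter settings from
#' `config`.
#'
#' @param object a `tv_fit`.
#' @param nsim number of simulated censuses.
#' @param seed optional seed.
#' @param config a [sim_config()] whose `params` and trait settings are
#'   overridden by the fit; defaults to the reference design.
#' @param ... unused.
#' @return a list of `tv_sim` objects (length `nsim`).
#' @export
simulate.tv_fit <- function(object, nsim = 1, seed = NULL,
                            config = sim_config(), ...) {
  if (!is.null(seed)) set.seed(seed)
  config$params <- as_params(object)
  config$seed <- NULL
  lapply(seq_len(nsim), function(i) simulate_census(config))
}

#' Trace plots of a fitted joint model
#'
#' @param x a `tv_fit`.
#' @param pars coefficients to plot (default: the vigor coefficient and the
#'   first growth coefficient).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tv_fit <- function(x, pars = c("beta0", "theta1"), ...) {
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "l", xlab = "retained draw",
                   ylab = p, main = paste("trace:", p), ...)
  }
  invisible(x)
}

#' Write retained draws to delimited text
#'
#' One row per retained draw, one column per coefficient plus one per
#' selection indicator.
#'
#' @param fit a `tv_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  invisible(path)
}
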