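#' Ontogenetic basis of the mortality model
#'
#' The two ontogenetic-trajectory covariates of the mortality linear
#' predictor are functions of the ontogenetic stage `x = DBH / DBH95`. The
#' default pair `f1(x) = x`, `f2(x) = 1/x` yields, with positive
#' coefficients, the U-shaped size-mortality relationship expected of closed
#' forests (young and senescent trees die more). The basis is injectable:
#' any pair of finite functions of `x > 0` may be supplied.
#'
#' @param f1,f2 functions of the ontogenetic stage.
#' @return an object of class `tv_basis`.
#' @export
ontogeny_basis <- function(f1 = function(x) x, f2 = function(x) 1 / x) {
  stopifnot(is.function(f1), is.function(f2))
  structure(list(f1 = f1, f2 = f2), class = "tv_basis")
}

#' Tree vigor: the growth-model residual
#'
#' Vigor is the difference between the growth observed in the field and the
#' growth the model expects for that tree, on the modelled log(AGR+1) scale:
#' `v = observed - predicted`. A tree growing exactly as expected has vigor
#' zero; a tree growing less than expected has negative vigor.
#'
#' @param observed_log_agr1 observed log(AGR+1).
#' @param predicted_log_agr1 model-expected log(AGR+1).
#' @return the vigor residual (vectorised).
#' @export
compute_vigor <- function(observed_log_agr1, predicted_log_agr1) {
  observed_log_agr1 - predicted_log_agr1
}

#' Linear predictor of the mortality submodel
#'
#' `eta = beta0*v + beta1*f1(x) + beta2*f2(x) + beta3*Hmax + beta4*Ortho +
#' beta5*WD + beta6*Tough`, with ontogenetic stage `x = dbh / DBH95`
#' (diameters compared in cm). Predictors deselected through `params$gamma`
#' contribute zero; there is no separate intercept (baseline mortality is
#' absorbed by the ontogeny terms).
#'
#' @param v vigor (lagged growth residual; 0 where unavailable).
#' @param dbh diameter at the start of the interval, cm.
#' @param traits named list / data frame with `dbh95`, `hmax`, `ortho`,
#'   `wd`, `tough` (a `d13c` field is tolerated and ignored).
#' @param params a `tv_params`.
#' @param basis a [ontogeny_basis()].
#' @return the linear predictor eta (vectorised).
#' @export
mortality_linear_predictor <- function(v, dbh, traits, params,
                                       basis = ontogeny_basis()) {
  if (is.data.frame(traits)) traits <- as.list(traits)
  alias <- c(dbh95_m = "dbh95", hmax_dm = "hmax")
  hit <- names(traits) %in% names(alias)
  names(traits)[hit] <- alias[names(traits)[hit]]
  need <- c("dbh95", "hmax", "ortho", "wd", "tough")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits missing fields: ", paste(miss, collapse = ", "))
  x <- dbh / m_to_cm(traits$dbh95)
  if (any(x <= 0)) stop("ontogenetic stage x = dbh/dbh95 must be positive")
  be <- params$beta
  g <- params$gamma
  be[["beta0"]] * v +
    be[["beta1"]] * basis$f1(x) +
    be[["beta2"]] * basis$f2(x) +
    be[["beta3"]] * g[["Hmax_mort"]] * traits$hmax +
    be[["beta4"]] * g[["Ortho_mort"]] * traits$ortho +
    be[["beta5"]] * g[["WD_mort"]] * traits$wd +
    be[["beta6"]] * g[["Tough_mort"]] * traits$tough
}

#' Probability of dying over a census interval
#'
#' Logistic link: `p = 1 / (1 + exp(-eta))`, interpreted per census interval
#' (10 years in the reference design).
#'
#' @param eta linear predictor.
#' @return probability in (0, 1) (vectorised).
#' @export
mortality_probability <- function(eta) {
  stats::plogis(eta)
}

#' Annualise an interval mortality probability
#'
#' Reporting helper converting a per-interval death probability into an
#' annual rate under within-interval independence: `1 - (1-p)^(1/dt)`. Used
#' for presentation only; the model itself works per census interval.
#'
#' @param p per-interval probability of dying.
#' @param interval_years interval length, years.
#' @return annual probability of dying.
#' @export
annualize_mortality <- function(p, interval_years) {
  1 - (1 - p)^(1 / interval_years)
}
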