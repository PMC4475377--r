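#' Maximum log-growth of a species
#'
#' The asymptotic (size-optimal) growth of the hump-shaped growth model is a
#' linear combination of four functional traits:
#' `Gmax = theta1*DBH95 + theta2*WD + theta3*Hmax + theta4*d13C`,
#' with DBH95 in metres and the other traits in their native units.
#' Deselected growth predictors (via `params$gamma`) contribute zero.
#'
#' @param traits named list / data frame with fields `dbh95`, `wd`, `hmax`,
#'   `d13c` (vectorised).
#' @param params a `tv_params` object (only `theta` and `gamma` are used).
#' @return numeric, the maximum expected log(AGR+1).
#' @export
gmax <- function(traits, params) {
  tr <- .as_traits_growth(traits)
  th <- params$theta
  g <- params$gamma
  th[["theta1"]] * g[["DBH95_growth"]] * tr$dbh95 +
    th[["theta2"]] * g[["WD_growth"]] * tr$wd +
    th[["theta3"]] * g[["Hmax_growth"]] * tr$hmax +
    th[["theta4"]] * g[["d13C_growth"]] * tr$d13c
}

# growth needs only four of the six traits; tolerate their absence elsewhere
.as_traits_growth <- function(traits) {
  if (is.data.frame(traits)) traits <- as.list(traits)
  alias <- c(dbh95_m = "dbh95", hmax_dm = "hmax")
  hit <- names(traits) %in% names(alias)
  names(traits)[hit] <- alias[names(traits)[hit]]
  need <- c("dbh95", "wd", "hmax", "d13c")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits missing fields: ", paste(miss, collapse = ", "))
  traits[need]
}

#' Expected log-growth at a given diameter
#'
#' The hump-shaped ontogenetic growth trajectory: expected log(AGR+1) is
#' `mu = Gmax * exp(-0.5 * (log(D / Dopt) / K)^2)` with optimum diameter
#' `Dopt = theta5 * DBH95` and width `K = theta6 * WD`; `D` and `DBH95` are
#' compared in centimetres. For positive `Gmax` the curve rises to its
#' unique maximum `Gmax` at `Dopt` and falls towards zero on either side
#' (lognormal in diameter).
#'
#' @param dbh diameter at breast height, cm (vectorised).
#' @param traits named list / data frame with `dbh95`, `wd`, `hmax`, `d13c`.
#' @param params a `tv_params`.
#' @return expected log(AGR+1), same length as the broadcast inputs.
#' @export
predict_log_growth <- function(dbh, traits, params) {
  tr <- .as_traits_growth(traits)
  th <- params$theta
  if (any(dbh <= 0)) stop("dbh must be positive")
  dopt <- th[["theta5"]] * m_to_cm(tr$dbh95)
  width <- th[["theta6"]] * tr$wd
  if (any(dopt <= 0)) stop("optimum diameter theta5*DBH95 must be positive")
  if (any(width <= 0)) stop("growth-curve width theta6*WD must be positive")
  z <- log(dbh / dopt) / width
  gmax(tr, params) * exp(-0.5 * z * z)
}

#' Log-density of an observed growth increment
#'
#' Gaussian observation density of the modelled growth scale: `log_agr1`
#' given the start-of-interval diameter is Normal with mean
#' [predict_log_growth()] and standard deviation `sigma`. This is the
#' `f(D_t | D_{t-1})` factor of the joint likelihood up to the parameter-free
#' Jacobian of the diameter-to-log(AGR+1) change of variable, which is a
#' constant shift and therefore omitted (inference-invariant).
#'
#' @param obs a growth observation (row of [compute_growth_observations()]),
#'   or a numeric log(AGR+1) value.
#' @param dbh_prev diameter at the start of the interval, cm.
#' @param traits species traits (see [predict_log_growth()]).
#' @param params a `tv_params`; `params$theta[["sigma"]]` must be positive.
#' @return the log-density (numeric, vectorised).
#' @export
growth_logdensity <- function(obs, dbh_prev, traits, params) {
  y <- if (is.list(obs) || is.data.frame(obs)) obs$log_agr1 else obs
  sigma <- params$theta[["sigma"]]
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  mu <- predict_log_growth(dbh_prev, traits, params)
  stats::dnorm(y, mean = mu, sd = sigma, log = TRUE)
}
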