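#' Joint growth-mortality parameter vector
#'
#' Bundles the parameters of the two coupled submodels. The growth submodel
#' has coefficients `theta1..theta4` (linear combination of DBH95, WD, Hmax
#' and d13C giving the maximum log-growth Gmax), `theta5` (relative diameter
#' at maximum growth, a dimensionless multiplier of DBH95), `theta6`
#' (growth-curve width coefficient, multiplied by WD) and `sigma` (the
#' residual standard deviation of log(AGR+1), often written theta7). The
#' mortality submodel has `beta0` (vigor), `beta1`, `beta2` (the two
#' ontogenetic-trajectory covariates), `beta3` (Hmax), `beta4` (Ortho, absent
#' from the final model when deselected), `beta5` (WD) and `beta6` (Tough).
#'
#' `gamma` carries the binary inclusion indicators of the eight selectable
#' predictors; a deselected predictor contributes exactly zero to every
#' linear predictor while its coefficient is retained (Kuo-Mallick
#' construction).
#'
#' @param theta numeric length 7: theta1..theta6 and sigma (in that order, or
#'   named `theta1..theta6`, `sigma`).
#' @param beta numeric length 7: beta0..beta6 (or so named).
#' @param gamma named binary vector over [tv_candidates()]; defaults to all 1
#'   (every candidate included).
#' @return an object of class `tv_params`.
#' @seealso [default_params()] for the community-scale reference vector.
#' @export
joint_params <- function(theta, beta, gamma = NULL) {
  theta <- as.numeric(theta)
  beta <- as.numeric(beta)
  if (length(theta) != 7L) stop("`theta` must have length 7 (theta1..theta6, sigma)")
  if (length(beta) != 7L) stop("`beta` must have length 7 (beta0..beta6)")
  names(theta) <- c(paste0("theta", 1:6), "sigma")
  names(beta) <- paste0("beta", 0:6)
  if (!is.finite(theta[["sigma"]]) || theta[["sigma"]] <= 0) {
    stop("sigma (theta7) must be a finite positive number")
  }
  if (!is.finite(theta[["theta5"]]) || theta[["theta5"]] <= 0) {
    stop("theta5 (relative diameter at maximum growth) must be positive")
  }
  if (is.null(gamma)) {
    gamma <- stats::setNames(rep(1L, length(tv_candidates())), tv_candidates())
  } else {
    if (is.null(names(gamma)) || !all(names(gamma) %in% tv_candidates())) {
      stop("`gamma` must be named after tv_candidates()")
    }
    full <- stats::setNames(rep(1L, length(tv_candidates())), tv_candidates())
    full[names(gamma)] <- as.integer(gamma)
    gamma <- full
  }
  if (!all(gamma %in% c(0L, 1L))) stop("gamma entries must be 0 or 1")
  structure(list(theta = theta, beta = beta, gamma = gamma),
            class = "tv_params")
}

#' The eight selectable predictors
#'
#' Candidate predictors screened by Kuo-Mallick indicator selection: DBH95,
#' WD, Hmax and d13C in the growth process, and Hmax, Ortho, WD and Tough in
#' the mortality process.
#'
#' @return character vector of candidate identifiers.
#' @export
tv_candidates <- function() {
  c("DBH95_growth", "WD_growth", "Hmax_growth", "d13C_growth",
    "Hmax_mort", "Ortho_mort", "WD_mort", "Tough_mort")
}

# coefficient slot each candidate gates
.candidate_coef <- c(
  DBH95_growth = "theta1", WD_growth = "theta2", Hmax_growth = "theta3",
  d13C_growth = "theta4", Hmax_mort = "beta3", Ortho_mort = "beta4",
  WD_mort = "beta5", Tough_mort = "beta6"
)

#' Reference community-scale parameter vector
#'
#' The posterior medians of the Paracou community fit (vigor coefficient
#' -0.403; ontogeny 0.140, 0.502; Hmax -0.414; WD -0.951; Tough -0.327;
#' growth 2.43, -0.384, 0.0318, -0.403; optimum at 0.767 DBH95; width 4.81),
#' with the Ortho effect set to zero (it was not retained by selection) and a
#' residual standard deviation of 0.5 on the log(AGR+1) scale. This is the
#' default generating vector of [sim_config()], so recovery experiments
#' target these values.
#'
#' @return a `tv_params` object.
#' @export
default_params <- function() {
  joint_params(
    theta = c(2.43, -0.384, 0.0318, -0.403, 0.767, 4.81, 0.5),
    beta = c(-0.403, 0.140, 0.502, -0.414, 0, -0.951, -0.327)
  )
}

#' @export
print.tv_params <- function(x, ...) {
  cat("Joint growth-mortality parameters\n")
  cat("  growth:    ", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                             collapse = " "), "\n")
  cat("  mortality: ", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                             collapse = " "), "\n")
  off <- names(x$gamma)[x$gamma == 0L]
  if (length(off)) cat("  deselected:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

#' Reference ranges of the six functional traits
#'
#' Species-level trait ranges of the Guianan community used to parameterise
#' the synthetic generator: maximum diameter DBH95 (m), maximum height Hmax
#' (dm, used verbatim as a covariate), trunk xylem density WD (g/cm^3),
#' laminar toughness Tough (N) and foliar d13C composition (per mil scale).
#' Ortho (stem orientation) is binary and has no range.
#'
#' @return named list of length-2 numeric ranges.
#' @export
trait_ranges <- function() {
  list(
    dbh95 = c(0.13, 1.11),
    hmax = c(0.8, 5.6),
    wd = c(0.28, 0.91),
    tough = c(0.22, 11.4),
    d13c = c(-3.61, -2.62)
  )
}

# normalise a traits argument (named list / one-row data frame / data frame)
# to a list of numeric vectors with fields dbh95, hmax, ortho, wd, tough, d13c
.as_traits <- function(traits) {
  if (is.data.frame(traits)) traits <- as.list(traits)
  need <- c("dbh95", "hmax", "ortho", "wd", "tough", "d13c")
  # accept file-style names
  alias <- c(dbh95_m = "dbh95", hmax_dm = "hmax")
  hit <- names(traits) %in% names(alias)
  names(traits)[hit] <- alias[names(traits)[hit]]
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits missing fields: ", paste(miss, collapse = ", "))
  traits[need]
}
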