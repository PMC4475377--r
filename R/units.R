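#' Unit conversions used throughout the package
#'
#' Diameters are stored in centimetres in census files, annual growth rates
#' (AGR) are modelled in millimetres per year, and the species maximum
#' diameter trait (DBH95) is recorded in metres. These helpers are the single
#' place where scale factors live, so every conversion in the package is
#' applied exactly once.
#'
#' @param x numeric vector.
#' @return numeric vector on the target scale.
#' @name units
NULL

#' @rdname units
#' @export
cm_to_mm <- function(x) x * 10

#' @rdname units
#' @export
mm_to_cm <- function(x) x / 10

#' @rdname units
#' @export
m_to_cm <- function(x) x * 100

#' Annualised diameter increment
#'
#' Converts a diameter change observed over a census interval into an annual
#' growth rate in mm/yr: `AGR = 10 * (d_end - d_start) / dt`.
#'
#' @param d_start_cm,d_end_cm diameters at the interval endpoints, cm.
#' @param dt_years interval length, years.
#' @return annual diameter increment, mm per year (may be negative; clamping
#'   is the caller's concern, see [compute_growth_observations()]).
#' @export
annual_increment <- function(d_start_cm, d_end_cm, dt_years) {
  cm_to_mm(d_end_cm - d_start_cm) / dt_years
}
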