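#' Read a tree census table
#'
#' Reads a comma-delimited census file with one record per tree per census
#' and header `tree_id,species_id,time_index,time_years,dbh_cm,status`
#' (status `alive` or `dead`; `dbh_cm` empty/NA on dead records). The table
#' is validated: census indices must increase strictly within a tree,
#' diameters must be present exactly on alive records and positive, a dead
#' record must be the tree's last, and duplicate (tree, time) records are an
#' error. Trees with fewer than two records are flagged unusable (kept in
#' the table, listed in `attr(x, "unusable")`).
#'
#' @param path path to the delimited census file.
#' @param interval_years census spacing in years (constant by design).
#' @return a `tv_census` data frame with attributes `interval_years` and
#'   `unusable` (data frame of tree_id + reason).
#' @export
read_census <- function(path, interval_years = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_census(df, interval_years = interval_years)
}

#' Validate a census data frame
#'
#' @param df data frame with the census columns (see [read_census()]).
#' @param interval_years census spacing, years.
#' @return a validated `tv_census` object.
#' @export
as_census <- function(df, interval_years = 10) {
  need <- c("tree_id", "species_id", "time_index", "time_years", "dbh_cm", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("census file missing columns: ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(interval_years) || interval_years <= 0) {
    stop("`interval_years` must be a positive number of years")
  }
  df <- df[order(df$tree_id, df$time_index), need, drop = FALSE]
  df$status <- as.character(df$status)
  bad_status <- setdiff(unique(df$status), c("alive", "dead"))
  if (length(bad_status)) {
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  }

  dup <- duplicated(df[c("tree_id", "time_index")])
  if (any(dup)) {
    stop("duplicate (tree_id, time_index) record for tree ",
         df$tree_id[which(dup)[1]])
  }

  alive <- df$status == "alive"
  has_dbh <- !is.na(df$dbh_cm)
  if (any(!alive & has_dbh)) {
    stop("dbh present on a dead record for tree ",
         df$tree_id[which(!alive & has_dbh)[1]])
  }
  if (any(alive & !has_dbh)) {
    stop("dbh missing on an alive record for tree ",
         df$tree_id[which(alive & !has_dbh)[1]])
  }
  if (any(has_dbh & df$dbh_cm <= 0)) {
    stop("non-positive dbh for tree ", df$tree_id[which(has_dbh & df$dbh_cm <= 0)[1]])
  }

  # per-tree ordering checks, vectorised over consecutive same-tree rows
  n <- nrow(df)
  if (n > 1) {
    same <- df$tree_id[-1] == df$tree_id[-n]
    if (any(same & df$time_index[-1] <= df$time_index[-n])) {
      stop("non-increasing time_index for tree ",
           df$tree_id[-1][which(same & df$time_index[-1] <= df$time_index[-n])[1]])
    }
    dead_first <- same & df$status[-n] == "dead"
    if (any(dead_first)) {
      stop("record after death for tree ", df$tree_id[-1][which(dead_first)[1]])
    }
  }

  counts <- table(df$tree_id)
  singletons <- names(counts)[counts < 2]
  unusable <- data.frame(tree_id = singletons,
                         reason = rep("fewer than 2 records", length(singletons)),
                         stringsAsFactors = FALSE)

  structure(df,
            interval_years = interval_years,
            unusable = unusable,
            class = c("tv_census", "data.frame"))
}

#' Write a census table to delimited text
#'
#' @param census a `tv_census` (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.csv(as.data.frame(census), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a species trait table
#'
#' Reads a comma-delimited trait file with header
#' `species_id,dbh95_m,hmax_dm,ortho,wd,tough,d13c`: maximum diameter (m),
#' maximum height (dm), stem orientation (1 orthotropic / 0 plagiotropic),
#' trunk xylem density (g/cm^3), laminar toughness (N) and foliar d13C.
#' Column names are normalised to `dbh95`, `hmax`, `ortho`, `wd`, `tough`,
#' `d13c`. Positivity of dbh95 and wd and binarity of ortho are enforced;
#' range plausibility is the synthetic generator's concern, not the
#' reader's.
#'
#' @param path path to the trait file.
#' @return data frame of species traits.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "dbh95_m", "hmax_dm", "ortho", "wd", "tough", "d13c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait file missing columns: ", paste(miss, collapse = ", "))
  names(df)[names(df) == "dbh95_m"] <- "dbh95"
  names(df)[names(df) == "hmax_dm"] <- "hmax"
  validate_traits(df)
}

validate_traits <- function(df) {
  num <- c("dbh95", "hmax", "wd", "tough", "d13c")
  for (f in num) {
    if (any(!is.finite(df[[f]]))) stop("non-finite trait value in column ", f)
  }
  if (any(df$dbh95 <= 0)) stop("dbh95 must be positive")
  if (any(df$wd <= 0)) stop("wd must be positive")
  if (!all(df$ortho %in% c(0, 1))) stop("ortho must be 0 or 1")
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in trait table")
  df
}

#' Write a species trait table
#'
#' @param traits data frame as returned by [read_traits()] or
#'   [sample_species_traits()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  out <- traits[c("species_id", "dbh95", "hmax", "ortho", "wd", "tough", "d13c")]
  names(out)[names(out) == "dbh95"] <- "dbh95_m"
  names(out)[names(out) == "hmax"] <- "hmax_dm"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annualised growth observations from a census table
#'
#' One observation per alive-to-alive pair of consecutive censuses:
#' `agr = 10 * (dbh_t - dbh_{t-1}) / dt` (cm to mm, annualised) and
#' `log_agr1 = log(agr + 1)`, the modelled scale. Negative raw increments
#' (field shrinkage, treated as measurement noise) are clamped to zero and
#' flagged; the number clamped is reported in `attr(x, "n_clamped")`.
#' Clamped observations are excluded from the growth density of the joint
#' likelihood (see [total_loglik()]).
#'
#' @param census a `tv_census`.
#' @return data frame with columns `tree_id`, `species_id`, `interval_index`
#'   (the census index ending the interval), `dbh_prev` (cm), `agr` (mm/yr),
#'   `log_agr1`, `clamped`; attribute `n_clamped`.
#' @export
compute_growth_observations <- function(census) {
  df <- as.data.frame(census)
  dt <- attr(census, "interval_years")
  if (is.null(dt)) stop("census lacks an interval_years attribute; use as_census()")
  n <- nrow(df)
  if (n < 2) {
    out <- data.frame(tree_id = character(), species_id = character(),
                      interval_index = integer(), dbh_prev = numeric(),
                      agr = numeric(), log_agr1 = numeric(), clamped = logical())
    attr(out, "n_clamped") <- 0L
    return(out)
  }
  i <- seq_len(n - 1)
  j <- i + 1L
  ok <- df$tree_id[i] == df$tree_id[j] &
    df$time_index[j] == df$time_index[i] + 1L &
    df$status[i] == "alive" & df$status[j] == "alive" &
    !is.na(df$dbh_cm[i]) & !is.na(df$dbh_cm[j])
  i <- i[ok]; j <- j[ok]
  raw <- annual_increment(df$dbh_cm[i], df$dbh_cm[j], dt)
  clamped <- raw < 0
  agr <- pmax(raw, 0)
  out <- data.frame(
    tree_id = df$tree_id[i],
    species_id = df$species_id[i],
    interval_index = df$time_index[j],
    dbh_prev = df$dbh_cm[i],
    agr = agr,
    log_agr1 = log1p(agr),
    clamped = clamped,
    stringsAsFactors = FALSE
  )
  attr(out, "n_clamped") <- sum(clamped)
  out
}
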