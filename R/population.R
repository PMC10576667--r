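#' Stratified population container
#'
#' Holds the census material the scan needs: per-municipality total
#' population counts at the calendar years where they are known (only census
#' years early on, annual thereafter), plus sex-by-age-class strata for the
#' years where the full breakdown exists. Totals at intermediate years are
#' obtained by [interpolate_census()] semantics: the difference between two
#' anchors is spread evenly over the years in between.
#'
#' @param totals data.frame with columns `municipality_id`, `year`, `count`:
#'   total population where known. Every municipality must be observed at the
#'   same set of years, with at least two years.
#' @param strata optional data.frame with columns `municipality_id`, `year`,
#'   `sex`, `age_class`, `count` for the years with a full sex/age breakdown.
#'   Strata must sum to the municipality total for any year also present in
#'   `totals`; years present only in `strata` contribute their sums as
#'   totals.
#' @return an object of class `stratified_population`.
#' @seealso [population_at_risk()], [expected_counts()]
#' @export
stratified_population <- function(totals, strata = NULL) {
  need <- c("municipality_id", "year", "count")
  if (!all(need %in% names(totals))) {
    stop("totals must have columns: ", paste(need, collapse = ", "))
  }
  if (any(totals$count < 0)) stop("population counts must be non-negative")
  munis <- sort(unique(as.character(totals$municipality_id)))

  if (!is.null(strata)) {
    needs <- c("municipality_id", "year", "sex", "age_class", "count")
    if (!all(needs %in% names(strata))) {
      stop("strata must have columns: ", paste(needs, collapse = ", "))
    }
    if (any(strata$count < 0)) stop("stratum counts must be non-negative")
    bad_ac <- setdiff(unique(strata$age_class), age_classes())
    if (length(bad_ac)) {
      stop("unknown age classes: ", paste(bad_ac, collapse = ", "))
    }
    # strata years contribute totals; where a total already exists it must
    # agree with the stratum sum
    ssum <- stats::aggregate(count ~ municipality_id + year, strata, sum)
    key_t <- paste(totals$municipality_id, totals$year)
    key_s <- paste(ssum$municipality_id, ssum$year)
    shared <- intersect(key_t, key_s)
    if (length(shared)) {
      tv <- totals$count[match(shared, key_t)]
      sv <- ssum$count[match(shared, key_s)]
      if (any(abs(tv - sv) > 1e-8)) {
        stop("stratum counts do not sum to the municipality totals")
      }
    }
    extra <- ssum[!(key_s %in% key_t), need]
    totals <- rbind(totals[need], extra)
  }

  years <- sort(unique(totals$year))
  if (length(years) < 2) stop("at least two census years are required")
  tm <- matrix(NA_real_, length(munis), length(years),
               dimnames = list(munis, years))
  tm[cbind(match(as.character(totals$municipality_id), munis),
           match(totals$year, years))] <- totals$count
  if (anyNA(tm)) {
    stop("every municipality must have a count at every census year")
  }

  adj_years <- integer(0)
  sa <- NULL
  if (!is.null(strata)) {
    adj_years <- sort(unique(strata$year))
    strat_labels <- as.vector(outer(sex_levels(), age_classes(), paste,
                                    sep = "."))
    sa <- array(0, dim = c(length(munis), length(strat_labels),
                           length(adj_years)),
                dimnames = list(munis, strat_labels, adj_years))
    idx <- cbind(match(as.character(strata$municipality_id), munis),
                 match(paste(strata$sex, strata$age_class, sep = "."),
                       strat_labels),
                 match(strata$year, adj_years))
    if (anyNA(idx)) stop("invalid sex or municipality label in strata")
    sa[idx] <- strata$count
  }

  structure(
    list(municipalities = munis, years = years, totals = tm,
         adjusted_years = adj_years, strata = sa),
    class = "stratified_population")
}

#' @export
print.stratified_population <- function(x, ...) {
  cat("Stratified population:", length(x$municipalities),
      "municipalities,", "years", min(x$years), "-", max(x$years), "\n")
  if (length(x$adjusted_years)) {
    cat("  sex/age strata available for", length(x$adjusted_years),
        "years (", min(x$adjusted_years), "-", max(x$adjusted_years), ")\n")
  } else {
    cat("  totals only (no sex/age strata)\n")
  }
  invisible(x)
}

#' Intercensal interpolation of population totals
#'
#' Imputes totals between census anchors by spreading the inter-census
#' difference evenly over the years of each interval, so the annual increment
#' is constant within an interval and anchor years are reproduced exactly.
#'
#' @param census a named numeric vector (names are census years) or a
#'   two-column data.frame (`year`, `count`) with at least two anchors.
#' @param target_years integer vector of years, all within the span of the
#'   anchors.
#' @return numeric vector of interpolated totals, one per target year.
#' @examples
#' interpolate_census(c("1971" = 4000, "1981" = 4500), 1975)  # 4200
#' @export
interpolate_census <- function(census, target_years) {
  if (is.data.frame(census)) {
    yrs <- census$year
    val <- census$count
  } else {
    yrs <- as.numeric(names(census))
    val <- as.numeric(census)
  }
  if (length(yrs) < 2) stop("at least two census points are required")
  if (anyNA(yrs) || is.unsorted(yrs, strictly = FALSE)) {
    o <- order(yrs)
    yrs <- yrs[o]
    val <- val[o]
  }
  if (any(duplicated(yrs))) stop("duplicated census years")
  if (any(target_years < yrs[1] | target_years > yrs[length(yrs)])) {
    stop("target year outside census coverage [", yrs[1], ", ",
         yrs[length(yrs)], "]")
  }
  stats::approx(yrs, val, xout = target_years, method = "linear")$y
}

# Vectorized per-municipality totals at one calendar year (interpolating
# between anchors when needed). Returns a named vector over municipalities.
.totals_at_year <- function(pop, year) {
  yrs <- pop$years
  if (year < yrs[1] || year > yrs[length(yrs)]) {
    stop("year ", year, " outside census coverage [", yrs[1], ", ",
         yrs[length(yrs)], "]")
  }
  i <- findInterval(year, yrs)
  if (yrs[i] == year) return(pop$totals[, i])
  w <- (year - yrs[i]) / (yrs[i + 1] - yrs[i])
  pop$totals[, i] * (1 - w) + pop$totals[, i + 1] * w
}

#' Population at risk for a pre-onset offset
#'
#' Because onsets are asynchronous, the population assigned to offset `k`
#' (years before onset) is the unweighted mean of the populations of the
#' distinct calendar years `onset year - k` observed in the cohort. The
#' snapshot carries full sex/age strata only when every contributing year has
#' them; otherwise it downgrades to municipality totals (and downstream
#' expected counts use a crude rate).
#'
#' @param pop a [stratified_population()].
#' @param k integer offset in years before onset, in `[0, 50]`.
#' @param onset_years integer vector of the cohort's onset years (duplicates
#'   are collapsed: the mean is over distinct calendar years).
#' @param weight_years if `TRUE`, weight each contributing calendar year by
#'   the number of cohort onsets anchored to it instead of the default
#'   unweighted mean over distinct years.
#' @return an object of class `at_risk_snapshot`: a list with `offset`,
#'   `years`, `stratified`, `totals` (named vector over municipalities) and,
#'   when stratified, `strata` (data.frame municipality/sex/age_class/pop).
#' @export
population_at_risk <- function(pop, k, onset_years, weight_years = FALSE) {
  stopifnot(inherits(pop, "stratified_population"))
  if (length(onset_years) == 0) stop("empty cohort")
  k <- as.integer(k)
  if (is.na(k) || k < 0 || k > 50) stop("offset k must be in [0, 50]")
  tab <- table(onset_years - k)
  years <- as.integer(names(tab))
  w <- if (weight_years) as.numeric(tab) else rep(1, length(years))
  w <- w / sum(w)

  tot <- Reduce(`+`, Map(function(y, wy) wy * .totals_at_year(pop, y),
                         years, w))
  stratified <- length(pop$adjusted_years) > 0 &&
    all(years %in% pop$adjusted_years)
  strata_df <- NULL
  if (stratified) {
    sl <- Reduce(`+`, Map(function(y, wy) {
      wy * pop$strata[, , as.character(y)]
    }, years, w))
    lab <- strsplit(colnames(sl), ".", fixed = TRUE)
    strata_df <- data.frame(
      municipality_id = rep(rownames(sl), times = ncol(sl)),
      sex = rep(vapply(lab, `[`, "", 1), each = nrow(sl)),
      age_class = rep(vapply(lab, `[`, "", 2), each = nrow(sl)),
      pop = as.vector(sl))
  }
  structure(list(offset = k, years = years, stratified = stratified,
                 totals = tot, strata = strata_df),
            class = "at_risk_snapshot")
}

#' @export
print.at_risk_snapshot <- function(x, ...) {
  cat("Population at risk, offset", x$offset, "y before onset\n")
  cat("  contributing years:", paste(x$years, collapse = ", "), "\n")
  cat("  ", if (x$stratified) "sex/age stratified" else "totals only (crude)",
      "; total population ", format(round(sum(x$totals))), "\n", sep = "")
  invisible(x)
}

#' Global stratum-specific rates
#'
#' First step of indirect standardization: disease rates per sex/age stratum
#' from regional case and population counts.
#'
#' @param cases data.frame with columns `sex`, `age_class`, `cases`.
#' @param population data.frame with columns `sex`, `age_class`, `count`
#'   (regional person counts; strata missing from `cases` count zero cases).
#' @return data.frame `sex`, `age_class`, `rate`.
#' @export
global_stratum_rates <- function(cases, population) {
  stopifnot(all(c("sex", "age_class", "cases") %in% names(cases)),
            all(c("sex", "age_class", "count") %in% names(population)))
  key_p <- paste(population$sex, population$age_class)
  key_c <- paste(cases$sex, cases$age_class)
  if (!all(key_c %in% key_p)) {
    stop("cases observed in strata absent from the population table")
  }
  n_cases <- cases$cases[match(key_p, key_c)]
  n_cases[is.na(n_cases)] <- 0
  if (any(n_cases > 0 & population$count <= 0)) {
    stop("cases observed in a zero-population stratum")
  }
  rate <- ifelse(population$count > 0, n_cases / population$count, 0)
  data.frame(sex = population$sex, age_class = population$age_class,
             rate = rate)
}

#' Expected case counts by municipality
#'
#' Second step of indirect standardization: applies global stratum rates to
#' each municipality's stratum populations (or a single crude rate to totals
#' when the snapshot carries no strata). When the rates were derived from the
#' same snapshot, expected counts sum to the total case count.
#'
#' @param snapshot an `at_risk_snapshot` from [population_at_risk()].
#' @param rates either a data.frame from [global_stratum_rates()] (stratified
#'   snapshot) or a single crude rate (totals-only snapshot).
#' @return named numeric vector of expected counts per municipality.
#' @export
expected_counts <- function(snapshot, rates) {
  stopifnot(inherits(snapshot, "at_risk_snapshot"))
  if (snapshot$stratified && is.data.frame(rates)) {
    st <- snapshot$strata
    key <- paste(st$sex, st$age_class)
    rkey <- paste(rates$sex, rates$age_class)
    m <- match(key, rkey)
    if (anyNA(m)) stop("strata mismatch between snapshot and rates")
    e <- st$pop * rates$rate[m]
    out <- tapply(e, st$municipality_id, sum)
    res <- as.numeric(out)[match(names(snapshot$totals), names(out))]
    names(res) <- names(snapshot$totals)
    res
  } else {
    if (is.data.frame(rates)) {
      stop("snapshot is totals-only; supply a single crude rate")
    }
    stopifnot(is.numeric(rates), length(rates) == 1, rates >= 0)
    snapshot$totals * rates
  }
}
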