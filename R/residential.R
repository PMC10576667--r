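# Residential histories: location-at-offset queries, completeness, address
# stability between onset and diagnosis, and shared-dwelling extraction.

.check_residences <- function(residences) {
  need <- c("patient_id", "dwelling_id", "municipality_id", "start_date",
            "end_date")
  if (!all(need %in% names(residences))) {
    stop("residences must have columns: ", paste(need, collapse = ", "))
  }
  if (!inherits(residences$start_date, "Date") ||
      !inherits(residences$end_date, "Date")) {
    stop("start_date and end_date must be Date columns")
  }
  if (any(residences$end_date < residences$start_date)) {
    stop("residence intervals must have end >= start")
  }
  invisible(residences)
}

# residence row index covering `date` for each (patient, date) pair; NA when
# no interval covers the date
.interval_at <- function(residences, patient_id, date) {
  hit <- rep(NA_integer_, length(patient_id))
  idx <- split(seq_len(nrow(residences)), residences$patient_id)
  for (i in seq_along(patient_id)) {
    rows <- idx[[as.character(patient_id[i])]]
    if (is.null(rows)) next
    ok <- rows[residences$start_date[rows] <= date[i] &
                 residences$end_date[rows] >= date[i]]
    if (length(ok)) hit[i] <- ok[1]
  }
  hit
}

#' Municipality of residence k years before onset
#'
#' Looks up the residence interval containing the date exactly `k` years
#' before each patient's onset (same calendar day; February 29 maps to
#' February 28) and returns its municipality, or `NA` when the history does
#' not reach back that far.
#'
#' @param residences residence-record data.frame (`patient_id`,
#'   `dwelling_id`, `municipality_id`, `start_date`, `end_date`).
#' @param patients data.frame with at least `patient_id` and `onset_date`.
#' @param k integer offset in `[0, 50]`.
#' @return character vector of municipality ids named by patient id; `NA`
#'   where the location is unknown.
#' @export
location_at_offset <- function(residences, patients, k) {
  .check_residences(residences)
  k <- as.integer(k)
  if (is.na(k) || k < 0 || k > 50) stop("offset k must be in [0, 50]")
  target <- shift_years(patients$onset_date, k)
  hit <- .interval_at(residences, patients$patient_id, target)
  out <- ifelse(is.na(hit), NA_character_,
                as.character(residences$municipality_id[hit]))
  names(out) <- patients$patient_id
  out
}

#' Fraction of the cohort with unknown location per offset
#'
#' @inheritParams location_at_offset
#' @param offsets integer vector of offsets (default 0 to 50).
#' @return data.frame `offset`, `fraction_missing`.
#' @export
completeness_profile <- function(residences, patients, offsets = 0:50) {
  if (nrow(patients) == 0) stop("empty cohort")
  miss <- vapply(offsets, function(k) {
    mean(is.na(location_at_offset(residences, patients, k)))
  }, numeric(1))
  data.frame(offset = offsets, fraction_missing = miss)
}

#' Address stability between onset and diagnosis
#'
#' A patient is "unchanged" when the dwelling of residence at onset equals
#' the dwelling at diagnosis.
#'
#' @inheritParams location_at_offset
#' @return list with `n_unchanged`, `n`, and `percent_unchanged` (one
#'   decimal).
#' @export
address_stability <- function(residences, patients) {
  .check_residences(residences)
  if (nrow(patients) == 0) stop("empty cohort")
  if (any(patients$diagnosis_date < patients$onset_date)) {
    stop("diagnosis before onset")
  }
  at_on <- .interval_at(residences, patients$patient_id, patients$onset_date)
  at_dx <- .interval_at(residences, patients$patient_id,
                        patients$diagnosis_date)
  d_on <- residences$dwelling_id[at_on]
  d_dx <- residences$dwelling_id[at_dx]
  unchanged <- !is.na(d_on) & !is.na(d_dx) & d_on == d_dx
  list(n_unchanged = sum(unchanged), n = nrow(patients),
       percent_unchanged = round(100 * mean(unchanged), 1))
}

# total months (mean-month = 30.44 days) during which the two patients'
# intervals in one dwelling overlap
.overlap_months <- function(recs_a, recs_b) {
  tot <- 0
  for (i in seq_len(nrow(recs_a))) {
    lo <- pmax(recs_a$start_date[i], recs_b$start_date)
    hi <- pmin(recs_a$end_date[i], recs_b$end_date)
    d <- as.numeric(hi - lo, units = "days") + 1
    tot <- tot + sum(d[d > 0])
  }
  tot / 30.44
}

#' Dwellings shared by multiple unrelated patients
#'
#' Groups residence records by dwelling and reports dwellings housing two or
#' more distinct patients, after dropping occurrences in which any two
#' patients are relatives or any patient carries a known pathogenic variant.
#' For pairs, the months of simultaneous residence are reported (0 when the
#' two stays never overlapped in time).
#'
#' @inheritParams location_at_offset
#' @param patients data.frame with `patient_id`, `genetic_status` (one of
#'   `"positive"`, `"wild-type"`, `"missing"`) and `relatedness_group`
#'   (`NA` for patients with no known relatives in the cohort).
#' @param city optional municipality id: only residence records in this
#'   municipality are considered.
#' @param include_missing_genetic if `TRUE` (default) patients with unknown
#'   genetic status remain eligible; only known positives trigger exclusion.
#' @return an object of class `shared_dwellings`: list with `dwellings`
#'   (data.frame `dwelling_id`, `multiplicity`, `patients`,
#'   `overlap_months`), `exclusions` (data.frame `dwelling_id`, `reason`)
#'   and `counts` (named vector `pairs`, `trios`, `higher`).
#' @export
find_shared_dwellings <- function(residences, patients, city = NULL,
                                  include_missing_genetic = TRUE) {
  .check_residences(residences)
  key <- paste(residences$patient_id, residences$dwelling_id,
               residences$start_date, residences$end_date)
  if (any(duplicated(key))) {
    stop("duplicate (patient, dwelling, interval) residence records")
  }
  recs <- residences
  if (!is.null(city)) {
    recs <- recs[recs$municipality_id == city, , drop = FALSE]
  }
  gstat <- patients$genetic_status[match(recs$patient_id,
                                         patients$patient_id)]
  rgrp <- patients$relatedness_group[match(recs$patient_id,
                                           patients$patient_id)]

  by_dw <- split(seq_len(nrow(recs)), recs$dwelling_id)
  out <- list()
  excl <- list()
  for (dw in names(by_dw)) {
    rows <- by_dw[[dw]]
    pats <- unique(as.character(recs$patient_id[rows]))
    if (length(pats) < 2) next
    g <- gstat[rows][match(pats, recs$patient_id[rows])]
    r <- rgrp[rows][match(pats, recs$patient_id[rows])]
    r_known <- r[!is.na(r)]
    if (any(duplicated(r_known))) {
      excl[[length(excl) + 1]] <- data.frame(dwelling_id = dw,
                                             reason = "relatedness")
      next
    }
    bad <- g == "positive"
    if (!include_missing_genetic) bad <- bad | g == "missing"
    if (any(bad, na.rm = TRUE)) {
      excl[[length(excl) + 1]] <- data.frame(dwelling_id = dw,
                                             reason = "gene-positive")
      next
    }
    ov <- NA_real_
    if (length(pats) == 2) {
      ov <- .overlap_months(
        recs[rows[recs$patient_id[rows] == pats[1]], , drop = FALSE],
        recs[rows[recs$patient_id[rows] == pats[2]], , drop = FALSE])
    }
    out[[length(out) + 1]] <- data.frame(
      dwelling_id = dw, multiplicity = length(pats),
      patients = paste(sort(pats), collapse = ";"), overlap_months = ov)
  }
  dwellings <- if (length(out)) do.call(rbind, out) else
    data.frame(dwelling_id = character(), multiplicity = integer(),
               patients = character(), overlap_months = numeric())
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dwelling_id = character(), reason = character())
  counts <- c(pairs = sum(dwellings$multiplicity == 2),
              trios = sum(dwellings$multiplicity == 3),
              higher = sum(dwellings$multiplicity >= 4))
  structure(list(dwellings = dwellings, exclusions = exclusions,
                 counts = counts),
            class = "shared_dwellings")
}

#' @export
print.shared_dwellings <- function(x, ...) {
  cat("Shared dwellings:", x$counts["pairs"], "pairs,", x$counts["trios"],
      "trios", if (x$counts["higher"] > 0)
        paste(",", x$counts["higher"], "with >3 patients") else "", "\n")
  cat("  excluded occurrences:", nrow(x$exclusions), "\n")
  invisible(x)
}
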