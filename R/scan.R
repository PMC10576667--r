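# Circular spatial scan with a Poisson likelihood-ratio statistic and Monte
# Carlo inference (conditional on the total case count), in the style of the
# classic scan-statistic software: circles of growing radius around every
# municipality centroid, capped at a fraction of the total population at
# risk.

#' Enumerate candidate circular zones
#'
#' For every centroid, municipalities are sorted by distance (ties broken by
#' municipality id) and cumulative prefixes are retained while the zone
#' population stays within `max_fraction` of the regional total. Duplicate
#' member sets arising from different centers are removed. A center whose own
#' population already exceeds the cap yields no zone (a warning lists such
#' centers).
#'
#' @param centroids data.frame `municipality_id`, `x`, `y` (projected meters
#'   by default; lon/lat with `coord_mode = "lonlat"`).
#' @param populations named numeric vector of populations at risk, names
#'   matching `municipality_id`.
#' @param max_fraction largest allowed zone population as a fraction of the
#'   total (default 0.25).
#' @param coord_mode `"planar"` (Euclidean, default) or `"lonlat"`
#'   (great-circle).
#' @return list of zones; each zone is a list with `center`, `radius`,
#'   `members` (character vector of ids) and `population`.
#' @export
enumerate_zones <- function(centroids, populations, max_fraction = 0.25,
                            coord_mode = c("planar", "lonlat")) {
  coord_mode <- match.arg(coord_mode)
  stopifnot(nrow(centroids) >= 1, max_fraction > 0, max_fraction <= 1)
  ids <- as.character(centroids$municipality_id)
  pop <- populations[ids]
  if (anyNA(pop)) stop("populations missing for some municipalities")
  if (any(pop < 0)) stop("populations must be non-negative")
  dm <- .distance_matrix(centroids$x, centroids$y, coord_mode)
  cap <- max_fraction * sum(pop)

  zones <- list()
  seen <- character(0)
  capped_out <- character(0)
  for (i in seq_along(ids)) {
    ord <- order(dm[i, ], ids)          # distance, then id for determinism
    cum <- cumsum(pop[ord])
    dsort <- dm[i, ord]
    # a prefix is a circle only if it does not split a distance-tie group
    circle_end <- c(dsort[-1] > dsort[-length(dsort)], TRUE)
    valid <- which(cum <= cap & circle_end)
    if (length(valid) == 0) {
      if (!any(cum <= cap)) capped_out <- c(capped_out, ids[i])
      next
    }
    for (k in valid) {
      members <- ids[ord[seq_len(k)]]
      key <- paste(sort(members), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      zones[[length(zones) + 1]] <- list(
        center = ids[i], radius = dm[i, ord[k]], members = members,
        population = unname(cum[k]))
    }
  }
  if (length(capped_out)) {
    warning("no zone for center(s) exceeding the population cap: ",
            paste(capped_out, collapse = ", "))
  }
  zones
}

# 0/1 membership matrix (zones x municipalities)
.zone_matrix <- function(zones, ids) {
  Z <- matrix(0, length(zones), length(ids),
              dimnames = list(NULL, ids))
  for (j in seq_along(zones)) Z[j, zones[[j]]$members] <- 1
  Z
}

# vectorized LLR over zone counts; degenerate zones (E <= 0 or E >= C) score 0
.zone_llr <- function(c_in, e_in, C, direction) {
  n <- max(length(c_in), length(e_in))
  c_in <- rep_len(c_in, n)
  e_in <- rep_len(e_in, n)
  llr <- numeric(n)
  ok <- e_in > 0 & e_in < C
  gate <- if (direction == "high") c_in > e_in else c_in < e_in
  sel <- ok & gate
  if (any(sel)) {
    cc <- c_in[sel]
    ee <- e_in[sel]
    t1 <- ifelse(cc == 0, 0, cc * log(cc / ee))
    t2 <- ifelse(cc == C, 0, (C - cc) * log((C - cc) / (C - ee)))
    llr[sel] <- t1 + t2
  }
  llr
}

#' Poisson scan log-likelihood ratio
#'
#' The log-likelihood ratio comparing in-zone to out-of-zone incidence under
#' the conditional Poisson model:
#' `LLR = c log(c/E) + (C - c) log((C - c)/(C - E))`, with the `0 log 0 = 0`
#' convention, and 0 when the direction condition fails (`high` requires
#' `c > E`, `low` requires `c < E`).
#'
#' @param c observed in-zone cases.
#' @param E expected in-zone cases (0 < E < C).
#' @param C total cases.
#' @param direction `"high"` (excess) or `"low"` (deficit).
#' @return non-negative LLR (vectorized over `c` and `E`).
#' @examples
#' poisson_llr(150, 105, 1124)  # 9.51
#' @export
poisson_llr <- function(c, E, C, direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(length(C) == 1, C > 0)
  if (any(E <= 0) || any(E >= C)) stop("E must satisfy 0 < E < C")
  if (any(c < 0) || any(c > C)) stop("c must satisfy 0 <= c <= C")
  .zone_llr(c, E, C, direction)
}

#' Relative risk of a scan zone
#'
#' In-zone versus out-of-zone risk from observed and expected counts:
#' `RR = (c/E) / ((C - c)/(C - E))`. Returns `Inf` when all cases fall in
#' the zone.
#'
#' @inheritParams poisson_llr
#' @return relative risk (vectorized over `c` and `E`).
#' @examples
#' relative_risk(150, 105, 1124)  # 1.49
#' @export
relative_risk <- function(c, E, C) {
  stopifnot(length(C) == 1, C > 0)
  if (any(E <= 0) || any(E >= C)) stop("E must satisfy 0 < E < C")
  if (any(c < 0) || any(c > C)) stop("c must satisfy 0 <= c <= C")
  ifelse(c == C, Inf, (c / E) / ((C - c) / (C - E)))
}

#' Scan one case map for clusters
#'
#' Finds the most likely cluster (maximum LLR over candidate zones) and
#' ranked non-overlapping secondary clusters, with Monte Carlo p-values.
#' Replicates redistribute the `C` cases over municipalities with
#' probabilities proportional to the expected counts (the conditional null);
#' `p = (1 + #{replicate max >= observed}) / (1 + R)`. High- and
#' low-incidence scans are run as separate tracks.
#'
#' @param cases named numeric vector of observed cases per municipality.
#' @param expected named numeric vector of expected counts (same names,
#'   summing to `sum(cases)`).
#' @param zones zone list from [enumerate_zones()].
#' @param directions subset of `c("high", "low")`.
#' @param R number of Monte Carlo replicates (default 999).
#' @param seed integer seed; required whenever `R > 0`.
#' @param max_reported maximum number of ranked clusters per direction.
#' @return object of class `scan_result`: `clusters` data.frame (`direction`,
#'   `rank`, `center`, `members`, `n_members`, `c`, `E`, `RR`, `LLR`, `p`),
#'   plus the per-direction null max-LLR distributions, `R` and `seed`.
#' @export
scan_once <- function(cases, expected, zones,
                      directions = c("high", "low"), R = 999, seed = NULL,
                      max_reported = 5) {
  if (length(zones) == 0) stop("no candidate zones")
  directions <- match.arg(directions, c("high", "low"), several.ok = TRUE)
  ids <- names(cases)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(expected))))
  expected <- expected[ids]
  C <- sum(cases)
  if (abs(sum(expected) - C) > 1e-6 * max(1, C)) {
    stop("expected counts must sum to the total case count")
  }
  if (R > 0 && is.null(seed)) stop("a seed is required when R > 0")

  Z <- .zone_matrix(zones, ids)
  zc <- as.vector(Z %*% cases)
  zE <- as.vector(Z %*% expected)

  null_max <- list()
  if (R > 0) {
    set.seed(as.integer(seed))
    sims <- stats::rmultinom(R, C, expected / C)   # municipalities x R
    zsim <- Z %*% sims                             # zones x R
    for (d in directions) {
      lm <- .zone_llr(as.vector(zsim), rep(zE, times = R), C, d)
      dim(lm) <- c(length(zones), R)
      null_max[[d]] <- apply(lm, 2, max)
    }
  }

  rows <- list()
  for (d in directions) {
    llr <- .zone_llr(zc, zE, C, d)
    ord <- order(llr, decreasing = TRUE)
    taken <- character(0)
    rank <- 0
    for (j in ord) {
      if (llr[j] <= 0 || rank >= max_reported) break
      mem <- zones[[j]]$members
      if (any(mem %in% taken)) next
      rank <- rank + 1
      taken <- c(taken, mem)
      p <- if (R > 0) {
        (1 + sum(null_max[[d]] >= llr[j])) / (1 + R)
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        direction = d, rank = rank, center = zones[[j]]$center,
        members = paste(mem, collapse = ";"), n_members = length(mem),
        c = zc[j], E = zE[j],
        RR = relative_risk(zc[j], zE[j], C), LLR = llr[j], p = p)
    }
    if (rank == 0) {
      # flat map: no zone exceeds its expectation in this direction
      p1 <- if (R > 0) 1.0 else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        direction = d, rank = 1, center = NA_character_,
        members = "", n_members = 0L, c = NA_real_, E = NA_real_,
        RR = NA_real_, LLR = 0, p = p1)
    }
  }
  structure(list(clusters = do.call(rbind, rows), null_max = null_max,
                 C = C, R = R, seed = seed),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Spatial scan:", x$C, "cases,", x$R, "Monte Carlo replicates\n")
  print(x$clusters[, c("direction", "rank", "center", "n_members", "c", "E",
                       "RR", "LLR", "p")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Time-shifted cluster scan across pre-onset offsets
#'
#' Runs the full per-offset pipeline: locate every patient `k` years before
#' their onset, average the populations of the contributing calendar years
#' into a population at risk, compute expected counts (sex/age standardized
#' when every contributing year carries strata, crude otherwise), enumerate
#' zones and scan. Patients whose history does not reach offset `k` are
#' dropped from the numerator at that offset; the population denominator is
#' not reduced.
#'
#' @param patients cohort data.frame (`patient_id`, `sex`, `birth_date`,
#'   `onset_date`).
#' @param residences residence records (see [location_at_offset()]).
#' @param pop a [stratified_population()].
#' @param centroids data.frame `municipality_id`, `x`, `y`.
#' @param offsets integer offsets to scan (default 0:50).
#' @param max_fraction zone population cap (default 0.25).
#' @param directions scan directions (default high and low).
#' @param R Monte Carlo replicates per offset (default 999).
#' @param seed master seed; per-offset replicate streams are spawned from it
#'   so each offset is reproducible on its own via the reported seed.
#' @param weight_years see [population_at_risk()].
#' @return object of class `timeshift_scan`: `summary` data.frame with one
#'   row per (offset, direction, rank) and a `per_offset` list of
#'   `scan_result` objects (named by offset).
#' @export
timeshift_scan <- function(patients, residences, pop, centroids,
                           offsets = 0:50, max_fraction = 0.25,
                           directions = c("high", "low"), R = 999,
                           seed = NULL, weight_years = FALSE) {
  if (R > 0 && is.null(seed)) stop("a seed is required when R > 0")
  seeds <- if (R > 0) .spawn_seeds(seed, length(offsets)) else
    rep(NA_integer_, length(offsets))
  ids <- as.character(centroids$municipality_id)

  per_offset <- list()
  rows <- list()
  for (oi in seq_along(offsets)) {
    k <- offsets[oi]
    loc <- location_at_offset(residences, patients, k)
    located <- !is.na(loc)
    if (!any(located)) stop("no patient has a known location at offset ", k)
    snap <- population_at_risk(pop, k,
                               as.integer(format(patients$onset_date,
                                                 "%Y")),
                               weight_years = weight_years)
    cases <- table(factor(loc[located], levels = ids))
    cases <- stats::setNames(as.numeric(cases), ids)
    C <- sum(cases)

    if (snap$stratified) {
      age_then <- floor(as.numeric(
        shift_years(patients$onset_date, k) - patients$birth_date) / 365.25)
      cdf <- data.frame(sex = patients$sex[located],
                        age_class = age_class_of(pmax(0, age_then[located])),
                        cases = 1)
      cases_strat <- stats::aggregate(cases ~ sex + age_class, cdf, sum)
      reg <- stats::aggregate(pop ~ sex + age_class, snap$strata, sum)
      names(reg)[names(reg) == "pop"] <- "count"
      rates <- global_stratum_rates(cases_strat, reg)
      E <- expected_counts(snap, rates)
    } else {
      E <- expected_counts(snap, C / sum(snap$totals))
    }

    zones <- enumerate_zones(centroids[match(ids,
                                             centroids$municipality_id), ],
                             snap$totals, max_fraction)
    res <- scan_once(cases, E, zones, directions = directions, R = R,
                     seed = seeds[oi])
    per_offset[[as.character(k)]] <- res
    cl <- res$clusters
    cl <- cbind(offset = k, cl, n_located = sum(located),
                replicate_seed = seeds[oi])
    rows[[length(rows) + 1]] <- cl
  }
  structure(list(summary = do.call(rbind, rows), per_offset = per_offset,
                 offsets = offsets, R = R, seed = seed),
            class = "timeshift_scan")
}

#' @export
print.timeshift_scan <- function(x, ...) {
  cat("Time-shifted scan over offsets",
      paste(range(x$offsets), collapse = "-"), "years before onset\n")
  mlc <- x$summary[x$summary$rank == 1 & x$summary$direction == "high", ]
  print(mlc[, c("offset", "center", "n_members", "c", "E", "RR", "p")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
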