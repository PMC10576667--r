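# Synthetic registry fixtures: a region with heterogeneous municipality
# populations and census structure (decadal totals early on, annual sex/age
# strata later), a patient cohort with residential histories and an optional
# implanted elevated-risk zone, and a city-scale dwelling registry with a
# heavy-tailed capacity distribution. All generators are deterministic for a
# given seed.

#' Default regional sex/age pyramid
#'
#' One pyramid applied to every municipality: shares over the 16 sex-by-age
#' strata, loosely shaped like an aged Western European population.
#'
#' @return data.frame `sex`, `age_class`, `share` (shares sum to 1).
#' @export
default_pyramid <- function() {
  age_share <- c(0.24, 0.12, 0.15, 0.15, 0.13, 0.11, 0.08, 0.02)
  male_frac <- c(0.51, 0.50, 0.50, 0.50, 0.49, 0.47, 0.42, 0.30)
  data.frame(
    sex = rep(sex_levels(), each = 8),
    age_class = rep(age_classes(), 2),
    share = c(age_share * male_frac, age_share * (1 - male_frac)))
}

#' Default disease-incidence weights per sex/age stratum
#'
#' Relative incidence used to draw case strata: strongly age-dependent with
#' a late-life peak and a modest male excess, as in motor neuron disease.
#'
#' @return data.frame `sex`, `age_class`, `weight`.
#' @export
default_stratum_weights <- function() {
  inc <- c(0.1, 0.5, 1.2, 3, 7, 12, 9, 3)   # per 100k person-years, roughly
  data.frame(
    sex = rep(sex_levels(), each = 8),
    age_class = rep(age_classes(), 2),
    weight = c(inc * 1.2, inc))
}

#' Specify an implanted elevated-risk zone
#'
#' @param members municipality ids forming the zone.
#' @param multiplier relative-risk multiplier (> 0) applied inside the zone.
#' @param window inclusive pair of offsets (years before onset) during which
#'   the multiplier is active, within `[0, 50]`.
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(members, multiplier, window) {
  stopifnot(length(members) >= 1, multiplier > 0, length(window) == 2,
            window[1] <= window[2], window[1] >= 0, window[2] <= 50)
  structure(list(members = as.character(members),
                 multiplier = multiplier,
                 window = as.integer(window)),
            class = "cluster_spec")
}

#' Generate a synthetic region with census structure
#'
#' Municipality populations follow a heavy-tailed (log-normal) law with one
#' "metropolis" forced to hold `metro_share` of the regional total. Total
#' counts exist at decadal census years and annually thereafter; annual
#' years additionally carry the full sex/age breakdown obtained from a
#' single regional pyramid. Every year's counts are apportioned so that the
#' regional total is met exactly and strata sum exactly to municipality
#' totals.
#'
#' @param n_municipalities number of municipalities (>= 1).
#' @param total_population regional total, constant across years (default
#'   mirrors a region of ~4.4 million).
#' @param metro_share population share of the largest municipality.
#' @param sdlog log-normal dispersion of the remaining municipality sizes.
#' @param growth_sd standard deviation of per-municipality log drift over
#'   the study span (0 freezes all population shares over time).
#' @param census_years years with totals only (default decadal 1951-1981).
#' @param annual_years years with full strata (default 1982-2014).
#' @param pyramid regional pyramid (see [default_pyramid()]).
#' @param extent side length, in meters, of the square the centroids are
#'   scattered over.
#' @param seed integer seed (required).
#' @return a `region_fixture`: list with `municipalities` (data.frame
#'   `municipality_id`, `name`, `x`, `y`), `population` (a
#'   [stratified_population()]), the pyramid and the generation parameters.
#' @export
generate_region <- function(n_municipalities, total_population = 4416475,
                            metro_share = 0.2, sdlog = 1.2, growth_sd = 0.1,
                            census_years = c(1951, 1961, 1971, 1981),
                            annual_years = 1982:2014,
                            pyramid = default_pyramid(),
                            extent = 1e5, seed) {
  stopifnot(n_municipalities >= 1, total_population >= n_municipalities,
            sdlog > 0, metro_share > 0, metro_share < 1,
            abs(sum(pyramid$share) - 1) < 1e-8)
  set.seed(as.integer(seed))
  n <- n_municipalities
  ids <- sprintf("M%04d", seq_len(n))

  if (n == 1) {
    w <- 1
  } else {
    w <- stats::rlnorm(n - 1, 0, sdlog)
    w <- c(metro_share / (1 - metro_share) * sum(w), w)
  }
  x <- stats::runif(n, 0, extent)
  y <- stats::runif(n, 0, extent)

  all_years <- sort(unique(c(census_years, annual_years)))
  span <- diff(range(all_years))
  drift <- stats::rnorm(n, 0, growth_sd)
  ref <- max(all_years)
  totals_l <- lapply(all_years, function(yr) {
    wy <- w * exp(drift * (yr - ref) / max(1, span))
    data.frame(municipality_id = ids, year = yr,
               count = .integerize(wy, total_population))
  })
  totals <- do.call(rbind, totals_l)

  # full sex/age strata for the annual years, integerized per municipality
  shares <- pyramid$share
  strata <- do.call(rbind, lapply(annual_years, function(yr) {
    tot_y <- totals$count[totals$year == yr]
    mat <- .integerize_rows(tot_y, shares)   # n x 16
    data.frame(municipality_id = rep(ids, times = length(shares)),
               year = yr,
               sex = rep(pyramid$sex, each = n),
               age_class = rep(pyramid$age_class, each = n),
               count = as.vector(mat))
  }))

  pop <- stratified_population(
    totals[totals$year %in% setdiff(all_years, annual_years), ], strata)
  structure(list(
    municipalities = data.frame(municipality_id = ids,
                                name = sprintf("Municipality %04d",
                                               seq_len(n)),
                                x = x, y = y),
    population = pop, pyramid = pyramid,
    total_population = total_population,
    census_years = census_years, annual_years = annual_years,
    seed = seed), class = "region_fixture")
}

#' @export
print.region_fixture <- function(x, ...) {
  cat("Synthetic region:", nrow(x$municipalities), "municipalities,",
      format(x$total_population, big.mark = ","), "residents\n")
  print(x$population)
  invisible(x)
}

# interpolate the missing-history curve at integer offsets 0..50
.missing_curve <- function(anchors) {
  stats::approx(anchors$offset, anchors$fraction, xout = 0:50, rule = 2)$y
}

#' Generate a synthetic patient cohort with residential histories
#'
#' Patients receive an onset date, sex/age stratum (pyramid times incidence
#' weights), a genetic status and a backward residential trajectory. At each
#' offset the marginal distribution of the municipality of residence is
#' multinomial with probabilities proportional to the population at that
#' calendar year, multiplied by the cluster's relative-risk multiplier
#' inside its member set during its active window. Trajectories are made
#' temporally coherent with a yearly move hazard: between moves the
#' municipality is carried over with a maximal-coupling step, which
#' preserves the per-offset multinomial exactly while keeping addresses
#' stable for `mean_stay` years on average. Histories are left-truncated
#' according to a missingness curve (and never precede birth).
#'
#' @param region a [generate_region()] fixture.
#' @param n_cases number of patients.
#' @param cluster optional [cluster_spec()].
#' @param onset_years calendar years the onsets are drawn from (uniformly).
#' @param stratum_weights incidence weights (see
#'   [default_stratum_weights()]).
#' @param mean_stay mean years between address changes (default 50/3.6, so
#'   a full 50-year history averages 3.6 moves).
#' @param truncation_anchors data.frame `offset`, `fraction`: probability
#'   that the history is missing at that offset (linearly interpolated in
#'   between; defaults 0.6% at onset, 10.5% at 40 and 19.7% at 50 years).
#' @param genetic_probs named probabilities for `positive`, `wild-type`,
#'   `missing` status.
#' @param move_after_onset probability of an address change between onset
#'   and diagnosis.
#' @param seed integer seed (required).
#' @return list with `patients`, `residences` (see
#'   [location_at_offset()] for the schemas), the `cluster` used, and
#'   `trajectory` (matrix of municipality ids, patients by offsets 0-50,
#'   `NA` beyond the truncation point).
#' @export
generate_cohort <- function(region, n_cases, cluster = NULL,
                            onset_years = 2007:2014,
                            stratum_weights = default_stratum_weights(),
                            mean_stay = 50 / 3.6,
                            truncation_anchors = data.frame(
                              offset = c(0, 40, 50),
                              fraction = c(0.006, 0.105, 0.197)),
                            genetic_probs = c(positive = 0.092,
                                              `wild-type` = 0.721,
                                              missing = 0.187),
                            move_after_onset = 0.006, seed) {
  stopifnot(inherits(region, "region_fixture"), n_cases >= 1)
  if (!is.null(cluster)) {
    stopifnot(inherits(cluster, "cluster_spec"))
    if (!all(cluster$members %in% region$municipalities$municipality_id)) {
      stop("cluster members must belong to the region")
    }
  }
  if (all(stratum_weights$weight <= 0)) stop("empty stratum weights")
  set.seed(as.integer(seed))
  ids <- region$municipalities$municipality_id
  n_m <- length(ids)
  pop <- region$population

  pid <- sprintf("P%05d", seq_len(n_cases))
  onset_year <- sample(onset_years, n_cases, replace = TRUE)
  onset_date <- as.Date(sprintf("%d-01-01", onset_year)) +
    sample(0:364, n_cases, replace = TRUE)

  # sex/age stratum: pyramid x incidence weight
  pkey <- paste(region$pyramid$sex, region$pyramid$age_class)
  wkey <- paste(stratum_weights$sex, stratum_weights$age_class)
  pr <- region$pyramid$share *
    stratum_weights$weight[match(pkey, wkey)]
  si <- sample(seq_along(pkey), n_cases, replace = TRUE, prob = pr)
  sex <- region$pyramid$sex[si]
  acl <- region$pyramid$age_class[si]
  lo <- .age_breaks[match(acl, age_classes())]
  hi <- pmin(.age_breaks[match(acl, age_classes()) + 1], 95)
  age <- lo + floor(stats::runif(n_cases) * (hi - lo))
  birth_date <- shift_years(onset_date, age) -
    sample(0:364, n_cases, replace = TRUE)
  diagnosis_date <- onset_date +
    round(stats::rlnorm(n_cases, log(274), 0.5))
  genetic_status <- sample(names(genetic_probs), n_cases, replace = TRUE,
                           prob = genetic_probs)

  # truncation offsets: P(history missing at k) follows the anchor curve,
  # capped at age (no residence before birth)
  mcurve <- .missing_curve(truncation_anchors)
  u <- stats::runif(n_cases)
  first_ge <- vapply(u, function(ui) {
    j <- which(mcurve >= ui)
    if (length(j)) j[1] - 2L else 50L    # offset of last covered year
  }, integer(1))
  last_offset <- pmin(first_ge, age)

  # backward trajectories, grouped by onset year so the per-offset target
  # distribution is shared within a group
  p_move <- 1 - exp(-1 / mean_stay)
  traj <- matrix(NA_integer_, n_cases, 51)
  target_probs <- function(yr, k) {
    p <- .totals_at_year(pop, yr - k)
    if (!is.null(cluster) && k >= cluster$window[1] &&
        k <= cluster$window[2]) {
      p[cluster$members] <- p[cluster$members] * cluster$multiplier
    }
    p / sum(p)
  }
  for (yr in sort(unique(onset_year))) {
    g <- which(onset_year == yr)
    pi_prev <- target_probs(yr, 0)
    traj[g, 1] <- sample.int(n_m, length(g), replace = TRUE, prob = pi_prev)
    for (k in 1:50) {
      pi_k <- target_probs(yr, k)
      cur <- traj[g, k]
      mv <- stats::runif(length(g)) < p_move
      nxt <- cur
      if (any(mv)) {
        nxt[mv] <- sample.int(n_m, sum(mv), replace = TRUE, prob = pi_k)
      }
      stay <- which(!mv)
      if (length(stay)) {
        ratio <- pi_k[cur[stay]] / pi_prev[cur[stay]]
        rej <- stats::runif(length(stay)) > ratio
        if (any(rej)) {
          excess <- pmax(pi_k - pi_prev, 0)
          if (sum(excess) > 1e-12) {
            nxt[stay[rej]] <- sample.int(n_m, sum(rej), replace = TRUE,
                                         prob = excess)
          }
        }
      }
      traj[g, k + 1] <- nxt
      pi_prev <- pi_k
    }
  }
  # blank out offsets beyond the truncation point
  for (i in seq_len(n_cases)) {
    if (last_offset[i] < 50) {
      traj[i, seq(last_offset[i] + 2, 51)] <- NA_integer_
    }
  }

  # compress trajectories into residence intervals (newest last)
  res <- vector("list", n_cases)
  movers_dx <- stats::runif(n_cases) < move_after_onset
  for (i in seq_len(n_cases)) {
    L <- last_offset[i]
    if (L < 0) next                      # no usable history at all
    path <- traj[i, seq_len(L + 1)]      # offsets 0..L
    r <- rle(rev(path))                  # oldest first
    k_hi <- L - c(0, cumsum(r$lengths)[-length(r$lengths)])
    k_lo <- k_hi - r$lengths + 1
    start <- shift_years(onset_date[i], k_hi)
    end <- c(shift_years(onset_date[i], k_hi[-1]) - 1,
             diagnosis_date[i] + 30)
    dwell <- sprintf("DW-%s-%02d", pid[i], seq_along(r$values))
    df <- data.frame(patient_id = pid[i], dwelling_id = dwell,
                     municipality_id = ids[r$values],
                     start_date = start, end_date = end)
    if (movers_dx[i] && diagnosis_date[i] > onset_date[i] + 1) {
      j <- nrow(df)
      split_at <- onset_date[i] +
        floor(stats::runif(1) *
                as.numeric(diagnosis_date[i] - onset_date[i]))
      new <- df[j, ]
      new$dwelling_id <- sprintf("DW-%s-dx", pid[i])
      new$start_date <- split_at + 1
      df$end_date[j] <- split_at
      df <- rbind(df, new)
    }
    res[[i]] <- df
  }
  residences <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(residences) <- NULL

  patients <- data.frame(
    patient_id = pid, sex = sex, age_class = acl, birth_date = birth_date,
    onset_date = onset_date, diagnosis_date = diagnosis_date,
    genetic_status = genetic_status, relatedness_group = NA_character_)
  traj_id <- matrix(ids[traj], n_cases, 51,
                    dimnames = list(pid, 0:50))
  list(patients = patients, residences = residences, cluster = cluster,
       trajectory = traj_id, seed = seed)
}

#' Generate a synthetic city dwelling registry
#'
#' Resident capacities are drawn from a truncated log-normal law, forced to
#' be at least 1 each, and apportioned so they sum exactly to the configured
#' number of residents. Defaults mirror a large city's stock of ~39k
#' dwellings housing ~870k residents (mean capacity ~22).
#'
#' @param n_dwellings number of dwellings (>= 1).
#' @param total_residents total resident capacity (>= `n_dwellings`).
#' @param sdlog log-normal dispersion of capacities (heavier tail for
#'   larger values).
#' @param max_capacity optional cap on any single capacity.
#' @param seed integer seed (required).
#' @return a `dwelling_registry` data.frame: `dwelling_id`, `capacity`.
#' @export
generate_dwelling_registry <- function(n_dwellings = 39184,
                                       total_residents = 870474,
                                       sdlog = 1, max_capacity = Inf,
                                       seed) {
  stopifnot(n_dwellings >= 1, total_residents >= n_dwellings,
            sdlog > 0, max_capacity >= 1)
  set.seed(as.integer(seed))
  z <- stats::rlnorm(n_dwellings, 0, sdlog)
  cap <- 1L + .integerize(z, total_residents - n_dwellings)
  if (is.finite(max_capacity) && any(cap > max_capacity)) {
    # clamp and push the excess onto dwellings still under the cap
    repeat {
      over <- cap > max_capacity
      if (!any(over)) break
      excess <- sum(cap[over] - max_capacity)
      cap[over] <- as.integer(max_capacity)
      room <- which(cap < max_capacity)
      if (length(room) == 0 && excess > 0) {
        stop("infeasible: total residents exceed n_dwellings * max_capacity")
      }
      add <- .integerize(max_capacity - cap[room], excess)
      cap[room] <- cap[room] + pmin(add, max_capacity - cap[room])
      if (sum(cap) == total_residents) break
    }
  }
  structure(data.frame(dwelling_id = sprintf("T%05d", seq_len(n_dwellings)),
                       capacity = cap),
            total_residents = total_residents, seed = seed,
            class = c("dwelling_registry", "data.frame"))
}
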