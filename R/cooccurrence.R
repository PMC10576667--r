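# Monte Carlo null for unrelated patients sharing dwellings: patients are
# repeatedly reallocated over a city's dwelling stock with probability
# proportional to resident capacity, and the number of dwellings receiving
# exactly two or exactly three distinct patients is tallied per iteration.

#' Default address-count law
#'
#' Number of distinct addresses per simulated patient: `3 + Bernoulli(0.6)`,
#' i.e. 3 or 4 with mean 3.6, matching the observed mean number of address
#' changes in city cohorts.
#'
#' @param n number of patients.
#' @return integer vector of address counts.
#' @export
address_law_mean36 <- function(n) 3L + stats::rbinom(n, 1L, 0.6)

# capacity-proportional sampling with replacement via inverse-CDF lookup
.sample_capacity <- function(n, cum_w) {
  findInterval(stats::runif(n), cum_w) + 1L
}

# one patient's distinct-dwelling draw: capacity-proportional draws with
# replacement, redrawing collisions until k distinct dwellings are held
# (the "no dwelling twice" rule)
.draw_distinct <- function(k, cum_w, n_dw) {
  d <- unique(.sample_capacity(k, cum_w))
  while (length(d) < k) {
    d <- unique(c(d, .sample_capacity(k - length(d), cum_w)))
  }
  d
}

#' Simulate one reallocation of patients over dwellings
#'
#' Each patient draws an address count from `address_law`, then occupies that
#' many distinct dwellings, each draw proportional to resident capacity; a
#' draw landing on a dwelling the patient already holds is redrawn, so no
#' patient occupies the same dwelling twice within an iteration.
#'
#' @param registry a [generate_dwelling_registry()] result or data.frame with
#'   `dwelling_id` and `capacity`.
#' @param n_patients number of patients to place.
#' @param address_law function of `n` returning integer address counts
#'   (default [address_law_mean36()]).
#' @param seed optional integer seed.
#' @return list of character vectors: the dwelling ids held by each patient.
#' @export
simulate_iteration <- function(registry, n_patients,
                               address_law = address_law_mean36,
                               seed = NULL) {
  reg <- as.data.frame(registry)
  stopifnot(all(c("dwelling_id", "capacity") %in% names(reg)),
            n_patients >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_dw <- nrow(reg)
  k <- as.integer(address_law(n_patients))
  if (any(k < 1)) stop("address counts must be >= 1")
  if (any(k > n_dw)) stop("address count exceeds the registry size")
  cum_w <- cumsum(reg$capacity) / sum(reg$capacity)
  lapply(k, function(ki) as.character(reg$dwelling_id)[
    .draw_distinct(ki, cum_w, n_dw)])
}

#' Count dwellings shared by 2, 3 or more patients
#'
#' @param sequences list of per-patient dwelling-id vectors (as produced by
#'   [simulate_iteration()]).
#' @return list with `pairs` (dwellings held by exactly 2 distinct
#'   patients), `trios` (exactly 3) and `higher` (4 or more).
#' @export
count_cooccurrences <- function(sequences) {
  if (length(sequences) == 0) {
    return(list(pairs = 0L, trios = 0L, higher = 0L))
  }
  tab <- table(unlist(lapply(sequences, unique)))
  list(pairs = sum(tab == 2L), trios = sum(tab == 3L),
       higher = sum(tab >= 4L))
}

#' Build the co-occurrence null distribution
#'
#' Runs `R` independent reallocation iterations and records, for each, the
#' number of pair- and trio-dwellings.
#'
#' @inheritParams simulate_iteration
#' @param R number of iterations (default 2000).
#' @param seed integer seed (required).
#' @return object of class `cooccurrence_null`: integer vectors `pairs` and
#'   `trios` of length `R`, `higher`, plus the configuration.
#' @export
run_null <- function(registry, n_patients,
                     address_law = address_law_mean36, R = 2000, seed) {
  stopifnot(R >= 1)
  reg <- as.data.frame(registry)
  set.seed(as.integer(seed))
  n_dw <- nrow(reg)
  cum_w <- cumsum(reg$capacity) / sum(reg$capacity)
  pairs <- integer(R)
  trios <- integer(R)
  higher <- integer(R)
  for (r in seq_len(R)) {
    k <- as.integer(address_law(n_patients))
    if (any(k < 1) || any(k > n_dw)) {
      stop("address counts must be in [1, number of dwellings]")
    }
    # all patients' draws at once; collisions within a patient (first
    # occurrence kept) are redrawn until every patient holds distinct
    # dwellings -- the same redraw-on-collision rule as
    # simulate_iteration, vectorized over patients
    pat <- rep.int(seq_len(n_patients), k)
    draws <- .sample_capacity(length(pat), cum_w)
    repeat {
      dup <- duplicated(pat * (n_dw + 1L) + draws)
      if (!any(dup)) break
      draws[dup] <- .sample_capacity(sum(dup), cum_w)
    }
    tab <- tabulate(tabulate(draws, nbins = n_dw), nbins = n_patients)
    pairs[r] <- if (n_patients >= 2) tab[2] else 0L
    trios[r] <- if (n_patients >= 3) tab[3] else 0L
    higher[r] <- if (n_patients >= 4) sum(tab[4:n_patients]) else 0L
  }
  structure(list(pairs = pairs, trios = trios, higher = higher, R = R,
                 n_patients = n_patients, seed = seed,
                 n_dwellings = n_dw),
            class = "cooccurrence_null")
}

#' @export
print.cooccurrence_null <- function(x, ...) {
  cat("Dwelling co-occurrence null:", x$R, "iterations,", x$n_patients,
      "patients over", x$n_dwellings, "dwellings\n")
  cat("  pair-dwellings:  mean", round(mean(x$pairs), 2), " range",
      paste(range(x$pairs), collapse = "-"), "\n")
  cat("  trio-dwellings:  mean", round(mean(x$trios), 2), " range",
      paste(range(x$trios), collapse = "-"), "\n")
  invisible(x)
}

#' Tail probability of the observed co-occurrence counts
#'
#' @param null a [run_null()] result.
#' @param observed_pairs,observed_trios observed counts.
#' @param convention `"raw"` (default): `P = #{simulated >= observed} / R`;
#'   `"plus-one"`: `(1 + #) / (1 + R)`.
#' @return named numeric vector `P_pairs`, `P_trios`.
#' @export
cooccurrence_probability <- function(null, observed_pairs, observed_trios,
                                     convention = c("raw", "plus-one")) {
  stopifnot(inherits(null, "cooccurrence_null"),
            observed_pairs >= 0, observed_trios >= 0)
  convention <- match.arg(convention)
  tail_p <- function(sim, obs) {
    if (convention == "raw") mean(sim >= obs) else
      (1 + sum(sim >= obs)) / (1 + null$R)
  }
  c(P_pairs = tail_p(null$pairs, observed_pairs),
    P_trios = tail_p(null$trios, observed_trios))
}

#' Capacity-restricted re-analysis
#'
#' Repeats the co-occurrence analysis after excluding large dwellings. In
#' quantile mode the capacity ceiling is set from the observed
#' co-occurrence dwellings themselves: the top `value` fraction by capacity
#' is excluded (exclusion count rounded down, ties broken by larger
#' capacity then dwelling id) and the ceiling is the largest capacity among
#' those kept. In ceiling mode the cap is given directly. The null is then
#' re-simulated over the restricted registry (dwellings with capacity at or
#' below the ceiling) and compared with the observed counts recounted among
#' restricted dwellings.
#'
#' @param registry the full dwelling registry.
#' @param observed data.frame of observed co-occurrence dwellings:
#'   `dwelling_id`, `capacity`, `multiplicity`.
#' @param restriction list with `mode` (`"quantile"` or `"ceiling"`) and
#'   `value` (fraction in (0, 1] or an absolute capacity).
#' @inheritParams run_null
#' @return list with `ceiling`, `n_excluded`, `n_dwellings_kept`,
#'   `observed_pairs`, `observed_trios`, `P_pairs`, `P_trios` and the
#'   restricted `null`.
#' @export
restrict_and_rerun <- function(registry, observed, restriction, n_patients,
                               address_law = address_law_mean36, R = 2000,
                               seed) {
  reg <- as.data.frame(registry)
  stopifnot(all(c("dwelling_id", "capacity", "multiplicity") %in%
                  names(observed)))
  mode <- match.arg(restriction$mode, c("quantile", "ceiling"))
  if (mode == "quantile") {
    frac <- restriction$value
    if (nrow(observed) == 0) stop("quantile mode needs observed dwellings")
    stopifnot(frac > 0, frac <= 1)
    n_excl <- floor(frac * nrow(observed))
    ord <- order(-observed$capacity, as.character(observed$dwelling_id))
    kept <- observed[ord, ][-seq_len(n_excl), , drop = FALSE]
    if (n_excl == 0) kept <- observed
    if (nrow(kept) == 0) stop("restriction excludes every observed dwelling")
    ceiling_cap <- max(kept$capacity)
  } else {
    n_excl <- NA_integer_
    ceiling_cap <- restriction$value
    stopifnot(ceiling_cap >= 1)
  }
  reg_r <- reg[reg$capacity <= ceiling_cap, , drop = FALSE]
  if (nrow(reg_r) == 0) stop("capacity ceiling excludes the whole registry")

  obs_r <- observed[observed$capacity <= ceiling_cap, , drop = FALSE]
  obs_pairs <- sum(obs_r$multiplicity == 2)
  obs_trios <- sum(obs_r$multiplicity == 3)
  null <- run_null(reg_r, n_patients, address_law, R, seed)
  p <- cooccurrence_probability(null, obs_pairs, obs_trios)
  list(ceiling = ceiling_cap, n_excluded = n_excl,
       n_dwellings_kept = nrow(reg_r),
       observed_pairs = obs_pairs, observed_trios = obs_trios,
       P_pairs = unname(p["P_pairs"]), P_trios = unname(p["P_trios"]),
       null = null)
}
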