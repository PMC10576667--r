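# Shared fixture builders: everything is constructed in code at test time.

# A minimal stratified population: two municipalities, decadal totals from
# 1951 to 1981 and full strata for annual years >= 1982.
tiny_population <- function(munis = c("A", "B"),
                            base = c(A = 6000, B = 4000),
                            strata_years = 1982:2014) {
  census_years <- c(1951, 1961, 1971, 1981)
  totals <- expand.grid(municipality_id = munis, year = census_years,
                        stringsAsFactors = FALSE)
  totals$count <- base[totals$municipality_id]
  shares <- default_pyramid()
  strata <- do.call(rbind, lapply(strata_years, function(yr) {
    do.call(rbind, lapply(munis, function(m) {
      cnt <- presymscan:::.integerize(shares$share, base[[m]])
      data.frame(municipality_id = m, year = yr, sex = shares$sex,
                 age_class = shares$age_class, count = cnt)
    }))
  }))
  stratified_population(totals, strata)
}

# One patient with an explicit sequence of residence intervals.
make_history <- function(pid, onset, diagnosis = as.Date(onset) + 270,
                         intervals) {
  res <- do.call(rbind, lapply(seq_along(intervals), function(j) {
    iv <- intervals[[j]]
    data.frame(patient_id = pid,
               dwelling_id = iv$dwelling %||% sprintf("%s-d%d", pid, j),
               municipality_id = iv$muni,
               start_date = as.Date(iv$start),
               end_date = as.Date(iv$end))
  }))
  pat <- data.frame(patient_id = pid, sex = "M", age_class = "65-74",
                    birth_date = as.Date(onset) - 25000,
                    onset_date = as.Date(onset),
                    diagnosis_date = as.Date(diagnosis),
                    genetic_status = "wild-type",
                    relatedness_group = NA_character_)
  list(patients = pat, residences = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bind_cohort <- function(...) {
  hs <- list(...)
  list(patients = do.call(rbind, lapply(hs, `[[`, "patients")),
       residences = do.call(rbind, lapply(hs, `[[`, "residences")))
}

# Exact distribution of (pair, trio) dwelling counts under the co-occurrence
# null, by enumeration. Patients draw their dwelling sets by successive
# capacity-weighted sampling without replacement (the scheme the simulator
# realizes by redrawing collisions). Supports k in {1, 2} addresses.
exact_cooccurrence_dist <- function(capacity, k_per_patient) {
  w <- capacity / sum(capacity)
  n_dw <- length(capacity)
  set_dist <- lapply(k_per_patient, function(k) {
    stopifnot(k %in% c(1, 2))
    if (k == 1) {
      sets <- as.list(seq_len(n_dw))
      probs <- w
    } else {
      cmb <- utils::combn(n_dw, 2)
      sets <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
      probs <- apply(cmb, 2, function(s) {
        w[s[1]] * w[s[2]] / (1 - w[s[1]]) +
          w[s[2]] * w[s[1]] / (1 - w[s[2]])
      })
    }
    list(sets = sets, probs = probs)
  })
  grid <- do.call(expand.grid, lapply(set_dist, function(d)
    seq_along(d$sets)))
  out <- new.env()
  for (r in seq_len(nrow(grid))) {
    pr <- 1
    held <- integer(0)
    for (i in seq_along(set_dist)) {
      j <- grid[r, i]
      pr <- pr * set_dist[[i]]$probs[j]
      held <- c(held, set_dist[[i]]$sets[[j]])
    }
    tab <- table(held)
    key <- paste(sum(tab == 2), sum(tab == 3), sep = ",")
    out[[key]] <- (out[[key]] %||% 0) + pr
  }
  probs <- unlist(as.list(out))
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  probs
}
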