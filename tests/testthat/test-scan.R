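test_that("LLR matches the worked example and direction gating", {
  expect_equal(poisson_llr(105, 105, 1124), 0)
  expect_equal(round(poisson_llr(150, 105, 1124), 2), 9.51)
  # a deficit scores zero on the high track and positive on the low track
  expect_equal(poisson_llr(50, 105, 1124, "high"), 0)
  expect_gt(poisson_llr(50, 105, 1124, "low"), 0)
  expect_error(poisson_llr(10, 0, 100), "E must")
  expect_error(poisson_llr(10, 100, 100), "E must")
})

test_that("relative risk matches the worked example and edge contracts", {
  expect_equal(round(relative_risk(150, 105, 1124), 2), 1.49)
  expect_equal(relative_risk(105, 105, 1124), 1.0)
  expect_equal(relative_risk(1124, 105, 1124), Inf)
  expect_equal(relative_risk(0, 105, 1124), 0)
  expect_error(relative_risk(10, 0, 100), "E must")
})

test_that("LLR and RR agree with independent evaluation and are monotone", {
  # independent oracle: the likelihood terms evaluated in a different
  # algebraic arrangement
  oracle_llr <- function(c, E, C) {
    if (c <= E) return(0)
    t1 <- c * (log(c) - log(E))
    t2 <- if (c == C) 0 else (C - c) * (log(C - c) - log(C - E))
    t1 + t2
  }
  oracle_rr <- function(c, E, C) (c * (C - E)) / (E * (C - c))
  set.seed(7)
  for (i in 1:1000) {
    C <- sample(10:5000, 1)
    E <- runif(1, 0.5, C - 0.5)
    c <- sample(0:C, 1)
    expect_equal(poisson_llr(c, E, C, "high"),
                 oracle_llr(c, E, C), tolerance = 1e-10)
    if (c < C) {
      expect_equal(relative_risk(c, E, C), oracle_rr(c, E, C),
                   tolerance = 1e-10)
    }
  }
  # strict monotonicity in c (E, C fixed, c > E)
  C <- 500; E <- 60
  llr <- poisson_llr(61:499, E, C, "high")
  rr <- relative_risk(61:499, E, C)
  expect_true(all(diff(llr) > 0))
  expect_true(all(diff(rr) > 0))
})

line_centroids <- function(n) {
  data.frame(municipality_id = sprintf("L%d", seq_len(n)),
             x = seq_len(n) * 1000, y = 0)
}

test_that("zone enumeration yields distance-sorted prefixes under the cap", {
  cen <- line_centroids(3)
  pop <- stats::setNames(c(10, 10, 10), cen$municipality_id)

  # cap never binds: all distance-sorted prefixes from each center
  z <- enumerate_zones(cen, pop, max_fraction = 1.0)
  keys <- sort(vapply(z, function(zz) paste(sort(zz$members),
                                            collapse = "|"), ""))
  expect_equal(keys, sort(c("L1", "L2", "L3", "L1|L2", "L2|L3",
                            "L1|L2|L3")))
  for (zz in z) {
    expect_true(zz$center %in% zz$members)
    expect_equal(zz$population, sum(pop[zz$members]))
  }

  # a single municipality holds 100% > 25%: no zone at all
  cen1 <- line_centroids(1)
  expect_warning(z1 <- enumerate_zones(cen1, c(L1 = 10),
                                       max_fraction = 0.25), "cap")
  expect_length(z1, 0)

  expect_error(enumerate_zones(data.frame(municipality_id = "A", x = NaN,
                                          y = 0), c(A = 1)), "finite")
})

# brute force: every (center, radius) circle whose population respects the
# cap, deduplicated by member set
brute_zone_keys <- function(cen, pop, max_fraction) {
  d <- as.matrix(dist(cen[, c("x", "y")]))
  ids <- cen$municipality_id
  keys <- character(0)
  for (i in seq_along(ids)) {
    for (r in sort(unique(d[i, ]))) {
      members <- ids[d[i, ] <= r]
      if (sum(pop[members]) <= max_fraction * sum(pop)) {
        keys <- c(keys, paste(sort(members), collapse = "|"))
      }
    }
  }
  sort(unique(keys))
}

test_that("zone enumeration equals exhaustive center-radius enumeration", {
  set.seed(31)
  for (n in 3:6) {
    for (rep in 1:3) {
      cen <- data.frame(municipality_id = sprintf("M%d", 1:n),
                        x = runif(n, 0, 100), y = runif(n, 0, 100))
      pop <- stats::setNames(sample(5:50, n), cen$municipality_id)
      for (frac in c(0.5, 1.0)) {
        z <- suppressWarnings(enumerate_zones(cen, pop, frac))
        keys <- sort(vapply(z, function(zz)
          paste(sort(zz$members), collapse = "|"), ""))
        expect_equal(keys, brute_zone_keys(cen, pop, frac))
      }
    }
  }
  # the spec case: 4 equal municipalities on a line, cap 0.5
  cen <- line_centroids(4)
  pop <- stats::setNames(rep(10, 4), cen$municipality_id)
  z <- enumerate_zones(cen, pop, 0.5)
  keys <- sort(vapply(z, function(zz) paste(sort(zz$members),
                                            collapse = "|"), ""))
  expect_equal(keys, brute_zone_keys(cen, pop, 0.5))
})

test_that("scan identifies a maximal concentration and ranks p-values", {
  cen <- line_centroids(4)
  pop <- stats::setNames(rep(100, 4), cen$municipality_id)
  zones <- enumerate_zones(cen, pop, max_fraction = 1.0)
  E <- stats::setNames(rep(25, 4), cen$municipality_id)

  # all cases piled in one municipality: that singleton is the MLC
  cases <- stats::setNames(c(0, 100, 0, 0), cen$municipality_id)
  res <- scan_once(cases, E, zones, directions = "high", R = 999, seed = 5)
  mlc <- res$clusters[res$clusters$rank == 1, ]
  expect_equal(mlc$members, "L2")
  # observed LLR beyond every replicate: p at the lower rank bound
  expect_equal(mlc$p, 1 / 1000)

  # flat map: observed max LLR 0 -> p = 1
  flat <- stats::setNames(rep(25, 4), cen$municipality_id)
  res0 <- scan_once(flat, E, zones, directions = "high", R = 99, seed = 5)
  expect_equal(res0$clusters$p[1], 1.0)
  expect_equal(res0$clusters$LLR[1], 0)

  # contracts
  expect_error(scan_once(cases, E, zones, R = 999), "seed")
  expect_error(scan_once(cases, E, list(), R = 0), "zones")
  expect_error(scan_once(cases, E * 2, zones, R = 0), "sum")

  # determinism: identical replicate stream for identical seeds
  r1 <- scan_once(cases, E, zones, R = 199, seed = 11)
  r2 <- scan_once(cases, E, zones, R = 199, seed = 11)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("secondary clusters are disjoint from higher-ranked ones", {
  set.seed(13)
  cen <- data.frame(municipality_id = sprintf("M%d", 1:12),
                    x = runif(12, 0, 100), y = runif(12, 0, 100))
  pop <- stats::setNames(rep(50, 12), cen$municipality_id)
  zones <- enumerate_zones(cen, pop, max_fraction = 0.5)
  E <- stats::setNames(rep(10, 12), cen$municipality_id)
  cases <- stats::setNames(as.numeric(rmultinom(1, 120, rep(1, 12))),
                           cen$municipality_id)
  res <- scan_once(cases, E, zones, directions = "high", R = 99, seed = 3)
  cl <- res$clusters
  mem <- strsplit(cl$members, ";")
  if (nrow(cl) > 1) {
    for (i in 2:nrow(cl)) {
      for (j in 1:(i - 1)) {
        expect_length(intersect(mem[[i]], mem[[j]]), 0)
      }
    }
  }
  expect_true(all(cl$p >= 1 / 100 & cl$p <= 1))
})

test_that("a cohort that never moves scans identically at every offset", {
  totals <- data.frame(
    municipality_id = rep(c("A", "B", "C"), 2),
    year = rep(c(1950, 2020), each = 3),
    count = rep(c(500, 300, 200), 2))
  pop <- stratified_population(totals)
  cen <- data.frame(municipality_id = c("A", "B", "C"),
                    x = c(0, 1000, 5000), y = 0)
  pats <- data.frame(
    patient_id = sprintf("p%d", 1:30), sex = "M", age_class = "65-74",
    birth_date = as.Date("1940-01-01"),
    onset_date = as.Date("2005-06-01"),
    diagnosis_date = as.Date("2006-06-01"))
  res <- data.frame(
    patient_id = pats$patient_id,
    dwelling_id = sprintf("d%d", 1:30),
    municipality_id = rep(c("A", "A", "B"), 10),
    start_date = as.Date("1950-01-01"),
    end_date = as.Date("2007-01-01"))
  ts <- timeshift_scan(pats, res, pop, cen, offsets = 0:3, R = 49,
                       max_fraction = 0.6, seed = 21)
  s <- ts$summary
  base <- s[s$offset == 0, c("direction", "rank", "members", "c", "E",
                             "RR", "LLR")]
  for (k in 1:3) {
    expect_equal(s[s$offset == k, c("direction", "rank", "members", "c",
                                    "E", "RR", "LLR")],
                 base, ignore_attr = TRUE)
  }
})
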