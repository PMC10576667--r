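test_that("location at offset follows interval containment", {
  h <- make_history("p1", onset = "2010-06-15", intervals = list(
    list(muni = "A", start = "1950-01-01", end = "2011-12-31")))
  for (k in c(0, 10, 50)) {
    expect_equal(unname(location_at_offset(h$residences, h$patients, k)),
                 "A")
  }

  # truncated history: missing beyond the first recorded interval
  h2 <- make_history("p2", onset = "2010-06-15", intervals = list(
    list(muni = "A", start = "2000-06-15", end = "2011-12-31")))
  expect_equal(unname(location_at_offset(h2$residences, h2$patients, 20)),
               NA_character_)

  # move from A to B exactly 5 years before onset
  h3 <- make_history("p3", onset = "2010-06-15", intervals = list(
    list(muni = "A", start = "1980-01-01", end = "2005-06-14"),
    list(muni = "B", start = "2005-06-15", end = "2011-12-31")))
  expect_equal(unname(location_at_offset(h3$residences, h3$patients, 6)),
               "A")
  expect_equal(unname(location_at_offset(h3$residences, h3$patients, 4)),
               "B")

  expect_error(location_at_offset(h3$residences, h3$patients, -1),
               "\\[0, 50\\]")
  expect_error(location_at_offset(h3$residences, h3$patients, 51),
               "\\[0, 50\\]")
})

test_that("location lookup agrees with brute-force date containment", {
  set.seed(99)
  coh <- bind_cohort(
    make_history("q1", onset = "2012-02-29", intervals = list(
      list(muni = "A", start = "1970-03-05", end = "1991-10-20"),
      list(muni = "B", start = "1991-10-21", end = "2004-01-31"),
      list(muni = "C", start = "2004-02-01", end = "2012-12-31"))),
    make_history("q2", onset = "2008-07-01", intervals = list(
      list(muni = "B", start = "1999-01-01", end = "2009-12-31"))))
  for (k in 0:50) {
    got <- location_at_offset(coh$residences, coh$patients, k)
    for (i in seq_len(nrow(coh$patients))) {
      pid <- coh$patients$patient_id[i]
      # brute force: same calendar day k years earlier, Feb 29 -> Feb 28
      on <- as.POSIXlt(coh$patients$onset_date[i])
      yy <- on$year + 1900 - k
      dd <- if (on$mon == 1 && on$mday == 29 &&
                !((yy %% 4 == 0 && yy %% 100 != 0) || yy %% 400 == 0))
        28 else on$mday
      target <- as.Date(sprintf("%d-%02d-%02d", yy, on$mon + 1, dd))
      rows <- coh$residences[coh$residences$patient_id == pid, ]
      want <- NA_character_
      for (j in seq_len(nrow(rows))) {
        if (rows$start_date[j] <= target && target <= rows$end_date[j]) {
          want <- rows$municipality_id[j]
        }
      }
      expect_identical(unname(got[pid]), want)
    }
  }
})

test_that("completeness profile counts missing locations per offset", {
  full <- lapply(1:3, function(i) {
    make_history(paste0("f", i), onset = "2010-01-01", intervals = list(
      list(muni = "A", start = "1950-01-01", end = "2011-01-01")))
  })
  trunc <- make_history("t1", onset = "2010-01-01", intervals = list(
    list(muni = "A", start = "2000-06-01", end = "2011-01-01")))
  coh <- do.call(bind_cohort, c(full, list(trunc)))
  prof <- completeness_profile(coh$residences, coh$patients, 0:20)
  expect_equal(prof$fraction_missing[prof$offset <= 9], rep(0, 10))
  expect_equal(prof$fraction_missing[prof$offset > 10], rep(0.25, 10))
  expect_error(completeness_profile(coh$residences,
                                    coh$patients[0, ]), "empty")
})

test_that("address stability compares dwellings at onset and diagnosis", {
  stay <- make_history("s1", onset = "2010-01-01",
                       diagnosis = as.Date("2010-10-01"),
                       intervals = list(
    list(muni = "A", start = "1990-01-01", end = "2011-01-01",
         dwelling = "d-stay")))
  move <- make_history("m1", onset = "2010-01-01",
                       diagnosis = as.Date("2010-10-01"),
                       intervals = list(
    list(muni = "A", start = "1990-01-01", end = "2010-05-01",
         dwelling = "d-old"),
    list(muni = "A", start = "2010-05-02", end = "2011-01-01",
         dwelling = "d-new")))
  coh <- bind_cohort(stay, move)
  st <- address_stability(coh$residences, coh$patients)
  expect_equal(st$n_unchanged, 1)
  expect_equal(st$percent_unchanged, 50.0)

  st_all <- address_stability(stay$residences, stay$patients)
  expect_equal(st_all$percent_unchanged, 100.0)

  expect_error(address_stability(coh$residences, coh$patients[0, ]),
               "empty")
  bad <- coh$patients
  bad$diagnosis_date[1] <- bad$onset_date[1] - 1
  expect_error(address_stability(coh$residences, bad), "diagnosis")
})

shared_fixture <- function(status = c("wild-type", "wild-type", "wild-type"),
                           groups = c(NA, NA, NA)) {
  res <- data.frame(
    patient_id = c("a", "b", "c", "a"),
    dwelling_id = c("dw1", "dw1", "dw1", "dw2"),
    municipality_id = "CITY1",
    start_date = as.Date(c("1980-01-01", "1985-01-01", "1990-01-01",
                           "2000-01-01")),
    end_date = as.Date(c("1989-12-31", "1994-12-31", "1999-12-31",
                         "2010-12-31")))
  pats <- data.frame(patient_id = c("a", "b", "c"),
                     genetic_status = status,
                     relatedness_group = groups)
  list(res = res, pats = pats)
}

test_that("shared dwellings count pairs and trios with exclusions", {
  fx <- shared_fixture()
  sd <- find_shared_dwellings(fx$res, fx$pats)
  expect_equal(unname(sd$counts["trios"]), 1)
  expect_equal(unname(sd$counts["pairs"]), 0)

  # relatives sharing a dwelling are excluded entirely
  fx2 <- shared_fixture(groups = c("fam1", "fam1", NA))
  sd2 <- find_shared_dwellings(fx2$res, fx2$pats)
  expect_equal(sum(sd2$counts), 0)
  expect_equal(sd2$exclusions$reason, "relatedness")

  # a known gene-positive patient voids the occurrence
  fx3 <- shared_fixture(status = c("positive", "wild-type", "wild-type"))
  sd3 <- find_shared_dwellings(fx3$res, fx3$pats)
  expect_equal(sum(sd3$counts), 0)
  expect_equal(sd3$exclusions$reason, "gene-positive")

  # missing genetic status stays eligible by default, excludable on demand
  fx4 <- shared_fixture(status = c("missing", "wild-type", "wild-type"))
  expect_equal(unname(find_shared_dwellings(fx4$res,
                                            fx4$pats)$counts["trios"]), 1)
  sd4 <- find_shared_dwellings(fx4$res, fx4$pats,
                               include_missing_genetic = FALSE)
  expect_equal(sum(sd4$counts), 0)

  expect_error(find_shared_dwellings(rbind(fx$res, fx$res[1, ]), fx$pats),
               "duplicate")
})

test_that("shared-dwelling extraction is order-invariant and accounted", {
  fx <- shared_fixture(status = c("positive", "wild-type", "wild-type"))
  extra <- data.frame(patient_id = c("b", "c"), dwelling_id = "dw9",
                      municipality_id = "CITY1",
                      start_date = as.Date(c("1970-01-01", "1971-01-01")),
                      end_date = as.Date(c("1975-12-31", "1972-12-31")))
  res <- rbind(fx$res, extra)
  sd_fwd <- find_shared_dwellings(res, fx$pats)
  sd_rev <- find_shared_dwellings(res[rev(seq_len(nrow(res))), ], fx$pats)
  expect_equal(sd_fwd$counts, sd_rev$counts)
  expect_equal(sort(sd_fwd$dwellings$dwelling_id),
               sort(sd_rev$dwellings$dwelling_id))
  # exclusion log + counted occurrences = all multi-patient dwellings
  expect_equal(nrow(sd_fwd$dwellings) + nrow(sd_fwd$exclusions), 2)
})

test_that("pair overlap months equal the day-level intersection", {
  res <- data.frame(
    patient_id = c("a", "b"),
    dwelling_id = "dw1",
    municipality_id = "CITY1",
    start_date = as.Date(c("2000-01-01", "2003-01-01")),
    end_date = as.Date(c("2004-12-31", "2010-12-31")))
  pats <- data.frame(patient_id = c("a", "b"),
                     genetic_status = "wild-type",
                     relatedness_group = NA_character_)
  sd <- find_shared_dwellings(res, pats)
  # oracle: count the actual shared days
  days <- length(intersect(
    seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = "day"),
    seq(as.Date("2003-01-01"), as.Date("2010-12-31"), by = "day")))
  expect_equal(sd$dwellings$overlap_months, days / 30.44)

  # disjoint stays share the dwelling but never in time
  res2 <- res
  res2$start_date[2] <- as.Date("2006-01-01")
  sd2 <- find_shared_dwellings(res2, pats)
  expect_equal(sd2$dwellings$overlap_months, 0)
})
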