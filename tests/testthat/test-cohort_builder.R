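cfg <- study_config()

test_that("first in-period diagnosis is the earliest DM/PM date in the study window", {
  ev <- mk_events("p1", c("2017-03-01", "2018-01-01"), c("PM", "DM"))
  expect_equal(first_iim_diagnosis(ev, cfg), as.Date("2017-03-01"))

  pre <- mk_events("p1", "2015-06-01", "DM")
  expect_true(is.na(first_iim_diagnosis(pre, cfg)))
  expect_true(is.na(first_iim_diagnosis(mk_events(character(), character(),
                                                  character()), cfg)))
})

test_that("eligibility screen applies its checks in the fixed order", {
  ev <- mk_events("p1", "2017-06-15", "DM")
  pat <- mk_patient(activity_start = "2016-01-01", activity_end = "2020-01-01")
  expect_equal(check_eligibility(pat, ev, as.Date("2017-06-15"), cfg), "pass")

  early <- mk_events("p1", "2016-03-01", "DM")
  pat2 <- mk_patient(activity_start = "2016-01-01")
  expect_equal(check_eligibility(pat2, early, as.Date("2016-03-01"), cfg),
               "insufficient_pre_activity")

  prior <- mk_events("p1", c("2015-12-01", "2016-07-01"), c("DM", "DM"))
  expect_equal(check_eligibility(mk_patient(), prior, as.Date("2016-07-01"), cfg),
               "prior_iim_dx")

  expect_equal(check_eligibility(mk_patient(in_idn = FALSE), ev,
                                 as.Date("2017-06-15"), cfg), "not_in_idn")
  short <- mk_patient(activity_end = "2017-09-01")
  expect_equal(check_eligibility(short, ev, as.Date("2017-06-15"), cfg),
               "insufficient_post_activity")
})

test_that("EAW scoring weights inpatient diagnoses double and tracks the last diagnosis", {
  w0 <- as.Date("2017-01-10")
  w1 <- add_months(w0, 6)
  ev <- mk_events("p1", c("2017-01-10", "2017-02-01", "2017-03-01"),
                  c("DM", "DM", "PM"),
                  setting = c("inpatient", "outpatient", "outpatient"))
  s <- score_eaw(ev, w0, w1, cfg)
  expect_equal(s$dm_count, 3L)
  expect_equal(s$pm_count, 1L)
  expect_equal(s$dm_outpatient_n, 1)
  expect_equal(s$pm_outpatient_n, 1)
  expect_true(s$has_any_inpatient)
  expect_equal(s$last_dx_subtype, "PM")

  two_pm <- mk_events("p1", c("2017-01-10", "2017-04-01"), c("PM", "PM"))
  s2 <- score_eaw(two_pm, w0, w1, cfg)
  expect_equal(c(s2$dm_count, s2$pm_count), c(0L, 2L))

  tie <- mk_events("p1", c("2017-01-10", "2017-02-01", "2017-03-05"),
                   c("DM", "PM", "PM"),
                   setting = c("inpatient", "outpatient", "outpatient"))
  s3 <- score_eaw(tie, w0, w1, cfg)
  expect_equal(c(s3$dm_count, s3$pm_count), c(2L, 2L))
  expect_equal(s3$last_dx_subtype, "PM")

  # window is half-open: a diagnosis on the end date is outside
  edge <- mk_events("p1", c("2017-01-10", as.character(w1)), c("DM", "PM"))
  s4 <- score_eaw(edge, w0, w1, cfg)
  expect_equal(s4$pm_count, 0L)

  none <- score_eaw(mk_events("p1", "2016-01-01", "DM"), w0, w1, cfg)
  expect_true(none$degenerate)
})

test_that("subtype assignment follows max count, tie-to-last, and the outpatient-only gate", {
  s <- function(dm, pm, last = "DM", any_in = TRUE, dm_out = 0, pm_out = 0) {
    list(dm_count = dm, pm_count = pm, dm_outpatient_n = dm_out,
         pm_outpatient_n = pm_out, has_any_inpatient = any_in,
         last_dx_subtype = last, degenerate = FALSE)
  }
  expect_equal(assign_subtype(s(3, 1), cfg), "DM")
  expect_equal(assign_subtype(s(2, 2, last = "PM"), cfg), "PM")
  expect_true(is.na(assign_subtype(s(1, 0, any_in = FALSE, dm_out = 1), cfg)))
  expect_equal(assign_subtype(s(2, 0, any_in = FALSE, dm_out = 2), cfg), "DM")
  # same-day tie: later input row wins through last_dx_subtype
  same_day <- mk_events("p1", c("2017-01-10", "2017-01-10"), c("DM", "PM"),
                        setting = "inpatient")
  sc_ <- score_eaw(same_day, as.Date("2017-01-10"), as.Date("2017-07-10"), cfg)
  expect_equal(assign_subtype(sc_, cfg), "PM")
})

test_that("cohort builder splits juvenile and adult cohorts at the index date", {
  pat <- dplyr::bind_rows(
    mk_patient("j1", birth_date = "2004-03-01"),
    mk_patient("a1", birth_date = "1967-09-01"),
    mk_patient("u1", birth_date = "2010-01-01")
  )
  ev <- mk_events(c("j1", "j1", "a1", "a1", "u1", "u1"),
                  c("2017-03-01", "2017-04-01", "2017-03-01", "2017-04-01",
                    "2017-07-01", "2017-08-01"),
                  c("DM", "DM", "PM", "PM", "DM", "DM"))
  res <- build_cohorts(pat, ev, cfg)
  a <- res$assignments
  expect_equal(a$cohort[a$patient_id == "j1"], "JDM")
  expect_equal(a$index_date[a$patient_id == "j1"], as.Date("2017-09-01"))
  expect_equal(a$age_at_index[a$patient_id == "j1"], 13L)
  expect_equal(a$cohort[a$patient_id == "a1"], "PM")
  expect_equal(as.character(res$exclusions$reason[res$exclusions$patient_id == "u1"]),
               "under_min_age")
})

test_that("every in-period diagnosed patient lands in exactly one output", {
  sc <- simulation_scenario(n_cases = 120, n_background = 240,
                            misclass_prob = 0.3, under_min_age_fraction = 0.1,
                            seed = 21)
  pop <- simulate_population(sc, cfg)
  res <- build_cohorts(pop$patients, pop$events, cfg)
  diagnosed <- unique(pop$events$patient_id[
    pop$events$category %in% c("DM", "PM") &
      pop$events$event_class == "diagnosis" &
      pop$events$date >= cfg$study_start & pop$events$date <= cfg$study_end])
  ids <- c(res$assignments$patient_id, as.character(res$exclusions$patient_id))
  expect_setequal(ids, diagnosed)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("perfect-recovery: zero miscoding assigns every case its true subtype", {
  sc <- simulation_scenario(n_cases = 200, n_background = 0, misclass_prob = 0,
                            seed = 13)
  pop <- simulate_population(sc, cfg)
  res <- build_cohorts(pop$patients, pop$events, cfg)
  expect_equal(nrow(res$exclusions), 0)
  expect_equal(nrow(res$assignments), 200)
  truth <- pop$truth$patients
  expect_equal(res$assignments$subtype,
               truth$true_subtype[match(res$assignments$patient_id,
                                        truth$patient_id)])
})

test_that("assignment accuracy does not increase with the miscoding rate", {
  acc <- vapply(c(0, 0.15, 0.45), function(mp) {
    sc <- simulation_scenario(n_cases = 150, n_background = 0,
                              misclass_prob = mp, seed = 31)
    pop <- simulate_population(sc, cfg)
    res <- build_cohorts(pop$patients, pop$events, cfg)
    truth <- pop$truth$patients
    mean(res$assignments$subtype ==
           truth$true_subtype[match(res$assignments$patient_id,
                                    truth$patient_id)])
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
})

test_that("an extra inpatient DM diagnosis in the window never flips DM to PM", {
  set.seed(77)
  w0 <- as.Date("2017-01-10")
  w1 <- add_months(w0, 6)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    days <- sort(sample(0:150, n, replace = TRUE))
    days[1] <- 0
    ev <- mk_events("p1", w0 + days,
                    sample(c("DM", "PM"), n, replace = TRUE),
                    setting = sample(c("inpatient", "outpatient"), n, TRUE))
    base <- assign_subtype(score_eaw(ev, w0, w1, cfg), cfg)
    extra <- sort_events_for_test(dplyr::bind_rows(
      ev, mk_events("p1", w0 + sample(0:150, 1), "DM", setting = "inpatient")))
    boosted <- assign_subtype(score_eaw(extra, w0, w1, cfg), cfg)
    if (identical(base, "DM")) expect_identical(boosted, "DM")
  }
})

test_that("build_cohorts agrees with the scalar operations patient by patient", {
  sc <- simulation_scenario(n_cases = 60, n_background = 0, misclass_prob = 0.4,
                            inpatient_prob = 0.5, seed = 57)
  pop <- simulate_population(sc, cfg)
  res <- build_cohorts(pop$patients, pop$events, cfg)
  for (pid in pop$patients$patient_id[1:30]) {
    ev <- pop$events[pop$events$patient_id == pid, ]
    fd <- first_iim_diagnosis(ev, cfg)
    sub <- assign_subtype(score_eaw(ev, fd, add_months(fd, cfg$eaw_months), cfg),
                          cfg)
    row <- res$assignments[res$assignments$patient_id == pid, ]
    if (nrow(row) == 1) {
      expect_identical(row$subtype, sub)
      expect_equal(row$first_iim_date, fd)
    } else {
      excl <- res$exclusions[res$exclusions$patient_id == pid, ]
      expect_equal(nrow(excl), 1)
    }
  }
})
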