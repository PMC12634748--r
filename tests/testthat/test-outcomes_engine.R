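cfg <- study_config()
idx <- as.Date("2019-01-15")

test_that("follow-up ends at the earliest trigger with the documented reasons", {
  # no triggers: clamped to study end
  pat <- mk_patient(activity_end = "2022-06-01")
  r <- compute_followup_end(pat, mk_events(character(), character(), character()),
                            idx, "case", "DM", cfg)
  expect_equal(r$fu_end, cfg$study_end)
  expect_equal(r$censor_reason, "study_end")

  # single inpatient other-subtype diagnosis
  ev <- mk_events("p1", idx + 100, "PM", setting = "inpatient")
  r2 <- compute_followup_end(pat, ev, idx, "case", "DM", cfg)
  expect_equal(r2$fu_end, idx + 100)
  expect_equal(r2$censor_reason, "subtype_switch")

  # two outpatient other-subtype diagnoses: the second one triggers
  ev3 <- mk_events(c("p1", "p1"), c(idx + 50, idx + 80), c("PM", "PM"))
  r3 <- compute_followup_end(pat, ev3, idx, "case", "DM", cfg)
  expect_equal(r3$fu_end, idx + 80)
  expect_equal(r3$censor_reason, "subtype_switch")

  # one outpatient other-subtype diagnosis alone never censors a case
  ev3b <- mk_events("p1", idx + 50, "PM")
  expect_equal(compute_followup_end(pat, ev3b, idx, "case", "DM", cfg)$censor_reason,
               "study_end")

  # controls are censored by any single DM/PM diagnosis
  ev4 <- mk_events("p1", idx + 30, "DM")
  r4 <- compute_followup_end(pat, ev4, idx, "control", NULL, cfg)
  expect_equal(r4$fu_end, idx + 30)
  expect_equal(r4$censor_reason, "control_iim_dx")

  # death before index violates the contract
  dead <- mk_patient(death_date = idx - 1)
  expect_error(compute_followup_end(dead, ev4, idx, "case", "DM", cfg),
               class = "iimcohort_contract_error")
})

test_that("washout removes a subject from the affected outcome only", {
  ev <- mk_events("p1", add_months(idx, -3), "GERD")
  expect_false(washout_eligibility("GERD", ev, idx, cfg))
  expect_true(washout_eligibility("ILD", ev, idx, cfg))

  old <- mk_events("p1", add_months(idx, -13), "GERD")
  expect_true(washout_eligibility("GERD", old, idx, cfg))
  expect_true(washout_eligibility("all_cause_death", ev, idx, cfg))
})

test_that("per-outcome observation takes the first event and censors the rest", {
  pat <- mk_patient()
  fu_end <- idx + 730
  none <- observe_events(pat, mk_events(character(), character(), character()),
                         idx, fu_end, cfg)
  expect_equal(nrow(none), 13)
  expect_true(all(none$eligible))
  expect_true(all(is.na(none$event_date)))
  expect_true(all(none$time_at_risk_days == 730))

  ev <- mk_events(c("p1", "p1"), c(idx + 10, idx + 200), c("GERD", "GERD"))
  obs <- observe_events(pat, ev, idx, fu_end, cfg)
  g <- obs[obs$outcome == "GERD", ]
  expect_equal(g$event_date, idx + 10)
  expect_equal(g$time_at_risk_days, 10)

  # death is both an event (all-cause death) and the censor for the others
  dpat <- mk_patient(death_date = idx + 365, activity_end = idx + 365)
  dobs <- observe_events(dpat, mk_events(character(), character(), character()),
                         idx, idx + 365, cfg)
  expect_equal(dobs$event_date[dobs$outcome == "all_cause_death"], idx + 365)
  expect_true(all(dobs$time_at_risk_days == 365))
})

test_that("vectorized engine matches the day-by-day scan oracle on random fixtures", {
  set.seed(1234)
  short_cfg <- study_config(study_start = "2016-01-01", study_end = "2017-12-31")
  n <- 60
  subjects <- list()
  patients <- list()
  events <- list()
  for (i in seq_len(n)) {
    id <- sprintf("s%03d", i)
    role <- sample(c("case", "control"), 1)
    subtype <- if (role == "case") sample(c("DM", "PM"), 1) else NA_character_
    index <- short_cfg$study_start + sample(0:500, 1)
    act_end <- index + sample(0:800, 1)
    death <- if (runif(1) < 0.3) index + sample(0:800, 1) else NA
    pat <- mk_patient(id, activity_start = index - 400,
                      activity_end = max(act_end, if (is.na(death)) act_end else death),
                      death_date = death)
    k <- sample(0:4, 1)
    ev <- if (k > 0) {
      mk_events(rep(id, k), index + sample(-50:700, k, replace = TRUE),
                sample(c("DM", "PM"), k, replace = TRUE),
                setting = sample(c("inpatient", "outpatient"), k, TRUE))
    } else {
      mk_events(character(), character(), character())
    }
    patients[[i]] <- pat
    events[[i]] <- ev
    subjects[[i]] <- tibble::tibble(subject_id = id, role = role,
                                    group = "g", index_date = index,
                                    subtype = subtype)
  }
  pt <- dplyr::bind_rows(patients)
  ev <- sort_events_for_test(dplyr::bind_rows(events))
  sub <- dplyr::bind_rows(subjects)
  got <- compute_follow_up(sub, ev, pt, short_cfg)
  for (i in seq_len(n)) {
    want <- oracle_followup(pt[i, ], ev[ev$patient_id == sub$subject_id[i], ],
                            sub$index_date[i], sub$role[i], sub$subtype[i],
                            short_cfg)
    expect_equal(got$fu_end[i], want$fu_end, label = sub$subject_id[i])
    expect_equal(got$censor_reason[i], want$censor_reason,
                 label = sub$subject_id[i])
  }
})

test_that("risk time never exceeds follow-up and events precede censoring", {
  sc <- simulation_scenario(n_cases = 80, n_background = 160, seed = 61)
  pop <- simulate_population(sc, cfg)
  res <- run_study(pop$patients, pop$events, cfg)
  obs <- res$observations
  fu <- res$followup
  span <- as.numeric(fu$fu_end - fu$index_date)[match(obs$subject_id,
                                                      fu$subject_id)]
  expect_true(all(obs$time_at_risk_days <= span + 1e-9))
  has <- !is.na(obs$event_date)
  expect_true(all(obs$event_date[has] <=
                    fu$fu_end[match(obs$subject_id[has], fu$subject_id)]))
  expect_true(all(obs$time_at_risk_days[!obs$eligible] == 0))
})
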