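# Grid-search calibration of initial naive:ADT1R heterogeneity.

test_that("the scenario grid is the canonical 11-mix ladder", {
  g <- scenario_grid()
  expect_equal(nrow(g), 11)
  expect_equal(g$naive_frac[1], 1)            # 100% naive first
  expect_equal(g$adt1r_frac[11], 1)           # down to 100% ADT1R
  expect_equal(g$naive_frac + g$adt1r_frac, rep(1, 11))
  expect_equal(diff(g$adt1r_frac), rep(0.1, 10))
})

test_that("trajectory distance is Euclidean in linear PSA at exact days", {
  traj <- fake_trajectory(0:10, rep(10, 11))
  # passing exactly through the measurements gives zero
  exact <- data.frame(day = c(0, 5, 10), psa_ng_ml = c(10, 10, 10))
  expect_equal(trajectory_distance(traj, exact), 0)
  # residuals (3, 4) give 5
  obs <- data.frame(day = c(2, 7), psa_ng_ml = c(13, 6))
  expect_equal(trajectory_distance(traj, obs), 5)
  # single residual of 2
  expect_equal(trajectory_distance(traj, data.frame(day = 3, psa_ng_ml = 12)), 2)
  expect_error(
    trajectory_distance(traj, data.frame(day = 99, psa_ng_ml = 1)), "99")
})

test_that("distance ignores trajectory days after the last measurement", {
  obs <- data.frame(day = c(0, 4), psa_ng_ml = c(10, 12))
  short <- fake_trajectory(0:4, c(10, 11, 11, 11, 11))
  long <- fake_trajectory(0:50, c(10, 11, 11, 11, 11, runif(46, 0, 1000)))
  expect_identical(trajectory_distance(short, obs),
                   trajectory_distance(long, obs))
})

test_that("noise-free synthetic patients are recovered exactly on the grid", {
  # parameter recovery for all 11 mixes under three distinct regimens,
  # one containing a debulk event; the oracle is the generating simulation
  grid <- scenario_grid()
  days <- seq(0, 560, by = 56)
  for (reg in recovery_regimens) {
    for (i in c(1, 4, 8, 11)) {
      mix <- c(NAIVE = grid$naive_frac[i], ADT1R = grid$adt1r_frac[i])
      vp <- make_virtual_patient(
        synth_spec(mix, psa0 = 10, regimen = reg, measurement_days = days,
                   noise_sigma = 0), base_params)
      cal <- calibrate_patient(vp$record, base_params)
      expect_equal(unname(cal$best_mix[["ADT1R"]]), grid$adt1r_frac[i])
      expect_lte(cal$scenarios$distance[1], 1e-6)
    }
  }
})

test_that("a purely resistant PSA course calibrates to 100% ADT1R", {
  # a patient whose PSA keeps rising under sustained first-line ADT:
  # forward-simulate the two extreme scenarios and compare by hand
  reg <- recovery_regimens$adt1_only
  vp <- make_virtual_patient(
    synth_spec(c(NAIVE = 0, ADT1R = 1), regimen = reg,
               measurement_days = seq(0, 392, 56), noise_sigma = 0),
    base_params)
  cal <- calibrate_patient(vp$record, base_params)
  expect_equal(unname(cal$best_mix[["ADT1R"]]), 1)
  d_naive <- trajectory_distance(
    simulate_tumor(c(NAIVE = 1), 10, reg, base_params, 392),
    vp$record$psa_series)
  expect_gt(d_naive, cal$scenarios$distance[1])
})

test_that("a single measurement is ill-posed and tie-breaks to 100% naive", {
  pat <- patient_record("P1", data.frame(day = 0, psa_ng_ml = 10))
  expect_warning(cal <- calibrate_patient(pat, base_params), "ill-posed")
  expect_equal(cal$scenarios$distance, rep(0, 11))  # all anchored to psa0
  expect_equal(unname(cal$best_mix[["NAIVE"]]), 1)
  # flipping the tie-break prior selects the fully resistant scenario
  cal2 <- suppressWarnings(
    calibrate_patient(pat, base_params, tie_break_low_resistance = FALSE))
  expect_equal(unname(cal2$best_mix[["ADT1R"]]), 1)
})

test_that("noisy recovery lands within one grid step in >= 90% of replicates", {
  # multiplicative lognormal noise sigma = 0.1 on 12 measurements over
  # 600 days; 200 seeded replicates cycling through the grid
  grid <- scenario_grid()
  days <- round(seq(0, 600, length.out = 12))
  hits <- 0L
  for (r in 1:200) {
    g <- ((r - 1) %% 11) + 1
    vp <- make_virtual_patient(
      synth_spec(c(NAIVE = grid$naive_frac[g], ADT1R = grid$adt1r_frac[g]),
                 regimen = recovery_regimens$adt1_then_adt2,
                 measurement_days = days, noise_sigma = 0.1, seed = 5000 + r),
      base_params)
    cal <- calibrate_patient(vp$record, base_params)
    if (abs(cal$best_mix[["ADT1R"]] - grid$adt1r_frac[g]) <= 0.1 + 1e-9)
      hits <- hits + 1L
  }
  expect_gte(hits, 180L)
})

test_that("patient records validate and round-trip through JSON and CSV", {
  reg <- recovery_regimens$with_debulk
  pat <- patient_record("MC-042",
                        data.frame(day = c(0, 56, 112), psa_ng_ml = c(10, 4, 6.5)),
                        reg, death_day = 400)
  expect_error(patient_record("x", data.frame(day = c(5, 10),
                                              psa_ng_ml = c(1, 2))), "day 0")
  expect_error(patient_record("x", data.frame(day = c(0, 0),
                                              psa_ng_ml = c(1, 2))),
               "strictly increasing")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_patient_json(pat, jpath)
  back <- read_patient_json(jpath)
  expect_equal(back$psa_series, pat$psa_series)
  expect_equal(back$regimen$intervals, pat$regimen$intervals)
  expect_equal(back$regimen$events, pat$regimen$events)
  expect_equal(back$death_day, pat$death_day)
  ppath <- withr::local_tempfile(fileext = ".csv")
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(pat, ppath, rpath)
  back2 <- read_patient_csv(ppath, rpath)
  expect_equal(back2$patient_id, pat$patient_id)
  expect_equal(back2$psa_series, pat$psa_series)
  expect_equal(back2$regimen$intervals, pat$regimen$intervals)
})

test_that("the calibration report round-trips with full precision", {
  vp <- make_virtual_patient(
    synth_spec(c(NAIVE = 0.6, ADT1R = 0.4),
               regimen = recovery_regimens$adt1_only,
               measurement_days = seq(0, 280, 56), noise_sigma = 0.1, seed = 3),
    base_params)
  cal <- calibrate_patient(vp$record, base_params)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_report(cal, path)
  back <- read_calibration_report(path)
  expect_identical(back$distance, cal$scenarios$distance)
  expect_identical(back$rank, cal$scenarios$rank)
})
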