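test_that("SCR kernel is causal, unit-peak, and peaks at the analytic time", {
  # d/dt [exp(-t/td) - exp(-t/tr)] = 0  =>  t* = tr*td/(td-tr) * log(td/tr)
  tr <- 0.75; td <- 2
  t_peak <- tr * td / (td - tr) * log(td / tr)
  expect_identical(scrKernel(0, tr, td), 0)
  expect_identical(scrKernel(-3, tr, td), 0)
  expect_equal(scrKernel(t_peak, tr, td), 1, tolerance = 1e-12)
  tt <- seq(0.01, 30, by = 0.01)
  v <- scrKernel(tt, tr, td)
  expect_true(all(v > 0 & v <= 1))
  expect_error(scrKernel(1, 2, 2), "tau_decay > tau_rise")
  expect_error(scrKernel(1, -1, 2), "tau_decay > tau_rise")
})

test_that("schedule has one baseline plus shuffled trials and fixed arithmetic", {
  cfg <- synthConfig(seed = 5)
  ev <- buildSchedule(cfg)
  lab <- as.character(S4Vectors::mcols(ev)$label)
  expect_length(ev, 25L)
  expect_identical(lab[1], "NoPain")
  expect_identical(sum(lab == "LowPain"), 12L)
  expect_identical(sum(lab == "HighPain"), 12L)
  expect_true(all(IRanges::width(ev)[-1] == 1000L))
  expect_identical(IRanges::width(ev)[1], 6000L)
  # non-overlapping, sorted
  expect_true(all(diff(IRanges::start(ev)) > 0))
  expect_true(all(IRanges::start(ev)[-1] > IRanges::end(ev)[-25]))
  # determinism and seed-dependence of the label permutation
  ev2 <- buildSchedule(cfg)
  expect_identical(as.character(S4Vectors::mcols(ev2)$label), lab)
  ev3 <- buildSchedule(cfg, seed = 6L)
  expect_false(identical(as.character(S4Vectors::mcols(ev3)$label), lab))

  only_base <- buildSchedule(synthConfig(n_low = 0, n_high = 0))
  expect_length(only_base, 1L)
})

test_that("recording length follows the schedule arithmetic for any config", {
  for (cfg in list(synthConfig(n_subjects = 1),
                   synthConfig(n_subjects = 1, n_low = 3, n_high = 5,
                               rest_dur = 7, trial_dur = 4, baseline_dur = 30),
                   synthConfig(n_subjects = 1, n_low = 0, n_high = 0))) {
    rec <- generateRecording(cfg, "S01", seed = 3)
    n_tr <- cfg$n_low + cfg$n_high
    expect_identical(
      length(conductance(rec)),
      as.integer(cfg$fs * (cfg$baseline_dur +
                             n_tr * (cfg$trial_dur + cfg$rest_dur))))
    expect_identical(length(stimulusEvents(rec)), 1L + n_tr)
  }
})

test_that("noise-free trial-free recording is exactly tonic plus drift", {
  cfg <- synthConfig(n_subjects = 1, n_low = 0, n_high = 0, noise_sd = 0)
  rec <- generateRecording(cfg, "S01", seed = 11)
  x <- conductance(rec)
  tt <- (seq_along(x) - 1) / cfg$fs
  fit <- stats::lm(x ~ tt)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
})

test_that("high-pain deflections exceed low-pain deflections without noise/habituation", {
  cfg <- synthConfig(n_subjects = 1, noise_sd = 0, habituation = 1)
  for (seed in c(1, 23, 99)) {
    rec <- generateRecording(cfg, "S01", seed = seed)
    x <- conductance(rec)
    ev <- stimulusEvents(rec)
    lab <- as.character(S4Vectors::mcols(ev)$label)
    base <- x[IRanges::start(ev)]  # pre-stimulus level at each onset
    defl <- vapply(seq_along(ev), function(i) {
      idx <- IRanges::start(ev)[i]:IRanges::end(ev)[i]
      max(x[idx]) - x[idx[1]]
    }, numeric(1))
    expect_gt(min(defl[lab == "HighPain"]), max(defl[lab == "LowPain"]))
  }
})

test_that("mean peak deflection ratio tracks the amplitude ratio", {
  # Monte-Carlo over many subjects; drift/noise off to isolate amplitudes
  cfg <- synthConfig(n_subjects = 150, noise_sd = 0, habituation = 1,
                     drift_slope_sd = 0, seed = 17)
  co <- generateCohort(cfg)
  ratio_num <- c(); ratio_den <- c()
  for (rec in recordings(co)) {
    x <- conductance(rec)
    ev <- stimulusEvents(rec)
    lab <- as.character(S4Vectors::mcols(ev)$label)
    defl <- vapply(seq_along(ev), function(i) {
      idx <- IRanges::start(ev)[i]:IRanges::end(ev)[i]
      max(x[idx]) - x[idx[1]]
    }, numeric(1))
    ratio_num <- c(ratio_num, defl[lab == "HighPain"])
    ratio_den <- c(ratio_den, defl[lab == "LowPain"])
  }
  expect_equal(mean(ratio_num) / mean(ratio_den),
               cfg$scr_amp_high_mean / cfg$scr_amp_low_mean,
               tolerance = 0.05)
})

test_that("cohorts are deterministic functions of the config", {
  cfg <- tinyCohortConfig(n_subjects = 3)
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  expect_length(co1, 3L)
  expect_identical(vapply(recordings(co1), subjectId, character(1)),
                   c("S01", "S02", "S03"))
  for (i in 1:3) {
    expect_identical(conductance(co1[[i]]), conductance(co2[[i]]))
  }
  # different subjects differ
  expect_false(identical(conductance(co1[[1]]), conductance(co1[[2]])))
})

test_that("cohort CSV round-trip preserves samples and annotations exactly", {
  dir <- withr::local_tempdir()
  co <- generateCohort(tinyCohortConfig())
  writeCohort(co, dir)
  expect_identical(sort(list.files(dir)),
                   sort(c("S01.csv", "S02.csv", "annotations.csv",
                          "config.yaml")))
  co2 <- readCohort(dir)
  expect_length(co2, 2L)
  for (i in 1:2) {
    expect_identical(conductance(co2[[i]]), conductance(co[[i]]))
    expect_identical(IRanges::start(stimulusEvents(co2[[i]])),
                     IRanges::start(stimulusEvents(co[[i]])))
    expect_identical(
      as.character(S4Vectors::mcols(stimulusEvents(co2[[i]]))$label),
      as.character(S4Vectors::mcols(stimulusEvents(co[[i]]))$label))
  }
  expect_error(readCohort(withr::local_tempdir()), "missing")
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(synthConfig(scr_amp_low_mean = 0.9), "separability")
  expect_error(synthConfig(fs = 0), "fs")
  expect_error(synthConfig(trial_dur = -1), "durations")
  expect_error(synthConfig(habituation = 0), "habituation")
})
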