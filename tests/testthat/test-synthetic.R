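null_effects <- c(background_rate = 1, burst_rate = 1, burst_duration = 1,
                  ibi = 1, network_event_rate = 1)

small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, nControlWells = 3L, nTreatmentWells = 3L,
                   divs = 9:10, duration = 60, electrodesPerWell = 8L,
                   treatmentEffects = null_effects)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

test_that("zero rates produce an empty but valid recording", {
  set.seed(71)
  cfg <- small_config(backgroundRateHz = 0, burstRatePerMin = 0,
                      networkEventRatePerMin = 0)
  rec <- simulateWell(cfg, "control", div = 9)
  expect_s4_class(rec, "MEARecording")
  expect_equal(nrow(spikeEvents(rec)), 0L)
})

test_that("background-only spike counts follow the Poisson expectation", {
  set.seed(72)
  # 1 Hz x 64 alive electrodes x 900 s -> 57,600 expected spikes
  cfg <- simulationConfig(seed = 72, electrodesPerWell = 64L,
                          duration = 900, backgroundRateHz = 1,
                          burstRatePerMin = 0, networkEventRatePerMin = 0,
                          pElectrodeActive = 1, wellVariabilityCV = 0,
                          treatmentEffects = null_effects)
  rec <- simulateWell(cfg, "control", div = 12,
                      wellEffect = 1)  # div 12: maturation ~ 1
  mat <- cfg@maturationCurve[["12"]]
  expected <- 1 * 64 * 900 * mat
  n <- nrow(spikeEvents(rec))
  expect_lt(abs(n - expected), 4 * sqrt(expected))
})

test_that("identical seeds give identical experiments, different differ", {
  cfg <- small_config(seed = 5)
  e1 <- simulateExperiment(cfg)
  e2 <- simulateExperiment(cfg)
  expect_identical(lapply(recordings(e1), spikeEvents),
                   lapply(recordings(e2), spikeEvents))
  cfg2 <- small_config(seed = 6)
  e3 <- simulateExperiment(cfg2)
  expect_false(identical(spikeEvents(recordings(e1)[[1]]),
                         spikeEvents(recordings(e3)[[1]])))
})

test_that("generated recordings satisfy the recording invariants", {
  cfg <- small_config(seed = 73)
  exp <- simulateExperiment(cfg)
  for (rec in recordings(exp)) {
    expect_true(validObject(rec))
    ev <- spikeEvents(rec)
    expect_false(is.unsorted(ev$time_s))
    expect_true(all(ev$time_s >= 0 & ev$time_s <= recordingDuration(rec)))
  }
  # and they round-trip through the spike-list dialect
  d <- withr::local_tempdir()
  simulateExperiment(small_config(seed = 74), dir = d)
  files <- list.files(d, pattern = "spikelist_div[0-9]+\\.csv",
                      full.names = TRUE)
  expect_length(files, 2L)
  layout <- plateLayout(nWells = 6, electrodesPerWell = 8)
  rec <- readSpikeList(files[1], div = 9, layout = layout)
  expect_gt(nrow(spikeEvents(rec)), 0)
  expect_equal(attr(rec, "n_rejected"), 0L)
  expect_true(file.exists(file.path(d, "groups.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
})

test_that("empirical rates approach the configured rate with duration", {
  set.seed(75)
  rate_err <- vapply(c(60, 600), function(dur) {
    cfg <- simulationConfig(seed = 75, duration = dur,
                            electrodesPerWell = 16L, backgroundRateHz = 2,
                            burstRatePerMin = 0, networkEventRatePerMin = 0,
                            pElectrodeActive = 1, wellVariabilityCV = 0,
                            treatmentEffects = null_effects)
    err <- vapply(1:10, function(i) {
      rec <- simulateWell(cfg, "control", div = 12, wellEffect = 1)
      mat <- cfg@maturationCurve[["12"]]
      abs(nrow(spikeEvents(rec)) / (16 * dur) - 2 * mat)
    }, numeric(1))
    mean(err)
  }, numeric(1))
  expect_lt(rate_err[2], rate_err[1])
})

test_that("simulated network events are found by the detector", {
  set.seed(76)
  hits <- 0; total <- 0
  for (i in 1:10) {
    cfg <- simulationConfig(seed = 76 + i, duration = 120,
                            electrodesPerWell = 64L, backgroundRateHz = 0.2,
                            burstRatePerMin = 0,
                            networkEventRatePerMin = 2,
                            participationProb = 0.8, pElectrodeActive = 1,
                            wellVariabilityCV = 0,
                            treatmentEffects = null_effects)
    rec <- simulateWell(cfg, "control", div = 12, wellEffect = 1)
    ev <- spikeEvents(rec)
    ns <- detectNetworkSpikes(ev[c("time_s", "electrode")],
                              plateElectrodes(rec), networkParams())
    total <- total + 1
    if (nrow(ns) >= 1) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("imposed multipliers are recovered from feature ratios", {
  # isolate the background process so the MFR ratio estimates its multiplier
  cfg <- simulationConfig(seed = 77, nControlWells = 8L,
                          nTreatmentWells = 8L, divs = 9:11, duration = 120,
                          electrodesPerWell = 8L, backgroundRateHz = 2,
                          burstRatePerMin = 0, networkEventRatePerMin = 0,
                          wellVariabilityCV = 0.1,
                          treatmentEffects = c(background_rate = 1.5,
                                               burst_rate = 1,
                                               burst_duration = 1, ibi = 1,
                                               network_event_rate = 1))
  exp <- simulateExperiment(cfg)
  ana <- analyzeExperiment(exp, minActiveElectrodes = 1,
                           networkParams = networkParams(electrodesPerWell = 8))
  rep <- recoverParameters(cfg, ana$features, window = 9:11)
  mfr <- rep[rep$feature == "mfr_hz", ]
  expect_equal(mfr$imposed, 1.5)
  expect_lt(abs(mfr$estimated - 1.5) / 1.5, 0.15)

  # null multiplier recovers ~1
  cfg0 <- small_config(seed = 78, backgroundRateHz = 2,
                       burstRatePerMin = 0, networkEventRatePerMin = 0,
                       nControlWells = 8L, nTreatmentWells = 8L,
                       wellVariabilityCV = 0.1)
  exp0 <- simulateExperiment(cfg0)
  ana0 <- analyzeExperiment(exp0, minActiveElectrodes = 1,
                            networkParams = networkParams(electrodesPerWell = 8))
  rep0 <- recoverParameters(cfg0, ana0$features, window = 9:10)
  expect_lt(abs(rep0$estimated[rep0$feature == "mfr_hz"] - 1), 0.2)
})

test_that("recovery error shrinks as wells are added", {
  errs <- vapply(c(4L, 10L, 24L), function(nw) {
    reps <- vapply(1:6, function(i) {
      cfg <- simulationConfig(seed = 1000 + 17 * nw + i, nControlWells = nw,
                              nTreatmentWells = nw, divs = 10L,
                              duration = 60, electrodesPerWell = 8L,
                              backgroundRateHz = 2, burstRatePerMin = 0,
                              networkEventRatePerMin = 0,
                              wellVariabilityCV = 0.3,
                              treatmentEffects = c(background_rate = 1.5,
                                                   burst_rate = 1,
                                                   burst_duration = 1,
                                                   ibi = 1,
                                                   network_event_rate = 1))
      exp <- simulateExperiment(cfg)
      ana <- analyzeExperiment(exp, minActiveElectrodes = 1,
                               networkParams = networkParams(electrodesPerWell = 8))
      rec <- recoverParameters(cfg, ana$features, window = 10L)
      rec$rel_error[rec$feature == "mfr_hz"]
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})
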