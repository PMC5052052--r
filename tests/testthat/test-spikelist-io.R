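random_recording <- function(n = 50, layout = plateLayout(), div = 8,
                             with_amp = TRUE) {
  MEARecording(
    data.frame(
      time_s = sort(runif(n, 0, 900)),
      well = sample(layout@wellIds, n, replace = TRUE),
      electrode = sample(layout@electrodeIds, n, replace = TRUE),
      amplitude_mV = if (with_amp) rlnorm(n, log(0.02), 0.3) else NA_real_),
    div = div, layout = layout)
}

test_that("a small spike list reads into a sorted recording", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time (s),Electrode,Amplitude(mV)",
               "0.1,A1_11,0.02", "0.2,A1_12,0.03", "0.3,A1_13,0.02"), f)
  rec <- readSpikeList(f, div = 8)
  ev <- spikeEvents(rec)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$time_s, c(0.1, 0.2, 0.3))
  expect_equal(ev$well, rep("A1", 3))
  expect_equal(ev$electrode, c("11", "12", "13"))
  expect_equal(recordingDuration(rec), 900)  # configured, not max spike time
})

test_that("rows out of time order are re-sorted and row order is immaterial", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  rows <- c("0.3,A1_13,0.02", "0.1,A1_11,0.02", "0.2,B2_12,0.03")
  writeLines(c("Time (s),Electrode,Amplitude(mV)", rows), f1)
  writeLines(c("Time (s),Electrode,Amplitude(mV)", rev(rows)), f2)
  r1 <- readSpikeList(f1, div = 8)
  r2 <- readSpikeList(f2, div = 8)
  expect_false(is.unsorted(spikeEvents(r1)$time_s))
  expect_equal(spikeEvents(r1), spikeEvents(r2))
})

test_that("electrodes outside the 8x8 grid are rejected per strict/lenient", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time (s),Electrode,Amplitude(mV)",
               "0.1,A1_11,0.02", "0.2,A1_99,0.03"), f)
  expect_error(readSpikeList(f, div = 8, strict = TRUE), "line 3")
  rec <- readSpikeList(f, div = 8, strict = FALSE)
  expect_equal(nrow(spikeEvents(rec)), 1L)
  expect_equal(attr(rec, "n_rejected"), 1L)
})

test_that("missing required columns and empty files are handled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Timestamp,Electrode", "0.1,A1_11"), f)
  expect_error(readSpikeList(f, div = 8), "Time \\(s\\)")
  writeLines("Time (s),Electrode,Amplitude(mV)", f)
  expect_warning(rec <- readSpikeList(f, div = 8), "empty")
  expect_equal(nrow(spikeEvents(rec)), 0L)
})

test_that("write/read round-trip is the identity on events", {
  set.seed(11)
  for (i in 1:10) {
    rec <- random_recording(n = sample(0:80, 1), with_amp = i %% 2 == 0)
    f <- withr::local_tempfile(fileext = ".csv")
    writeSpikeList(rec, f)
    back <- if (nrow(spikeEvents(rec)) == 0L)
      suppressWarnings(readSpikeList(f, div = recordingDiv(rec)))
    else readSpikeList(f, div = recordingDiv(rec))
    ev0 <- spikeEvents(rec); ev1 <- spikeEvents(back)
    # ties in time may legitimately reorder; compare as sorted row sets
    key <- function(e) do.call(order, e[c("time_s", "well", "electrode")])
    ev0 <- ev0[key(ev0), ]; ev1 <- ev1[key(ev1), ]
    rownames(ev0) <- rownames(ev1) <- NULL
    expect_equal(ev1, ev0)
  }
})

test_that("amplitude-free recordings round-trip with a blank column", {
  rec <- random_recording(n = 5, with_amp = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpikeList(rec, f)
  hdr <- readLines(f, n = 1)
  expect_false(grepl("Amplitude", hdr))
  back <- readSpikeList(f, div = 8)
  expect_true(all(is.na(spikeEvents(back)$amplitude_mV)))
})

test_that("group assignment reads 33 wells and rejects conflicts", {
  layout <- plateLayout(nWells = 33)
  f <- withr::local_tempfile(fileext = ".csv")
  g <- data.frame(well = layout@wellIds,
                  condition = rep(c("control", "sponge"), c(17, 16)))
  utils::write.csv(g, f, row.names = FALSE)
  got <- readGroupAssignment(f, layout)
  expect_equal(nrow(got), 33L)
  expect_equal(sum(got$condition == "control"), 17L)
  expect_equal(sum(got$condition == "sponge"), 16L)

  # same-condition duplicate collapses; conflicting duplicate errors
  utils::write.csv(rbind(g, g[1, ]), f, row.names = FALSE)
  expect_equal(nrow(readGroupAssignment(f, layout)), 33L)
  bad <- rbind(g, data.frame(well = g$well[1], condition = "sponge"))
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(readGroupAssignment(f, layout), g$well[1])

  writeLines("well,condition", f)
  expect_error(readGroupAssignment(f, layout), "empty")
})

test_that("recording validity enforces layout and time ordering", {
  layout <- plateLayout()
  expect_error(MEARecording(
    data.frame(time_s = 1, well = "Z9", electrode = "11"),
    div = 8, layout = layout), "layout")
  expect_error(MEARecording(
    data.frame(time_s = 1000, well = "A1", electrode = "11"),
    div = 8, duration = 900, layout = layout), "duration")
})
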