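elecs64 <- plateLayout()@electrodeIds

test_that("16 coincident electrodes form a network spike; 15 are filtered", {
  p <- networkParams()  # 16 of 64, 25 ms bins
  mk <- function(k) data.frame(time_s = rep(5.001, k),
                               electrode = elecs64[seq_len(k)])
  hit <- detectNetworkSpikes(mk(16), elecs64, p)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_participants, 16L)
  expect_true(hit$start_s <= 5.001 && hit$end_s >= 5.001)
  expect_equal(nrow(detectNetworkSpikes(mk(15), elecs64, p)), 0L)
})

test_that("back-to-back qualifying bins merge into one event", {
  p <- networkParams(minParticipants = 3, nsBin = 0.025)
  ev <- data.frame(
    time_s = c(rep(0.010, 3), rep(0.030, 3)),  # bins 0 and 1
    electrode = c("11", "12", "13", "13", "14", "15"))
  got <- detectNetworkSpikes(ev, elecs64, p)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start_s, 0)
  expect_equal(got$end_s, 0.05)
  expect_equal(got$n_participants, 5L)   # union of distinct electrodes
  expect_equal(got$n_spikes, 6L)
})

test_that("network-spike detection matches the bin-scan oracle", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    ev <- data.frame(time_s = round(runif(n, 0, 2), 3),
                     electrode = sample(elecs64[1:10], n, replace = TRUE))
    thr <- sample(2:5, 1)
    p <- networkParams(minParticipants = thr, nsBin = 0.025)
    got <- detectNetworkSpikes(ev, elecs64, p)
    want <- oracle_network_spikes(ev$time_s, ev$electrode, 0.025, thr)
    expect_equal(got[c("start_s", "end_s", "n_participants")], want,
                 info = paste("case", i))
  }
})

test_that("16 overlapping bursts make a network burst, 15 do not", {
  p <- networkParams()
  b16 <- data.frame(electrode = elecs64[1:16], start_s = 10, end_s = 11)
  got <- detectNetworkBursts(b16, elecs64, p)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start_s, 10)
  expect_equal(got$end_s, 11)
  expect_equal(got$n_participants, 16L)

  # 16 bursts staggered so at most 15 ever overlap: electrode k covers
  # [k, k+14.5]; at any instant at most 15 intervals overlap
  b15 <- data.frame(electrode = elecs64[1:16],
                    start_s = 1:16, end_s = 1:16 + 14.5)
  expect_equal(nrow(detectNetworkBursts(b15, elecs64, p)), 0L)
  expect_equal(nrow(detectNetworkBursts(b15[0, ], elecs64, p)), 0L)
})

test_that("network-burst sweep equals the interval-stabbing oracle", {
  set.seed(42)
  for (i in 1:500) {
    nb <- sample(1:25, 1)
    e <- sample(elecs64[1:8], nb, replace = TRUE)
    # boundaries on an exact 0.01 grid derived from integers, so that equal
    # times have identical floating-point representations
    s_i <- sample(0:1000, nb, replace = TRUE)
    d_i <- sample(5:300, nb, replace = TRUE)
    b <- data.frame(electrode = e, start_s = s_i / 100,
                    end_s = (s_i + d_i) / 100)
    b <- b[order(b$electrode, b$start_s), ]
    keep <- rep(TRUE, nrow(b))
    last_end <- -Inf; last_e <- ""
    for (k in seq_len(nrow(b))) {
      if (b$electrode[k] == last_e && b$start_s[k] <= last_end) {
        keep[k] <- FALSE
      } else {
        last_end <- b$end_s[k]; last_e <- b$electrode[k]
      }
    }
    b <- b[keep, ]
    thr <- sample(2:4, 1)
    p <- networkParams(minParticipants = thr, nsBin = 0.025)
    got <- detectNetworkBursts(b, elecs64, p)
    want <- oracle_network_bursts(b, thr)
    expect_equal(got[c("start_s", "end_s")], want, info = paste("case", i))
  }
})

test_that("raising minParticipants never increases the event count", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(20:150, 1)
    ev <- data.frame(time_s = round(runif(n, 0, 3), 3),
                     electrode = sample(elecs64[1:12], n, replace = TRUE))
    counts <- vapply(2:8, function(thr) {
      nrow(detectNetworkSpikes(ev, elecs64,
                               networkParams(minParticipants = thr)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # every reported event satisfies the participant floor
    got <- detectNetworkSpikes(ev, elecs64, networkParams(minParticipants = 4))
    expect_true(all(got$n_participants >= 4))
  }
})

test_that("network summaries report counts, rates and percentages", {
  ns <- data.frame(start_s = c(1, 5), end_s = c(1.05, 5.025),
                   n_participants = c(16L, 17L))
  nb <- data.frame(start_s = 100, end_s = 101, n_participants = 16L)
  spikes <- c(1.01, 5.01, 100.5, 300, 400)
  s <- summarizeNetworkEvents(ns, nb, spikes, 900)
  expect_equal(s$n_network_spikes, 2L)
  expect_equal(s$network_burst_rate_per_s, 1 / 900)
  expect_equal(s$pct_spikes_in_network_events, 100 * 3 / 5)

  s0 <- summarizeNetworkEvents(ns[0, ], nb[0, ], spikes, 900)
  expect_equal(s0$n_network_spikes, 0L)
  expect_equal(s0$network_burst_rate_per_s, 0)
  expect_equal(s0$pct_spikes_in_network_events, 0)

  sNA <- summarizeNetworkEvents(ns, nb, numeric(0), 900)
  expect_true(is.na(sNA$pct_spikes_in_network_events))

  s100 <- summarizeNetworkEvents(ns, nb, c(1.0, 100.2), 900)
  expect_equal(s100$pct_spikes_in_network_events, 100)
})

test_that("three network bursts in 900 s give rate 1/300 per second", {
  nb <- data.frame(start_s = c(10, 20, 30), end_s = c(11, 21, 31),
                   n_participants = rep(16L, 3))
  s <- summarizeNetworkEvents(nb[0, ], nb, c(10.5), 900)
  expect_equal(s$network_burst_rate_per_s, 3 / 900)
})
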