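# Independent brute-force oracles used to validate the optimized detectors
# and the statistics. These are literal transcriptions of the rules, written
# as plain loops, deliberately separate from the package's implementations.

# Max-interval burst rules, O(n^2)-style loop transcription:
# (1) a burst begins at a spike whose following ISI <= max_begin;
# (2) it extends while ISIs <= max_end;
# (3) bursts separated by < min_ibi merge (a merged burst owns every spike
#     in its span);
# (4) bursts with duration < min_dur or spikes < min_n are discarded.
oracle_bursts <- function(t, max_begin, max_end, min_ibi, min_dur, min_n) {
  n <- length(t)
  cores <- list()
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] <= max_begin) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= max_end) j <- j + 1L
      cores[[length(cores) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge
  merged <- list()
  for (b in cores) {
    if (length(merged)) {
      prev <- merged[[length(merged)]]
      if (t[b[1L]] - t[prev[2L]] < min_ibi) {
        merged[[length(merged)]] <- c(prev[1L], b[2L])
        next
      }
    }
    merged[[length(merged) + 1L]] <- b
  }
  out <- data.frame(start_s = numeric(), end_s = numeric(),
                    n_spikes = integer(), duration_s = numeric())
  for (b in merged) {
    dur <- t[b[2L]] - t[b[1L]]
    nsp <- b[2L] - b[1L] + 1L
    if (dur >= min_dur && nsp >= min_n)
      out <- rbind(out, data.frame(start_s = t[b[1L]], end_s = t[b[2L]],
                                   n_spikes = nsp, duration_s = dur))
  }
  rownames(out) <- NULL
  out
}

# Interval-stabbing network-burst oracle: evaluate the number of electrodes
# concurrently inside a (closed) burst at every boundary and between every
# pair of adjacent boundaries, then return the maximal qualifying intervals.
oracle_network_bursts <- function(bursts, thr) {
  if (!nrow(bursts))
    return(data.frame(start_s = numeric(), end_s = numeric()))
  stab <- function(x) {
    length(unique(bursts$electrode[bursts$start_s <= x & bursts$end_s >= x]))
  }
  bd <- sort(unique(c(bursts$start_s, bursts$end_s)))
  pts <- numeric(0); qual <- logical(0)
  for (k in seq_along(bd)) {
    pts <- c(pts, bd[k]); qual <- c(qual, stab(bd[k]) >= thr)
    if (k < length(bd)) {
      mid <- (bd[k] + bd[k + 1L]) / 2
      pts <- c(pts, mid); qual <- c(qual, stab(mid) >= thr)
    }
  }
  # maximal runs of qualifying points -> [first boundary, last boundary]
  out <- data.frame(start_s = numeric(), end_s = numeric())
  k <- 1L
  while (k <= length(pts)) {
    if (qual[k]) {
      j <- k
      while (j < length(pts) && qual[j + 1L]) j <- j + 1L
      out <- rbind(out, data.frame(start_s = pts[k], end_s = pts[j]))
      k <- j + 1L
    } else k <- k + 1L
  }
  rownames(out) <- NULL
  out
}

# Fixed-bin network-spike oracle: plain loop over bins.
oracle_network_spikes <- function(times, electrodes, bin_w, thr) {
  if (!length(times))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_participants = integer()))
  bins <- floor(times / bin_w)
  qual <- c()
  for (b in sort(unique(bins))) {
    if (length(unique(electrodes[bins == b])) >= thr) qual <- c(qual, b)
  }
  out <- data.frame(start_s = numeric(), end_s = numeric(),
                    n_participants = integer())
  k <- 1L
  while (k <= length(qual)) {
    j <- k
    while (j < length(qual) && qual[j + 1L] == qual[j] + 1) j <- j + 1L
    members <- qual[k:j]
    parts <- unique(electrodes[bins %in% members])
    out <- rbind(out, data.frame(start_s = min(members) * bin_w,
                                 end_s = (max(members) + 1) * bin_w,
                                 n_participants = length(parts)))
    k <- j + 1L
  }
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, na) rank
# arrangements (no ties assumed). The U distribution is symmetric, so the
# two-sided p is P(U <= lo) + P(U >= hi) with lo/hi the symmetric pair of
# the observed U.
enum_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  m <- na * nb
  lo <- min(u_obs, m - u_obs); hi <- max(u_obs, m - u_obs)
  min(1, (sum(us <= lo) + sum(us >= hi)) / ncol(idx))
}

# random small spike train for oracle cross-checks
random_spike_train <- function(n_max = 200) {
  n <- sample.int(n_max, 1)
  sort(round(cumsum(rexp(n, rate = sample(c(2, 10, 40), 1))), 4))
}

random_burst_params <- function() {
  begin <- runif(1, 0.02, 0.2)
  burstParams(maxBeginISI = begin,
              maxEndISI = begin + runif(1, 0, 0.2),
              minIBI = runif(1, 0.1, 1),
              minDuration = runif(1, 0.01, 0.1),
              minSpikes = sample(2:6, 1))
}
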