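#' Max-interval burst detection on one spike train
#'
#' Detects bursts on a single electrode's spike train with the fixed-parameter
#' max-interval method: (1) a burst begins at a spike whose following
#' inter-spike interval (ISI) is at most \code{maxBeginISI}; (2) the burst
#' extends while ISIs stay at most \code{maxEndISI}; (3) consecutive bursts
#' whose inter-burst gap (end of one to start of the next) is smaller than
#' \code{minIBI} are merged; (4) bursts shorter than \code{minDuration} or
#' with fewer than \code{minSpikes} spikes are discarded. A merged burst
#' comprises every spike inside its time span. Burst duration is last spike
#' time minus first spike time, not padded by the ISI allowances.
#'
#' @param spikeTimes numeric vector of spike times in seconds, sorted
#'   ascending.
#' @param params a \linkS4class{BurstParams}.
#' @return \code{data.frame} with columns \code{start_s}, \code{end_s},
#'   \code{n_spikes}, \code{duration_s}; zero rows when no burst qualifies.
#'   Returned bursts are non-overlapping and time-ordered.
#' @examples
#' p <- burstParams(maxBeginISI = 0.1, maxEndISI = 0.2, minIBI = 0.5,
#'                  minDuration = 0.02, minSpikes = 5)
#' detectBursts(c(1.00, 1.01, 1.02, 1.03, 1.04), p)
#' @export
detectBursts <- function(spikeTimes, params = burstParams()) {
  stopifnot(is(params, "BurstParams"))
  validObject(params)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer(), duration_s = numeric())
  n <- length(spikeTimes)
  if (n == 0L) return(empty)
  if (is.unsorted(spikeTimes)) stop("spikeTimes must be sorted ascending")
  if (n < 2L) return(empty)

  isi <- diff(spikeTimes)
  in_ext <- isi <= params@maxEndISI
  if (!any(in_ext)) return(empty)

  # maximal runs of ISIs <= maxEndISI; within each run a burst opens at the
  # first ISI <= maxBeginISI (if any) and extends to the run's end
  r <- rle(in_ext)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  run_start <- run_start[keep]; run_end <- run_end[keep]

  opens <- isi <= params@maxBeginISI
  starts <- integer(0); ends <- integer(0)
  for (k in seq_along(run_start)) {
    idx <- run_start[k]:run_end[k]
    first_open <- idx[opens[idx]][1L]
    if (!is.na(first_open)) {
      starts <- c(starts, first_open)        # burst spikes first_open..run_end+1
      ends <- c(ends, run_end[k] + 1L)
    }
  }
  if (!length(starts)) return(empty)

  # merge bursts separated by < minIBI; a merged burst comprises every spike
  # inside its time span (gap spikes fall within the merged extent)
  if (length(starts) > 1L) {
    gap <- spikeTimes[starts[-1L]] - spikeTimes[ends[-length(ends)]]
    grp <- cumsum(c(TRUE, gap >= params@minIBI))
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }
  out <- data.frame(start_s = spikeTimes[starts], end_s = spikeTimes[ends],
                    n_spikes = as.integer(ends - starts + 1L),
                    duration_s = spikeTimes[ends] - spikeTimes[starts])
  keep <- out$duration_s >= params@minDuration &
    out$n_spikes >= params@minSpikes
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Burst detection across the electrodes of a recording
#'
#' Runs \code{\link{detectBursts}} on every active electrode of every well of
#' one recording day and returns the pooled burst event table (the export
#' behind raster-style renderings of burst activity).
#'
#' @param recording an \linkS4class{MEARecording}.
#' @param activeByWell named list well -> character vector of active
#'   electrodes (e.g. from \code{\link{activeElectrodes}} or
#'   \code{\link{activeSet}}); electrodes not listed are skipped.
#' @param params a \linkS4class{BurstParams}.
#' @return \code{data.frame} with columns \code{div}, \code{well},
#'   \code{electrode}, \code{start_s}, \code{end_s}, \code{n_spikes},
#'   \code{duration_s}.
#' @export
detectBurstsRecording <- function(recording, activeByWell,
                                  params = burstParams()) {
  ev <- recording@events
  by_we <- split(ev$time_s, list(well = ev$well, electrode = ev$electrode),
                 sep = "\r", drop = TRUE)
  out <- list()
  for (w in names(activeByWell)) {
    act <- activeByWell[[w]]
    if (!length(act)) next
    for (e in act) {
      tt <- by_we[[paste(w, e, sep = "\r")]]
      if (is.null(tt)) next
      b <- detectBursts(tt, params)
      if (nrow(b)) {
        b$div <- recording@div; b$well <- w; b$electrode <- e
        out[[length(out) + 1L]] <- b
      }
    }
  }
  if (!length(out))
    return(data.frame(div = integer(), well = character(),
                      electrode = character(), start_s = numeric(),
                      end_s = numeric(), n_spikes = integer(),
                      duration_s = numeric()))
  res <- do.call(rbind, out)
  res <- res[c("div", "well", "electrode", "start_s", "end_s", "n_spikes",
               "duration_s")]
  rownames(res) <- NULL
  res
}

#' Well-level burst summary
#'
#' Summarises the bursts of one well-day over its active electrodes:
#' burst rate per minute per active electrode, mean burst duration,
#' inter-burst intervals (end of one burst to start of the next on the same
#' electrode, pooled across electrodes), percentage of spikes inside bursts,
#' and mean spikes per burst. With zero active electrodes every feature is
#' \code{NA} (missing, not zero).
#'
#' @param bursts burst table for one well (columns \code{electrode},
#'   \code{start_s}, \code{end_s}, \code{n_spikes}, \code{duration_s}).
#' @param spikeCounts named numeric: total spike count per active electrode.
#' @param duration recording duration in seconds.
#' @param activeSet character vector of the well's active electrodes.
#' @return list with \code{burst_rate_per_min}, \code{mean_burst_duration_s},
#'   \code{ibis_s} (numeric vector), \code{mean_ibi_s},
#'   \code{pct_spikes_in_bursts}, \code{spikes_per_burst}, \code{n_bursts}.
#' @export
summarizeBursts <- function(bursts, spikeCounts, duration, activeSet) {
  nA <- length(activeSet)
  if (nA == 0L)
    return(list(burst_rate_per_min = NA_real_,
                mean_burst_duration_s = NA_real_, ibis_s = numeric(),
                mean_ibi_s = NA_real_, pct_spikes_in_bursts = NA_real_,
                spikes_per_burst = NA_real_, n_bursts = NA_integer_))
  bursts <- bursts[bursts$electrode %in% activeSet, , drop = FALSE]
  nb <- nrow(bursts)
  total_spikes <- sum(spikeCounts[activeSet], na.rm = TRUE)
  ibis <- numeric(0)
  if (nb) {
    for (e in unique(bursts$electrode)) {
      be <- bursts[bursts$electrode == e, , drop = FALSE]
      if (nrow(be) > 1L) {
        o <- order(be$start_s)
        ibis <- c(ibis, be$start_s[o][-1L] - be$end_s[o][-nrow(be)])
      }
    }
  }
  list(
    burst_rate_per_min = nb / nA / (duration / 60),
    mean_burst_duration_s = if (nb) mean(bursts$duration_s) else 0,
    ibis_s = ibis,
    mean_ibi_s = if (length(ibis)) mean(ibis) else NA_real_,
    pct_spikes_in_bursts = if (total_spikes > 0)
      100 * sum(bursts$n_spikes) / total_spikes else NA_real_,
    spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    n_bursts = nb
  )
}
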