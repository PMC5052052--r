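#' Detect synchronous network spikes in one well
#'
#' Partitions the time axis into fixed half-open bins of width
#' \code{nsBin} seconds; a bin in which spikes from at least
#' \code{minParticipants} distinct active electrodes occur is a candidate
#' population spike, and runs of consecutive qualifying bins merge into one
#' network spike. Events with fewer participating electrodes are filtered
#' out. Participants of a merged event are the union of distinct electrodes
#' over its bins.
#'
#' @param events spike table of one well (columns \code{time_s},
#'   \code{electrode}), or an \linkS4class{MEARecording} together with
#'   \code{well}.
#' @param activeSet electrodes eligible to participate; spikes from other
#'   electrodes are ignored.
#' @param params a \linkS4class{NetworkParams}.
#' @param well when \code{events} is an \linkS4class{MEARecording}, the well
#'   to analyse.
#' @return \code{data.frame} with columns \code{start_s}, \code{end_s} (bin
#'   edges of the merged run), \code{n_participants}, \code{n_spikes}, and a
#'   list column \code{participants}.
#' @export
detectNetworkSpikes <- function(events, activeSet,
                                params = networkParams(), well = NULL) {
  if (is(events, "MEARecording")) {
    stopifnot(!is.null(well))
    ev <- events@events
    events <- ev[ev$well == well, c("time_s", "electrode")]
  }
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_participants = integer(), n_spikes = integer())
  empty$participants <- list()
  ev <- events[events$electrode %in% activeSet, , drop = FALSE]
  if (!nrow(ev)) return(empty)

  bin <- floor(ev$time_s / params@nsBin)
  # distinct (bin, electrode) pairs -> participant count per bin
  key <- paste(bin, ev$electrode, sep = "\r")
  first <- !duplicated(key)
  pb <- bin[first]; pe <- ev$electrode[first]
  ub <- sort(unique(pb))
  cnt <- tabulate(match(pb, ub), nbins = length(ub))
  qual <- ub[cnt >= params@minParticipants]
  if (!length(qual)) return(empty)
  grp <- cumsum(c(TRUE, diff(qual) > 1))
  # per merged run: bin range, distinct-electrode union, spike count
  run_lo <- as.numeric(tapply(qual, grp, min))
  run_hi <- as.numeric(tapply(qual, grp, max))
  pair_grp <- grp[match(pb, qual)]          # NA for non-qualifying bins
  parts <- lapply(split(pe[!is.na(pair_grp)], pair_grp[!is.na(pair_grp)]),
                  function(e) sort(unique(e)))
  spike_grp <- grp[match(bin, qual)]
  n_spk <- tabulate(spike_grp[!is.na(spike_grp)], nbins = max(grp))
  res <- data.frame(start_s = run_lo * params@nsBin,
                    end_s = (run_hi + 1) * params@nsBin,
                    n_participants = lengths(parts),
                    n_spikes = n_spk)
  res$participants <- parts
  rownames(res) <- NULL
  res
}

#' Detect synchronous network bursts in one well
#'
#' Sweeps over the burst start/end boundaries of one well's electrodes and
#' reports the maximal time intervals during which at least
#' \code{minParticipants} electrodes are simultaneously inside a burst
#' (burst intervals are treated as closed, so an interval ending exactly when
#' another starts still counts as overlap at that instant). Qualifying
#' intervals separated by less than \code{nbMergeGap} merge (default 0: no
#' merging). Participants are the union of electrodes whose bursts overlap
#' the interval.
#'
#' @param bursts burst table of one well (columns \code{electrode},
#'   \code{start_s}, \code{end_s}), e.g. from
#'   \code{\link{detectBurstsRecording}}.
#' @param activeSet electrodes eligible to participate.
#' @param params a \linkS4class{NetworkParams}.
#' @return \code{data.frame} with columns \code{start_s}, \code{end_s},
#'   \code{n_participants} and a list column \code{participants}.
#' @export
detectNetworkBursts <- function(bursts, activeSet,
                                params = networkParams()) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_participants = integer())
  empty$participants <- list()
  b <- bursts[bursts$electrode %in% activeSet, , drop = FALSE]
  if (!nrow(b)) return(empty)

  # boundary sweep; at ties starts are processed before ends so that closed
  # intervals touching at a point count as overlapping
  t <- c(b$start_s, b$end_s)
  d <- c(rep(1L, nrow(b)), rep(-1L, nrow(b)))
  o <- order(t, -d)
  t <- t[o]; d <- d[o]
  depth <- cumsum(d)
  thr <- params@minParticipants
  above <- depth >= thr
  if (!any(above)) return(empty)
  # qualifying stretches: from the boundary where depth rises to >= thr until
  # the boundary where it drops below
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  sel <- r$values
  starts <- t[idx_start[sel]]
  # the stretch ends at the *next* boundary time (where depth drops)
  ends <- ifelse(idx_end[sel] < length(t), t[idx_end[sel] + 1L],
                 t[length(t)])
  iv <- data.frame(start_s = starts, end_s = ends)
  # merge across small gaps
  if (nrow(iv) > 1L && params@nbMergeGap > 0) {
    gap <- iv$start_s[-1L] - iv$end_s[-nrow(iv)]
    grp <- cumsum(c(TRUE, gap >= params@nbMergeGap))
    iv <- data.frame(start_s = as.numeric(tapply(iv$start_s, grp, min)),
                     end_s = as.numeric(tapply(iv$end_s, grp, max)))
  }
  parts <- lapply(seq_len(nrow(iv)), function(i)
    sort(unique(b$electrode[b$start_s <= iv$end_s[i] &
                              b$end_s >= iv$start_s[i]])))
  iv$n_participants <- lengths(parts)
  iv <- iv[iv$n_participants >= thr, , drop = FALSE]
  iv$participants <- parts[lengths(parts) >= thr]
  rownames(iv) <- NULL
  iv
}

#' Summarise network events of one well-day
#'
#' @param networkSpikes,networkBursts event tables from
#'   \code{\link{detectNetworkSpikes}} and \code{\link{detectNetworkBursts}}.
#' @param spikeTimes spike times of the well's active electrodes (used to
#'   compute the percentage of spikes inside events).
#' @param duration recording duration in seconds.
#' @return list with \code{n_network_spikes},
#'   \code{network_burst_rate_per_s}, and
#'   \code{pct_spikes_in_network_events} (percentage of active-electrode
#'   spikes falling inside any event's \code{[start_s, end_s]}; \code{NA}
#'   when there are no spikes).
#' @export
summarizeNetworkEvents <- function(networkSpikes, networkBursts, spikeTimes,
                                   duration) {
  n_ns <- nrow(networkSpikes)
  n_nb <- nrow(networkBursts)
  total <- length(spikeTimes)
  pct <- if (total == 0L) NA_real_ else {
    iv <- rbind(networkSpikes[c("start_s", "end_s")],
                networkBursts[c("start_s", "end_s")])
    if (nrow(iv) == 0L) 0 else {
      # union of (possibly overlapping) closed intervals, then membership
      o <- order(iv$start_s)
      s <- iv$start_s[o]; e <- cummax(iv$end_s[o])
      new_grp <- c(TRUE, s[-1L] > e[-length(e)])
      g <- cumsum(new_grp)
      us <- s[new_grp]
      ue <- as.numeric(tapply(e, g, max))
      idx <- findInterval(spikeTimes, us)
      inside <- idx >= 1L & spikeTimes <= ue[pmax(idx, 1L)]
      100 * mean(inside)
    }
  }
  list(n_network_spikes = n_ns,
       network_burst_rate_per_s = n_nb / duration,
       pct_spikes_in_network_events = pct)
}
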