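.FEATURE_COLUMNS <- c(
  "div", "well", "condition", "n_active_electrodes", "mfr_hz",
  "burst_rate_per_min", "mean_burst_duration_s", "mean_ibi_s",
  "n_network_spikes", "network_burst_rate_per_s", "pct_spikes_in_bursts",
  "pct_spikes_in_network_events")

#' Per-well activity features of one recording day
#'
#' Computes the per-well feature vector of one DIV for every well the
#' activity mask retains: number of active electrodes, mean firing rate
#' normalised to the number of active electrodes (Hz), burst rate per minute
#' per active electrode, mean burst duration, mean inter-burst interval,
#' network-spike count, network-burst rate per second, and the percentages of
#' spikes in bursts and in network events. On a day where an included well
#' has zero active electrodes the activity features are missing (\code{NA}),
#' never zero.
#'
#' @param recording an \linkS4class{MEARecording}.
#' @param mask an \linkS4class{ActivityMask} built on the experiment the
#'   recording belongs to.
#' @param burstParams,networkParams detector parameter objects.
#' @param groups optional group assignment (\code{well}, \code{condition});
#'   wells missing from it get condition \code{NA}.
#' @param bursts optional precomputed burst table for this recording (from
#'   \code{\link{detectBurstsRecording}}); computed when \code{NULL}.
#' @param networkSpikes,networkBursts optional precomputed event tables for
#'   this recording (columns \code{well}, \code{start_s}, \code{end_s});
#'   detected per well when \code{NULL}.
#' @return \code{data.frame}, one row per included well, columns
#'   \code{div, well, condition, n_active_electrodes, mfr_hz,
#'   burst_rate_per_min, mean_burst_duration_s, mean_ibi_s,
#'   n_network_spikes, network_burst_rate_per_s, pct_spikes_in_bursts,
#'   pct_spikes_in_network_events}.
#' @export
computeWellFeatures <- function(recording, mask,
                                burstParams = MEAactivity::burstParams(),
                                networkParams = NULL, groups = NULL,
                                bursts = NULL, networkSpikes = NULL,
                                networkBursts = NULL) {
  if (is.null(networkParams))
    networkParams <- MEAactivity::networkParams(
      electrodesPerWell = recording@layout@electrodesPerWell)
  div <- recording@div
  duration <- recording@duration
  wells <- includedWells(mask)
  ev <- recording@events
  if (is.null(bursts)) {
    activeByWell <- lapply(stats::setNames(wells, wells),
                           function(w) activeSet(mask, div, w))
    bursts <- detectBurstsRecording(recording, activeByWell, burstParams)
  }
  ev_idx <- split(seq_len(nrow(ev)), ev$well)
  b_idx <- split(seq_len(nrow(bursts)), bursts$well)
  rows <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[i]
    act <- activeSet(mask, div, w)
    cond <- if (!is.null(groups)) {
      m <- match(w, groups$well)
      if (is.na(m)) NA_character_ else groups$condition[m]
    } else NA_character_
    nA <- length(act)
    if (nA == 0L) {
      rows[[i]] <- data.frame(
        div = div, well = w, condition = cond, n_active_electrodes = 0L,
        mfr_hz = NA_real_, burst_rate_per_min = NA_real_,
        mean_burst_duration_s = NA_real_, mean_ibi_s = NA_real_,
        n_network_spikes = NA_integer_, network_burst_rate_per_s = NA_real_,
        pct_spikes_in_bursts = NA_real_,
        pct_spikes_in_network_events = NA_real_, stringsAsFactors = FALSE)
      next
    }
    evw <- ev[ev_idx[[w]], , drop = FALSE]
    evw <- evw[evw$electrode %in% act, , drop = FALSE]
    counts <- table(factor(evw$electrode, levels = act))
    spikeCounts <- stats::setNames(as.numeric(counts), act)
    total <- sum(spikeCounts)
    bw <- bursts[b_idx[[w]], , drop = FALSE]
    bs <- summarizeBursts(bw, spikeCounts, duration, act)
    ns <- if (is.null(networkSpikes))
      detectNetworkSpikes(evw[c("time_s", "electrode")], act, networkParams)
    else networkSpikes[networkSpikes$well == w, , drop = FALSE]
    nb <- if (is.null(networkBursts))
      detectNetworkBursts(bw, act, networkParams)
    else networkBursts[networkBursts$well == w, , drop = FALSE]
    net <- summarizeNetworkEvents(ns, nb, evw$time_s, duration)
    rows[[i]] <- data.frame(
      div = div, well = w, condition = cond, n_active_electrodes = nA,
      mfr_hz = total / duration / nA,
      burst_rate_per_min = bs$burst_rate_per_min,
      mean_burst_duration_s = bs$mean_burst_duration_s,
      mean_ibi_s = bs$mean_ibi_s,
      n_network_spikes = as.integer(net$n_network_spikes),
      network_burst_rate_per_s = net$network_burst_rate_per_s,
      pct_spikes_in_bursts = bs$pct_spikes_in_bursts,
      pct_spikes_in_network_events = net$pct_spikes_in_network_events,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(.FEATURE_COLUMNS), logical(0), simplify = FALSE),
      .FEATURE_COLUMNS))
  }
  rownames(out) <- NULL
  out
}

#' Read or write a feature table
#'
#' CSV round-trip of the per-well per-DIV feature table with a stable column
#' order; missing values survive as missing (empty fields), not as zero.
#'
#' @param features feature table as produced by
#'   \code{\link{computeWellFeatures}} (rows from several DIVs may be bound
#'   together).
#' @param path CSV file.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns the \code{data.frame} and errors when
#'   required columns are absent, listing them.
#' @export
writeFeatureTable <- function(features, path) {
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(features))
  if (length(missing_cols))
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  out <- features[.FEATURE_COLUMNS]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      y <- sprintf("%.17g", out[[j]])
      y[is.na(out[[j]])] <- NA_character_
      out[[j]] <- y
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("feature table schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab$well <- as.character(tab$well)
  tab$condition <- as.character(tab$condition)
  tab$div <- as.integer(tab$div)
  tab$n_active_electrodes <- as.integer(tab$n_active_electrodes)
  tab$n_network_spikes <- as.integer(tab$n_network_spikes)
  tab[.FEATURE_COLUMNS]
}
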