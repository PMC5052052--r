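#' Run the full analysis on an experiment
#'
#' Orchestrates QC, burst detection, network-event detection and feature
#' aggregation over every recording day of an experiment: builds the
#' activity mask, detects per-electrode bursts and well-level network events
#' on each day's active sets, and assembles the per-well per-DIV feature
#' table that the group statistics consume. Deterministic given its inputs.
#'
#' @param experiment an \linkS4class{MEAExperiment} (e.g. from
#'   \code{\link{simulateExperiment}} or assembled from
#'   \code{\link{readSpikeList}} calls).
#' @param minSpikesPerMin,minActiveElectrodes,maxInactiveDayFraction QC
#'   parameters, see \code{\link{buildActivityMask}}.
#' @param burstParams a \linkS4class{BurstParams}.
#' @param networkParams a \linkS4class{NetworkParams}; default derives
#'   \code{minParticipants} as 25\% of the layout's electrodes per well.
#' @param verbose log per-stage counts to the console.
#' @return list with \code{features} (feature table), \code{bursts} (burst
#'   event table), \code{network_spikes} and \code{network_bursts} (event
#'   tables with \code{div}, \code{well}, \code{start_s}, \code{end_s},
#'   \code{n_participants}), and \code{mask} (the
#'   \linkS4class{ActivityMask}).
#' @export
analyzeExperiment <- function(experiment,
                              minSpikesPerMin = 5,
                              minActiveElectrodes = 16,
                              maxInactiveDayFraction = 0.30,
                              burstParams = MEAactivity::burstParams(),
                              networkParams = NULL,
                              verbose = FALSE) {
  stopifnot(is(experiment, "MEAExperiment"))
  if (is.null(networkParams))
    networkParams <- MEAactivity::networkParams(
      electrodesPerWell = experiment@layout@electrodesPerWell)
  say <- function(...) if (verbose) message(...)

  mask <- buildActivityMask(experiment, minSpikesPerMin,
                            minActiveElectrodes, maxInactiveDayFraction)
  say("QC: ", sum(mask@wells$included), "/", nrow(mask@wells),
      " wells included")
  groups <- experiment@groups
  feats <- list(); bursts <- list(); ns_tab <- list(); nb_tab <- list()
  for (rec in experiment@recordings) {
    d <- rec@div
    wells <- includedWells(mask)
    activeByWell <- lapply(stats::setNames(wells, wells),
                           function(w) activeSet(mask, d, w))
    b <- detectBurstsRecording(rec, activeByWell, burstParams)
    bursts[[length(bursts) + 1L]] <- b
    ev <- rec@events
    ev_idx <- split(seq_len(nrow(ev)), ev$well)
    b_idx <- split(seq_len(nrow(b)), b$well)
    ns_day <- list(); nb_day <- list()
    for (w in wells) {
      act <- activeByWell[[w]]
      if (!length(act)) next
      evw <- ev[ev_idx[[w]], c("time_s", "electrode")]
      evw <- evw[evw$electrode %in% act, , drop = FALSE]
      ns <- detectNetworkSpikes(evw, act, networkParams)
      nb <- detectNetworkBursts(b[b_idx[[w]], , drop = FALSE], act,
                                networkParams)
      if (nrow(ns))
        ns_day[[length(ns_day) + 1L]] <-
          data.frame(div = d, well = w, kind = "network_spike",
                     ns[c("start_s", "end_s", "n_participants")],
                     stringsAsFactors = FALSE)
      if (nrow(nb))
        nb_day[[length(nb_day) + 1L]] <-
          data.frame(div = d, well = w, kind = "network_burst",
                     nb[c("start_s", "end_s", "n_participants")],
                     stringsAsFactors = FALSE)
    }
    ns_day <- if (length(ns_day)) do.call(rbind, ns_day) else NULL
    nb_day <- if (length(nb_day)) do.call(rbind, nb_day) else NULL
    ev_empty <- data.frame(well = character(), start_s = numeric(),
                           end_s = numeric(), n_participants = integer(),
                           stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <-
      computeWellFeatures(rec, mask, burstParams, networkParams, groups,
                          bursts = b,
                          networkSpikes = if (is.null(ns_day)) ev_empty
                                          else ns_day,
                          networkBursts = if (is.null(nb_day)) ev_empty
                                          else nb_day)
    if (!is.null(ns_day)) ns_tab[[length(ns_tab) + 1L]] <- ns_day
    if (!is.null(nb_day)) nb_tab[[length(nb_tab) + 1L]] <- nb_day
    say("DIV ", d, ": ", nrow(rec@events), " spikes, ",
        nrow(b), " bursts")
  }
  bind <- function(x, proto) {
    if (length(x)) { out <- do.call(rbind, x); rownames(out) <- NULL; out }
    else proto
  }
  ev_proto <- data.frame(div = integer(), well = character(),
                         kind = character(), start_s = numeric(),
                         end_s = numeric(), n_participants = integer())
  list(features = bind(feats, NULL),
       bursts = bind(bursts, data.frame(
         div = integer(), well = character(), electrode = character(),
         start_s = numeric(), end_s = numeric(), n_spikes = integer(),
         duration_s = numeric())),
       network_spikes = bind(ns_tab, ev_proto),
       network_bursts = bind(nb_tab, ev_proto),
       mask = mask)
}

.DEFAULT_STAT_FEATURES <- c(
  "mfr_hz", "burst_rate_per_min", "mean_burst_duration_s", "mean_ibi_s",
  "n_network_spikes", "network_burst_rate_per_s", "pct_spikes_in_bursts",
  "pct_spikes_in_network_events")

#' Compare conditions across all activity features
#'
#' Runs \code{\link{compareFeature}} (per-DIV MWU + Fisher combination and
#' the pooled-window label-permutation test) for every requested feature and
#' returns the comparisons plus a tidy report table. Per-feature permutation
#' seeds are derived deterministically from \code{seed}.
#'
#' @param features feature table from \code{\link{analyzeExperiment}} (or
#'   \code{\link{readFeatureTable}}).
#' @param groups optional group assignment; defaults to the table's
#'   \code{condition} column.
#' @param featureNames feature columns to test.
#' @param window,nPerm,reducer see \code{\link{permutationTest}}.
#' @param seed base RNG seed.
#' @return list with \code{comparisons} (named list of
#'   \linkS4class{GroupComparison}) and \code{table} (the
#'   \code{\link{comparisonTable}} report).
#' @export
compareGroups <- function(features, groups = NULL,
                          featureNames = .DEFAULT_STAT_FEATURES,
                          window = 8:16, nPerm = 10000L, seed = 1L,
                          reducer = "mean") {
  comparisons <- list()
  for (i in seq_along(featureNames)) {
    fn <- featureNames[i]
    comparisons[[fn] ] <- compareFeature(
      features, groups, fn, window = window, nPerm = nPerm,
      seed = if (is.null(seed)) NULL else seed + i,
      reducer = reducer)
  }
  list(comparisons = comparisons, table = comparisonTable(comparisons))
}

#' Write analysis outputs to a directory
#'
#' Writes the feature table, burst table, network-event tables and QC audit
#' tables of \code{\link{analyzeExperiment}} as CSV files with fixed names.
#'
#' @param analysis result of \code{\link{analyzeExperiment}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeAnalysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(df) {
    for (j in seq_along(df)) if (is.double(df[[j]])) {
      y <- sprintf("%.17g", df[[j]]); y[is.na(df[[j]])] <- NA_character_
      df[[j]] <- y
    }
    df
  }
  writeFeatureTable(analysis$features, file.path(dir, "features.csv"))
  utils::write.csv(num(analysis$bursts), file.path(dir, "bursts.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(num(rbind(analysis$network_spikes,
                             analysis$network_bursts)),
                   file.path(dir, "network_events.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  writeActivityMask(analysis$mask,
                    file.path(dir, "qc_electrodes.csv"),
                    file.path(dir, "qc_wells.csv"))
  invisible(dir)
}

#' Write a stats report
#'
#' Serialises a \code{\link{compareGroups}} result as CSV (the tidy table)
#' and JSON (full per-DIV detail).
#'
#' @param comparison result of \code{\link{compareGroups}}.
#' @param csvPath,jsonPath output files (either may be \code{NULL}).
#' @return Invisibly, the paths written.
#' @export
writeStatsReport <- function(comparison, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(comparison$table, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    detail <- lapply(comparison$comparisons, function(g) list(
      feature = g@feature, window = range(g@window),
      per_div_p = as.list(g@perDivP), fisher_chi2 = g@fisherChi2,
      fisher_df = g@fisherDf, fisher_p = g@fisherP,
      observed_mwu_p = g@observedMwuP, perm_p = g@permP, n_perm = g@nPerm,
      n_per_group = as.list(g@nPerGroup), seed = g@seed,
      reducer = g@reducer))
    jsonlite::write_json(detail, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csvPath, jsonPath))
}

#' Raster-style event export for one well
#'
#' Extracts, for one well and day, the per-electrode spike ticks, burst
#' intervals and network-event intervals inside a time window, clipped to
#' the window boundaries (intervals straddling a boundary are clipped, not
#' dropped) — the table behind raster renderings of burst and network-event
#' activity (e.g. the 440-520 s stretch of a 15-minute recording).
#'
#' @param analysis result of \code{\link{analyzeExperiment}}.
#' @param experiment the analysed \linkS4class{MEAExperiment} (source of the
#'   spike ticks).
#' @param well well id.
#' @param div day in vitro.
#' @param window numeric length-2 time window in seconds
#'   (default \code{c(440, 520)}).
#' @return list of data.frames: \code{spikes} (\code{time_s},
#'   \code{electrode}), \code{bursts} and \code{events} (both with
#'   \code{start_s}, \code{end_s} clipped to the window; \code{events} also
#'   carries \code{kind}).
#' @export
rasterData <- function(analysis, experiment, well, div,
                       window = c(440, 520)) {
  if (!well %in% experiment@layout@wellIds)
    stop("unknown well: ", well)
  rec <- NULL
  for (r in experiment@recordings) if (r@div == div) rec <- r
  if (is.null(rec)) stop("no recording for DIV ", div)
  lo <- min(window); hi <- max(window)
  ev <- rec@events
  sp <- ev[ev$well == well & ev$time_s >= lo & ev$time_s <= hi,
           c("time_s", "electrode")]
  clip <- function(df) {
    df <- df[df$well == well & df$div == div &
               df$end_s >= lo & df$start_s <= hi, , drop = FALSE]
    df$start_s <- pmax(df$start_s, lo)
    df$end_s <- pmin(df$end_s, hi)
    rownames(df) <- NULL
    df
  }
  b <- clip(analysis$bursts)[c("electrode", "start_s", "end_s")]
  evs <- clip(rbind(analysis$network_spikes, analysis$network_bursts))
  evs <- evs[c("kind", "start_s", "end_s", "n_participants")]
  rownames(sp) <- NULL
  list(spikes = sp, bursts = b, events = evs)
}
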