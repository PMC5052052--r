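#' @import methods
NULL

#' Plate geometry of a multiwell MEA
#'
#' Describes the well and electrode naming of a multiwell microelectrode
#' array plate. The default corresponds to a 12-well plate (wells \code{"A1"}
#' to \code{"C4"}) with 64 electrodes per well laid out on an 8x8 grid and
#' named \code{"11"} to \code{"88"} (row digit then column digit).
#'
#' @slot nWells number of wells on the plate.
#' @slot electrodesPerWell number of electrodes in each well.
#' @slot wellIds character vector of well labels.
#' @slot electrodeIds character vector of electrode labels (shared by all
#'   wells).
#' @export
setClass("PlateLayout",
  representation(
    nWells = "integer",
    electrodesPerWell = "integer",
    wellIds = "character",
    electrodeIds = "character"
  )
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (length(object@wellIds) != object@nWells)
    msg <- c(msg, "length(wellIds) must equal nWells")
  if (length(object@electrodeIds) != object@electrodesPerWell)
    msg <- c(msg, "length(electrodeIds) must equal electrodesPerWell")
  if (anyDuplicated(object@wellIds))
    msg <- c(msg, "wellIds must be unique")
  if (anyDuplicated(object@electrodeIds))
    msg <- c(msg, "electrodeIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a plate layout
#'
#' @param nWells number of wells (default 12, arranged in rows A..C and
#'   columns 1..4 when \code{wellIds} is not given).
#' @param electrodesPerWell electrodes per well (default 64; default ids form
#'   an 8x8 grid \code{"11".."88"}).
#' @param wellIds,electrodeIds optional explicit label vectors overriding the
#'   generated defaults.
#' @return A \linkS4class{PlateLayout}.
#' @examples
#' plateLayout()
#' plateLayout(nWells = 2, electrodesPerWell = 4)
#' @export
plateLayout <- function(nWells = 12L, electrodesPerWell = 64L,
                        wellIds = NULL, electrodeIds = NULL) {
  nWells <- as.integer(nWells)
  electrodesPerWell <- as.integer(electrodesPerWell)
  if (is.null(wellIds)) {
    ncol <- ceiling(sqrt(nWells / 0.75))  # roughly 3:4 plate aspect
    ncol <- max(1L, as.integer(ncol))
    nrow <- ceiling(nWells / ncol)
    wellIds <- as.vector(t(outer(LETTERS[seq_len(nrow)], seq_len(ncol),
                                 paste0)))[seq_len(nWells)]
  }
  if (is.null(electrodeIds)) {
    side <- ceiling(sqrt(electrodesPerWell))
    electrodeIds <- as.vector(t(outer(seq_len(side), seq_len(side),
                                      paste0)))[seq_len(electrodesPerWell)]
  }
  new("PlateLayout", nWells = nWells, electrodesPerWell = electrodesPerWell,
      wellIds = as.character(wellIds), electrodeIds = as.character(electrodeIds))
}

#' One day's spike-list recording of a whole plate
#'
#' Holds the per-spike event table of one recording session (one day in
#' vitro, DIV), sorted by time, together with the plate layout and the
#' configured recording duration. The duration is a configured constant
#' (default 900 s = 15 min), never inferred from the last spike, so that rate
#' denominators do not shrink when late spikes happen to be absent.
#'
#' @slot div day in vitro of the recording (positive integer).
#' @slot duration recording length in seconds.
#' @slot events \code{data.frame} with columns \code{time_s}, \code{well},
#'   \code{electrode}, \code{amplitude_mV} (amplitude may be all \code{NA});
#'   rows sorted by \code{time_s}.
#' @slot layout the \linkS4class{PlateLayout}.
#' @export
setClass("MEARecording",
  representation(
    div = "integer",
    duration = "numeric",
    events = "data.frame",
    layout = "PlateLayout"
  )
)

setValidity("MEARecording", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("time_s", "well", "electrode", "amplitude_mV")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (length(object@div) != 1L || is.na(object@div) || object@div < 1L)
    msg <- c(msg, "div must be a single positive integer")
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  if (nrow(ev)) {
    if (is.unsorted(ev$time_s))
      msg <- c(msg, "events must be sorted by time_s")
    if (any(ev$time_s < 0) || any(ev$time_s > object@duration))
      msg <- c(msg, "event times must lie in [0, duration]")
    if (!all(ev$well %in% object@layout@wellIds))
      msg <- c(msg, "all event wells must belong to the plate layout")
    if (!all(ev$electrode %in% object@layout@electrodeIds))
      msg <- c(msg, "all event electrodes must belong to the well layout")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MEARecording from an event table
#'
#' Events are sorted by time; well/electrode columns are coerced to
#' character. An absent \code{amplitude_mV} column is filled with \code{NA}.
#'
#' @param events data.frame with \code{time_s}, \code{well}, \code{electrode}
#'   and optionally \code{amplitude_mV}.
#' @param div day in vitro.
#' @param duration recording duration in seconds (default 900).
#' @param layout a \linkS4class{PlateLayout} (default \code{plateLayout()}).
#' @return An \linkS4class{MEARecording}.
#' @export
MEARecording <- function(events, div, duration = 900,
                         layout = plateLayout()) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(time_s = numeric(), well = character(),
                         electrode = character(), amplitude_mV = numeric(),
                         stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events)
    if (!"amplitude_mV" %in% names(events)) events$amplitude_mV <- NA_real_
    events <- events[c("time_s", "well", "electrode", "amplitude_mV")]
    events$well <- as.character(events$well)
    events$electrode <- as.character(events$electrode)
    events$time_s <- as.numeric(events$time_s)
    o <- order(events$time_s)
    events <- events[o, , drop = FALSE]
    rownames(events) <- NULL
  }
  new("MEARecording", div = as.integer(div), duration = as.numeric(duration),
      events = events, layout = layout)
}

#' A multi-day MEA experiment with group assignment
#'
#' Bundles the per-DIV recordings of one experiment with the well-to-condition
#' assignment used by the group statistics.
#'
#' @slot recordings list of \linkS4class{MEARecording}, one per DIV, named by
#'   DIV.
#' @slot groups \code{data.frame} with columns \code{well}, \code{condition}.
#' @slot layout shared \linkS4class{PlateLayout}.
#' @export
setClass("MEAExperiment",
  representation(
    recordings = "list",
    groups = "data.frame",
    layout = "PlateLayout"
  )
)

setValidity("MEAExperiment", function(object) {
  msg <- character()
  if (!all(vapply(object@recordings, is, logical(1), "MEARecording")))
    return("recordings must all be MEARecording objects")
  divs <- vapply(object@recordings, function(r) r@div, integer(1))
  if (anyDuplicated(divs))
    msg <- c(msg, "each DIV may appear only once")
  if (!all(c("well", "condition") %in% names(object@groups)))
    msg <- c(msg, "groups must have columns well, condition")
  else if (anyDuplicated(object@groups$well))
    msg <- c(msg, "each well may carry only one condition")
  if (length(msg)) msg else TRUE
})

#' Construct an MEAExperiment
#'
#' @param recordings list of \linkS4class{MEARecording} objects.
#' @param groups data.frame with columns \code{well}, \code{condition}
#'   (see \code{\link{readGroupAssignment}}).
#' @param layout plate layout; defaults to the first recording's layout.
#' @return An \linkS4class{MEAExperiment} with recordings ordered and named
#'   by DIV.
#' @export
MEAExperiment <- function(recordings, groups, layout = NULL) {
  divs <- vapply(recordings, function(r) r@div, integer(1))
  recordings <- recordings[order(divs)]
  names(recordings) <- sort(divs)
  if (is.null(layout)) layout <- recordings[[1L]]@layout
  groups <- as.data.frame(groups)
  groups$well <- as.character(groups$well)
  groups$condition <- as.character(groups$condition)
  new("MEAExperiment", recordings = recordings, groups = groups,
      layout = layout)
}

#' Max-interval burst detection parameters
#'
#' Parameters of the max-interval burst detector (the sjemea lineage of
#' fixed-parameter detectors): a burst begins at a spike whose following
#' inter-spike interval (ISI) is at most \code{maxBeginISI}; it extends while
#' ISIs stay at most \code{maxEndISI}; bursts separated by less than
#' \code{minIBI} are merged; bursts shorter than \code{minDuration} or with
#' fewer than \code{minSpikes} spikes are discarded.
#'
#' @slot maxBeginISI seconds; ISI threshold to open a burst.
#' @slot maxEndISI seconds; ISI threshold to continue a burst
#'   (>= maxBeginISI).
#' @slot minIBI seconds; bursts closer than this are merged.
#' @slot minDuration seconds; minimum burst duration kept.
#' @slot minSpikes minimum spike count kept.
#' @export
setClass("BurstParams",
  representation(
    maxBeginISI = "numeric",
    maxEndISI = "numeric",
    minIBI = "numeric",
    minDuration = "numeric",
    minSpikes = "integer"
  )
)

setValidity("BurstParams", function(object) {
  msg <- character()
  vals <- c(object@maxBeginISI, object@maxEndISI, object@minIBI,
            object@minDuration, object@minSpikes)
  if (any(vals <= 0)) msg <- c(msg, "all burst parameters must be positive")
  if (object@maxEndISI < object@maxBeginISI)
    msg <- c(msg, "maxEndISI must be >= maxBeginISI")
  if (length(msg)) msg else TRUE
})

#' @rdname BurstParams-class
#' @param maxBeginISI,maxEndISI,minIBI,minDuration,minSpikes see slots.
#' @return A \linkS4class{BurstParams}.
#' @examples
#' burstParams()
#' @export
burstParams <- function(maxBeginISI = 0.1, maxEndISI = 0.25, minIBI = 0.8,
                        minDuration = 0.05, minSpikes = 5L) {
  new("BurstParams", maxBeginISI = maxBeginISI, maxEndISI = maxEndISI,
      minIBI = minIBI, minDuration = minDuration,
      minSpikes = as.integer(minSpikes))
}

#' Network-event detection parameters
#'
#' A synchronous network event (network spike or network burst) qualifies only
#' when at least \code{minParticipants} distinct electrodes participate —
#' by default 25\% of the electrodes in a well, i.e. 16 of 64. Events with
#' fewer participating electrodes are filtered out.
#'
#' @slot minParticipants minimum number of distinct participating electrodes.
#' @slot nsBin seconds; fixed bin width used to detect population (network)
#'   spikes.
#' @slot nbMergeGap seconds; adjacent network bursts closer than this merge
#'   (default 0: no merging).
#' @export
setClass("NetworkParams",
  representation(
    minParticipants = "integer",
    nsBin = "numeric",
    nbMergeGap = "numeric"
  )
)

setValidity("NetworkParams", function(object) {
  msg <- character()
  if (object@minParticipants < 1L)
    msg <- c(msg, "minParticipants must be >= 1")
  if (object@nsBin <= 0) msg <- c(msg, "nsBin must be > 0")
  if (object@nbMergeGap < 0) msg <- c(msg, "nbMergeGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NetworkParams-class
#' @param minParticipants minimum distinct electrodes per event; default
#'   \code{ceiling(0.25 * electrodesPerWell)} so non-64-electrode layouts keep
#'   the 25\%-of-the-well semantics.
#' @param nsBin network-spike bin width in seconds (default 0.025).
#' @param nbMergeGap merge gap for network bursts in seconds (default 0).
#' @param electrodesPerWell used only to derive the default
#'   \code{minParticipants}.
#' @return A \linkS4class{NetworkParams}.
#' @examples
#' networkParams()                          # 16 of 64
#' networkParams(electrodesPerWell = 16)    # 4 of 16
#' @export
networkParams <- function(minParticipants = NULL, nsBin = 0.025,
                          nbMergeGap = 0, electrodesPerWell = 64L) {
  if (is.null(minParticipants))
    minParticipants <- ceiling(0.25 * electrodesPerWell)
  new("NetworkParams", minParticipants = as.integer(minParticipants),
      nsBin = nsBin, nbMergeGap = nbMergeGap)
}

#' Activity-based QC mask
#'
#' Records, for every (DIV, well, electrode) of an experiment, whether the
#' electrode met the activity criterion that day, and for every well whether
#' it is retained by the well-inclusion rule.
#'
#' @slot electrodes \code{data.frame} with columns \code{div}, \code{well},
#'   \code{electrode}, \code{active} covering the full grid.
#' @slot wells \code{data.frame} with columns \code{well}, \code{included},
#'   \code{inactive_day_fraction}.
#' @slot params list of the parameters used (\code{minSpikesPerMin},
#'   \code{minActiveElectrodes}, \code{maxInactiveDayFraction}).
#' @seealso \code{\link{buildActivityMask}}
#' @export
setClass("ActivityMask",
  representation(
    electrodes = "data.frame",
    wells = "data.frame",
    params = "list"
  )
)

setValidity("ActivityMask", function(object) {
  msg <- character()
  if (!all(c("div", "well", "electrode", "active") %in%
             names(object@electrodes)))
    msg <- c(msg, "electrodes needs columns div, well, electrode, active")
  if (!all(c("well", "included", "inactive_day_fraction") %in%
             names(object@wells)))
    msg <- c(msg, "wells needs columns well, included, inactive_day_fraction")
  if (length(msg)) msg else TRUE
})

#' Two-group comparison of one activity feature
#'
#' Result container for the two-tier nonparametric comparison of one feature
#' between two conditions: per-DIV Mann-Whitney U p-values with Fisher's
#' combined probability over the analysis window, and the pooled-window
#' Mann-Whitney U test calibrated by permutation of well labels.
#'
#' @slot feature feature name.
#' @slot window integer DIVs pooled/combined (default 8:16).
#' @slot perDivP named numeric, two-sided MWU p per DIV (skipped DIVs absent).
#' @slot fisherChi2,fisherDf,fisherP Fisher combination of the window's
#'   per-DIV p-values.
#' @slot observedMwuP two-sided MWU p on the pooled window (one reduced value
#'   per well).
#' @slot permP empirical permutation p-value with the +1 correction,
#'   \code{(1 + #\{p_perm <= p_obs\}) / (nPerm + 1)}.
#' @slot nPerm number of label permutations.
#' @slot nPerGroup named integer, wells per condition.
#' @slot seed RNG seed used for the permutations (NA if none set).
#' @slot reducer how well-day values were pooled over the window
#'   ("mean" or "concat").
#' @export
setClass("GroupComparison",
  representation(
    feature = "character",
    window = "integer",
    perDivP = "numeric",
    fisherChi2 = "numeric",
    fisherDf = "integer",
    fisherP = "numeric",
    observedMwuP = "numeric",
    permP = "numeric",
    nPerm = "integer",
    nPerGroup = "integer",
    seed = "integer",
    reducer = "character"
  )
)

#' Simulation configuration for synthetic MEA experiments
#'
#' Parameters of the doubly stochastic point-process generator that emulates
#' a two-group multiwell MEA experiment: per-electrode Poisson background
#' firing, Poisson burst onsets emitting spike clusters, and well-level
#' synchronous network events recruiting a random electrode subset. Rates are
#' modulated per condition (multiplicative effects), per DIV (maturation
#' curve) and per well (lognormal random effect).
#'
#' @slot seed integer RNG seed for \code{\link{simulateExperiment}}.
#' @slot nControlWells,nTreatmentWells wells per condition (defaults 17, 16).
#' @slot divs integer DIVs simulated (default 3:19).
#' @slot duration recording length in seconds (default 900).
#' @slot electrodesPerWell electrodes per well (default 64).
#' @slot pElectrodeActive probability an electrode is alive.
#' @slot backgroundRateHz per-electrode Poisson background rate (Hz).
#' @slot burstRatePerMin per-electrode burst onset rate (per minute).
#' @slot spikesPerBurst mean spikes per burst.
#' @slot intraBurstISI mean within-burst inter-spike interval (s).
#' @slot networkEventRatePerMin well-level synchronous event rate (per
#'   minute).
#' @slot participationProb probability an alive electrode joins a network
#'   event.
#' @slot wellVariabilityCV between-well lognormal coefficient of variation.
#' @slot effects named list per condition of multipliers on
#'   \code{background_rate}, \code{burst_rate}, \code{burst_duration},
#'   \code{ibi}, \code{network_event_rate}; the control condition is all 1.
#' @slot maturationCurve named numeric, per-DIV global rate multiplier
#'   (default: sigmoidal rise over DIV3..DIV10, plateau after).
#' @slot conditions character of length 2: control then treatment label.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateExperiment}}
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nControlWells = "integer",
    nTreatmentWells = "integer",
    divs = "integer",
    duration = "numeric",
    electrodesPerWell = "integer",
    pElectrodeActive = "numeric",
    backgroundRateHz = "numeric",
    burstRatePerMin = "numeric",
    spikesPerBurst = "numeric",
    intraBurstISI = "numeric",
    networkEventRatePerMin = "numeric",
    participationProb = "numeric",
    wellVariabilityCV = "numeric",
    effects = "list",
    maturationCurve = "numeric",
    conditions = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(object@pElectrodeActive, object@participationProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  rates <- c(object@backgroundRateHz, object@burstRatePerMin,
             object@networkEventRatePerMin, object@wellVariabilityCV)
  if (any(rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(object@conditions) != 2L)
    msg <- c(msg, "exactly two conditions are required")
  if (!all(object@conditions %in% names(object@effects)))
    msg <- c(msg, "effects must name every condition")
  ctl <- object@effects[[object@conditions[1L]]]
  if (!is.null(ctl) && any(ctl != 1))
    msg <- c(msg, "control condition multipliers must all be 1")
  if (!all(as.character(object@divs) %in% names(object@maturationCurve)))
    msg <- c(msg, "maturationCurve must cover every simulated DIV")
  if (length(msg)) msg else TRUE
})
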