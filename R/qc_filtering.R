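#' Active electrodes of one recording day
#'
#' An electrode counts as active on a given day when it recorded at least
#' \code{minSpikesPerMin} spikes per minute over the whole recording — i.e.
#' total spike count >= \code{minSpikesPerMin * duration / 60}, boundary
#' inclusive (an electrode at exactly the threshold is active).
#'
#' @param recording an \linkS4class{MEARecording}.
#' @param minSpikesPerMin activity threshold in spikes per minute
#'   (default 5).
#' @return Named list mapping each well id of the layout to the character
#'   vector of its active electrode ids (possibly empty).
#' @examples
#' ev <- data.frame(time_s = seq(0, 899, length.out = 75),
#'                  well = "A1", electrode = "11")
#' rec <- MEARecording(ev, div = 8)
#' activeElectrodes(rec)$A1   # exactly 5/min -> active
#' @export
activeElectrodes <- function(recording, minSpikesPerMin = 5) {
  stopifnot(minSpikesPerMin > 0)
  if (recording@duration <= 0) stop("recording duration must be positive")
  need <- minSpikesPerMin * recording@duration / 60
  ev <- recording@events
  counts <- table(factor(paste(ev$well, ev$electrode, sep = "\r"),
                         levels = as.vector(outer(recording@layout@wellIds,
                                                  recording@layout@electrodeIds,
                                                  paste, sep = "\r"))))
  active <- counts >= need
  keys <- names(counts)[active]
  wells <- sub("\r.*$", "", keys)
  elecs <- sub("^.*\r", "", keys)
  out <- split(elecs, factor(wells, levels = recording@layout@wellIds))
  lapply(out, as.character)
}

#' Well-inclusion rule over recording days
#'
#' A well is removed from analysis when fewer than
#' \code{minActiveElectrodes} of its electrodes were active on more than
#' \code{maxInactiveDayFraction} of its recorded days (strictly greater: a
#' well inactive on exactly 30\% of days is retained). The denominator is
#' the number of days this well's plate was actually recorded.
#'
#' @param activeCounts named numeric vector: active-electrode count per
#'   recorded DIV for one well.
#' @param minActiveElectrodes minimum active electrodes for a day to count as
#'   an active day (default 16).
#' @param maxInactiveDayFraction tolerated fraction of inactive days
#'   (default 0.30).
#' @return \code{TRUE} (included) or \code{FALSE} (excluded), with the
#'   fraction of inactive days attached as
#'   \code{attr(x, "inactive_day_fraction")}.
#' @export
wellInclusion <- function(activeCounts, minActiveElectrodes = 16,
                          maxInactiveDayFraction = 0.30) {
  if (length(activeCounts) == 0L)
    stop("no recorded days: cannot evaluate well inclusion")
  frac <- mean(activeCounts < minActiveElectrodes)
  included <- !(frac > maxInactiveDayFraction)
  attr(included, "inactive_day_fraction") <- frac
  included
}

#' Build the experiment-wide activity mask
#'
#' Applies the per-day electrode activity rule and the across-day well
#' inclusion rule to every recording of an experiment. Electrode activity is
#' assessed per day, so an electrode may be active on some days and not on
#' others; downstream features are normalised by each day's active set.
#'
#' @param experiment an \linkS4class{MEAExperiment} (or a plain list of
#'   \linkS4class{MEARecording} objects sharing one layout).
#' @param minSpikesPerMin see \code{\link{activeElectrodes}}.
#' @param minActiveElectrodes,maxInactiveDayFraction see
#'   \code{\link{wellInclusion}}.
#' @return An \linkS4class{ActivityMask}.
#' @export
buildActivityMask <- function(experiment, minSpikesPerMin = 5,
                              minActiveElectrodes = 16,
                              maxInactiveDayFraction = 0.30) {
  recs <- if (is(experiment, "MEAExperiment")) experiment@recordings
          else experiment
  stopifnot(length(recs) > 0L)
  layout <- recs[[1L]]@layout
  divs <- vapply(recs, function(r) r@div, integer(1))

  per_div <- lapply(recs, activeElectrodes, minSpikesPerMin = minSpikesPerMin)
  grids <- mapply(function(act, div) {
    g <- expand.grid(electrode = layout@electrodeIds, well = layout@wellIds,
                     stringsAsFactors = FALSE)
    g$div <- div
    g$active <- mapply(function(w, e) e %in% act[[w]], g$well, g$electrode,
                       USE.NAMES = FALSE)
    g[c("div", "well", "electrode", "active")]
  }, per_div, divs, SIMPLIFY = FALSE)
  electrodes <- do.call(rbind, grids)
  rownames(electrodes) <- NULL

  wells <- data.frame(well = layout@wellIds, included = NA,
                      inactive_day_fraction = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(wells))) {
    w <- wells$well[i]
    counts <- vapply(per_div, function(act) length(act[[w]]), numeric(1))
    inc <- wellInclusion(counts, minActiveElectrodes, maxInactiveDayFraction)
    wells$included[i] <- as.logical(inc)
    wells$inactive_day_fraction[i] <- attr(inc, "inactive_day_fraction")
  }
  new("ActivityMask", electrodes = electrodes, wells = wells,
      params = list(minSpikesPerMin = minSpikesPerMin,
                    minActiveElectrodes = minActiveElectrodes,
                    maxInactiveDayFraction = maxInactiveDayFraction))
}

#' Audit-table serialization of an activity mask
#'
#' Writes (or reads back) the mask as two CSV audit tables: the per-day
#' per-electrode active flags and the per-well inclusion decisions.
#'
#' @param mask an \linkS4class{ActivityMask}.
#' @param electrodePath,wellPath output (or input) CSV paths.
#' @return \code{writeActivityMask} returns the paths invisibly;
#'   \code{readActivityMask} reconstructs the \linkS4class{ActivityMask}
#'   (parameters are stored as a comment-free sidecar in the well table's
#'   extra columns).
#' @export
writeActivityMask <- function(mask, electrodePath, wellPath) {
  utils::write.csv(mask@electrodes, electrodePath, row.names = FALSE,
                   quote = FALSE)
  w <- mask@wells
  w$min_spikes_per_min <- mask@params$minSpikesPerMin
  w$min_active_electrodes <- mask@params$minActiveElectrodes
  w$max_inactive_day_fraction <- mask@params$maxInactiveDayFraction
  utils::write.csv(w, wellPath, row.names = FALSE, quote = FALSE)
  invisible(c(electrodePath, wellPath))
}

#' @rdname writeActivityMask
#' @export
readActivityMask <- function(electrodePath, wellPath) {
  e <- utils::read.csv(electrodePath, stringsAsFactors = FALSE,
                       colClasses = c(div = "integer", well = "character",
                                      electrode = "character",
                                      active = "logical"))
  w <- utils::read.csv(wellPath, stringsAsFactors = FALSE,
                       colClasses = c(well = "character"))
  params <- list(minSpikesPerMin = w$min_spikes_per_min[1L],
                 minActiveElectrodes = w$min_active_electrodes[1L],
                 maxInactiveDayFraction = w$max_inactive_day_fraction[1L])
  new("ActivityMask", electrodes = e,
      wells = w[c("well", "included", "inactive_day_fraction")],
      params = params)
}
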