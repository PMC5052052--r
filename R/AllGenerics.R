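#' @rdname MEARecording-class
#' @param object,x an object.
#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))

#' @rdname MEARecording-class
#' @export
setGeneric("recordingDiv", function(x) standardGeneric("recordingDiv"))

#' @rdname MEARecording-class
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname PlateLayout-class
#' @param x an object carrying a plate layout.
#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))

#' @rdname PlateLayout-class
#' @export
setGeneric("plateElectrodes", function(x) standardGeneric("plateElectrodes"))

#' @rdname MEAExperiment-class
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))

#' @rdname MEAExperiment-class
#' @export
setGeneric("groupAssignment", function(x) standardGeneric("groupAssignment"))

#' @rdname ActivityMask-class
#' @param x an \linkS4class{ActivityMask}.
#' @export
setGeneric("includedWells", function(x) standardGeneric("includedWells"))

#' @rdname ActivityMask-class
#' @param div,well which slice of the mask to return.
#' @export
setGeneric("activeSet", function(x, div, well) standardGeneric("activeSet"))

## ---- accessors ----

#' @rdname MEARecording-class
#' @export
setMethod("spikeEvents", "MEARecording", function(x) x@events)

#' @rdname MEARecording-class
#' @export
setMethod("recordingDiv", "MEARecording", function(x) x@div)

#' @rdname MEARecording-class
#' @export
setMethod("recordingDuration", "MEARecording", function(x) x@duration)

#' @rdname PlateLayout-class
#' @export
setMethod("plateWells", "PlateLayout", function(x) x@wellIds)

#' @rdname PlateLayout-class
#' @export
setMethod("plateWells", "MEARecording", function(x) x@layout@wellIds)

#' @rdname PlateLayout-class
#' @export
setMethod("plateElectrodes", "PlateLayout", function(x) x@electrodeIds)

#' @rdname PlateLayout-class
#' @export
setMethod("plateElectrodes", "MEARecording", function(x) x@layout@electrodeIds)

#' @rdname MEAExperiment-class
#' @export
setMethod("recordings", "MEAExperiment", function(x) x@recordings)

#' @rdname MEAExperiment-class
#' @export
setMethod("groupAssignment", "MEAExperiment", function(x) x@groups)

#' @rdname ActivityMask-class
#' @export
setMethod("includedWells", "ActivityMask",
          function(x) x@wells$well[x@wells$included])

#' @rdname ActivityMask-class
#' @export
setMethod("activeSet", "ActivityMask", function(x, div, well) {
  e <- x@electrodes
  e$electrode[e$div == div & e$well == well & e$active]
})

## ---- show methods ----

setMethod("show", "PlateLayout", function(object) {
  cat("PlateLayout:", object@nWells, "wells x",
      object@electrodesPerWell, "electrodes\n")
  cat("  wells:", paste(utils::head(object@wellIds, 6), collapse = " "),
      if (object@nWells > 6) "...\n" else "\n")
})

setMethod("show", "MEARecording", function(object) {
  cat("MEARecording (DIV", object@div, ")\n", sep = "")
  cat("  duration:", object@duration, "s;",
      nrow(object@events), "spikes on",
      length(unique(paste(object@events$well, object@events$electrode))),
      "electrodes in", length(unique(object@events$well)), "wells\n")
})

setMethod("show", "MEAExperiment", function(object) {
  divs <- as.integer(names(object@recordings))
  cat("MEAExperiment:", length(divs), "recording days (DIV",
      min(divs), "-", max(divs), ")\n")
  print(table(object@groups$condition))
})

setMethod("show", "ActivityMask", function(object) {
  nw <- nrow(object@wells)
  cat("ActivityMask:", sum(object@wells$included), "of", nw,
      "wells included\n")
  cat("  rules: >=", object@params$minSpikesPerMin, "spikes/min;",
      "well kept unless <", object@params$minActiveElectrodes,
      "active electrodes on >",
      100 * object@params$maxInactiveDayFraction, "% of days\n")
})

setMethod("show", "BurstParams", function(object) {
  cat("BurstParams: beginISI<=", object@maxBeginISI,
      "s, endISI<=", object@maxEndISI, "s, merge IBI<", object@minIBI,
      "s, keep duration>=", object@minDuration, "s & spikes>=",
      object@minSpikes, "\n", sep = "")
})

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams: >=", object@minParticipants,
      " electrodes; spike bin ", object@nsBin, " s; burst merge gap ",
      object@nbMergeGap, " s\n", sep = "")
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison:", object@feature, "\n")
  cat("  window DIV", min(object@window), "-", max(object@window),
      "; wells per group:",
      paste(names(object@nPerGroup), object@nPerGroup, collapse = ", "), "\n")
  cat(sprintf("  Fisher: chi2 = %.3f (df %d), p = %.3g\n",
              object@fisherChi2, object@fisherDf, object@fisherP))
  cat(sprintf("  pooled MWU p = %.3g; permutation p = %.3g (%d permutations)\n",
              object@observedMwuP, object@permP, object@nPerm))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nControlWells, "+",
      object@nTreatmentWells, "wells;",
      length(object@divs), "DIVs;", object@duration, "s;",
      object@electrodesPerWell, "electrodes/well\n")
  tr <- object@effects[[object@conditions[2L]]]
  cat("  treatment effects:",
      paste(names(tr), signif(unlist(tr), 3), sep = "=", collapse = ", "),
      "\n")
})
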