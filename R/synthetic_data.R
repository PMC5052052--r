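#' Construct a simulation configuration
#'
#' Builds the parameter object of the synthetic MEA experiment generator.
#' Defaults emulate the design the analysis expects: 17 control and 16
#' treatment wells, daily 15-minute recordings over DIV3-DIV19, 64
#' electrodes per well, per-electrode Poisson background firing with
#' electrode-level bursting, well-level synchronous network events, a
#' sigmoidal maturation of activity from DIV3 to a plateau around DIV10, and
#' lognormal between-well variability. Treatment effects are multiplicative
#' on background rate, burst rate, burst duration, inter-burst interval and
#' network-event rate; the control condition is always all-1.
#'
#' @param seed RNG seed consumed by \code{\link{simulateExperiment}}.
#' @param nControlWells,nTreatmentWells wells per condition.
#' @param divs integer vector of simulated DIVs.
#' @param duration recording length in seconds.
#' @param electrodesPerWell electrodes per well.
#' @param pElectrodeActive probability an electrode is alive.
#' @param backgroundRateHz per-electrode Poisson background rate at full
#'   maturation (Hz).
#' @param burstRatePerMin per-electrode burst-onset rate (bursts/min).
#' @param spikesPerBurst mean spikes per burst (burst size is
#'   \code{1 + Poisson(spikesPerBurst - 1)}).
#' @param intraBurstISI mean within-burst inter-spike interval (s,
#'   exponential).
#' @param networkEventRatePerMin well-level synchronous event rate
#'   (events/min).
#' @param participationProb probability an alive electrode is recruited into
#'   a network event.
#' @param wellVariabilityCV lognormal coefficient of variation of the
#'   per-well rate multiplier (mean 1).
#' @param treatmentEffects named numeric multipliers applied to the treatment
#'   condition: \code{background_rate}, \code{burst_rate},
#'   \code{burst_duration}, \code{ibi}, \code{network_event_rate}. The
#'   \code{ibi} multiplier rescales the gap between bursts (values < 1 pack
#'   bursts more densely); \code{burst_duration} rescales the within-burst
#'   ISI.
#' @param maturationCurve optional named numeric per-DIV multiplier; default
#'   is the logistic \code{1 / (1 + exp(-(div - 6.5) / 1.2))} rising over
#'   DIV3-DIV10 then plateauing near 1.
#' @param conditions labels, control first.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nControlWells = 17L, nTreatmentWells = 16L,
                             divs = 3:19, duration = 900,
                             electrodesPerWell = 64L,
                             pElectrodeActive = 0.85,
                             backgroundRateHz = 1.0,
                             burstRatePerMin = 5,
                             spikesPerBurst = 8,
                             intraBurstISI = 0.01,
                             networkEventRatePerMin = 2,
                             participationProb = 0.6,
                             wellVariabilityCV = 0.3,
                             treatmentEffects = c(background_rate = 1.5,
                                                  burst_rate = 1.5,
                                                  burst_duration = 1.3,
                                                  ibi = 0.7,
                                                  network_event_rate = 1.5),
                             maturationCurve = NULL,
                             conditions = c("control", "treatment")) {
  divs <- as.integer(divs)
  if (is.null(maturationCurve)) {
    maturationCurve <- stats::setNames(
      1 / (1 + exp(-(divs - 6.5) / 1.2)), as.character(divs))
  }
  eff_names <- c("background_rate", "burst_rate", "burst_duration", "ibi",
                 "network_event_rate")
  tr <- stats::setNames(rep(1, length(eff_names)), eff_names)
  tr[names(treatmentEffects)] <- treatmentEffects
  effects <- list(stats::setNames(rep(1, length(eff_names)), eff_names),
                  tr)
  names(effects) <- conditions
  new("SimulationConfig",
      seed = as.integer(seed),
      nControlWells = as.integer(nControlWells),
      nTreatmentWells = as.integer(nTreatmentWells),
      divs = divs, duration = as.numeric(duration),
      electrodesPerWell = as.integer(electrodesPerWell),
      pElectrodeActive = pElectrodeActive,
      backgroundRateHz = backgroundRateHz,
      burstRatePerMin = burstRatePerMin,
      spikesPerBurst = spikesPerBurst,
      intraBurstISI = intraBurstISI,
      networkEventRatePerMin = networkEventRatePerMin,
      participationProb = participationProb,
      wellVariabilityCV = wellVariabilityCV,
      effects = effects,
      maturationCurve = maturationCurve,
      conditions = conditions)
}

## layout for a simulated experiment: one virtual plate holding every well
.simLayout <- function(config) {
  nW <- config@nControlWells + config@nTreatmentWells
  plateLayout(nWells = nW, electrodesPerWell = config@electrodesPerWell)
}

#' Simulate one well of one recording day
#'
#' Draws the spike events of a single well as the union of three point
#' processes on each alive electrode: homogeneous Poisson background firing;
#' a burst process (Poisson burst onsets, each emitting a
#' \code{1 + Poisson} spike cluster with exponential within-burst ISIs); and
#' well-level synchronous network events (Poisson onsets; each recruits
#' every alive electrode independently with \code{participationProb}, and a
#' recruited electrode fires a short high-rate cluster at the event time).
#' All rates are scaled by the condition's multipliers, the DIV's maturation
#' multiplier, and the well's lognormal random effect. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param condition condition label (must be one of
#'   \code{config@conditions}).
#' @param div day in vitro (must be in \code{config@divs}).
#' @param well well id to stamp on the events.
#' @param layout plate layout for the resulting recording.
#' @param wellEffect lognormal well multiplier; drawn if \code{NULL}.
#' @param aliveElectrodes electrode ids alive in this well; drawn if
#'   \code{NULL}.
#' @return An \linkS4class{MEARecording} containing the well's events.
#' @export
simulateWell <- function(config, condition, div, well = NULL, layout = NULL,
                         wellEffect = NULL, aliveElectrodes = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(layout)) layout <- .simLayout(config)
  if (is.null(well)) well <- layout@wellIds[1L]
  eff <- config@effects[[condition]]
  mat <- config@maturationCurve[[as.character(div)]]
  if (is.null(wellEffect)) {
    cv <- config@wellVariabilityCV
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      wellEffect <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else wellEffect <- 1
  }
  if (is.null(aliveElectrodes)) {
    alive <- stats::runif(layout@electrodesPerWell) <= config@pElectrodeActive
    aliveElectrodes <- layout@electrodeIds[alive]
  }
  dur <- config@duration
  scale <- mat * wellEffect
  t_parts <- list(); e_parts <- list()

  if (length(aliveElectrodes)) {
    nE <- length(aliveElectrodes)
    bg_rate <- config@backgroundRateHz * eff[["background_rate"]] * scale
    br_rate <- config@burstRatePerMin / 60 * eff[["burst_rate"]] /
      eff[["ibi"]] * scale
    isi_mean <- config@intraBurstISI * eff[["burst_duration"]]
    # background: one Poisson count per electrode, uniform times
    nbg <- stats::rpois(nE, bg_rate * dur)
    if (sum(nbg)) {
      t_parts[[length(t_parts) + 1L]] <- stats::runif(sum(nbg), 0, dur)
      e_parts[[length(e_parts) + 1L]] <- rep(aliveElectrodes, nbg)
    }
    # electrode bursts: Poisson onsets, 1 + Poisson cluster sizes,
    # exponential within-burst ISIs (first spike at the onset)
    nb <- stats::rpois(nE, br_rate * dur)
    if (sum(nb)) {
      onsets <- stats::runif(sum(nb), 0, dur)
      sizes <- 1L + stats::rpois(sum(nb), max(config@spikesPerBurst - 1, 0))
      isis <- stats::rexp(sum(sizes), rate = 1 / isi_mean)
      burst_id <- rep(seq_along(sizes), sizes)
      off <- stats::ave(isis, burst_id, FUN = cumsum) - isis
      tt <- onsets[burst_id] + off
      ee <- rep(rep(aliveElectrodes, nb), sizes)
      keep <- tt < dur
      t_parts[[length(t_parts) + 1L]] <- tt[keep]
      e_parts[[length(e_parts) + 1L]] <- ee[keep]
    }
    # well-level synchronous network events: each recruits alive electrodes
    # independently; a recruited electrode fires a short high-rate cluster
    nev_rate <- config@networkEventRatePerMin / 60 *
      eff[["network_event_rate"]] * scale
    nev <- stats::rpois(1, nev_rate * dur)
    if (nev > 0) {
      onsets <- stats::runif(nev, 0, dur)
      recruited <- stats::runif(nev * nE) <= config@participationProb
      ev_elec <- rep(aliveElectrodes, nev)[recruited]
      ev_onset <- rep(onsets, each = nE)[recruited]
      if (length(ev_elec)) {
        nsp <- 3L + stats::rpois(length(ev_elec), 2)
        isis <- stats::rexp(sum(nsp), rate = 1 / 0.002)
        cl_id <- rep(seq_along(nsp), nsp)
        off <- stats::ave(isis, cl_id, FUN = cumsum)
        tt <- rep(ev_onset, nsp) + off
        ee <- rep(ev_elec, nsp)
        keep <- tt < dur
        t_parts[[length(t_parts) + 1L]] <- tt[keep]
        e_parts[[length(e_parts) + 1L]] <- ee[keep]
      }
    }
  }
  times <- unlist(t_parts, use.names = FALSE)
  elec <- unlist(e_parts, use.names = FALSE)
  if (is.null(times)) { times <- numeric(0); elec <- character(0) }
  n <- length(times)
  amp <- if (n) stats::rlnorm(n, log(0.02), 0.3) else numeric(0)
  MEARecording(
    data.frame(time_s = times, well = rep(well, n), electrode = elec,
               amplitude_mV = amp, stringsAsFactors = FALSE),
    div = div, duration = dur, layout = layout)
}

#' Simulate a complete two-group MEA experiment
#'
#' Generates the full experiment described by the configuration: every well
#' of both conditions on every DIV, with per-well lognormal effects and
#' alive-electrode sets drawn once per well and held fixed across days.
#' With \code{dir} set, one spike-list CSV per DIV, the group-assignment CSV
#' and a JSON manifest of the full configuration are written in the standard
#' dialect; the in-memory experiment is returned either way. Identical seeds
#' yield identical experiments.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory for spike-list files.
#' @param dialect CSV dialect used when writing.
#' @return An \linkS4class{MEAExperiment}.
#' @export
simulateExperiment <- function(config, dir = NULL,
                               dialect = spikeListDialect()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  layout <- .simLayout(config)
  nC <- config@nControlWells; nT <- config@nTreatmentWells
  wells <- layout@wellIds
  cond <- rep(config@conditions, c(nC, nT))
  groups <- data.frame(well = wells, condition = cond,
                       stringsAsFactors = FALSE)

  cv <- config@wellVariabilityCV
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  wellEffects <- if (sdlog > 0)
    stats::rlnorm(length(wells), -sdlog^2 / 2, sdlog) else
      rep(1, length(wells))
  aliveSets <- lapply(wells, function(w) {
    layout@electrodeIds[stats::runif(layout@electrodesPerWell) <=
                          config@pElectrodeActive]
  })

  recs <- vector("list", length(config@divs))
  for (i in seq_along(config@divs)) {
    d <- config@divs[i]
    parts <- vector("list", length(wells))
    for (j in seq_along(wells)) {
      r <- simulateWell(config, cond[j], d, well = wells[j], layout = layout,
                        wellEffect = wellEffects[j],
                        aliveElectrodes = aliveSets[[j]])
      parts[[j]] <- r@events
    }
    ev <- do.call(rbind, parts)
    recs[[i]] <- MEARecording(ev, div = d, duration = config@duration,
                              layout = layout)
  }
  exp <- MEAExperiment(recs, groups, layout)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (r in exp@recordings)
      writeSpikeList(r, file.path(dir, sprintf("spikelist_div%02d.csv",
                                               r@div)), dialect)
    writeGroupAssignment(groups, file.path(dir, "groups.csv"))
    manifest <- list(
      seed = config@seed, n_control_wells = nC, n_treatment_wells = nT,
      divs = config@divs, duration_s = config@duration,
      electrodes_per_well = config@electrodesPerWell,
      p_electrode_active = config@pElectrodeActive,
      background_rate_hz = config@backgroundRateHz,
      burst_rate_per_min = config@burstRatePerMin,
      spikes_per_burst = config@spikesPerBurst,
      intra_burst_isi_s = config@intraBurstISI,
      network_event_rate_per_min = config@networkEventRatePerMin,
      participation_prob = config@participationProb,
      well_variability_cv = config@wellVariabilityCV,
      effects = config@effects,
      maturation_curve = as.list(config@maturationCurve),
      conditions = config@conditions)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  exp
}

#' Compare imposed simulation effects with recovered feature ratios
#'
#' For a simulated experiment with known multiplicative treatment effects,
#' computes the treatment/control ratio of mean well-level features over a
#' DIV window and reports it against the imposed multiplier. The mapping is
#' exact when each feature is dominated by the process its multiplier
#' scales (e.g. the \code{mfr_hz} ratio equals the background multiplier
#' only when background firing dominates or the other multipliers are
#' equal); known-truth recovery studies should isolate processes
#' accordingly.
#'
#' @param config the \linkS4class{SimulationConfig} that generated the data.
#' @param features feature table from the analysis pipeline (with
#'   \code{condition} filled).
#' @param window DIVs over which to average (default 8:16 intersected with
#'   the simulated DIVs).
#' @return \code{data.frame} with columns \code{feature}, \code{imposed},
#'   \code{estimated} (group ratio) and \code{rel_error}.
#' @export
recoverParameters <- function(config, features, window = NULL) {
  if (is.null(window)) window <- intersect(8:16, config@divs)
  f <- features[features$div %in% window & !is.na(features$condition), ,
                drop = FALSE]
  ctl <- config@conditions[1L]; trt <- config@conditions[2L]
  eff <- config@effects[[trt]]
  ratio <- function(col) {
    mean(f[[col]][f$condition == trt], na.rm = TRUE) /
      mean(f[[col]][f$condition == ctl], na.rm = TRUE)
  }
  map <- data.frame(
    feature = c("mfr_hz", "burst_rate_per_min", "network_burst_rate_per_s"),
    imposed = c(eff[["background_rate"]], eff[["burst_rate"]] / eff[["ibi"]],
                eff[["network_event_rate"]]),
    stringsAsFactors = FALSE)
  map$estimated <- vapply(map$feature, ratio, numeric(1))
  map$rel_error <- abs(map$estimated - map$imposed) / map$imposed
  rownames(map) <- NULL
  map
}
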