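#' Spike-list CSV dialect
#'
#' Column-name configuration for spike-list files. Axion Maestro exports vary
#' across software versions, so the mapping is configurable; the defaults are
#' \code{"Time (s)"} for the timestamp, \code{"Electrode"} for a combined
#' well_electrode token such as \code{"A1_12"} (split on \code{sep}), and
#' \code{"Amplitude(mV)"} for the optional spike amplitude.
#'
#' @param time,electrode,amplitude header names in the file; \code{amplitude}
#'   may be absent from the file.
#' @param sep separator between the well and electrode parts of the combined
#'   electrode token.
#' @return A named list usable as the \code{dialect} argument of
#'   \code{\link{readSpikeList}} and \code{\link{writeSpikeList}}.
#' @export
spikeListDialect <- function(time = "Time (s)", electrode = "Electrode",
                             amplitude = "Amplitude(mV)", sep = "_") {
  list(time = time, electrode = electrode, amplitude = amplitude, sep = sep)
}

#' Read a spike-list file
#'
#' Reads one recording day's spike list (one row per detected spike) into an
#' \linkS4class{MEARecording}. Rows are validated against the plate layout:
#' in lenient mode (the default) rows whose well or electrode is not part of
#' the layout, or whose timestamp cannot be parsed, are dropped and counted;
#' in strict mode the first bad row raises an error with its line number.
#' The recording duration is the configured constant \code{duration}, never
#' the maximum spike time.
#'
#' @param path file to read.
#' @param div day in vitro to stamp on the recording.
#' @param dialect column mapping, see \code{\link{spikeListDialect}}.
#' @param layout plate layout used for validation.
#' @param duration recording duration in seconds (default 900).
#' @param strict if \code{TRUE}, any invalid row is an error; if \code{FALSE}
#'   invalid rows are dropped with a report.
#' @return An \linkS4class{MEARecording}; the number of rejected rows is
#'   attached as \code{attr(x, "n_rejected")} (with the offending line
#'   numbers in \code{attr(x, "rejected_lines")}).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Time (s),Electrode,Amplitude(mV)",
#'              "0.10,A1_11,0.02", "0.20,A1_12,0.03"), f)
#' rec <- readSpikeList(f, div = 8)
#' spikeEvents(rec)
#' @export
readSpikeList <- function(path, div, dialect = spikeListDialect(),
                          layout = plateLayout(), duration = 900,
                          strict = FALSE) {
  if (!file.exists(path)) stop("spike-list file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("empty spike list: ", path)
    rec <- MEARecording(NULL, div = div, duration = duration, layout = layout)
    attr(rec, "n_rejected") <- 0L
    return(rec)
  }
  for (col in c("time", "electrode")) {
    if (!dialect[[col]] %in% names(raw))
      stop("spike-list format error: missing required column '",
           dialect[[col]], "' in ", path)
  }
  time_s <- suppressWarnings(as.numeric(raw[[dialect$time]]))
  tok <- raw[[dialect$electrode]]
  parts <- strsplit(tok, dialect$sep, fixed = TRUE)
  well <- vapply(parts, function(p) if (length(p) >= 1L) p[[1L]] else NA_character_,
                 character(1))
  electrode <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                      character(1))
  amp <- if (!is.null(dialect$amplitude) && dialect$amplitude %in% names(raw))
    suppressWarnings(as.numeric(raw[[dialect$amplitude]])) else
      rep(NA_real_, nrow(raw))

  bad_time <- is.na(time_s) | time_s < 0 | time_s > duration
  bad_elec <- is.na(well) | is.na(electrode) |
    !(well %in% layout@wellIds) | !(electrode %in% layout@electrodeIds)
  bad <- bad_time | bad_elec
  if (any(bad) && strict) {
    line <- which(bad)[1L] + 1L  # header is line 1
    what <- if (bad_time[which(bad)[1L]]) "unparseable or out-of-range timestamp"
            else "well/electrode outside the plate layout"
    stop("spike-list row error at line ", line, ": ", what,
         " ('", tok[which(bad)[1L]], "')")
  }
  keep <- !bad
  rec <- MEARecording(
    data.frame(time_s = time_s[keep], well = well[keep],
               electrode = electrode[keep], amplitude_mV = amp[keep],
               stringsAsFactors = FALSE),
    div = div, duration = duration, layout = layout)
  attr(rec, "n_rejected") <- sum(bad)
  if (any(bad)) attr(rec, "rejected_lines") <- which(bad) + 1L
  rec
}

#' Write a spike-list file
#'
#' Writes an \linkS4class{MEARecording} back to the spike-list CSV dialect,
#' such that \code{readSpikeList(writeSpikeList(x))} reproduces the events
#' exactly. When every amplitude is missing the amplitude column is omitted.
#'
#' @param recording an \linkS4class{MEARecording}.
#' @param path output file.
#' @param dialect column mapping, see \code{\link{spikeListDialect}}.
#' @return \code{path}, invisibly.
#' @export
writeSpikeList <- function(recording, path, dialect = spikeListDialect()) {
  stopifnot(is(recording, "MEARecording"))
  validObject(recording)
  ev <- recording@events
  out <- data.frame(
    time = sprintf("%.17g", ev$time_s),
    electrode = paste(ev$well, ev$electrode, sep = dialect$sep),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(dialect$time, dialect$electrode)
  if (nrow(ev) == 0L) {
    out <- out[, , drop = FALSE]
  }
  if (nrow(ev) > 0L && !all(is.na(ev$amplitude_mV))) {
    out[[dialect$amplitude]] <- sprintf("%.17g", ev$amplitude_mV)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write spike list to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a well-to-condition assignment table
#'
#' Reads the two-column CSV (\code{well}, \code{condition}) mapping wells to
#' experimental groups. A well listed twice with the same condition collapses
#' to one entry; conflicting duplicates are an error naming the well; wells
#' absent from the layout raise a warning.
#'
#' @param path file with columns \code{well} and \code{condition} (header
#'   names are matched case-insensitively; the first two columns are used if
#'   the names differ).
#' @param layout plate layout used to warn about unknown wells, or
#'   \code{NULL} to skip the check.
#' @return \code{data.frame} with columns \code{well}, \code{condition}.
#' @export
readGroupAssignment <- function(path, layout = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop("empty group-assignment table: no comparison possible")
  nm <- tolower(names(tab))
  wcol <- match("well", nm); ccol <- match("condition", nm)
  if (is.na(wcol)) wcol <- 1L
  if (is.na(ccol)) ccol <- 2L
  out <- data.frame(well = as.character(tab[[wcol]]),
                    condition = as.character(tab[[ccol]]),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  dup <- out$well[duplicated(out$well)]
  if (length(dup))
    stop("conflicting conditions for well(s): ",
         paste(unique(dup), collapse = ", "))
  if (!is.null(layout)) {
    unknown <- setdiff(out$well, layout@wellIds)
    if (length(unknown))
      warning("wells not in the plate layout: ",
              paste(unknown, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' @rdname readGroupAssignment
#' @param groups data.frame with columns \code{well}, \code{condition}.
#' @export
writeGroupAssignment <- function(groups, path) {
  utils::write.csv(groups[c("well", "condition")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
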