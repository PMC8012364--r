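# Plain-text containers: the event log is a straight CSV following the
# schema in ?SessionEvents; traces travel in a CSV body preceded by
# `#key: value` metadata lines (fs_hz, t0_s, provenance), so every artifact
# is diffable and survives text-only archiving.

#' Write / read a session event log (CSV)
#'
#' @param events a \linkS4class{SessionEvents}
#' @param path file path
#' @return \code{writeSessionEvents} returns \code{path} invisibly;
#'   \code{readSessionEvents} returns a validated
#'   \linkS4class{SessionEvents}.
#' @export
writeSessionEvents <- function(events, path) {
  stopifnot(is(events, "SessionEvents"))
  write.csv(eventTable(events), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSessionEvents
#' @export
readSessionEvents <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.EVENT_COLUMNS, names(ev))
  if (length(missing_cols))
    stop("event log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.EVENT_COLUMNS, c("session_id", "outcome")))
    ev[[col]] <- as.numeric(ev[[col]])
  SessionEvents(ev)
}

.writeMetaCsv <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, format(meta[[k]], digits = 17)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.readMetaCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isMeta <- startsWith(lines, "#")
  metaLines <- lines[isMeta & seq_along(lines) <= which(!isMeta)[1L]]
  meta <- list()
  for (ln in metaLines) {
    kv <- sub("^#", "", ln)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- read.csv(text = lines[!startsWith(lines, "#")],
                 stringsAsFactors = FALSE)
  list(meta = meta, data = df)
}

#' Write / read a two-channel raw recording (text container)
#'
#' @param recording a \linkS4class{RawPhotometryRecording}
#' @param path file path
#' @return the recording (read) or the path, invisibly (write).
#' @export
writePhotometryRecording <- function(recording, path) {
  stopifnot(is(recording, "RawPhotometryRecording"))
  .writeMetaCsv(data.frame(sig470 = recording@sig470,
                           sig405 = recording@sig405),
                list(fs_hz = recording@fsHz, t0_s = recording@t0S), path)
}

#' @rdname writePhotometryRecording
#' @export
readPhotometryRecording <- function(path) {
  x <- .readMetaCsv(path)
  if (is.null(x$meta$fs_hz)) stop("fs_hz attribute absent in ", path)
  if (!all(c("sig470", "sig405") %in% names(x$data)))
    stop("trace container must hold sig470 and sig405 columns")
  RawPhotometryRecording(x$data$sig470, x$data$sig405,
                         as.numeric(x$meta$fs_hz),
                         as.numeric(x$meta$t0_s %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a processed trace (text container)
#'
#' @param trace a \linkS4class{ProcessedTrace}
#' @param path file path
#' @return the trace (read) or the path, invisibly (write).
#' @export
writeProcessedTrace <- function(trace, path) {
  stopifnot(is(trace, "ProcessedTrace"))
  .writeMetaCsv(data.frame(dff = trace@dff),
                list(fs_hz = trace@fsHz, t0_s = trace@t0S), path)
}

#' @rdname writeProcessedTrace
#' @export
readProcessedTrace <- function(path) {
  x <- .readMetaCsv(path)
  if (is.null(x$meta$fs_hz)) stop("fs_hz attribute absent in ", path)
  ProcessedTrace(x$data$dff, as.numeric(x$meta$fs_hz),
                 as.numeric(x$meta$t0_s %||% 0))
}

#' Export a significance mask as frame table and interval list
#'
#' Writes \code{<stem>_frames.csv} (frame_time_s, significant) and
#' \code{<stem>_windows.csv} (start_s, end_s, label) — the interval list is
#' BED-like, half-open.
#'
#' @param mask a \linkS4class{SignificanceMask}
#' @param stem output path stem
#' @param label interval label
#' @return character(2) of written paths, invisibly.
#' @export
writeSignificanceMask <- function(mask, stem, label = "significant") {
  stopifnot(is(mask, "SignificanceMask"))
  framesPath <- paste0(stem, "_frames.csv")
  windowsPath <- paste0(stem, "_windows.csv")
  write.csv(data.frame(frame_time_s = mask@frameTimesS,
                       significant = mask@significant),
            framesPath, row.names = FALSE)
  w <- mask@windows
  w$label <- if (nrow(w)) label else character(0)
  write.csv(w, windowsPath, row.names = FALSE)
  invisible(c(framesPath, windowsPath))
}

#' Load a session: event log plus raw recording
#'
#' Schema violations are reported with the offending file and field; events
#' referencing times beyond the trace end load fine (epoching drops and logs
#' such trials later).
#'
#' @param eventsPath event-log CSV path
#' @param tracesPath trace-container path
#' @return list(events =, recording =).
#' @export
loadSession <- function(eventsPath, tracesPath) {
  list(events = readSessionEvents(eventsPath),
       recording = readPhotometryRecording(tracesPath))
}
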