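#' Uniformly sampled channel trace
#'
#' The carrier object for every signal in the simulated chain: a start time,
#' a sampling rate, a vector of sample values in volts and an optional
#' per-sample staleness flag (set by the FIFO aligner when an SPR value had to
#' be re-emitted because its packet was late or lost).
#'
#' @param values numeric vector of sample values, in volts.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, in seconds.
#' @param channel one of `"SPR1"`, `"SPR2"`, `"ECG1"`, `"ECG2"`, `"GEN"`.
#' @param stale logical vector of the same length as `values`; `FALSE` by
#'   default.
#' @param meta optional named list of free-form metadata (true event times,
#'   generator spec, ...). Kept verbatim.
#' @return An object of class `spr_trace`.
#' @export
spr_trace <- function(values, fs_hz, t0_s = 0,
                      channel = c("GEN", "SPR1", "SPR2", "ECG1", "ECG2"),
                      stale = NULL, meta = list()) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0)
    stop("`fs_hz` must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("trace values must be finite", call. = FALSE)
  if (is.null(stale)) stale <- rep(FALSE, length(values))
  if (length(stale) != length(values))
    stop("`stale` must have one flag per sample", call. = FALSE)
  structure(
    list(values = values, fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s),
         channel = channel, stale = as.logical(stale), meta = meta),
    class = "spr_trace"
  )
}

#' Sample times of a trace
#' @param x an [spr_trace].
#' @return numeric vector of sample instants in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "spr_trace"))
  x$t0_s + (seq_along(x$values) - 1L) / x$fs_hz
}

#' @export
length.spr_trace <- function(x) length(x$values)

#' Duration of a trace in seconds
#' @param x an [spr_trace].
#' @export
trace_duration <- function(x) length(x$values) / x$fs_hz

#' @export
print.spr_trace <- function(x, ...) {
  cat(sprintf("<spr_trace> channel %s: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              x$channel, length(x$values), x$fs_hz,
              trace_duration(x), x$t0_s))
  if (any(x$stale))
    cat(sprintf("  stale samples: %d (%.3f%%)\n", sum(x$stale),
                100 * mean(x$stale)))
  rng <- range(x$values)
  cat(sprintf("  range: [%.6g, %.6g] V\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.spr_trace <- function(x, ..., max_points = 20000L) {
  t <- trace_times(x)
  idx <- if (length(t) > max_points)
    round(seq(1L, length(t), length.out = max_points)) else seq_along(t)
  graphics::plot(t[idx], x$values[idx], type = "l",
                 xlab = "time (s)", ylab = "value (V)",
                 main = paste("channel", x$channel), ...)
  invisible(x)
}

#' Write traces to a CSV file (long format) with a JSON sidecar
#'
#' The dialect is `time_s,channel,value_V,stale` with a header row, UTF-8,
#' `.` decimal separator and full double precision. A JSON sidecar
#' `<path>.json` stores per-channel sampling rate, start time and any
#' metadata so that [read_trace()] can reconstruct the traces losslessly.
#'
#' @param traces a single [spr_trace] or a list of them.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "spr_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "spr_trace")))
  rows <- lapply(traces, function(tr) {
    data.frame(time_s = format(trace_times(tr), digits = 17),
               channel = rep(tr$channel, length(tr$values)),
               value_V = format(tr$values, digits = 17),
               stale = as.integer(tr$stale))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  side <- lapply(traces, function(tr)
    list(channel = tr$channel, fs_hz = tr$fs_hz, t0_s = tr$t0_s,
         n = length(tr$values), meta = tr$meta))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read traces written by [write_trace()]
#'
#' @param path CSV file path written by [write_trace()].
#' @return A named list of [spr_trace] objects (names are channel ids).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  need <- c("time_s", "channel", "value_V", "stale")
  head_names <- names(utils::read.csv(path, nrows = 1))
  if (!identical(head_names, need))
    stop("trace CSV schema mismatch in '", path, "' (line 1): expected header ",
         paste(need, collapse = ","), call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, colClasses = c("numeric", "character", "numeric", "integer")),
    error = function(e) stop("trace CSV parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  sidepath <- paste0(path, ".json")
  side <- if (file.exists(sidepath)) jsonlite::read_json(sidepath) else NULL
  out <- list()
  for (ch in unique(tab$channel)) {
    sub <- tab[tab$channel == ch, , drop = FALSE]
    info <- NULL
    if (!is.null(side)) {
      hit <- Filter(function(s) identical(s$channel, ch), side)
      if (length(hit)) info <- hit[[1]]
    }
    fs <- if (!is.null(info)) info$fs_hz else {
      dt <- diff(sub$time_s)
      if (length(dt) == 0) 1 else 1 / stats::median(dt)
    }
    t0 <- if (!is.null(info)) info$t0_s else if (nrow(sub)) sub$time_s[1] else 0
    meta <- if (!is.null(info) && length(info$meta)) info$meta else list()
    out[[ch]] <- spr_trace(sub$value_V, fs_hz = fs, t0_s = t0,
                           channel = ch, stale = sub$stale > 0, meta = meta)
  }
  out
}
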