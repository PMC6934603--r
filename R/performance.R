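# Canonical timeline: 960 ticks per quarter note. All internal timing math is
# done in ticks as doubles; integerisation happens only when a MIDI file is
# written.
TPQ <- 960

#' Construct a performance
#'
#' A `performance` holds the note events of one solo recording on the
#' canonical 960-ticks-per-quarter timeline, together with its (single,
#' constant) tempo and all non-note MIDI events carried through opaquely.
#'
#' @param notes data frame with columns `onset` (ticks, >= 0, may be
#'   fractional), `pitch` (0-127), `velocity` (1-127), `duration` (ticks, > 0)
#'   and `channel` (0-15). Rows are sorted by `(onset, pitch)`.
#' @param bpm tempo in quarter notes per minute (positive).
#' @param passthrough data frame of non-note MIDI events (tempo, control
#'   change including CC64 sustain, program change, sysex, other meta events)
#'   with columns `tick`, `status`, `type` and a list column `data` of raw
#'   byte vectors. Defaults to none.
#' @return an object of class `performance`.
#' @examples
#' p <- performance(data.frame(onset = c(0, 640), pitch = c(60, 64),
#'                             velocity = 80, duration = 240, channel = 0),
#'                  bpm = 140)
#' p
#' @export
performance <- function(notes, bpm, passthrough = empty_passthrough()) {
  stopifnot(is.data.frame(notes))
  required <- c("onset", "pitch", "velocity", "duration", "channel")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols)) {
    stop("notes is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  notes <- notes[required]
  if (nrow(notes)) {
    if (any(notes$onset < 0)) stop("note onsets must be >= 0")
    if (any(notes$duration <= 0)) stop("note durations must be > 0")
    if (any(notes$pitch < 0 | notes$pitch > 127)) stop("pitch out of MIDI range 0-127")
    if (any(notes$velocity < 1 | notes$velocity > 127)) stop("velocity out of range 1-127")
    if (any(notes$channel < 0 | notes$channel > 15)) stop("channel out of range 0-15")
    notes <- notes[order(notes$onset, notes$pitch), , drop = FALSE]
    rownames(notes) <- NULL
  }
  if (!is.numeric(bpm) || length(bpm) != 1L || !is.finite(bpm) || bpm <= 0) {
    stop("bpm must be a single positive number")
  }
  structure(
    list(notes = notes, bpm = as.numeric(bpm), tpq = TPQ,
         passthrough = passthrough),
    class = "performance"
  )
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf("<performance> %d notes, %.6g BPM, %d ticks/quarter\n",
              nrow(x$notes), x$bpm, x$tpq))
  if (nrow(x$notes)) {
    span <- max(x$notes$onset + x$notes$duration) / x$tpq
    cat(sprintf("  span: %.1f quarter notes (%.1f s)\n",
                span, span * 60 / x$bpm))
  }
  n_cc64 <- sum(x$passthrough$status >= 0xB0 & x$passthrough$status <= 0xBF &
                  vapply(x$passthrough$data,
                         function(d) length(d) > 0 && as.integer(d[1]) == 64L,
                         logical(1)))
  cat(sprintf("  passthrough events: %d (of which CC64 sustain: %d)\n",
              nrow(x$passthrough), n_cc64))
  invisible(x)
}

#' @rdname performance
#' @export
empty_passthrough <- function() {
  data.frame(tick = numeric(0), status = integer(0), type = integer(0),
             data = I(list()))
}

is_performance <- function(x) inherits(x, "performance")

#' Convert between ticks and milliseconds
#'
#' One tick is 1/960 of a quarter note, so at tempo `bpm` a tick lasts
#' `60000 / (bpm * 960)` milliseconds.
#'
#' @param ticks,ms numeric vectors of durations/positions.
#' @param bpm tempo in quarter notes per minute (positive).
#' @return numeric vector in the other unit.
#' @examples
#' ticks_to_ms(960, 60)   # one quarter note at 60 BPM: 1000 ms
#' ticks_to_ms(24, 140)   # ~10.7 ms
#' @export
ticks_to_ms <- function(ticks, bpm) {
  check_bpm(bpm)
  ticks / TPQ * 60000 / bpm
}

#' @rdname ticks_to_ms
#' @export
ms_to_ticks <- function(ms, bpm) {
  check_bpm(bpm)
  ms * bpm / 60000 * TPQ
}

check_bpm <- function(bpm) {
  if (!is.numeric(bpm) || length(bpm) != 1L || !is.finite(bpm) || bpm <= 0) {
    stop("bpm must be a single positive number")
  }
  invisible(bpm)
}

#' Export the note table of a performance as CSV
#'
#' Writes one row per note with columns `onset_ticks`, `pitch`, `velocity`,
#' `duration_ticks`, `channel`.
#'
#' @param perf a [performance()].
#' @param path output file path.
#' @return the exported data frame, invisibly.
#' @export
export_notes <- function(perf, path) {
  stopifnot(is_performance(perf))
  out <- data.frame(
    onset_ticks = perf$notes$onset,
    pitch = perf$notes$pitch,
    velocity = perf$notes$velocity,
    duration_ticks = perf$notes$duration,
    channel = perf$notes$channel
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
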