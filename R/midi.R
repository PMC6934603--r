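# Standard MIDI File (SMF) reading and writing, types 0 and 1.
#
# The reader rescales all timestamps from the source division to the canonical
# 960 ticks per quarter by exact rational scaling (no rounding: fractional
# ticks are kept). The writer integerises onsets half-away-from-zero at write
# time only. SMPTE divisions are not supported.

# --- byte helpers -----------------------------------------------------------

u16 <- function(raw, i) as.integer(raw[i]) * 256L + as.integer(raw[i + 1L])

u32 <- function(raw, i) {
  b <- as.integer(raw[i:(i + 3L)])
  ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]
}

# variable-length quantity: returns c(value, n_bytes_consumed)
read_varlen <- function(raw, i) {
  value <- 0
  n <- 0L
  repeat {
    b <- as.integer(raw[i + n])
    value <- value * 128 + (b %% 128L)
    n <- n + 1L
    if (b < 128L) break
    if (n > 4L) stop("malformed variable-length quantity")
  }
  c(value, n)
}

write_varlen <- function(value) {
  stopifnot(value >= 0)
  value <- as.integer(round(value))
  bytes <- value %% 128L
  value <- value %/% 128L
  while (value > 0L) {
    bytes <- c(value %% 128L + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

# --- reading ----------------------------------------------------------------

#' Read a Standard MIDI File into a performance
#'
#' Parses an SMF type 0 or 1 file, matches note-on/note-off pairs into notes
#' (first-in-first-out per channel and pitch), rescales all timestamps to the
#' canonical 960-ticks-per-quarter timeline, and takes the tempo from the
#' first `set_tempo` event (120 BPM if none is present). All non-note events
#' (tempo, control changes including the CC64 sustain pedal, program changes,
#' pitch bends, sysex and remaining meta events) are carried through
#' unchanged, with rescaled timestamps.
#'
#' @param path path to a `.mid` file.
#' @return a [performance()].
#' @details A note-on with no matching note-off is closed at the end of its
#'   track with a warning. If the file contains several distinct tempi, the
#'   first is used for tick/millisecond conversion and a warning is emitted;
#'   all tempo events are still preserved in the passthrough table.
#' @export
read_performance <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 14L || rawToChar(raw[1:4]) != "MThd") {
    stop("not a Standard MIDI File (missing MThd header): ", path)
  }
  if (u32(raw, 5L) != 6L) stop("unexpected MThd length")
  division <- u16(raw, 13L)
  if (division >= 0x8000) stop("SMPTE time division is not supported")
  if (division == 0L) stop("invalid time division 0")
  n_tracks <- u16(raw, 11L)
  scale <- TPQ / division

  notes_list <- list()
  pass_list <- list()
  tempi <- numeric(0)
  pos <- 15L

  for (trk in seq_len(n_tracks)) {
    if (pos + 7L > length(raw) || rawToChar(raw[pos:(pos + 3L)]) != "MTrk") {
      stop("expected MTrk chunk at byte ", pos)
    }
    trk_len <- u32(raw, pos + 4L)
    i <- pos + 8L
    trk_end <- i + trk_len
    tick <- 0
    running <- NA_integer_
    # open notes: FIFO queues keyed by channel*128 + pitch
    open <- new.env(parent = emptyenv())
    ons <- list()   # finished notes of this track

    close_note <- function(key, off_tick) {
      q <- get(key, envir = open)
      ev <- q[[1]]
      assign(key, q[-1], envir = open)
      if (length(get(key, envir = open)) == 0L) rm(list = key, envir = open)
      dur <- off_tick - ev$tick
      if (dur <= 0) dur <- 1  # zero-length pair: give minimal duration
      list(onset = ev$tick, pitch = ev$pitch, velocity = ev$velocity,
           duration = dur, channel = ev$channel)
    }

    while (i < trk_end) {
      vl <- read_varlen(raw, i)
      tick <- tick + vl[1]
      i <- i + vl[2]
      b <- as.integer(raw[i])
      if (b >= 0x80) {
        status <- b
        i <- i + 1L
        if (status < 0xF0) running <- status
      } else {
        if (is.na(running)) stop("data byte with no running status")
        status <- running
      }
      hi <- status %/% 16L
      ch <- status %% 16L
      if (status == 0xFF) {           # meta event
        type <- as.integer(raw[i])
        vl <- read_varlen(raw, i + 1L)
        data <- if (vl[1] > 0) raw[(i + 1L + vl[2]):(i + vl[2] + vl[1])] else raw(0)
        i <- i + 1L + vl[2] + vl[1]
        if (type == 0x2F) next        # end of track, not preserved
        if (type == 0x51) {
          usec <- ((as.integer(data[1]) * 256 + as.integer(data[2])) * 256 +
                     as.integer(data[3]))
          tempi <- c(tempi, 60e6 / usec)
        }
        pass_list[[length(pass_list) + 1L]] <-
          list(tick = tick * scale, status = 0xFFL, type = type, data = data)
      } else if (status == 0xF0 || status == 0xF7) {  # sysex
        vl <- read_varlen(raw, i)
        data <- if (vl[1] > 0) raw[(i + vl[2]):(i + vl[2] + vl[1] - 1L)] else raw(0)
        i <- i + vl[2] + vl[1]
        pass_list[[length(pass_list) + 1L]] <-
          list(tick = tick * scale, status = status, type = NA_integer_, data = data)
      } else if (hi == 0x9L || hi == 0x8L) {          # note on/off
        pitch <- as.integer(raw[i]); vel <- as.integer(raw[i + 1L])
        i <- i + 2L
        key <- sprintf("k%d", ch * 128L + pitch)
        if (hi == 0x9L && vel > 0L) {
          q <- if (exists(key, envir = open)) get(key, envir = open) else list()
          q[[length(q) + 1L]] <- list(tick = tick * scale, pitch = pitch,
                                      velocity = vel, channel = ch)
          assign(key, q, envir = open)
        } else {
          if (exists(key, envir = open)) {
            ons[[length(ons) + 1L]] <- close_note(key, tick * scale)
          }  # stray note-off: ignored
        }
      } else if (hi %in% c(0xAL, 0xBL, 0xEL)) {       # 2-data-byte channel msg
        data <- raw[i:(i + 1L)]
        i <- i + 2L
        pass_list[[length(pass_list) + 1L]] <-
          list(tick = tick * scale, status = status, type = NA_integer_, data = data)
      } else if (hi %in% c(0xCL, 0xDL)) {             # 1-data-byte channel msg
        data <- raw[i]
        i <- i + 1L
        pass_list[[length(pass_list) + 1L]] <-
          list(tick = tick * scale, status = status, type = NA_integer_, data = data)
      } else {
        stop(sprintf("unhandled status byte 0x%X", status))
      }
    }
    # notes still open at end of track
    open_keys <- ls(envir = open)
    if (length(open_keys)) {
      warning(sprintf("%d note-on event(s) without note-off; closed at end of track",
                      length(open_keys)))
      for (key in open_keys) {
        while (exists(key, envir = open)) {
          ons[[length(ons) + 1L]] <- close_note(key, tick * scale)
        }
      }
    }
    notes_list <- c(notes_list, ons)
    pos <- trk_end
  }

  if (!length(notes_list)) stop("MIDI file contains no notes: ", path)
  notes <- data.frame(
    onset = vapply(notes_list, `[[`, numeric(1), "onset"),
    pitch = vapply(notes_list, `[[`, integer(1), "pitch"),
    velocity = vapply(notes_list, `[[`, integer(1), "velocity"),
    duration = vapply(notes_list, `[[`, numeric(1), "duration"),
    channel = vapply(notes_list, `[[`, integer(1), "channel")
  )

  bpm <- 120
  if (length(tempi)) {
    bpm <- tempi[1]
    if (length(unique(round(tempi, 9))) > 1L) {
      warning("multiple distinct tempo events; using the first (",
              format(bpm), " BPM) for tick/ms conversion")
    }
  }

  pass <- if (length(pass_list)) {
    data.frame(
      tick = vapply(pass_list, `[[`, numeric(1), "tick"),
      status = vapply(pass_list, `[[`, integer(1), "status"),
      type = vapply(pass_list, `[[`, integer(1), "type"),
      data = I(lapply(pass_list, `[[`, "data"))
    )
  } else {
    empty_passthrough()
  }
  pass <- pass[order(pass$tick), , drop = FALSE]
  rownames(pass) <- NULL

  performance(notes, bpm = bpm, passthrough = pass)
}

# --- writing ----------------------------------------------------------------

round_half_up <- function(x) floor(x + 0.5)  # onsets are >= 0

#' Write a performance as a Standard MIDI File
#'
#' Writes an SMF type 0 file at 960 ticks per quarter. Fractional onsets and
#' durations are rounded half-away-from-zero to integer ticks at this point
#' (and nowhere else). Velocities, durations, channels and all passthrough
#' events (sustain pedal, program changes, ...) are emitted unchanged, so a
#' read-write-read round trip reproduces the note list exactly once onsets
#' are integral.
#'
#' @param perf a [performance()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(perf, path) {
  stopifnot(is_performance(perf))
  notes <- perf$notes
  if (any(notes$onset < 0)) stop("cannot write negative onsets")

  ev <- list()  # each: list(tick, prio, bytes)
  add <- function(tick, prio, bytes) {
    ev[[length(ev) + 1L]] <<- list(tick = tick, prio = prio, bytes = bytes)
  }

  pass <- perf$passthrough
  has_tempo <- any(pass$status == 0xFFL & pass$type == 0x51L, na.rm = TRUE)
  if (!has_tempo) {
    usec <- round(60e6 / perf$bpm)
    add(0, 0L, as.raw(c(0xFF, 0x51, 0x03,
                        usec %/% 65536, (usec %/% 256) %% 256, usec %% 256)))
  }
  if (nrow(pass)) {
    for (k in seq_len(nrow(pass))) {
      st <- pass$status[k]
      bytes <- if (st == 0xFFL) {
        c(as.raw(c(0xFF, pass$type[k])), write_varlen(length(pass$data[[k]])),
          pass$data[[k]])
      } else if (st == 0xF0L || st == 0xF7L) {
        c(as.raw(st), write_varlen(length(pass$data[[k]])), pass$data[[k]])
      } else {
        c(as.raw(st), pass$data[[k]])
      }
      add(round_half_up(pass$tick[k]), 0L, bytes)
    }
  }
  if (nrow(notes)) {
    on_tick <- round_half_up(notes$onset)
    dur <- pmax(1, round_half_up(notes$duration))
    for (k in seq_len(nrow(notes))) {
      add(on_tick[k], 2L,
          as.raw(c(0x90 + notes$channel[k], notes$pitch[k], notes$velocity[k])))
      add(on_tick[k] + dur[k], 1L,
          as.raw(c(0x80 + notes$channel[k], notes$pitch[k], 0x40)))
    }
  }

  ticks <- vapply(ev, `[[`, numeric(1), "tick")
  prios <- vapply(ev, `[[`, integer(1), "prio")
  ord <- order(ticks, prios)
  body <- raw(0)
  chunks <- vector("list", length(ord) + 1L)
  last <- 0
  for (j in seq_along(ord)) {
    e <- ev[[ord[j]]]
    chunks[[j]] <- c(write_varlen(e$tick - last), e$bytes)
    last <- e$tick
  }
  chunks[[length(ord) + 1L]] <- c(write_varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))
  body <- do.call(c, chunks)

  be16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  be32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                               (x %/% 256) %% 256, x %% 256))
  out <- c(charToRaw("MThd"), be32(6), be16(0), be16(1), be16(TPQ),
           charToRaw("MTrk"), be32(length(body)), body)
  writeBin(out, path)
  invisible(path)
}
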