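# Independent byte-level SMF builder, used as the oracle for the package's
# MIDI reader. Deliberately shares no code with the package: bytes are
# assembled by hand from the SMF grammar.

vlq <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

be <- function(x, n) as.raw(sapply((n - 1):0, function(s) (x %/% 256^s) %% 256))

# events: list of list(delta = ticks, bytes = raw vector)
smf_track <- function(events) {
  body <- do.call(c, lapply(events, function(e) c(vlq(e$delta), e$bytes)))
  body <- c(body, vlq(0), as.raw(c(0xFF, 0x2F, 0x00)))
  c(charToRaw("MTrk"), be(length(body), 4), body)
}

# Build a type-0/1 SMF with the given division and track event lists.
smf_bytes <- function(division, tracks, format = length(tracks) > 1) {
  c(charToRaw("MThd"), be(6, 4), be(as.integer(format), 2),
    be(length(tracks), 2), be(division, 2),
    do.call(c, lapply(tracks, smf_track)))
}

note_on <- function(pitch, vel = 80, ch = 0) as.raw(c(0x90 + ch, pitch, vel))
note_off <- function(pitch, ch = 0) as.raw(c(0x80 + ch, pitch, 0))
cc <- function(num, val, ch = 0) as.raw(c(0xB0 + ch, num, val))
tempo_meta <- function(bpm) {
  usec <- round(60e6 / bpm)
  c(as.raw(c(0xFF, 0x51, 0x03)), be(usec, 3))
}

write_smf <- function(bytes, path = tempfile(fileext = ".mid")) {
  writeBin(bytes, path)
  path
}

# simple single-track file: notes given as data.frame(onset, pitch, vel, dur)
# in source-division ticks, all on channel 0, with an optional tempo
simple_smf <- function(notes, division = 960, bpm = NULL) {
  ev <- list()
  if (!is.null(bpm)) ev[[1]] <- list(delta = 0, bytes = tempo_meta(bpm))
  # schedule on/off events sorted by absolute tick (offs before ons on ties)
  sched <- rbind(
    data.frame(tick = notes$onset, prio = 1, pitch = notes$pitch,
               vel = notes$vel, on = TRUE),
    data.frame(tick = notes$onset + notes$dur, prio = 0, pitch = notes$pitch,
               vel = 0, on = FALSE)
  )
  sched <- sched[order(sched$tick, sched$prio), ]
  last <- 0
  for (i in seq_len(nrow(sched))) {
    bytes <- if (sched$on[i]) note_on(sched$pitch[i], sched$vel[i])
             else note_off(sched$pitch[i])
    ev[[length(ev) + 1]] <- list(delta = sched$tick[i] - last, bytes = bytes)
    last <- sched$tick[i]
  }
  write_smf(smf_bytes(division, list(ev)))
}
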