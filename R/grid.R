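# Triplet-grid classification of note onsets.
#
# Swung eighths occupy the first and third notes of an eighth-note triplet.
# With 960 ticks per quarter the triplet anchors are 0 ("base", on the click),
# 320 (the middle-triplet position, "disregarded") and 640 ("swing"). Each
# onset is assigned to the nearest anchor modulo the quarter note, with a
# half-open window [-160, 160) of one half-triplet around each anchor, so the
# three windows tile the quarter exactly. Positions in [800, 960) wrap to the
# next quarter's base anchor.

GRID_ANCHORS <- c(base = 0, disregarded = 320, swing = 640)
HALF_WINDOW <- 160

#' Classify onsets on the swung-eighth triplet grid
#'
#' Assigns each onset to the nearest of the triplet anchors \{0, 320, 640\}
#' modulo the quarter note (960 ticks), yielding the note class
#' (`base` / `disregarded` / `swing`), the quarter-note index, and the signed
#' offset from the anchor in `[-160, 160)` ticks. A residue of exactly
#' `anchor + 160` belongs to the next anchor with offset -160; residues in
#' `[800, 960)` wrap to the following quarter's base anchor.
#'
#' @param onsets numeric vector of onsets in ticks (>= 0, possibly
#'   fractional), or a [performance()] whose note onsets are used.
#' @return data frame with columns `note_index`, `quarter_index`, `klass`
#'   (factor base/swing/disregarded), `anchor` and `signed_offset`.
#' @examples
#' classify_grid(c(0, 640, 320, 810))
#' @export
classify_grid <- function(onsets) {
  if (is_performance(onsets)) onsets <- onsets$notes$onset
  stopifnot(is.numeric(onsets), all(onsets >= 0))
  res <- onsets %% TPQ
  quarter <- onsets %/% TPQ
  # window index 0,1,2 -> anchors 0,320,640; index 3 -> next quarter's base
  win <- (res + HALF_WINDOW) %/% (2 * HALF_WINDOW)
  wrap <- win == 3
  quarter[wrap] <- quarter[wrap] + 1
  anchor <- ifelse(wrap, 0, win * 320)
  offset <- res - win * 320
  klass <- c("base", "disregarded", "swing", "base")[win + 1]
  data.frame(
    note_index = seq_along(onsets),
    quarter_index = as.integer(quarter),
    klass = factor(klass, levels = c("base", "swing", "disregarded")),
    anchor = as.integer(anchor),
    signed_offset = offset
  )
}

# Temporal bins: all notes sharing a (quarter_index, anchor) cell form one
# bin (a chord and/or melody note struck together). Per the earliest-onset
# rule only the first onset of a bin carries the bin's timing information.
# Returns the assignment table with bin ids and a logical `head` column;
# ties on onset are broken by pitch for determinism.
bin_assignments <- function(assign, onsets, pitches = NULL) {
  bin <- assign$quarter_index * 3L + assign$anchor %/% 320L
  if (is.null(pitches)) pitches <- rep(0L, length(onsets))
  ord <- order(bin, onsets, pitches)
  first <- !duplicated(bin[ord])
  head <- logical(length(bin))
  head[ord] <- first
  assign$bin <- bin
  assign$head <- head
  assign
}

grid_assignment_table <- function(perf) {
  assign <- classify_grid(perf$notes$onset)
  bin_assignments(assign, perf$notes$onset, perf$notes$pitch)
}

#' Mean base and swing positions of a performance
#'
#' Computes the average base note position `b_bar` (signed offset from the
#' metronome click, wrap-aware so that notes played slightly early count as
#' negative rather than near 960) and the average swing note position `s_bar`
#' (absolute position modulo the quarter, i.e. `640 +` mean swing offset).
#' When several notes fall in the same (quarter, anchor) bin — chords — only
#' the earliest onset of the bin enters the means.
#'
#' @param perf a [performance()].
#' @param per_bin use only the earliest onset of each temporal bin (default);
#'   `FALSE` uses every note.
#' @return list with `b_bar`, `s_bar` (ticks), note counts `n_base`,
#'   `n_swing`, `n_disregarded`, and bin counts `n_base_bins`, `n_swing_bins`.
#' @export
class_means <- function(perf, per_bin = TRUE) {
  stopifnot(is_performance(perf))
  assign <- grid_assignment_table(perf)
  use <- if (per_bin) assign$head else rep(TRUE, nrow(assign))
  base_off <- assign$signed_offset[use & assign$klass == "base"]
  swing_off <- assign$signed_offset[use & assign$klass == "swing"]
  if (!length(base_off) || !length(swing_off)) {
    stop("performance must contain at least one base and one swing note")
  }
  list(
    b_bar = mean(base_off),
    s_bar = GRID_ANCHORS[["swing"]] + mean(swing_off),
    n_base = sum(assign$klass == "base"),
    n_swing = sum(assign$klass == "swing"),
    n_disregarded = sum(assign$klass == "disregarded"),
    n_base_bins = length(base_off),
    n_swing_bins = length(swing_off)
  )
}

#' Export grid assignments as CSV
#'
#' One row per note: `note_index`, `quarter_index`, `class`, `anchor`,
#' `signed_offset_ticks`.
#'
#' @param perf a [performance()].
#' @param path output file path.
#' @return the exported data frame, invisibly.
#' @export
export_assignments <- function(perf, path) {
  stopifnot(is_performance(perf))
  a <- classify_grid(perf$notes$onset)
  out <- data.frame(
    note_index = a$note_index,
    quarter_index = a$quarter_index,
    class = as.character(a$klass),
    anchor = a$anchor,
    signed_offset_ticks = a$signed_offset
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
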