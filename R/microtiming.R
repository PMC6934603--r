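# Microtiming deviations (MTDs) and their summary statistics.
#
# The MTD of a base note is its deviation from the recording's mean base
# position b_bar (modulo the quarter note); swing-note MTDs are measured about
# s_bar. Deviations are therefore mean-zero per class by construction. Spreads
# are reported in milliseconds, the average swing ratio via per-note ratios
# r_i = (p mod 960) / (960 - (p mod 960)), and serial dependence via Spearman
# rank correlations between neighbouring base/swing deviations.

#' Per-bin microtiming deviations
#'
#' Computes the signed deviation `d_ticks` of every base/swing temporal bin
#' from its class mean position. Disregarded (middle-triplet) notes carry no
#' deviation. With `per_bin = TRUE` (default) one deviation is produced per
#' bin, taken from the earliest onset in the bin; chords therefore contribute
#' a single value.
#'
#' @param perf a [performance()].
#' @param means result of [class_means()] on the same performance; recomputed
#'   if `NULL`.
#' @param per_bin earliest-onset-per-bin rule (default `TRUE`).
#' @return data frame with columns `bin`, `quarter_index`, `klass`,
#'   `note_index`, `onset`, `signed_offset`, `d_ticks`.
#' @export
compute_mtds <- function(perf, means = NULL, per_bin = TRUE) {
  stopifnot(is_performance(perf))
  if (is.null(means)) means <- class_means(perf, per_bin = per_bin)
  assign <- grid_assignment_table(perf)
  use <- (if (per_bin) assign$head else rep(TRUE, nrow(assign))) &
    assign$klass != "disregarded"
  a <- assign[use, , drop = FALSE]
  mean_off <- ifelse(a$klass == "base", means$b_bar,
                     means$s_bar - GRID_ANCHORS[["swing"]])
  out <- data.frame(
    bin = a$bin,
    quarter_index = a$quarter_index,
    klass = factor(as.character(a$klass), levels = c("base", "swing")),
    note_index = a$note_index,
    onset = perf$notes$onset[a$note_index],
    signed_offset = a$signed_offset,
    d_ticks = a$signed_offset - mean_off
  )
  out[order(out$bin), , drop = FALSE]
}

#' Millisecond summary of microtiming deviations
#'
#' Standard deviations (n-1 divisor) of the base and swing deviations, their
#' pooled spread across both classes, and the pooled mean, all converted from
#' ticks to milliseconds at the given tempo.
#'
#' @param deviations output of [compute_mtds()].
#' @param bpm tempo used for the tick-to-millisecond conversion.
#' @return list with `sigma_b`, `sigma_s`, `pooled_sd_ms`, `mean_dev_ms`,
#'   `n_base`, `n_swing`. A class with fewer than two deviations yields `NA`.
#' @export
summarize_mtds <- function(deviations, bpm) {
  check_bpm(bpm)
  d_b <- deviations$d_ticks[deviations$klass == "base"]
  d_s <- deviations$d_ticks[deviations$klass == "swing"]
  sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  list(
    sigma_b = ticks_to_ms(sd_or_na(d_b), bpm),
    sigma_s = ticks_to_ms(sd_or_na(d_s), bpm),
    pooled_sd_ms = ticks_to_ms(sd_or_na(deviations$d_ticks), bpm),
    mean_dev_ms = ticks_to_ms(mean(deviations$d_ticks), bpm),
    n_base = length(d_b),
    n_swing = length(d_s)
  )
}

#' Average swing ratio
#'
#' For each swing note at position `p` ticks, the per-note swing ratio is
#' `r_i = (p mod 960) / (960 - (p mod 960))`: the length ratio of the long to
#' the short part of the swung pair if base notes sat exactly on the click.
#' Perfect triplets (p = 640) give 2, straight eighths (p = 480) give 1.
#' `r` is the mean of the `r_i` and `delta_r` their standard deviation (n-1).
#' Note that `r` averages per-note ratios, so for noisy positions it exceeds
#' the ratio evaluated at the mean position (the map is convex).
#'
#' @param positions onsets in ticks of the swing notes (bin heads), or a
#'   [performance()] from which swing-bin head onsets are taken.
#' @return list with `r`, `delta_r` and the per-note `ratios`.
#' @examples
#' swing_ratio(c(640, 640))   # perfect triplets: r = 2
#' swing_ratio(480)           # straight eighths: r = 1
#' @export
swing_ratio <- function(positions) {
  if (is_performance(positions)) {
    a <- grid_assignment_table(positions)
    positions <- positions$notes$onset[a$head & a$klass == "swing"]
  }
  stopifnot(is.numeric(positions), length(positions) >= 1)
  p <- positions %% TPQ
  if (any(p <= 0 | p >= TPQ)) {
    stop("swing positions must have residue strictly inside (0, 960)")
  }
  r_i <- p / (TPQ - p)
  list(
    r = mean(r_i),
    delta_r = if (length(r_i) >= 2) stats::sd(r_i) else NA_real_,
    ratios = r_i
  )
}

# Spearman rank correlation (average ranks for ties); NA when fewer than
# min_pairs pairs or when either margin is constant.
spearman_or_na <- function(x, y, min_pairs = 3L) {
  if (length(x) < min_pairs) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Serial correlations between neighbouring base and swing deviations
#'
#' Pairs every base bin with the following swing bin whose distance is at
#' most one quarter note (960 ticks), and symmetrically every swing bin with
#' the following base bin, then computes Spearman's rank correlation over the
#' paired deviations in each direction. Distances are measured between bin
#' anchor times (`quarter * 960 + anchor`) by default, so a strongly dragged
#' note still pairs with its own beat; set `distance = "onset"` to use raw
#' onsets instead.
#'
#' @param deviations output of [compute_mtds()].
#' @param distance `"anchor"` (default) or `"onset"`.
#' @param min_pairs minimum number of pairs per direction (default 3);
#'   fewer yields `NA`.
#' @return list with `rho_b_to_s`, `rho_s_to_b`, `n_pairs_bs`, `n_pairs_sb`.
#' @export
serial_correlations <- function(deviations, distance = c("anchor", "onset"),
                                min_pairs = 3L) {
  distance <- match.arg(distance)
  d <- deviations[order(deviations$bin), , drop = FALSE]
  tpos <- if (distance == "anchor") {
    d$quarter_index * TPQ + (d$bin %% 3L) * 320
  } else {
    d$onset
  }
  pair_up <- function(from, to) {
    idx_from <- which(d$klass == from)
    idx_to <- which(d$klass == to)
    if (!length(idx_from) || !length(idx_to)) {
      return(list(x = numeric(0), y = numeric(0)))
    }
    # for each source bin, the first target bin strictly after it
    j <- findInterval(tpos[idx_from], tpos[idx_to]) + 1L
    ok <- j <= length(idx_to)
    ok[ok] <- (tpos[idx_to[j[ok]]] - tpos[idx_from[ok]]) <= TPQ
    list(x = d$d_ticks[idx_from[ok]], y = d$d_ticks[idx_to[j[ok]]])
  }
  bs <- pair_up("base", "swing")
  sb <- pair_up("swing", "base")
  list(
    rho_b_to_s = spearman_or_na(bs$x, bs$y, min_pairs),
    rho_s_to_b = spearman_or_na(sb$x, sb$y, min_pairs),
    n_pairs_bs = length(bs$x),
    n_pairs_sb = length(sb$x)
  )
}

#' Full microtiming profile of a performance
#'
#' Runs the whole analysis chain — grid classification, class means, per-bin
#' deviations, millisecond spreads, average swing ratio and serial
#' correlations — and returns one object holding everything: one row of a
#' recordings table.
#'
#' @param perf a [performance()].
#' @param per_bin earliest-onset-per-bin rule (default `TRUE`).
#' @param distance pair-distance mode for [serial_correlations()].
#' @return an object of class `mtd_profile`: list with `deviations`, `b_bar`,
#'   `s_bar`, `sigma_b`, `sigma_s`, `pooled_sd_ms`, `mean_dev_ms`, `r`,
#'   `delta_r`, `anchor_ratio` (= `s_bar / (960 - s_bar)`), `rho_b_to_s`,
#'   `rho_s_to_b`, `middle_frac`, `bpm` and counts.
#' @export
mtd_profile <- function(perf, per_bin = TRUE, distance = c("anchor", "onset")) {
  stopifnot(is_performance(perf))
  distance <- match.arg(distance)
  means <- class_means(perf, per_bin = per_bin)
  devs <- compute_mtds(perf, means, per_bin = per_bin)
  summ <- summarize_mtds(devs, perf$bpm)
  swing_heads <- devs$onset[devs$klass == "swing"]
  sr <- swing_ratio(swing_heads)
  rho <- serial_correlations(devs, distance = distance)
  n_notes <- nrow(perf$notes)
  structure(
    c(list(deviations = devs), means, summ, list(
      r = sr$r, delta_r = sr$delta_r,
      anchor_ratio = means$s_bar / (TPQ - means$s_bar),
      rho_b_to_s = rho$rho_b_to_s, rho_s_to_b = rho$rho_s_to_b,
      n_pairs_bs = rho$n_pairs_bs, n_pairs_sb = rho$n_pairs_sb,
      middle_frac = means$n_disregarded / n_notes,
      n_notes = n_notes, bpm = perf$bpm, per_bin = per_bin
    )),
    class = "mtd_profile"
  )
}

#' @export
print.mtd_profile <- function(x, ...) {
  cat("<mtd_profile>\n")
  cat(sprintf("  %d notes at %.6g BPM; bins: %d base, %d swing; %.2f%% middle-triplet\n",
              x$n_notes, x$bpm, x$n_base_bins, x$n_swing_bins,
              100 * x$middle_frac))
  cat(sprintf("  b_bar = %.2f ticks, s_bar = %.2f ticks\n", x$b_bar, x$s_bar))
  cat(sprintf("  sigma_b = %.2f ms, sigma_s = %.2f ms (pooled %.2f ms, mean %.2f ms)\n",
              x$sigma_b, x$sigma_s, x$pooled_sd_ms, x$mean_dev_ms))
  cat(sprintf("  swing ratio r = %.3f (delta_r = %.3f; ratio at s_bar = %.3f)\n",
              x$r, x$delta_r, x$anchor_ratio))
  cat(sprintf("  serial Spearman rho: base->swing %.3f (n=%d), swing->base %.3f (n=%d)\n",
              x$rho_b_to_s, x$n_pairs_bs, x$rho_s_to_b, x$n_pairs_sb))
  invisible(x)
}

#' Recordings report: one row of microtiming statistics per performance
#'
#' @param perfs list of [performance()] objects, optionally named.
#' @param ... passed to [mtd_profile()].
#' @return data frame with one row per performance and columns `recording`,
#'   `bpm`, `n_notes`, `b_bar`, `s_bar`, `sigma_b`, `sigma_s`, `r`, `delta_r`,
#'   `rho_b_to_s`, `rho_s_to_b`, `middle_frac`. A performance that fails to
#'   analyse yields a row of `NA`s (with a warning), not an error.
#' @export
mtd_report <- function(perfs, ...) {
  stopifnot(is.list(perfs))
  nm <- names(perfs)
  if (is.null(nm)) nm <- sprintf("performance_%d", seq_along(perfs))
  rows <- lapply(seq_along(perfs), function(i) {
    prof <- tryCatch(mtd_profile(perfs[[i]], ...), error = function(e) {
      warning(sprintf("analysis of '%s' failed: %s", nm[i], conditionMessage(e)))
      NULL
    })
    if (is.null(prof)) {
      data.frame(recording = nm[i], bpm = NA_real_, n_notes = NA_integer_,
                 b_bar = NA_real_, s_bar = NA_real_, sigma_b = NA_real_,
                 sigma_s = NA_real_, r = NA_real_, delta_r = NA_real_,
                 rho_b_to_s = NA_real_, rho_s_to_b = NA_real_,
                 middle_frac = NA_real_)
    } else {
      data.frame(recording = nm[i], bpm = prof$bpm, n_notes = prof$n_notes,
                 b_bar = prof$b_bar, s_bar = prof$s_bar,
                 sigma_b = prof$sigma_b, sigma_s = prof$sigma_s,
                 r = prof$r, delta_r = prof$delta_r,
                 rho_b_to_s = prof$rho_b_to_s, rho_s_to_b = prof$rho_s_to_b,
                 middle_frac = prof$middle_frac)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export per-note deviations as CSV
#'
#' Columns: `note_index`, `class`, `d_ticks`, `d_ms`.
#'
#' @param profile an [mtd_profile()].
#' @param path output file path.
#' @return the exported data frame, invisibly.
#' @export
export_deviations <- function(profile, path) {
  stopifnot(inherits(profile, "mtd_profile"))
  d <- profile$deviations
  out <- data.frame(
    note_index = d$note_index,
    class = as.character(d$klass),
    d_ticks = d$d_ticks,
    d_ms = ticks_to_ms(d$d_ticks, profile$bpm)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
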