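# Synthetic swung-eighth performances with controlled timing statistics.
#
# The generator lays base anchors on the quarter-note click and swing anchors
# at 960 * r / (1 + r) ticks (the position whose anchor swing ratio is r),
# then adds per-note timing noise with a configurable spread (in ms),
# serial correlation structure (i.i.d., AR(1) or power-law / 1/f^beta), an
# optional intentional ahead/behind-the-beat offset per class, occasional
# chords, and a small fraction of middle-triplet notes. Defaults mirror the
# aggregate statistics of professional jazz piano recorded to a click:
# sigma ~ 18.5 ms, lag-1 rank correlation ~ 0.5, mean swing ratio ~ 1.9,
# ~0.7% middle-triplet notes.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic performance
#'
#' @param n_quarters number of quarter notes (each contributes one base and
#'   one swing bin).
#' @param bpm tempo in quarter notes per minute.
#' @param target_r target mean swing ratio; the swing anchor is placed at
#'   `960 * target_r / (1 + target_r)` ticks (640 for perfect triplets).
#' @param sigma_ms per-note timing standard deviation in milliseconds.
#' @param mean_offset_b_ticks,mean_offset_s_ticks intentional constant
#'   ahead/behind-the-beat offsets of the two classes, in ticks.
#' @param serial_rho target lag-1 (Pearson) correlation between neighbouring
#'   deviations, in `[0, 1)`; used by the `ar1` noise model.
#' @param noise_model `"ar1"` (default), `"iid_gaussian"` or `"powerlaw"`
#'   (spectral 1/f^beta synthesis, see `powerlaw_exponent`).
#' @param powerlaw_exponent spectral exponent beta for the power-law model.
#' @param chord_prob probability that a bin is a chord of 2-4 notes with a
#'   small positive strum spread.
#' @param middle_note_frac fraction of quarters receiving a middle-triplet
#'   (disregarded) note.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_quarters = 128, bpm = 150, target_r = 1.9,
                       sigma_ms = 18.5, mean_offset_b_ticks = 0,
                       mean_offset_s_ticks = 0, serial_rho = 0.5,
                       noise_model = c("ar1", "iid_gaussian", "powerlaw"),
                       powerlaw_exponent = 0.8, chord_prob = 0.3,
                       middle_note_frac = 0.007, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_quarters >= 2, sigma_ms >= 0, target_r > 0,
            serial_rho >= 0, serial_rho < 1,
            chord_prob >= 0, chord_prob <= 1,
            middle_note_frac >= 0, middle_note_frac <= 1)
  check_bpm(bpm)
  structure(
    list(n_quarters = as.integer(n_quarters), bpm = bpm, target_r = target_r,
         sigma_ms = sigma_ms, mean_offset_b_ticks = mean_offset_b_ticks,
         mean_offset_s_ticks = mean_offset_s_ticks, serial_rho = serial_rho,
         noise_model = noise_model, powerlaw_exponent = powerlaw_exponent,
         chord_prob = chord_prob, middle_note_frac = middle_note_frac,
         seed = seed),
    class = "synth_spec"
  )
}

#' Unit-variance AR(1) series
#'
#' Stationary Gaussian AR(1) with lag-1 correlation `rho` and unit marginal
#' variance: `x_t = rho * x_(t-1) + sqrt(1 - rho^2) * e_t`.
#'
#' @param n length (>= 2).
#' @param rho lag-1 correlation, `|rho| < 1`.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
ar1_series <- function(n, rho, seed = NULL) {
  stopifnot(n >= 2, is.numeric(rho), length(rho) == 1L, abs(rho) < 1)
  with_seed(seed, {
    init <- stats::rnorm(1)
    e <- stats::rnorm(n)
    as.numeric(stats::filter(sqrt(1 - rho^2) * e, rho,
                             method = "recursive", init = init))
  })
}

#' Power-law correlated series by spectral synthesis
#'
#' Shapes white Gaussian noise in the frequency domain with amplitude
#' `f^(-exponent/2)` (so the power spectrum decays as `1/f^exponent`, giving
#' a long-range, power-law-decaying autocorrelation for `0 < exponent < 1`),
#' then standardises the series to unit variance.
#'
#' @param n length (>= 2).
#' @param exponent spectral exponent beta in `[0, 2)`; 0 is white noise.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
powerlaw_series <- function(n, exponent = 0.8, seed = NULL) {
  stopifnot(n >= 2, is.numeric(exponent), length(exponent) == 1L,
            exponent >= 0, exponent < 2)
  with_seed(seed, {
    white <- stats::rnorm(n)
    spec <- stats::fft(white)
    k <- seq_len(n) - 1
    freq <- pmin(k, n - k) / n          # symmetric so the spectrum stays Hermitian
    freq[1] <- 1                        # DC removed below
    shaped <- spec * freq^(-exponent / 2)
    shaped[1] <- 0                      # mean-free series
    x <- Re(stats::fft(shaped, inverse = TRUE)) / n
    (x - mean(x)) / stats::sd(x)
  })
}

# draw the unit-variance deviation series for a spec
noise_series <- function(spec, n) {
  switch(spec$noise_model,
         iid_gaussian = stats::rnorm(n),
         ar1 = ar1_series(n, spec$serial_rho),
         powerlaw = powerlaw_series(n, spec$powerlaw_exponent))
}

#' Generate a synthetic swung-eighth performance
#'
#' Produces a [performance()] plus the ground-truth deviations used, so every
#' analysis stage can be tested against known truth. Deviations that would
#' push a note outside its half-open classification window (+/- 160 ticks
#' around the anchor) are rejected and redrawn (keeping the Gaussian shape
#' rather than clipping); the redraw count is returned.
#'
#' @param spec a [synth_spec()].
#' @return list with `performance`, `ground_truth` (data frame `quarter`,
#'   `klass`, `true_dev_ticks`, `onset`), `redraws` and `spec`. Pitches are
#'   random diatonic notes and velocities uniform in 60-100: musically
#'   arbitrary, since only timing matters here.
#' @examples
#' g <- generate_performance(synth_spec(n_quarters = 16, seed = 1))
#' g$performance
#' @export
generate_performance <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    nq <- spec$n_quarters
    n_bins <- 2L * nq
    sigma_ticks <- ms_to_ticks(spec$sigma_ms, spec$bpm)
    swing_pos <- TPQ * spec$target_r / (1 + spec$target_r)
    # total mean offset from the classification anchor, per class
    off_b <- spec$mean_offset_b_ticks
    off_s <- swing_pos - GRID_ANCHORS[["swing"]] + spec$mean_offset_s_ticks
    in_window <- function(x) x >= -HALF_WINDOW & x < HALF_WINDOW  # half-open
    if (!in_window(off_b) || !in_window(off_s)) {
      stop("mean class positions fall outside the classification window")
    }

    d <- noise_series(spec, n_bins) * sigma_ticks
    # interleaved bins: odd indices base, even indices swing
    mean_off <- rep(c(off_b, off_s), nq)
    redraws <- 0L
    bad <- which(!in_window(mean_off + d))
    while (length(bad)) {
      redraws <- redraws + length(bad)
      for (i in bad) {
        repeat {
          z <- stats::rnorm(1)
          di <- if (spec$noise_model == "ar1" && i > 1L) {
            spec$serial_rho * (d[i - 1L] / sigma_ticks) +
              sqrt(1 - spec$serial_rho^2) * z
          } else {
            z
          }
          di <- di * sigma_ticks
          if (in_window(mean_off[i] + di)) { d[i] <- di; break }
        }
      }
      bad <- integer(0)
    }
    if (redraws > 0) {
      warning(sprintf("%d deviation(s) redrawn at the classification window edge",
                      redraws))
    }

    # one silent lead-in quarter so an early-played first note stays >= 0
    quarter <- rep(seq_len(nq), each = 2L)
    klass <- rep(c("base", "swing"), nq)
    anchor_pos <- quarter * TPQ + rep(c(0, GRID_ANCHORS[["swing"]]), nq)
    onset <- anchor_pos + mean_off + d

    diatonic <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
    pick_pitch <- function(n) 60L + sample(diatonic, n, replace = TRUE) +
      12L * sample(0:1, n, replace = TRUE)

    gap <- rep(c(swing_pos, TPQ - swing_pos), nq)  # nominal time to next note
    notes <- data.frame(
      onset = onset,
      pitch = pick_pitch(n_bins),
      velocity = sample(60:100, n_bins, replace = TRUE),
      duration = pmax(10, 0.8 * gap),
      channel = 0L
    )

    # chords: extra notes strummed shortly after the bin head
    chord_bins <- which(stats::runif(n_bins) < spec$chord_prob)
    if (length(chord_bins)) {
      extra <- lapply(chord_bins, function(i) {
        k <- sample(1:3, 1)
        spread <- sort(stats::runif(k, 1, 12))
        # keep strummed notes inside the head's classification window
        spread <- spread[mean_off[i] + d[i] + spread < HALF_WINDOW]
        if (!length(spread)) return(NULL)
        data.frame(onset = onset[i] + spread,
                   pitch = pick_pitch(length(spread)),
                   velocity = sample(60:100, length(spread), replace = TRUE),
                   duration = notes$duration[i], channel = 0L)
      })
      notes <- rbind(notes, do.call(rbind, extra))
    }

    # middle-triplet (disregarded) notes
    mid_quarters <- which(stats::runif(nq) < spec$middle_note_frac)
    if (length(mid_quarters)) {
      md <- stats::rnorm(length(mid_quarters)) * sigma_ticks
      md[abs(md) >= HALF_WINDOW] <- 0
      notes <- rbind(notes, data.frame(
        onset = mid_quarters * TPQ + GRID_ANCHORS[["disregarded"]] + md,
        pitch = pick_pitch(length(mid_quarters)),
        velocity = sample(60:100, length(mid_quarters), replace = TRUE),
        duration = 160, channel = 0L
      ))
    }

    list(
      performance = performance(notes, bpm = spec$bpm),
      ground_truth = data.frame(quarter = quarter, klass = klass,
                                true_dev_ticks = d, onset = onset),
      redraws = redraws,
      spec = spec
    )
  })
}
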