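# fixture with a modest spread so that doubled deviations stay inside the
# classification windows (keeps the m = 2 relations exact, pre-rounding)
manip_fixture <- function(seed = 21, n_quarters = 300, sigma_ms = 8,
                          ...) {
  generate_performance(synth_spec(n_quarters = n_quarters, sigma_ms = sigma_ms,
                                  mean_offset_b_ticks = 6, seed = seed, ...))
}

test_that("preset factors map to the four study conditions", {
  expect_equal(manipulation_spec(preset = "original")$m, 1)
  expect_equal(manipulation_spec(preset = "quantized")$m, 0)
  expect_equal(manipulation_spec(preset = "exaggerated")$m, 2)
  expect_equal(manipulation_spec(preset = "inverted")$m, -1)
  expect_error(manipulation_spec(), "either m or preset")
  expect_error(manipulation_spec(m = 1, preset = "quantized"), "not both")
})

test_that("m = 1 is the identity on onsets", {
  g <- manip_fixture()
  out <- apply_manipulation(g$performance, manipulation_spec(m = 1))
  expect_equal(out$notes$onset, g$performance$notes$onset, tolerance = 1e-9)
})

test_that("m = 0 quantizes onto the class means and preserves b_bar, s_bar", {
  g <- manip_fixture()
  prof0 <- mtd_profile(g$performance)
  out <- apply_manipulation(g$performance, manipulation_spec(preset = "quantized"))
  prof <- mtd_profile(out)
  expect_equal(prof$sigma_b, 0, tolerance = 1e-9)
  expect_equal(prof$sigma_s, 0, tolerance = 1e-9)
  expect_equal(prof$b_bar, prof0$b_bar, tolerance = 1e-9)
  expect_equal(prof$s_bar, prof0$s_bar, tolerance = 1e-9)
  # every bin head sits exactly on its class mean position
  d <- compute_mtds(out)
  expect_lt(max(abs(d$d_ticks)), 1e-9)
  # the quantized piece's average swing ratio is the anchor ratio
  expect_equal(prof$r, prof0$s_bar / (960 - prof0$s_bar), tolerance = 1e-9)
})

test_that("m = -1 negates deviations, preserving their spread", {
  g <- manip_fixture()
  prof0 <- mtd_profile(g$performance)
  out <- apply_manipulation(g$performance, manipulation_spec(preset = "inverted"))
  prof <- mtd_profile(out)
  expect_equal(prof$sigma_b, prof0$sigma_b, tolerance = 1e-9)
  expect_equal(prof$sigma_s, prof0$sigma_s, tolerance = 1e-9)
  d0 <- compute_mtds(g$performance)
  d1 <- compute_mtds(out)
  expect_equal(d1$d_ticks, -d0$d_ticks, tolerance = 1e-9)
  # serial correlations are invariant under joint negation
  expect_equal(prof$rho_b_to_s, prof0$rho_b_to_s, tolerance = 1e-9)
})

test_that("m = 2 doubles the spreads exactly, pre-rounding", {
  g <- manip_fixture()
  prof0 <- mtd_profile(g$performance)
  out <- apply_manipulation(g$performance, manipulation_spec(preset = "exaggerated"))
  prof <- mtd_profile(out)
  expect_equal(prof$sigma_b, 2 * prof0$sigma_b, tolerance = 1e-9)
  expect_equal(prof$sigma_s, 2 * prof0$sigma_s, tolerance = 1e-9)
  expect_equal(prof$b_bar, prof0$b_bar, tolerance = 1e-9)
})

test_that("dynamics, durations and pedal are untouched for every m", {
  g <- manip_fixture(n_quarters = 60)
  perf <- g$performance
  perf$passthrough <- data.frame(
    tick = c(0, 480), status = c(0xB0L, 0xB0L), type = c(NA_integer_, NA_integer_),
    data = I(list(as.raw(c(64, 127)), as.raw(c(64, 0))))
  )
  perf <- performance(perf$notes, perf$bpm, perf$passthrough)
  for (m in c(0, 2, -1, 0.5)) {
    out <- apply_manipulation(perf, m)
    expect_identical(out$notes$velocity, perf$notes$velocity)
    expect_identical(out$notes$duration, perf$notes$duration)
    expect_identical(out$notes$channel, perf$notes$channel)
    expect_identical(out$passthrough, perf$passthrough)
  }
})

test_that("middle-triplet notes never move, even under quantization", {
  g <- manip_fixture(n_quarters = 200, middle_note_frac = 0.2)
  perf <- g$performance
  a <- classify_grid(perf)
  mid <- a$klass == "disregarded"
  expect_gt(sum(mid), 0)
  out <- apply_manipulation(perf, manipulation_spec(preset = "quantized"))
  expect_equal(out$notes$onset[mid], perf$notes$onset[mid])
})

test_that("rigid_bin mode preserves chord strum spread; per_note rescales it", {
  g <- manip_fixture(n_quarters = 150, chord_prob = 0.6)
  perf <- g$performance
  out <- apply_manipulation(perf, manipulation_spec(preset = "quantized"))
  a <- classify_grid(perf)
  bins <- paste(a$quarter_index, a$anchor)
  chord_bins <- names(which(table(bins) > 1))
  # intra-bin onset differences survive rigid quantization
  for (b in chord_bins[1:5]) {
    idx <- which(bins == b)
    expect_equal(diff(sort(out$notes$onset[idx])),
                 diff(sort(perf$notes$onset[idx])), tolerance = 1e-9)
  }
  # per-note quantization collapses every note onto the class mean
  out2 <- apply_manipulation(perf, manipulation_spec(preset = "quantized",
                                                     chord_mode = "per_note"))
  d2 <- classify_grid(out2)
  moving <- d2$klass != "disregarded"
  prof <- mtd_profile(perf)
  expected_off <- ifelse(d2$klass == "base", prof$b_bar, prof$s_bar - 640)
  expect_equal(d2$signed_offset[moving], expected_off[moving], tolerance = 1e-9)
})

test_that("composition and involution hold on deviations pre-rounding", {
  g <- manip_fixture(n_quarters = 120, sigma_ms = 6)
  perf <- g$performance
  # apply(m2) o apply(m1) == apply(m2 * m1)
  once <- apply_manipulation(apply_manipulation(perf, 0.5), -1.5)
  direct <- apply_manipulation(perf, -0.75)
  expect_equal(once$notes$onset, direct$notes$onset, tolerance = 1e-9)
  # inversion is an involution
  twice <- apply_manipulation(apply_manipulation(perf, -1), -1)
  expect_equal(twice$notes$onset, perf$notes$onset, tolerance = 1e-9)
})

test_that("verification report encodes the study invariances", {
  g <- manip_fixture()
  perf <- g$performance
  for (m in c(0, -1, 2)) {
    rep <- verify_manipulation(perf, apply_manipulation(perf, m), m)
    expect_true(rep$pass)
    expect_lt(max(rep$checks$delta[1:3]), 0.5)
  }
  # a deliberately broken pair fails
  broken <- apply_manipulation(perf, 2)
  rep <- verify_manipulation(perf, broken, 0)
  expect_false(rep$pass)
})

test_that("negative onsets clamp with a warning and crossings warn", {
  perf <- performance(
    data.frame(onset = c(30, 640, 930, 1640), pitch = 60:63, velocity = 80,
               duration = 100, channel = 0), bpm = 120)
  # base offsets +30/-30 about b_bar = 0: m = 40 throws one far negative
  w <- capture_warnings(out <- apply_manipulation(perf, 40))
  expect_true(any(grepl("clamped", w)))
  expect_true(all(out$notes$onset >= 0))

  g <- manip_fixture(n_quarters = 40, sigma_ms = 20)
  w <- capture_warnings(apply_manipulation(g$performance, 8))
  expect_true(any(grepl("reordered", w)))
})
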