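test_that("deviations are mean-zero per class by construction", {
  for (seed in 1:4) {
    g <- generate_performance(synth_spec(n_quarters = 50, seed = seed,
                                         mean_offset_b_ticks = 12))
    d <- compute_mtds(g$performance)
    expect_equal(mean(d$d_ticks[d$klass == "base"]), 0, tolerance = 1e-9)
    expect_equal(mean(d$d_ticks[d$klass == "swing"]), 0, tolerance = 1e-9)
  }
})

test_that("deviations recover the generator's ground truth", {
  g <- generate_performance(synth_spec(n_quarters = 80, seed = 5,
                                       chord_prob = 0.4))
  d <- compute_mtds(g$performance)
  truth <- g$ground_truth
  # measured deviations equal true deviations re-centred about their mean
  for (kl in c("base", "swing")) {
    t_k <- truth$true_dev_ticks[truth$klass == kl]
    d_k <- d$d_ticks[d$klass == kl]
    expect_equal(d_k, t_k - mean(t_k), tolerance = 1e-9)
  }
})

test_that("millisecond summary: degenerate and sampling-theory cases", {
  exact <- performance(
    data.frame(onset = c(0, 640, 960, 1600), pitch = 60:63, velocity = 80,
               duration = 100, channel = 0), bpm = 120)
  s <- summarize_mtds(compute_mtds(exact), 120)
  expect_equal(s$sigma_b, 0)
  expect_equal(s$sigma_s, 0)
  expect_equal(s$mean_dev_ms, 0)

  # i.i.d. Gaussian deviations at sigma = 18.39 ms, n = 5000 bins:
  # estimate within 3 standard errors, SE ~ sigma / sqrt(2 n)
  g <- suppressWarnings(
    generate_performance(synth_spec(n_quarters = 2500, sigma_ms = 18.39,
                                    noise_model = "iid_gaussian",
                                    chord_prob = 0, middle_note_frac = 0,
                                    seed = 9)))
  s <- summarize_mtds(compute_mtds(g$performance), 150)
  se <- 18.39 / sqrt(2 * 5000)
  expect_lt(abs(s$pooled_sd_ms - 18.39), 3 * se)

  # fewer than two deviations in a class: NA, not an error
  tiny <- performance(
    data.frame(onset = c(5, 640, 1605), pitch = 60:62, velocity = 80,
               duration = 100, channel = 0), bpm = 120)
  s_tiny <- summarize_mtds(compute_mtds(tiny), 120)
  expect_true(is.na(s_tiny$sigma_b))      # single base deviation
  expect_false(is.na(s_tiny$sigma_s))     # two swing deviations
})

test_that("swing ratio follows the per-note position ratio", {
  expect_equal(swing_ratio(c(640, 640, 640))$r, 2)        # perfect triplets
  expect_equal(swing_ratio(c(640, 640, 640))$delta_r, 0)
  expect_equal(swing_ratio(480)$r, 1)                     # straight eighths
  expect_equal(swing_ratio(582)$r, 582 / 378)             # ~1.540

  # strictly increasing in position on (0, 960)
  p <- seq(10, 950, by = 10)
  r <- swing_ratio(p)$ratios
  expect_true(all(diff(r) > 0))

  # r averages per-note ratios: with noisy positions it exceeds the ratio
  # at the mean position (convexity)
  pos <- 640 + c(-100, 100)
  expect_gt(swing_ratio(pos)$r, swing_ratio(640)$r)

  expect_error(swing_ratio(c(640, 960)), "strictly inside")
})

test_that("serial correlations match rank structure and the Spearman oracle", {
  mk_perf <- function(d_base, d_swing) {
    n <- length(d_base)
    onsets <- as.vector(rbind((1:n) * 960 + d_base,
                              (1:n) * 960 + 640 + d_swing))
    performance(data.frame(onset = onsets, pitch = 60, velocity = 80,
                           duration = 100, channel = 0), bpm = 120)
  }
  # identical ranks in both classes -> rho = 1
  d <- c(-30, -10, 0, 10, 30)
  p <- mk_perf(d, d)
  rho <- serial_correlations(compute_mtds(p))
  expect_equal(rho$rho_b_to_s, 1)
  expect_equal(rho$rho_s_to_b, 1)
  # reversed ranks -> rho = -1 (base i pairs with swing i; swing i with base i+1)
  p <- mk_perf(d, -d)
  rho <- serial_correlations(compute_mtds(p))
  expect_equal(rho$rho_b_to_s, -1)

  # implementation agrees with the rank-then-Pearson oracle, ties included
  set.seed(31)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    db <- sample(seq(-40, 40, by = 10), n, replace = TRUE)  # integer ticks: ties
    ds <- sample(seq(-40, 40, by = 10), n, replace = TRUE)
    rho <- serial_correlations(compute_mtds(mk_perf(db, ds)))
    dev_b <- db - mean(db)
    dev_s <- ds - mean(ds)
    expect_equal(rho$rho_b_to_s, oracle_spearman(dev_b, dev_s),
                 tolerance = 1e-12)
    expect_equal(rho$rho_s_to_b,
                 oracle_spearman(dev_s[-n], dev_b[-1]), tolerance = 1e-12)
  }

  # negating both members of every pair leaves rho unchanged
  db <- c(-30, 5, 12, -8, 20, 1)
  ds <- c(10, -25, 3, 18, -12, 7)
  r1 <- serial_correlations(compute_mtds(mk_perf(db, ds)))
  r2 <- serial_correlations(compute_mtds(mk_perf(-db, -ds)))
  expect_equal(r1$rho_b_to_s, r2$rho_b_to_s)
  expect_equal(r1$rho_s_to_b, r2$rho_s_to_b)

  # fewer than three pairs -> NA
  few <- mk_perf(c(1, 2), c(2, 1))
  expect_true(is.na(serial_correlations(compute_mtds(few))$rho_b_to_s))
})

test_that("pairing respects the one-quarter-note distance bound", {
  # swing bins missing in quarters 1 and 3: those base notes have no partner
  onsets <- c(0, 640, 960, 1920, 2580, 2880)
  p <- performance(data.frame(onset = onsets, pitch = 60, velocity = 80,
                              duration = 100, channel = 0), bpm = 120)
  rho <- serial_correlations(compute_mtds(p))
  expect_equal(rho$n_pairs_bs, 2)  # quarters 0 and 2 only
})

test_that("profile and report assemble the per-recording statistics", {
  # perfectly quantized synthetic piece at r = 2
  g <- generate_performance(synth_spec(n_quarters = 16, sigma_ms = 0,
                                       target_r = 2, chord_prob = 0,
                                       middle_note_frac = 0, seed = 1))
  prof <- mtd_profile(g$performance)
  expect_equal(prof$b_bar, 0)
  expect_equal(prof$s_bar, 640)
  expect_equal(prof$sigma_b, 0)
  expect_equal(prof$sigma_s, 0)
  expect_equal(prof$r, 2)
  expect_equal(prof$delta_r, 0)
  expect_true(is.na(prof$rho_b_to_s))  # constant margins: undefined

  report <- mtd_report(list(quantized = g$performance))
  expect_equal(report$recording, "quantized")
  expect_equal(report$r, 2)
  expect_equal(report$middle_frac, 0)

  # per-piece failure yields an NA row, not an abort
  bad <- performance(data.frame(onset = c(0, 960), pitch = 60:61,
                                velocity = 80, duration = 100, channel = 0),
                     bpm = 120)
  expect_warning(rep2 <- mtd_report(list(ok = g$performance, broken = bad)),
                 "failed")
  expect_equal(nrow(rep2), 2)
  expect_true(is.na(rep2$r[2]))
  expect_false(is.na(rep2$r[1]))
})

test_that("middle-triplet fraction matches the configured rate", {
  g <- suppressWarnings(
    generate_performance(synth_spec(n_quarters = 2000, middle_note_frac = 0.05,
                                    chord_prob = 0, seed = 12)))
  prof <- mtd_profile(g$performance)
  n <- prof$n_notes
  se <- sqrt(0.05 * 0.95 / n)
  # fraction of notes vs fraction of quarters: 1 middle note per flagged
  # quarter among ~2 notes/quarter + middles
  expected <- 0.05 / (2 + 0.05)
  expect_lt(abs(prof$middle_frac - expected), 3 * se)
})

test_that("deviation CSV export carries tick and millisecond columns", {
  g <- generate_performance(synth_spec(n_quarters = 10, seed = 4))
  prof <- mtd_profile(g$performance)
  path <- tempfile(fileext = ".csv")
  export_deviations(prof, path)
  tab <- read.csv(path)
  expect_named(tab, c("note_index", "class", "d_ticks", "d_ms"))
  expect_equal(tab$d_ms, ticks_to_ms(tab$d_ticks, g$performance$bpm))
})
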