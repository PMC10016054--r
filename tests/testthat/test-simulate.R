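test_that("parameter and design validation rejects out-of-range values", {
  expect_error(dyad_params(alpha_melody = 1), "alpha_melody")
  expect_error(dyad_params(alpha_bass = -0.1), "alpha_bass")
  expect_error(dyad_params(lambda_seg = 1.2), "lambda_seg")
  expect_error(dyad_params(sigma_timekeeper = -1), "sigma_timekeeper")
  expect_error(dyad_params(p_outlier = 1.5), "p_outlier")
  expect_error(dyad_params(seed = 1.5), "seed")
  expect_error(design_spec(trials_per_condition = 3), "even")
  expect_error(score_spec(1, 1:13, 1:14), "14 MIDI pitches")
})

test_that("nominal trial durations follow the paradigm arithmetic", {
  expect_equal(nominal_trial_duration("fast"), 14200)
  expect_equal(nominal_trial_duration("slow"), 16000)
  expect_equal(nominal_trial_duration("none"), 15000)
  # metronome block: 4 beats at 120 bpm
  d <- design_spec()
  expect_equal(d$metronome_beats * 60000 / d$base_tempo_bpm, 2000)
})

test_that("noiseless generator sits at the symmetric fixed point", {
  d <- simulate_dataset(quiet_params(seed = 3),
                        design_spec(n_pairs = 1, trials_per_condition = 2))
  ev1 <- d$events[d$events$phrase == 1, ]
  expect_setequal(unique(ev1$onset_ms), seq(3000, 6000, by = 500))
  a <- compute_asynchronies(d$events)
  expect_true(all(a$asynchrony == 0))
  # phrase-1 IKIs exactly 500 ms
  om <- duetsync:::.onset_matrices(d$events, 1L)
  expect_true(all(duetsync:::.iki_matrix(om$melody) == 500))
  # phrase 2 of a fast-cued player: onsets from 11000 at 400 ms
  fast_tr <- d$meta$trial_id[d$meta$cue_melody == "up"][1L]
  p2 <- d$events[d$events$trial_id == fast_tr & d$events$phrase == 2 &
                   d$events$player_role == "melody", ]
  expect_equal(p2$onset_ms, seq(11000, by = 400, length.out = 7))
})

test_that("anticipation drift matches the closed-form recursion", {
  # independent brute-force recursion, written before the implementation
  p <- quiet_params()
  p$kappa <- 0.1
  am <- p$alpha_melody; ab <- p$alpha_bass
  tm <- 3000; tb <- 3000
  expected <- numeric(7); expected[1] <- 0
  for (n in 1:6) {
    Tm <- 500 + 0.1 * (400 - 500) * (n / 7)
    Tb <- 500 + 0.1 * (625 - 500) * (n / 7)
    tm2 <- tm + Tm - am * (tm - tb)
    tb2 <- tb + Tb - ab * (tb - tm)
    tm <- tm2; tb <- tb2
    expected[n + 1] <- tm - tb
  }
  meta <- list(pair_id = 1, session = 1, trial_id = 1, piece_id = "1",
               familiarity = "U", cue_melody = "up", cue_bass = "down")
  ev <- simulate_trial(p, design_spec(), meta)
  a <- compute_asynchronies(ev)$asynchrony
  expect_equal(a, expected, tolerance = 1e-3)  # onsets stored at 0.001 ms
  expect_true(all(diff(a) < 0))  # melody drifts earlier, strictly
})

test_that("dataset layout matches the factorial design", {
  des <- design_spec(n_pairs = 2, trials_per_condition = 4)
  d <- simulate_dataset(dyad_params(seed = 1), des)
  expect_equal(nrow(d$meta), 32)
  expect_equal(unname(table(d$meta$condition)), rep(8L, 4),
               ignore_attr = TRUE)
  # instruction types balanced within condition
  tab <- table(d$meta$condition, d$meta$instruction_type)
  expect_equal(unname(tab["FC", c("UU", "DD")]), c(4L, 4L),
               ignore_attr = TRUE)
  expect_equal(unname(tab["FI", c("UD", "DU")]), c(4L, 4L),
               ignore_attr = TRUE)
  # paradigm default: 128 trials per pair
  meta_full <- simulate_dataset(dyad_params(seed = 1),
                                design_spec(n_pairs = 1))$meta
  expect_equal(nrow(meta_full), 128)
  # two sessions, roles fixed by design (one event table per player role)
  expect_setequal(unique(d$meta$session), 1:2)
})

test_that("simulation is deterministic and trial-order independent", {
  des <- design_spec(n_pairs = 2, trials_per_condition = 4)
  d1 <- simulate_dataset(dyad_params(seed = 9), des)
  d2 <- simulate_dataset(dyad_params(seed = 9), des)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$meta, d2$meta)
  d3 <- simulate_dataset(dyad_params(seed = 10), des)
  expect_false(identical(d1$events$onset_ms, d3$events$onset_ms))
  # a single trial re-simulated from its substream matches the dataset
  p <- dyad_params(seed = 9)
  for (i in c(3L, 17L)) {
    set.seed(duetsync:::.trial_seed(p$seed, i))
    ev <- simulate_trial(p, des, d1$meta[i, ])
    expect_identical(ev$onset_ms,
                     d1$events$onset_ms[d1$events$trial_id == i])
  }
})

test_that("invalid labels are rejected with diagnostics", {
  des <- design_spec()
  meta <- list(pair_id = 1, session = 1, trial_id = 1, piece_id = "1",
               familiarity = "F", cue_melody = "sideways",
               cue_bass = "down")
  expect_error(simulate_trial(dyad_params(), des, meta), "invalid cue")
  meta$cue_melody <- "up"; meta$familiarity <- "X"
  expect_error(simulate_trial(dyad_params(), des, meta),
               "invalid familiarity")
  meta$familiarity <- "F"; meta$piece_id <- "nope"
  expect_error(simulate_trial(dyad_params(), des, meta), "no score")
})

test_that("injections are logged and realized in the events", {
  p <- quiet_params(seed = 21)
  p$p_wrong_note <- 1  # every trial gets one wrong pitch
  des <- design_spec(n_pairs = 1, trials_per_condition = 4)
  d <- simulate_dataset(p, des)
  expect_true(all(d$injections$wrong_note))
  flags <- flag_wrong_notes(d$events, d$meta, des$pieces)
  expect_true(all(flags$wrong_note))
  # exactly one mismatching pitch per trial
  scores <- des$pieces
  bad_per_trial <- vapply(split(d$events, d$events$trial_id), function(ev) {
    sc <- scores[[as.character(d$meta$piece_id[
      d$meta$trial_id == ev$trial_id[1]])]]
    exp_pitch <- ifelse(ev$player_role == "melody",
                        sc$melody_pitches[(ev$phrase - 1) * 7 + ev$position],
                        sc$bass_pitches[(ev$phrase - 1) * 7 + ev$position])
    sum(ev$pitch != exp_pitch)
  }, 0)
  expect_true(all(bad_per_trial == 1))
})

test_that("lag -1 adaptation increases with the melody coupling gain", {
  # mean lag -1 Fisher z is non-decreasing in alpha_melody at fixed noise
  means <- ses <- numeric(4)
  gains <- c(0, 0.1, 0.2, 0.4)
  for (i in seq_along(gains)) {
    p <- dyad_params(seed = 7)
    p$alpha_melody <- gains[i]
    sim <- simulate_dataset(p, design_spec(n_pairs = 63,
                                           trials_per_condition = 16))
    tz <- duetsync:::.trial_lag_z(sim$events, sim$meta)
    means[i] <- mean(tz$z_lagm1, na.rm = TRUE)
    ses[i] <- sd(tz$z_lagm1, na.rm = TRUE) /
      sqrt(sum(!is.na(tz$z_lagm1)))
  }
  # non-decreasing within sampling tolerance (2 SE of each difference)
  for (i in 1:3)
    expect_gt(means[i + 1] - means[i], -2 * sqrt(ses[i]^2 + ses[i + 1]^2))
})
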