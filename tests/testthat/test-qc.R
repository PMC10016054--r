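test_that("wrong-note flags match score mismatches exactly", {
  des <- design_spec(n_pairs = 1, trials_per_condition = 4)
  d <- simulate_dataset(quiet_params(seed = 5), des)
  flags <- flag_wrong_notes(d$events, d$meta, des$pieces)
  expect_false(any(flags$wrong_note))

  ev <- d$events
  i <- which(ev$trial_id == 3 & ev$player_role == "bass" &
               ev$phrase == 2 & ev$position == 4)
  ev$pitch[i] <- ev$pitch[i] + 1L  # one bass note a semitone sharp
  flags <- flag_wrong_notes(ev, d$meta, des$pieces)
  expect_identical(flags$trial_id[flags$wrong_note], 3L)

  expect_error(flag_wrong_notes(ev, d$meta, des$pieces["1"]), "no score")
})

test_that("wrong-note counts agree with the simulator injection log", {
  p <- dyad_params(seed = 31, p_wrong_note = 0.3, p_mistempo = 0,
                   p_outlier = 0)
  des <- design_spec(n_pairs = 2, trials_per_condition = 8)
  d <- simulate_dataset(p, des)
  flags <- flag_wrong_notes(d$events, d$meta, des$pieces)
  expect_identical(flags$wrong_note[order(flags$trial_id)],
                   d$injections$wrong_note)
  expect_gt(sum(flags$wrong_note), 0)
})

test_that("tempo classification minimizes MSE with the stated tie rule", {
  expect_equal(classify_tempo(rep(400, 6)), "fast")
  expect_equal(classify_tempo(rep(625, 6)), "slow")
  expect_equal(classify_tempo(rep(500, 6)), "none")
  expect_equal(classify_tempo(c(410, 395, 405, 400, 390, 402)), "fast")
  # 450 ms ties fast (MSE 2500) and none (MSE 2500) against slow (30625):
  # the instructed tempo survives if tied, otherwise template order
  expect_equal(classify_tempo(rep(450, 6), instructed = "none"), "none")
  expect_equal(classify_tempo(rep(450, 6), instructed = "fast"), "fast")
  expect_equal(classify_tempo(rep(450, 6), instructed = "slow"), "fast")
  expect_equal(classify_tempo(rep(450, 6)), "fast")
  expect_error(classify_tempo(rep(400, 5)), "exactly 6")
  expect_error(classify_tempo(c(rep(400, 5), -1)), "positive")
})

test_that("pooled IKI outlier trimming reproduces hand-computed bounds", {
  # pool of 100 phrase-1 IKIs: 98 x 500 ms plus one 900 and one 100, in
  # two distinct trials; type-7 percentiles give [496, 504]
  n_tr <- 50L
  on_m <- matrix(rep(c(3000, 3500), n_tr), n_tr, 2, byrow = TRUE)
  on_b <- on_m
  on_m[1, 2] <- 3900  # 900 ms IKI
  on_m[2, 2] <- 3100  # 100 ms IKI
  ev <- make_events(on_m, on_b)
  res <- trim_iki_outliers(ev)
  expect_equal(res$bounds, c(496, 504))
  expect_equal(res$n_pooled, 100L)
  expect_identical(res$flags$trial_id[res$flags$iki_outlier], c(1L, 2L))

  # degenerate pool: all identical -> nothing flagged
  ev2 <- make_events(matrix(rep(c(3000, 3500), 60), 60, 2, byrow = TRUE),
                     matrix(rep(c(3000, 3500), 60), 60, 2, byrow = TRUE))
  expect_false(any(trim_iki_outliers(ev2)$flags$iki_outlier))

  # flags invariant to trial ordering (pooling is order-free)
  perm <- ev[rev(seq_len(nrow(ev))), ]
  res_p <- trim_iki_outliers(perm)
  expect_identical(sort(res_p$flags$trial_id[res_p$flags$iki_outlier]),
                   c(1L, 2L))

  # too few IKIs: warning, filter skipped
  small <- make_events(on_m[1:5, ], on_b[1:5, ])
  expect_warning(res_s <- trim_iki_outliers(small), "fewer than 100")
  expect_false(any(res_s$flags$iki_outlier))
})

test_that("full QC retains everything for a clean noiseless dataset", {
  des <- design_spec(n_pairs = 1, trials_per_condition = 4)
  d <- simulate_dataset(quiet_params(seed = 6), des)
  qc <- run_qc(d$events, d$meta, des$pieces)
  expect_true(all(qc$trials$retained))
  expect_equal(sum(qc$condition_counts$retained), nrow(d$meta))
  expect_equal(nrow(qc$events), nrow(d$events))
})

test_that("QC removes exactly the injected trials in a noiseless run", {
  p <- quiet_params(seed = 8)
  p$p_wrong_note <- 0.15; p$p_mistempo <- 0.1; p$p_outlier <- 0.1
  des <- design_spec(n_pairs = 3, trials_per_condition = 8)
  d <- simulate_dataset(p, des)
  qc <- run_qc(d$events, d$meta, des$pieces)
  injected <- d$injections$wrong_note | d$injections$mistempo |
    d$injections$outlier
  expect_gt(sum(injected), 0)
  expect_identical(qc$trials$retained[order(qc$trials$trial_id)],
                   !injected)
  expect_identical(qc$trials$wrong_note[order(qc$trials$trial_id)],
                   d$injections$wrong_note)
  mist <- qc$trials$mistempo_melody | qc$trials$mistempo_bass
  expect_identical(mist[order(qc$trials$trial_id)], d$injections$mistempo)
})

test_that("QC is idempotent with frozen percentile bounds", {
  d <- simulate_dataset(dyad_params(seed = 12),
                        design_spec(n_pairs = 2,
                                    trials_per_condition = 16))
  qc1 <- run_qc(d$events, d$meta)
  qc2 <- run_qc(qc1$events, d$meta, iki_bounds = qc1$iki_bounds)
  expect_true(all(qc2$trials$retained))
  expect_equal(nrow(qc2$events), nrow(qc1$events))
})

test_that("every flagged trial carries a machine-readable reason", {
  d <- simulate_dataset(dyad_params(seed = 13),
                        design_spec(n_pairs = 2,
                                    trials_per_condition = 16))
  qc <- run_qc(d$events, d$meta)
  reasons <- with(qc$trials, wrong_note | mistempo_melody |
                    mistempo_bass | technical_error | iki_outlier)
  expect_identical(qc$trials$retained, !reasons)
  expect_equal(sum(qc$trials$retained) + sum(!qc$trials$retained),
               nrow(d$meta))
})

test_that("the optional technical-error column excludes trials", {
  des <- design_spec(n_pairs = 1, trials_per_condition = 4)
  d <- simulate_dataset(quiet_params(seed = 6), des)
  meta <- d$meta
  meta$technical_error <- meta$trial_id %in% c(2L, 5L)
  qc <- run_qc(d$events, meta, des$pieces)
  expect_identical(qc$trials$trial_id[!qc$trials$retained], c(2L, 5L))
})
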