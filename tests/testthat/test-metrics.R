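test_that("asynchronies are melody minus bass per position", {
  on_m <- matrix(c(3000, 3500), 1)
  on_b <- matrix(c(2995, 3505), 1)
  a <- compute_asynchronies(make_events(on_m, on_b))
  expect_equal(a$asynchrony, c(5, -5))
  a0 <- compute_asynchronies(make_events(on_m, on_m))
  expect_equal(a0$asynchrony, c(0, 0))
})

test_that("incomplete trials are skipped with a warning", {
  on_m <- matrix(c(3000, 3500, 4000, 3000, 3500, 4000), 2, byrow = TRUE)
  ev <- make_events(on_m, on_m + 2)
  ev <- ev[!(ev$trial_id == 2 & ev$player_role == "bass" &
               ev$position == 3), ]
  expect_warning(a <- compute_asynchronies(ev), "incomplete")
  expect_equal(unique(a$trial_id), 1L)
})

test_that("mean-centering removes cell means exactly", {
  # two trials in one cell with asynchronies 4 and 6 -> -1 and +1
  on_m <- matrix(c(3000, 3500, 3000, 3500), 2, byrow = TRUE)
  on_b <- on_m; on_b[1, ] <- on_m[1, ] - 4; on_b[2, ] <- on_m[2, ] - 6
  ev <- make_events(on_m, on_b)
  meta <- make_meta(2)
  cen <- mean_center(compute_asynchronies(ev), meta)
  expect_equal(cen$centered[cen$trial_id == 1], c(-1, -1))
  expect_equal(cen$centered[cen$trial_id == 2], c(1, 1))
  expect_false(any(cen$single_trial_cell))

  # identical trials center to exactly zero
  cen0 <- mean_center(compute_asynchronies(make_events(on_m, on_m)), meta)
  expect_true(all(cen0$centered == 0))
})

test_that("centered asynchronies sum to zero within every cell", {
  d <- simulate_dataset(dyad_params(seed = 14),
                        design_spec(n_pairs = 2,
                                    trials_per_condition = 8))
  a <- mean_center(compute_asynchronies(d$events), d$meta)
  idx <- match(a$trial_id, d$meta$trial_id)
  cell <- paste(d$meta$pair_id[idx], d$meta$session[idx],
                d$meta$piece_id[idx], a$position)
  sums <- tapply(a$centered, cell, sum)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("accuracy summary averages |instruction means| into conditions", {
  # 4 trials, one per instruction type; constant asynchronies
  # +6 (UD), -6 (DU), +2 (UU), -2 (DD) before centering are irrelevant:
  # feed the asynchrony frame directly, bypassing centering
  asyn <- data.frame(trial_id = rep(1:4, each = 7),
                     position = rep(1:7, 4),
                     asynchrony = rep(c(6, -6, 2, -2), each = 7))
  meta <- derive_condition(data.frame(
    pair_id = 1L, session = 1L, trial_id = 1:4, piece_id = "1",
    familiarity = "F",
    cue_melody = c("up", "down", "up", "down"),
    cue_bass = c("down", "up", "up", "down")))
  out <- accuracy_summary(asyn, meta)
  expect_equal(out$mean_abs_async[out$condition == "FI"], 6)
  expect_equal(out$mean_abs_async[out$condition == "FC"], 2)
  # all-zero asynchronies give zero for every condition
  asyn0 <- transform(asyn, asynchrony = 0)
  expect_true(all(accuracy_summary(asyn0, meta)$mean_abs_async == 0))
  # both aggregation orders agree on balanced data
  out2 <- accuracy_summary(asyn, meta, trial_means_first = TRUE)
  expect_equal(out2$mean_abs_async, out$mean_abs_async)
})

test_that("stability summary is the mean per-trial SD (n-1)", {
  asyn <- data.frame(trial_id = rep(1L, 7), position = 1:7,
                     asynchrony = c(5, -5, 5, -5, 5, -5, 5))
  meta <- make_meta(1)
  out <- stability_summary(asyn, meta)
  expect_equal(out$mean_sd_async, 5.345225, tolerance = 1e-6)
  out0 <- stability_summary(transform(asyn, asynchrony = 3), meta)
  expect_equal(out0$mean_sd_async, 0)
})

test_that("lagged cross-correlations follow the shift convention", {
  m <- c(480, 510, 495, 520, 490, 505)
  expect_equal(lag_crosscorr(m, m, 0)$r, 1)
  # bass built so that bass(n-1) = melody(n): lag -1 correlation is 1
  b <- c(m[2:6], 999)
  expect_equal(lag_crosscorr(m, b, -1)$r, 1)
  # and the mirrored construction for lag +1
  b2 <- c(999, m[1:5])
  expect_equal(lag_crosscorr(m, b2, 1)$r, 1)
  # reversal example against the brute-force oracle
  b3 <- rev(m)
  expect_equal(lag_crosscorr(m, b3, 0)$r, oracle_pearson(m, b3),
               tolerance = 1e-12)
  # zero variance is missing, never zero
  expect_true(is.na(lag_crosscorr(m, rep(500, 6), 0)$r))
  expect_error(lag_crosscorr(m, b, 2), "lag")
})

test_that("lag correlations match the brute-force oracle on 1000 vectors", {
  set.seed(99)
  max_err <- 0
  for (i in 1:1000) {
    m <- rnorm(6, 500, 20)
    b <- rnorm(6, 500, 20)
    for (lag in c(-1L, 0L, 1L)) {
      r_pkg <- lag_crosscorr(m, b, lag)$r
      r_or <- oracle_lag_r(m, b, lag)
      max_err <- max(max_err, abs(r_pkg - r_or))
    }
  }
  expect_lt(max_err, 1e-12)
})

test_that("Fisher z is monotone in r and scale invariance holds", {
  rs <- seq(-0.9, 0.9, by = 0.2)
  zs <- atanh(rs)
  expect_true(all(diff(zs) > 0))
  set.seed(7)
  m <- rnorm(6, 500, 20); b <- rnorm(6, 500, 20)
  for (lag in c(-1L, 0L, 1L)) {
    base <- lag_crosscorr(m, b, lag)$r
    expect_equal(lag_crosscorr(2.5 * m - 40, b, lag)$r, base,
                 tolerance = 1e-12)
    expect_equal(lag_crosscorr(m, 0.3 * b + 11, lag)$r, base,
                 tolerance = 1e-12)
  }
})

test_that("adaptation summary averages per-trial Fisher z by condition", {
  # three trials with known IKI structure in one condition
  set.seed(5)
  iki_m <- matrix(rnorm(18, 500, 25), 3, 6)
  iki_b <- matrix(rnorm(18, 500, 25), 3, 6)
  on_m <- cbind(3000, 3000 + t(apply(iki_m, 1, cumsum)))
  on_b <- cbind(3000, 3000 + t(apply(iki_b, 1, cumsum)))
  ev <- make_events(on_m, on_b)
  meta <- make_meta(3)
  out <- adaptation_summary(ev, meta)
  # oracle: mean atanh(r) over trials at each lag
  for (lg in c(-1L, 0L, 1L)) {
    zs <- sapply(1:3, function(i)
      atanh(oracle_lag_r(iki_m[i, ], iki_b[i, ], lg)))
    lab <- c(`-1` = "lag-1", `0` = "lag0", `1` = "lag+1")[as.character(lg)]
    expect_equal(out$mean_z[out$lag == lab], mean(zs), tolerance = 1e-12)
  }
  # a trial whose IKI series correlate at exactly r = 0.5 at lag 0
  v <- vectors_with_cor(0.5, 6)
  onm <- matrix(c(3000, 3000 + cumsum(500 + 20 * v$x)), 1)
  onb <- matrix(c(3000, 3000 + cumsum(500 + 20 * v$y)), 1)
  ev1 <- make_events(onm, onb)
  out1 <- adaptation_summary(ev1, make_meta(1))
  expect_equal(out1$mean_z[out1$lag == "lag0"], atanh(0.5),
               tolerance = 1e-10)
})

test_that("role swap negates asynchronies and preserves SD", {
  d <- simulate_dataset(dyad_params(seed = 15),
                        design_spec(n_pairs = 1,
                                    trials_per_condition = 4))
  swapped <- d$events
  swapped$player_role <- ifelse(swapped$player_role == "melody",
                                "bass", "melody")
  a1 <- compute_asynchronies(d$events)
  a2 <- compute_asynchronies(swapped)
  expect_equal(a2$asynchrony, -a1$asynchrony)
  s1 <- stability_summary(mean_center(a1, d$meta), d$meta)
  s2 <- stability_summary(mean_center(a2, d$meta), d$meta)
  expect_equal(s2$mean_sd_async, s1$mean_sd_async)
  c1 <- accuracy_summary(mean_center(a1, d$meta), d$meta)
  c2 <- accuracy_summary(mean_center(a2, d$meta), d$meta)
  expect_equal(c2$mean_abs_async, c1$mean_abs_async)
})

test_that("condition summary has one row per participant and condition", {
  d <- simulate_dataset(dyad_params(seed = 16),
                        design_spec(n_pairs = 3,
                                    trials_per_condition = 8))
  qc <- run_qc(d$events, d$meta)
  cs <- condition_summary(qc$events, d$meta)
  expect_setequal(names(cs), c("participant", "condition",
                               "mean_abs_async", "mean_sd_async",
                               "z_lagm1", "z_lag0", "z_lagp1"))
  expect_lte(nrow(cs), 6 * 4)
  expect_false(any(duplicated(cs[, c("participant", "condition")])))
})
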