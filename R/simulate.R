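#' Nominal trial duration for a cued second-phrase tempo
#'
#' Sum of the paradigm's trial segments: visual cue, metronome count-in at
#' the base tempo, first phrase (notes plus closing quarter pause), silent
#' 2-bar pause at the base tempo, and second phrase at the cued tempo.
#' With defaults this gives 14,200 ms for the fast cue, 16,000 ms for the
#' slow cue and 15,000 ms for an uncued (base tempo) second phrase.
#'
#' @param cued_tempo One of `"fast"`, `"slow"`, `"none"`.
#' @param design A [design_spec()].
#' @return Duration in ms.
#' @export
#' @examples
#' nominal_trial_duration("fast")  # 14200
#' nominal_trial_duration("slow")  # 16000
nominal_trial_duration <- function(cued_tempo = c("fast", "slow", "none"),
                                   design = design_spec()) {
  cued_tempo <- match.arg(cued_tempo)
  base <- .beat_ms(design$base_tempo_bpm)
  p2_bpm <- switch(cued_tempo,
                   fast = design$fast_bpm,
                   slow = design$slow_bpm,
                   none = design$base_tempo_bpm)
  beats_per_phrase <- design$notes_per_phrase + 1L
  design$cue_ms +
    design$metronome_beats * base +
    beats_per_phrase * base +        # phrase 1
    beats_per_phrase * base +        # pause (2 bars at base tempo)
    beats_per_phrase * .beat_ms(p2_bpm)
}

# cued second-phrase inter-keystroke interval for a cue label ("up"/"down")
.cued_interval <- function(cue, design) {
  switch(cue,
         up = .beat_ms(design$fast_bpm),
         down = .beat_ms(design$slow_bpm),
         stop(sprintf("invalid cue label '%s' (must be 'up' or 'down')",
                      cue), call. = FALSE))
}

# Core onset generator for one trial. All Gaussian noise is drawn as one
# block, then three uniforms for the injection triggers, then any
# injection detail draws -- a fixed consumption order, so a seeded caller
# is fully deterministic and the vectorized dataset path (which pre-draws
# the same block per trial substream) reproduces it exactly.
#
# Noise block layout (npp = notes per phrase; length 6 + 4*(npp-1)):
#   1 delta_melody, 2 delta_bass, 3-4 phrase-1 start jitter (m, b),
#   5-6 phrase-2 start jitter (m, b), then four runs of npp-1 interval
#   innovations: phrase-1 melody, phrase-1 bass, phrase-2 melody,
#   phrase-2 bass.
#
# Phrase-1 recursion, n = 1..npp-1 (interval between notes n and n+1):
#   T_i(n)   = tau + kappa * (tau*_i - tau) * (n / npp) + delta_i
#   t_i(n+1) = t_i(n) + T_i(n) - alpha_i_eff * (t_i(n) - t_j(n)) + eta
# with tau the base interval, tau*_i the cued second-phrase interval,
# delta_i ~ N(0, sigma_fam^2) in familiar trials (else 0), and
# eta ~ N(0, sigma_timekeeper^2 + sigma_motor^2). Phrase 2 starts at its
# nominal onset and evolves uncoupled at tau*_i + eta.
.sim_trial_onsets <- function(params, design, familiarity, cue_melody,
                              cue_bass) {
  npp <- design$notes_per_phrase
  tau <- .beat_ms(design$base_tempo_bpm)
  t1_nom <- design$cue_ms + design$metronome_beats * tau
  p2_nom <- t1_nom + 2 * (npp + 1L) * tau
  congruent <- identical(cue_melody, cue_bass)

  tau_star_m <- .cued_interval(cue_melody, design)
  tau_star_b <- .cued_interval(cue_bass, design)

  a_m <- params$alpha_melody
  if (familiarity == "F" && !congruent)
    a_m <- a_m * (1 - params$lambda_seg)
  a_b <- params$alpha_bass

  sig_int <- sqrt(params$sigma_timekeeper^2 + params$sigma_motor^2)
  sig_fam <- if (familiarity == "F") params$sigma_fam else 0
  ni <- npp - 1L
  z <- stats::rnorm(6L + 4L * ni)
  u <- stats::runif(3L)

  delta_m <- z[1L] * sig_fam
  delta_b <- z[2L] * sig_fam
  on_m <- numeric(2L * npp)
  on_b <- numeric(2L * npp)
  on_m[1L] <- t1_nom + z[3L] * params$sigma_start
  on_b[1L] <- t1_nom + z[4L] * params$sigma_start
  e1m <- z[6L + seq_len(ni)] * sig_int
  e1b <- z[6L + ni + seq_len(ni)] * sig_int
  for (n in seq_len(ni)) {
    drift <- params$kappa * (n / npp)
    T_m <- tau + drift * (tau_star_m - tau) + delta_m
    T_b <- tau + drift * (tau_star_b - tau) + delta_b
    async <- on_m[n] - on_b[n]
    on_m[n + 1L] <- on_m[n] + T_m - a_m * async + e1m[n]
    on_b[n + 1L] <- on_b[n] + T_b + a_b * async + e1b[n]
  }

  # phrase 2: uncoupled, players no longer hear each other
  on_m[npp + 1L] <- p2_nom + z[5L] * params$sigma_start
  on_b[npp + 1L] <- p2_nom + z[6L] * params$sigma_start
  e2m <- z[6L + 2L * ni + seq_len(ni)] * sig_int
  e2b <- z[6L + 3L * ni + seq_len(ni)] * sig_int
  on_m[(npp + 2L):(2L * npp)] <- on_m[npp + 1L] + cumsum(tau_star_m + e2m)
  on_b[(npp + 2L):(2L * npp)] <- on_b[npp + 1L] + cumsum(tau_star_b + e2b)

  inj <- list(wrong_note = FALSE, mistempo = FALSE, outlier = FALSE,
              wrong_note_at = NULL, mistempo_player = NULL,
              outlier_at = NULL)

  # injection: one player re-plays phrase 2 at the base interval
  if (u[2L] < params$p_mistempo) {
    who <- if (stats::runif(1) < 0.5) "melody" else "bass"
    e_new <- stats::rnorm(ni) * sig_int
    if (who == "melody") {
      on_m[(npp + 2L):(2L * npp)] <- on_m[npp + 1L] + cumsum(tau + e_new)
    } else {
      on_b[(npp + 2L):(2L * npp)] <- on_b[npp + 1L] + cumsum(tau + e_new)
    }
    inj$mistempo <- TRUE
    inj$mistempo_player <- who
  }

  # injection: stretch/compress one random phrase-1 interval of one player
  if (u[3L] < params$p_outlier) {
    who <- if (stats::runif(1) < 0.5) "melody" else "bass"
    k <- sample.int(ni, 1L)
    f <- sample(c(0.5, 1.8), 1L)
    tgt <- if (who == "melody") on_m else on_b
    shift <- (f - 1) * (tgt[k + 1L] - tgt[k])
    tgt[(k + 1L):npp] <- tgt[(k + 1L):npp] + shift
    if (who == "melody") on_m <- tgt else on_b <- tgt
    inj$outlier <- TRUE
    inj$outlier_at <- list(player = who, interval = k, factor = f)
  }

  if (u[1L] < params$p_wrong_note) {
    pos <- sample.int(2L * npp, 1L)
    who <- if (stats::runif(1) < 0.5) "melody" else "bass"
    step <- sample(c(-1L, 1L), 1L)
    inj$wrong_note <- TRUE
    inj$wrong_note_at <- list(player = who, note = pos, step = step)
  }

  list(onset_melody = on_m, onset_bass = on_b, injections = inj)
}

# assemble the long event table for one trial from simulated onsets
.trial_events <- function(sim, score, pair_id, session, trial_id, npp) {
  pitches_m <- score$melody_pitches
  pitches_b <- score$bass_pitches
  wn <- sim$injections$wrong_note_at
  if (!is.null(wn)) {
    if (wn$player == "melody") {
      pitches_m[wn$note] <- pitches_m[wn$note] + wn$step
    } else {
      pitches_b[wn$note] <- pitches_b[wn$note] + wn$step
    }
  }
  n <- 2L * npp
  phrase <- rep(rep(1:2, each = npp), 2L)
  position <- rep(rep(seq_len(npp), 2L), 2L)
  data.frame(
    pair_id = pair_id, session = session, trial_id = trial_id,
    player_role = rep(c("melody", "bass"), each = n),
    phrase = phrase, position = position,
    pitch = c(pitches_m, pitches_b),
    onset_ms = round(c(sim$onset_melody, sim$onset_bass), 3),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single duet trial
#'
#' Generates both players' keystrokes for one trial of the paradigm from
#' the coupled linear phase-correction model (see [dyad_params()] and the
#' package vignette for the generative equations). The current RNG state
#' is consumed; seed it (`set.seed()`) for reproducibility.
#'
#' @param params A [dyad_params()].
#' @param design A [design_spec()].
#' @param trial_meta A one-row data frame (or list) with at least
#'   `pair_id`, `session`, `trial_id`, `piece_id`, `familiarity`
#'   (`"F"`/`"U"`), `cue_melody` and `cue_bass` (`"up"`/`"down"`).
#' @return An event table (one row per keystroke) with columns `pair_id`,
#'   `session`, `trial_id`, `player_role`, `phrase`, `position`, `pitch`,
#'   `onset_ms`, and an `"injections"` attribute logging any injected
#'   wrong note, wrong tempo or outlier interval.
#' @export
simulate_trial <- function(params, design, trial_meta) {
  stopifnot(inherits(params, "dyad_params"), inherits(design, "design_spec"))
  tm <- as.list(trial_meta)
  if (!tm$familiarity %in% c("F", "U"))
    stop(sprintf("invalid familiarity label '%s' (must be 'F' or 'U')",
                 tm$familiarity), call. = FALSE)
  for (cue in c(tm$cue_melody, tm$cue_bass))
    if (!cue %in% c("up", "down"))
      stop(sprintf("invalid cue label '%s' (must be 'up' or 'down')", cue),
           call. = FALSE)
  score <- design$pieces[[as.character(tm$piece_id)]]
  if (is.null(score))
    stop(sprintf("no score for piece '%s'", tm$piece_id), call. = FALSE)
  sim <- .sim_trial_onsets(params, design, tm$familiarity,
                           tm$cue_melody, tm$cue_bass)
  ev <- .trial_events(sim, score, tm$pair_id, tm$session, tm$trial_id,
                      design$notes_per_phrase)
  attr(ev, "injections") <- sim$injections
  ev
}

# derived per-trial seed substream; doubles stay exact (< 2^53)
.trial_seed <- function(seed, counter) {
  as.integer((abs(seed) * 69069 + counter * 104729) %% 2147483646) + 1L
}

#' Simulate a complete factorial duet dataset
#'
#' Builds the full 2 (FAMILIARITY) x 2 (TEMPO congruency) within-dyad
#' design for `design$n_pairs` pairs -- two sessions per pair with fixed
#' player roles, conditions and instruction types balanced within session,
#' familiar/unfamiliar pieces cycled -- and simulates every trial.
#'
#' Each trial draws from its own RNG substream derived from
#' `params$seed` and the trial counter, so realizations do not depend on
#' trial order and the output is byte-identical across runs with the same
#' seed.
#'
#' @param params A [dyad_params()].
#' @param design A [design_spec()].
#' @return A list with `events` (keystroke table, see [simulate_trial()]),
#'   `meta` (one row per trial with design labels and derived condition
#'   columns, see [derive_condition()]), and `injections` (per-trial
#'   injection log with columns `trial_id`, `wrong_note`, `mistempo`,
#'   `mistempo_player`, `outlier`).
#' @export
#' @examples
#' d <- simulate_dataset(dyad_params(seed = 1),
#'                       design_spec(n_pairs = 2, trials_per_condition = 4))
#' nrow(d$meta)  # 2 pairs x 4 conditions x 4 trials = 32
simulate_dataset <- function(params = dyad_params(),
                             design = design_spec()) {
  stopifnot(inherits(params, "dyad_params"), inherits(design, "design_spec"))
  meta <- .build_meta(design)
  npp <- design$notes_per_phrase
  nn <- 2L * npp
  n_trials <- nrow(meta)

  pm <- vapply(design$pieces, `[[`, integer(nn), "melody_pitches")
  pb <- vapply(design$pieces, `[[`, integer(nn), "bass_pitches")
  piece_col <- match(as.character(meta$piece_id), colnames(pm))
  pitch_m <- t(pm[, piece_col, drop = FALSE])
  pitch_b <- t(pb[, piece_col, drop = FALSE])

  # pre-draw every trial's noise block from its own substream, run the
  # coupled recursion vectorized over trials, then replay the few trials
  # with triggered injections through the scalar path (identical RNG
  # consumption, so both paths agree exactly)
  ni <- npp - 1L
  zlen <- 6L + 4L * ni
  Z <- matrix(NA_real_, n_trials, zlen)
  U <- matrix(NA_real_, n_trials, 3L)
  for (i in seq_len(n_trials)) {
    set.seed(.trial_seed(params$seed, i))
    Z[i, ] <- stats::rnorm(zlen)
    U[i, ] <- stats::runif(3L)
  }

  tau <- .beat_ms(design$base_tempo_bpm)
  t1_nom <- design$cue_ms + design$metronome_beats * tau
  p2_nom <- t1_nom + 2 * (npp + 1L) * tau
  sig_int <- sqrt(params$sigma_timekeeper^2 + params$sigma_motor^2)
  fam <- meta$familiarity == "F"
  congr <- meta$cue_melody == meta$cue_bass
  tau_star_m <- ifelse(meta$cue_melody == "up", .beat_ms(design$fast_bpm),
                       .beat_ms(design$slow_bpm))
  tau_star_b <- ifelse(meta$cue_bass == "up", .beat_ms(design$fast_bpm),
                       .beat_ms(design$slow_bpm))
  a_m <- ifelse(fam & !congr,
                params$alpha_melody * (1 - params$lambda_seg),
                params$alpha_melody)
  a_b <- params$alpha_bass
  delta_m <- Z[, 1L] * params$sigma_fam * fam
  delta_b <- Z[, 2L] * params$sigma_fam * fam

  on_m <- matrix(NA_real_, n_trials, nn)
  on_b <- matrix(NA_real_, n_trials, nn)
  on_m[, 1L] <- t1_nom + Z[, 3L] * params$sigma_start
  on_b[, 1L] <- t1_nom + Z[, 4L] * params$sigma_start
  for (n in seq_len(ni)) {
    drift <- params$kappa * (n / npp)
    T_m <- tau + drift * (tau_star_m - tau) + delta_m
    T_b <- tau + drift * (tau_star_b - tau) + delta_b
    async <- on_m[, n] - on_b[, n]
    on_m[, n + 1L] <- on_m[, n] + T_m - a_m * async +
      Z[, 6L + n] * sig_int
    on_b[, n + 1L] <- on_b[, n] + T_b + a_b * async +
      Z[, 6L + ni + n] * sig_int
  }
  on_m[, npp + 1L] <- p2_nom + Z[, 5L] * params$sigma_start
  on_b[, npp + 1L] <- p2_nom + Z[, 6L] * params$sigma_start
  e2m <- Z[, 6L + 2L * ni + seq_len(ni), drop = FALSE] * sig_int
  e2b <- Z[, 6L + 3L * ni + seq_len(ni), drop = FALSE] * sig_int
  on_m[, (npp + 2L):nn] <- on_m[, npp + 1L] +
    t(apply(tau_star_m + e2m, 1L, cumsum))
  on_b[, (npp + 2L):nn] <- on_b[, npp + 1L] +
    t(apply(tau_star_b + e2b, 1L, cumsum))

  inj <- data.frame(trial_id = meta$trial_id, wrong_note = FALSE,
                    mistempo = FALSE, mistempo_player = NA_character_,
                    outlier = FALSE, stringsAsFactors = FALSE)
  hit <- which(U[, 1L] < params$p_wrong_note |
                 U[, 2L] < params$p_mistempo |
                 U[, 3L] < params$p_outlier)
  for (i in hit) {
    set.seed(.trial_seed(params$seed, i))
    sim <- .sim_trial_onsets(params, design, meta$familiarity[i],
                             meta$cue_melody[i], meta$cue_bass[i])
    on_m[i, ] <- sim$onset_melody
    on_b[i, ] <- sim$onset_bass
    ji <- sim$injections
    inj$wrong_note[i] <- ji$wrong_note
    inj$mistempo[i] <- ji$mistempo
    if (ji$mistempo) inj$mistempo_player[i] <- ji$mistempo_player
    inj$outlier[i] <- ji$outlier
    if (ji$wrong_note) {
      wn <- ji$wrong_note_at
      if (wn$player == "melody") {
        pitch_m[i, wn$note] <- pitch_m[i, wn$note] + wn$step
      } else {
        pitch_b[i, wn$note] <- pitch_b[i, wn$note] + wn$step
      }
    }
  }

  events <- data.frame(
    pair_id = rep(meta$pair_id, each = 2L * nn),
    session = rep(meta$session, each = 2L * nn),
    trial_id = rep(meta$trial_id, each = 2L * nn),
    player_role = rep(rep(c("melody", "bass"), each = nn), n_trials),
    phrase = rep(rep(rep(1:2, each = npp), 2L), n_trials),
    position = rep(rep(rep(seq_len(npp), 2L), 2L), n_trials),
    pitch = as.vector(t(cbind(pitch_m, pitch_b))),
    onset_ms = round(as.vector(t(cbind(on_m, on_b))), 3),
    stringsAsFactors = FALSE)
  list(events = events, meta = meta, injections = inj)
}

# Balanced trial schedule: per pair and session, every condition gets
# trials_per_condition / 2 trials; instruction types (UU/DD for congruent,
# UD/DU for incongruent) alternate within condition; familiar and
# unfamiliar pieces are cycled among those allotted to the session.
.build_meta <- function(design) {
  tpc_sess <- design$trials_per_condition %/% 2L
  piece_ids <- vapply(design$pieces, function(s) as.character(s$piece_id),
                      "")
  half <- ceiling(length(piece_ids) / 2)
  sess_pieces <- list(piece_ids[seq_len(half)],
                      piece_ids[seq.int(half + 1L, length(piece_ids))])

  g <- expand.grid(k = seq_len(tpc_sess), congruency = c("C", "I"),
                   familiarity = c("F", "U"), session = 1:2,
                   pair_id = seq_len(design$n_pairs),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alt <- (g$k - 1L) %% 2L  # alternate instruction type within condition
  cue_melody <- ifelse(g$congruency == "C",
                       ifelse(alt == 0L, "up", "down"),
                       ifelse(alt == 0L, "up", "down"))
  cue_bass <- ifelse(g$congruency == "C", cue_melody,
                     ifelse(cue_melody == "up", "down", "up"))

  piece_id <- character(nrow(g))
  for (s in 1:2) {
    pieces <- sess_pieces[[s]]
    fam_pieces <- pieces[seq_along(pieces) %% 2L == 1L]
    unf_pieces <- pieces[seq_along(pieces) %% 2L == 0L]
    for (fam in c("F", "U")) {
      pool <- if (fam == "F") fam_pieces else unf_pieces
      sel <- g$session == s & g$familiarity == fam
      # cycle pieces in blocks of two trials so every piece meets both
      # instruction types of each condition (instruction alternates per
      # trial; a shared period would confound piece with instruction and
      # let per-piece mean-centering absorb the anticipation drift)
      piece_id[sel] <- pool[1L + ((g$k[sel] - 1L) %/% 2L) %% length(pool)]
    }
  }

  meta <- data.frame(
    pair_id = g$pair_id, session = g$session,
    trial_id = seq_len(nrow(g)), piece_id = piece_id,
    familiarity = g$familiarity, cue_melody = cue_melody,
    cue_bass = cue_bass, stringsAsFactors = FALSE)
  # order trials by pair/session as scheduled
  meta <- meta[order(meta$pair_id, meta$session, meta$trial_id), ]
  meta$trial_id <- seq_len(nrow(meta))
  rownames(meta) <- NULL
  derive_condition(meta)
}
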