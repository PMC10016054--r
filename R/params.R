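#' Generative parameters of the coupled-timekeeper duet simulator
#'
#' Bundles and validates the parameters of the two-player linear
#' phase-correction model used by [simulate_trial()] and
#' [simulate_dataset()]. Each player produces intervals from an internal
#' timekeeper and corrects a fraction (the gain `alpha`) of the current
#' interpersonal asynchrony on every keystroke.
#'
#' Defaults are calibrated so that a full factorial dataset lands in the
#' vicinity of expert duet performance: mean absolute asynchronies of a few
#' milliseconds, within-trial asynchrony SDs around 19-20 ms, and roughly
#' 19-20 of 32 trials per condition surviving quality control.
#'
#' @param alpha_melody Phase-correction gain of the melody (MR) player,
#'   dimensionless, in `[0, 1)`.
#' @param alpha_bass Phase-correction gain of the accompanying (bass)
#'   player, in `[0, 1)`.
#' @param lambda_seg Multiplicative reduction of `alpha_melody` applied only
#'   in familiar-incongruent trials (self-other segregation), in `[0, 1]`.
#' @param kappa Anticipation-drift gain toward the cued second-phrase tempo
#'   during phrase 1, dimensionless, >= 0.
#' @param sigma_timekeeper SD of per-interval central timekeeper noise, ms.
#' @param sigma_motor SD of per-keystroke motor implementation noise, ms.
#'   Folded with `sigma_timekeeper` into one Gaussian increment per
#'   interval.
#' @param sigma_fam SD of the per-trial, per-player tempo-signature offset
#'   applied only in familiar trials, ms.
#' @param sigma_start SD of first-keystroke onset jitter, ms.
#' @param p_wrong_note,p_mistempo,p_outlier Per-trial injection
#'   probabilities for a wrong-pitch keystroke, a wrong second-phrase
#'   tempo, and an outlier phrase-1 interval, each in `[0, 1]`.
#' @param seed Integer root RNG seed; per-trial substreams are derived from
#'   it by counter so that trial order does not change realizations.
#'
#' @return An object of class `dyad_params` (a validated named list).
#' @seealso [design_spec()], [simulate_dataset()]
#' @export
#' @examples
#' p <- dyad_params(seed = 42)
#' p$alpha_bass
dyad_params <- function(alpha_melody = 0.15,
                        alpha_bass = 0.30,
                        lambda_seg = 0.5,
                        kappa = 0.04,
                        sigma_timekeeper = 10,
                        sigma_motor = 8,
                        sigma_fam = 6,
                        sigma_start = 15,
                        p_wrong_note = 0.05,
                        p_mistempo = 0.03,
                        p_outlier = 0.01,
                        seed = 1L) {
  chk_unit <- function(x, nm, closed_hi = FALSE) {
    hi_ok <- if (closed_hi) x <= 1 else x < 1
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok)
      stop(sprintf("`%s` must be a single value in [0, 1%s)",
                   nm, if (closed_hi) "]" else ""), call. = FALSE)
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
  }
  chk_unit(alpha_melody, "alpha_melody")
  chk_unit(alpha_bass, "alpha_bass")
  chk_unit(lambda_seg, "lambda_seg", closed_hi = TRUE)
  chk_nonneg(kappa, "kappa")
  chk_nonneg(sigma_timekeeper, "sigma_timekeeper")
  chk_nonneg(sigma_motor, "sigma_motor")
  chk_nonneg(sigma_fam, "sigma_fam")
  chk_nonneg(sigma_start, "sigma_start")
  chk_unit(p_wrong_note, "p_wrong_note", closed_hi = TRUE)
  chk_unit(p_mistempo, "p_mistempo", closed_hi = TRUE)
  chk_unit(p_outlier, "p_outlier", closed_hi = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)

  structure(list(
    alpha_melody = alpha_melody, alpha_bass = alpha_bass,
    lambda_seg = lambda_seg, kappa = kappa,
    sigma_timekeeper = sigma_timekeeper, sigma_motor = sigma_motor,
    sigma_fam = sigma_fam, sigma_start = sigma_start,
    p_wrong_note = p_wrong_note, p_mistempo = p_mistempo,
    p_outlier = p_outlier, seed = as.integer(seed)
  ), class = "dyad_params")
}

#' Score of one duet piece
#'
#' A two-voice piece of two phrases, seven quarter notes per hand per
#' phrase (positions 1-7 are phrase 1, 8-14 phrase 2), as played in a
#' single trial.
#'
#' @param piece_id Integer or character piece identifier.
#' @param melody_pitches,bass_pitches MIDI note numbers (0-127), exactly 14
#'   values each.
#' @return An object of class `score_spec`.
#' @export
score_spec <- function(piece_id, melody_pitches, bass_pitches) {
  for (v in list(melody = melody_pitches, bass = bass_pitches)) {
    if (length(v) != 14L || any(v != round(v)) || any(v < 0 | v > 127))
      stop("each hand needs exactly 14 MIDI pitches in 0..127",
           call. = FALSE)
  }
  structure(list(piece_id = piece_id,
                 melody_pitches = as.integer(melody_pitches),
                 bass_pitches = as.integer(bass_pitches)),
            class = "score_spec")
}

#' Default set of eight synthetic two-voice pieces
#'
#' Deterministic stand-ins for the eight chorale excerpts of the paradigm:
#' diatonic (C major) stepwise lines, melody in the right-hand register,
#' bassline an octave and a half below. Pieces differ by starting degree so
#' wrong-note checks are piece-specific.
#'
#' @param n_pieces Number of pieces (default 8).
#' @return A list of [score_spec()] objects named by piece id.
#' @export
default_scores <- function(n_pieces = 8L) {
  cmaj <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  deg <- function(start, steps) {
    idx <- (start + cumsum(c(0L, steps))) # scale degrees, 0-based
    12L * (idx %/% 7L) + cmaj[idx %% 7L + 1L]
  }
  steps <- list(c(1, 1, -1, 1, 1, 1), c(-1, 1, 1, -1, -1, 1))
  out <- lapply(seq_len(n_pieces), function(k) {
    mel1 <- 60L + deg(k %% 7L, steps[[1L + k %% 2L]])
    mel2 <- 60L + deg((k + 2L) %% 7L, steps[[1L + (k + 1L) %% 2L]])
    bas1 <- 43L + deg((k + 4L) %% 7L, rev(steps[[1L + k %% 2L]]))
    bas2 <- 43L + deg((k + 1L) %% 7L, rev(steps[[1L + (k + 1L) %% 2L]]))
    score_spec(k, c(mel1, mel2), c(bas1, bas2))
  })
  names(out) <- vapply(out, function(s) as.character(s$piece_id), "")
  out
}

#' Factorial design of a duet experiment
#'
#' Describes the 2 (FAMILIARITY: familiar/unfamiliar) x 2 (TEMPO:
#' congruent/incongruent) within-dyad design: each pair plays
#' `4 * trials_per_condition` trials split over two sessions with fixed
#' player roles per session. Timing constants follow the paradigm: a
#' 1,000 ms visual tempo cue, four metronome beats at the 120 bpm base
#' tempo, a 7-note first phrase plus quarter pause, a 2-bar silent pause,
#' and a second phrase at the cued tempo (150 bpm fast / 96 bpm slow).
#'
#' @param n_pairs Number of dyads.
#' @param trials_per_condition Trials per condition per pair (paradigm
#'   default 32, i.e. 128 trials per pair). Must be even so that the two
#'   instruction types of each condition can be balanced.
#' @param pieces List of [score_spec()] objects; at least 4 (they are
#'   cycled over sessions, half familiar and half unfamiliar).
#' @param base_tempo_bpm,fast_bpm,slow_bpm Tempi of phrase 1 and of the
#'   cued second-phrase variants, beats per minute.
#' @param notes_per_phrase Notes per hand per phrase (7; each phrase spans
#'   `notes_per_phrase + 1` beats including the closing quarter pause).
#' @param cue_ms Visual cue duration, ms.
#' @param metronome_beats Count-in metronome beats at the base tempo.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_pairs = 20L,
                        trials_per_condition = 32L,
                        pieces = default_scores(),
                        base_tempo_bpm = 120,
                        fast_bpm = 150,
                        slow_bpm = 96,
                        notes_per_phrase = 7L,
                        cue_ms = 1000,
                        metronome_beats = 4L) {
  if (n_pairs < 1L) stop("`n_pairs` must be >= 1", call. = FALSE)
  if (trials_per_condition < 1L || trials_per_condition %% 2L != 0L)
    stop("`trials_per_condition` must be a positive even number ",
         "(instruction types are balanced within condition)", call. = FALSE)
  if (length(pieces) < 4L)
    stop("need at least 4 pieces (2 familiar + 2 unfamiliar per session)",
         call. = FALSE)
  stopifnot(all(vapply(pieces, inherits, TRUE, "score_spec")))
  structure(list(
    n_pairs = as.integer(n_pairs),
    trials_per_condition = as.integer(trials_per_condition),
    pieces = pieces,
    base_tempo_bpm = base_tempo_bpm, fast_bpm = fast_bpm,
    slow_bpm = slow_bpm,
    notes_per_phrase = as.integer(notes_per_phrase),
    cue_ms = cue_ms, metronome_beats = as.integer(metronome_beats)
  ), class = "design_spec")
}

# beat duration in ms at a given bpm
.beat_ms <- function(bpm) 60000 / bpm
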