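#' @name event_csv
#' @title Keystroke event and trial metadata CSV dialects
#'
#' @description
#' Event tables are stored one row per keystroke with the fixed column
#' order `pair_id, session, trial_id, player_role, phrase, position,
#' pitch, onset_ms` (UTF-8, comma-separated, mandatory header). Onsets are
#' milliseconds from trial onset, written with 0.001 ms precision so a
#' write/read round trip is exact. Trial metadata tables hold one row per
#' trial: `pair_id, session, trial_id, piece_id, familiarity, cue_melody,
#' cue_bass, congruency, condition, instruction_type` (the last three are
#' derived, see [derive_condition()]).
NULL

.EVENT_COLS <- c("pair_id", "session", "trial_id", "player_role",
                 "phrase", "position", "pitch", "onset_ms")
.META_COLS <- c("pair_id", "session", "trial_id", "piece_id",
                "familiarity", "cue_melody", "cue_bass",
                "congruency", "condition", "instruction_type")

#' Write / read keystroke event tables
#'
#' @param events Event table as produced by [simulate_dataset()] or
#'   [read_events()].
#' @param path CSV file path.
#' @param validate Run [validate_events()] after reading (default `TRUE`).
#' @return `read_events()` returns the event table; `write_events()`
#'   returns `path` invisibly.
#' @seealso [event_csv] for the dialect
#' @export
write_events <- function(events, path) {
  stopifnot(all(.EVENT_COLS %in% names(events)))
  out <- events[, .EVENT_COLS]
  out$onset_ms <- sprintf("%.3f", out$onset_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.EVENT_COLS, names(ev))
  if (length(missing))
    stop("event file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ev <- ev[, .EVENT_COLS]
  ev$onset_ms <- round(as.numeric(ev$onset_ms), 3)
  if (validate) validate_events(ev)
  ev
}

#' Validate a keystroke event table
#'
#' Enforces the structural invariants of the event dialect: no duplicate
#' `(trial, player, phrase, position)`, strictly increasing onsets within
#' `(trial, player, phrase)`, non-negative onsets, pitches in 0-127, and
#' dyadic completeness (melody events exist iff bass events exist for a
#' trial). Errors name the offending trial.
#'
#' @param events Event table.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events) {
  missing <- setdiff(.EVENT_COLS, names(events))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(events$onset_ms < 0))
    stop("negative onset in trial ",
         events$trial_id[which(events$onset_ms < 0)[1L]], call. = FALSE)
  if (any(events$pitch < 0 | events$pitch > 127))
    stop("pitch out of MIDI range in trial ",
         events$trial_id[which(events$pitch < 0 | events$pitch > 127)[1L]],
         call. = FALSE)
  if (!all(events$player_role %in% c("melody", "bass")))
    stop("player_role must be 'melody' or 'bass'", call. = FALSE)
  if (!all(events$phrase %in% 1:2))
    stop("phrase must be 1 or 2", call. = FALSE)

  key <- paste(events$trial_id, events$player_role, events$phrase,
               events$position, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (trial, player, phrase, position) in trial ",
         events$trial_id[which(dup)[1L]], call. = FALSE)

  o <- order(events$trial_id, events$player_role, events$phrase,
             events$position)
  ev <- events[o, ]
  grp <- paste(ev$trial_id, ev$player_role, ev$phrase, sep = "\r")
  same <- grp[-1L] == grp[-length(grp)]
  nonmono <- same & diff(ev$onset_ms) <= 0
  if (any(nonmono))
    stop("non-monotone onsets within trial ",
         ev$trial_id[which(nonmono)[1L] + 1L], call. = FALSE)

  roles <- unique(events[, c("trial_id", "player_role")])
  counts <- table(roles$trial_id)
  if (any(counts != 2L))
    stop("trial ", names(counts)[which(counts != 2L)[1L]],
         " lacks one player's events (dyadic completeness)",
         call. = FALSE)
  invisible(events)
}

#' Write / read trial metadata tables
#'
#' @param meta Trial metadata table (derived condition columns are added
#'   if absent).
#' @param path CSV file path.
#' @return `read_trial_meta()` returns the metadata table with derived
#'   columns; `write_trial_meta()` returns `path` invisibly.
#' @export
write_trial_meta <- function(meta, path) {
  if (!all(.META_COLS %in% names(meta))) meta <- derive_condition(meta)
  utils::write.csv(meta[, .META_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_meta
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(piece_id = "character"))
  derive_condition(meta)
}

#' Derive condition labels from cues and familiarity
#'
#' Congruency is `"C"` when both players received the same second-phrase
#' tempo cue and `"I"` otherwise; condition is the familiarity x
#' congruency cell (`FC`, `FI`, `UC`, `UI`); instruction type is the cue
#' pair (`UU`, `DD`, `UD`, `DU`, melody cue first).
#'
#' @param meta Trial metadata with columns `familiarity`, `cue_melody`,
#'   `cue_bass`.
#' @return `meta` with (re)derived `congruency`, `condition` and
#'   `instruction_type` columns.
#' @export
#' @examples
#' derive_condition(data.frame(familiarity = "F", cue_melody = "up",
#'                             cue_bass = "up"))$condition  # "FC"
derive_condition <- function(meta) {
  stopifnot(all(c("familiarity", "cue_melody", "cue_bass") %in%
                  names(meta)))
  if (!all(meta$familiarity %in% c("F", "U")))
    stop("unknown familiarity label (must be 'F' or 'U')", call. = FALSE)
  if (!all(meta$cue_melody %in% c("up", "down")) ||
      !all(meta$cue_bass %in% c("up", "down")))
    stop("unknown cue label (must be 'up' or 'down')", call. = FALSE)
  meta$congruency <- ifelse(meta$cue_melody == meta$cue_bass, "C", "I")
  meta$condition <- paste0(meta$familiarity, meta$congruency)
  code <- function(x) ifelse(x == "up", "U", "D")
  meta$instruction_type <- paste0(code(meta$cue_melody),
                                  code(meta$cue_bass))
  meta
}

# participant = the MR pianist of a session (pianist A in session 1,
# B in session 2); behavioral unit of analysis
.participant_id <- function(pair_id, session) {
  sprintf("pair%02d_%s", pair_id, c("A", "B")[session])
}
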