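# Minimal Standard MIDI File (format 0/1) support: enough to exchange
# two-channel keystroke recordings. Only note-on/note-off and set-tempo
# events are interpreted; everything else is skipped. Ticks are mapped to
# milliseconds through the file's tempo map (piecewise constant
# microseconds per quarter note).

.midi_vlq <- function(x) {
  # encode a non-negative integer as a MIDI variable-length quantity
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

.u32 <- function(x) as.raw(c(x %/% 16777216L, x %/% 65536L %% 256L,
                             x %/% 256L %% 256L, x %% 256L))
.u16 <- function(x) as.raw(c(x %/% 256L, x %% 256L))

#' Write one trial's keystrokes as a Standard MIDI File
#'
#' Emits a format-0 file with the melody on channel 0 and the bass on
#' channel 1, a set-tempo event fixing the base tempo, and a fixed note
#' duration of 100 ms. Intended for export and for constructing MIDI
#' fixtures; onsets are quantized to the tick grid (480 ticks per quarter
#' note, about 1 ms at 120 bpm).
#'
#' @param events Event table rows of a single trial.
#' @param path Output file path.
#' @param tempo_bpm Tempo of the tick grid (default 120).
#' @param ppq Ticks per quarter note (default 480).
#' @return `path`, invisibly.
#' @export
write_midi_events <- function(events, path, tempo_bpm = 120, ppq = 480L) {
  if (length(unique(events$trial_id)) != 1L)
    stop("write_midi_events() takes events of exactly one trial",
         call. = FALSE)
  us_per_qn <- round(60e6 / tempo_bpm)
  ms_per_tick <- us_per_qn / (ppq * 1000)
  chan <- ifelse(events$player_role == "melody", 0L, 1L)
  on_tick <- round(events$onset_ms / ms_per_tick)
  off_tick <- round((events$onset_ms + 100) / ms_per_tick)

  ev <- data.frame(tick = c(on_tick, off_tick),
                   status = c(0x90L + chan, 0x80L + chan),
                   pitch = rep(events$pitch, 2L),
                   vel = rep(c(64L, 0L), each = nrow(events)))
  ev <- ev[order(ev$tick, ev$status), ]

  track <- as.raw(c(0x00, 0xFF, 0x51, 0x03,
                    us_per_qn %/% 65536L, us_per_qn %/% 256L %% 256L,
                    us_per_qn %% 256L))
  last <- 0
  for (i in seq_len(nrow(ev))) {
    track <- c(track, .midi_vlq(ev$tick[i] - last),
               as.raw(c(ev$status[i], ev$pitch[i], ev$vel[i])))
    last <- ev$tick[i]
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .u32(6L), .u16(0L), .u16(1L), .u16(ppq),
             charToRaw("MTrk"), .u32(length(track)), track), con)
  invisible(path)
}

# decode all note-on and set-tempo events of one track chunk
.parse_track <- function(raw, ppq) {
  pos <- 1L
  n <- length(raw)
  read_vlq <- function() {
    val <- 0
    repeat {
      b <- as.integer(raw[pos]); pos <<- pos + 1L
      val <- val * 128 + b %% 128L
      if (b < 128L) return(val)
    }
  }
  tick <- 0
  running <- NA_integer_
  notes <- list(); tempos <- list()
  while (pos <= n) {
    tick <- tick + read_vlq()
    b <- as.integer(raw[pos])
    if (b >= 0x80L) { running <- b; pos <- pos + 1L } else b <- running
    hi <- b %/% 16L
    if (b == 0xFFL) {                      # meta event
      type <- as.integer(raw[pos]); pos <- pos + 1L
      len <- read_vlq()
      if (type == 0x51L) {
        d <- as.integer(raw[pos + 0:2])
        tempos[[length(tempos) + 1L]] <-
          c(tick, d[1L] * 65536 + d[2L] * 256 + d[3L])
      }
      pos <- pos + len
      if (type == 0x2FL) break             # end of track
    } else if (b %in% c(0xF0L, 0xF7L)) {   # sysex: skip
      len <- read_vlq(); pos <- pos + len
    } else if (hi %in% c(0x8L, 0x9L, 0xAL, 0xBL, 0xEL)) {
      d1 <- as.integer(raw[pos]); d2 <- as.integer(raw[pos + 1L])
      pos <- pos + 2L
      if (hi == 0x9L && d2 > 0L)
        notes[[length(notes) + 1L]] <- c(tick, b %% 16L, d1)
    } else if (hi %in% c(0xCL, 0xDL)) {    # 1-byte channel messages
      pos <- pos + 1L
    } else {
      stop("unsupported MIDI event byte: ", b, call. = FALSE)
    }
  }
  list(notes = notes, tempos = tempos)
}

#' Read keystrokes from a Standard MIDI File
#'
#' Parses a format 0 or 1 file, converts note-on ticks to milliseconds via
#' the file's tempo map (default 120 bpm where no set-tempo event
#' precedes), and assembles an event table: per channel, note-ons are
#' ordered by time and assigned phrase 1 / phrase 2 positions in blocks of
#' `notes_per_phrase`.
#'
#' @param path MIDI file path.
#' @param pair_id,session,trial_id Identifiers stamped onto the resulting
#'   rows (a MIDI file carries none).
#' @param channel_roles Named character vector mapping MIDI channel
#'   numbers (as names) to player roles.
#' @param notes_per_phrase Notes per hand per phrase (default 7).
#' @return An event table (see [event_csv]).
#' @export
read_midi_events <- function(path, pair_id = 1L, session = 1L,
                             trial_id = 1L,
                             channel_roles = c(`0` = "melody",
                                               `1` = "bass"),
                             notes_per_phrase = 7L) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:4]), "MThd"))
    stop("not a Standard MIDI File (missing MThd)", call. = FALSE)
  u16 <- function(i) as.integer(raw[i]) * 256L + as.integer(raw[i + 1L])
  u32 <- function(i) ((as.integer(raw[i]) * 256L + as.integer(raw[i + 1L])) *
                        256L + as.integer(raw[i + 2L])) * 256L +
    as.integer(raw[i + 3L])
  format <- u16(9L)
  ntrks <- u16(11L)
  ppq <- u16(13L)
  if (format > 1L)
    stop("only MIDI formats 0 and 1 are supported", call. = FALSE)
  if (ppq >= 32768L)
    stop("SMPTE time division is not supported", call. = FALSE)

  pos <- 15L
  notes <- list(); tempos <- list()
  for (k in seq_len(ntrks)) {
    if (!identical(rawToChar(raw[pos + 0:3]), "MTrk"))
      stop("malformed track chunk", call. = FALSE)
    len <- u32(pos + 4L)
    parsed <- .parse_track(raw[(pos + 8L):(pos + 7L + len)], ppq)
    notes <- c(notes, parsed$notes)
    tempos <- c(tempos, parsed$tempos)
    pos <- pos + 8L + len
  }
  if (!length(notes)) stop("no note-on events found", call. = FALSE)

  nm <- do.call(rbind, notes)   # tick, channel, pitch
  tm <- if (length(tempos)) do.call(rbind, tempos) else
    matrix(numeric(0), ncol = 2)
  # tempo map: piecewise constant us/qn, default 500000 before first event
  tm <- tm[order(tm[, 1L]), , drop = FALSE]
  seg_ticks <- c(0, tm[, 1L])
  seg_tempo <- c(500000, if (nrow(tm)) tm[, 2L])
  keep <- !duplicated(seg_ticks, fromLast = TRUE)
  seg_ticks <- seg_ticks[keep]; seg_tempo <- seg_tempo[keep]
  seg_ms_at <- cumsum(c(0, diff(seg_ticks) * utils::head(seg_tempo, -1) /
                          (ppq * 1000)))
  tick_to_ms <- function(t) {
    i <- findInterval(t, seg_ticks)
    seg_ms_at[i] + (t - seg_ticks[i]) * seg_tempo[i] / (ppq * 1000)
  }

  chans <- sort(unique(nm[, 2L]))
  rows <- lapply(chans, function(ch) {
    role <- unname(channel_roles[as.character(ch)])
    if (length(role) != 1L || is.na(role))
      stop("no role mapping for MIDI channel ", ch, call. = FALSE)
    sub <- nm[nm[, 2L] == ch, , drop = FALSE]
    sub <- sub[order(sub[, 1L]), , drop = FALSE]
    idx <- seq_len(nrow(sub)) - 1L
    data.frame(pair_id = pair_id, session = session, trial_id = trial_id,
               player_role = role,
               phrase = idx %/% notes_per_phrase + 1L,
               position = idx %% notes_per_phrase + 1L,
               pitch = sub[, 3L],
               onset_ms = round(tick_to_ms(sub[, 1L]), 3),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev
}
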