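# Trial quality control: wrong notes -> tempo goodness of fit ->
# (optional technical-error column) -> pooled IKI outlier trimming.

# Onset matrices of complete trials for one phrase: trials x npp onsets
# per role, trials with missing keystrokes dropped with a warning.
.onset_matrices <- function(events, phrase = 1L) {
  ph <- events$phrase == phrase
  tid <- events$trial_id[ph]
  mel <- events$player_role[ph] == "melody"
  pos <- events$position[ph]
  ons <- events$onset_ms[ph]
  pit <- events$pitch[ph]
  npp <- max(pos)

  o <- order(tid, !mel, pos)  # melody block first within each trial
  key <- tid[o] * 2L + !mel[o]
  r <- rle(key)
  run_tid <- r$values %/% 2L
  good <- r$lengths == npp
  ut <- unique(run_tid)
  # a trial is complete when both its role runs have exactly npp rows
  cnt <- rowsum(as.integer(good) + 1L, run_tid)  # 2 per good run
  complete_tid <- as.numeric(rownames(cnt))[cnt[, 1L] == 4L]
  if (length(complete_tid) < length(ut))
    warning(length(ut) - length(complete_tid),
            " trial(s) dropped: incomplete keystrokes in phrase ", phrase,
            call. = FALSE)
  keep <- rep(run_tid %in% complete_tid, r$lengths)
  ko <- o[keep]
  n_tr <- length(ko) %/% (2L * npp)
  # rows per trial: npp melody then npp bass
  sel_m <- rep(c(TRUE, FALSE), each = npp, times = n_tr)
  list(trial_id = tid[ko][seq(1L, length(ko), by = 2L * npp)], npp = npp,
       melody = matrix(ons[ko][sel_m], ncol = npp, byrow = TRUE),
       bass = matrix(ons[ko][!sel_m], ncol = npp, byrow = TRUE),
       pitch_melody = matrix(pit[ko][sel_m], ncol = npp, byrow = TRUE),
       pitch_bass = matrix(pit[ko][!sel_m], ncol = npp, byrow = TRUE))
}

# row-wise IKIs (diff along positions): trials x (npp - 1)
.iki_matrix <- function(onsets) {
  onsets[, -1L, drop = FALSE] - onsets[, -ncol(onsets), drop = FALSE]
}

#' Flag trials containing a wrong note
#'
#' A trial is flagged when any played pitch differs from the score pitch
#' at its position, for either player in either phrase.
#'
#' @param events Event table.
#' @param meta Trial metadata (maps trials to pieces).
#' @param scores List of [score_spec()] objects named by piece id.
#' @return Data frame with columns `trial_id` and `wrong_note`.
#' @export
flag_wrong_notes <- function(events, meta, scores = default_scores()) {
  piece <- meta$piece_id[match(events$trial_id, meta$trial_id)]
  if (anyNA(piece))
    stop("events reference trials absent from `meta`", call. = FALSE)
  missing <- setdiff(unique(as.character(piece)), names(scores))
  if (length(missing))
    stop("no score for piece(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  npp <- max(events$position)
  slot <- (events$phrase - 1L) * npp + events$position
  pm <- vapply(scores, `[[`, integer(2L * npp), "melody_pitches")
  pb <- vapply(scores, `[[`, integer(2L * npp), "bass_pitches")
  col <- match(as.character(piece), colnames(pm))
  expected <- ifelse(events$player_role == "melody",
                     pm[cbind(slot, col)], pb[cbind(slot, col)])
  bad <- events$pitch != expected
  agg <- rowsum(as.integer(bad), events$trial_id)
  data.frame(trial_id = as.integer(rownames(agg)),
             wrong_note = agg[, 1L] > 0L, row.names = NULL)
}

#' Classify a second-phrase tempo from its six IKIs
#'
#' Compares the played inter-keystroke intervals against constant
#' templates for the fast (400 ms), slow (625 ms) and unchanged (500 ms)
#' tempi by mean squared error and returns the best-fitting label. On an
#' exact MSE tie the instructed tempo wins if it is among the tied
#' minima (so only demonstrably better-fitting wrong tempi lead to
#' exclusion); otherwise ties resolve in template order.
#'
#' @param ikis_phase2 Numeric vector of exactly 6 positive intervals, ms.
#' @param instructed Optional instructed label used for tie-breaking.
#' @param templates Named template intervals, ms.
#' @return One of `names(templates)`.
#' @export
#' @examples
#' classify_tempo(rep(400, 6))  # "fast"
classify_tempo <- function(ikis_phase2, instructed = NULL,
                           templates = c(fast = 400, slow = 625,
                                         none = 500)) {
  if (length(ikis_phase2) != 6L || any(ikis_phase2 <= 0))
    stop("need exactly 6 positive second-phrase IKIs", call. = FALSE)
  mse <- vapply(templates, function(tpl) mean((ikis_phase2 - tpl)^2), 0)
  tied <- names(mse)[mse <= min(mse) + 1e-9]
  if (!is.null(instructed) && instructed %in% tied) instructed else tied[1L]
}

# vectorized variant over an IKI matrix; instructed is a label vector
.classify_tempo_rows <- function(iki, instructed,
                                 templates = c(fast = 400, slow = 625,
                                               none = 500)) {
  mse <- vapply(templates,
                function(tpl) rowMeans((iki - tpl)^2), numeric(nrow(iki)))
  if (nrow(iki) == 1L) mse <- matrix(mse, nrow = 1L,
                                     dimnames = list(NULL, names(templates)))
  is_min <- mse <= .row_mins(mse) + 1e-9
  out <- character(nrow(iki))
  instr_col <- match(instructed, colnames(mse))
  instr_ok <- is_min[cbind(seq_len(nrow(iki)), instr_col)]
  out[instr_ok] <- instructed[instr_ok]
  if (any(!instr_ok))
    out[!instr_ok] <- colnames(mse)[apply(is_min[!instr_ok, , drop = FALSE],
                                          1L, which.max)]
  out
}

# row minima without extra dependencies
.row_mins <- function(m) do.call(pmin, as.data.frame(m))

#' Flag trials with pooled first-phrase IKI outliers
#'
#' Pools the first-phrase IKIs of all supplied trials (both players, all
#' conditions), computes the `lower_pct` and `upper_pct` percentiles
#' (linear interpolation between order statistics, `quantile` type 7) and
#' flags any trial containing at least one IKI strictly outside the
#' bounds. Applied to QC survivors only; whole trials are removed, never
#' individual intervals. With fewer than 100 pooled IKIs the cut is
#' unreliable, so a warning is issued and nothing is flagged.
#'
#' @param events Event table (survivors of the earlier filters).
#' @param lower_pct,upper_pct Percentile cuts (default 1 and 99).
#' @param bounds Optional frozen `c(lower, upper)` bounds in ms,
#'   bypassing percentile estimation (used for idempotent re-runs).
#' @return List with `flags` (data frame `trial_id`, `iki_outlier`),
#'   `bounds`, and `n_pooled`.
#' @export
trim_iki_outliers <- function(events, lower_pct = 1, upper_pct = 99,
                              bounds = NULL) {
  om <- .onset_matrices(events, phrase = 1L)
  iki <- rbind(.iki_matrix(om$melody), .iki_matrix(om$bass))
  n_pooled <- length(iki)
  if (is.null(bounds)) {
    if (n_pooled < 100L) {
      warning("fewer than 100 pooled IKIs (", n_pooled,
              "); outlier filter skipped", call. = FALSE)
      return(list(flags = data.frame(trial_id = om$trial_id,
                                     iki_outlier = FALSE),
                  bounds = c(NA_real_, NA_real_), n_pooled = n_pooled))
    }
    bounds <- unname(stats::quantile(iki, c(lower_pct, upper_pct) / 100,
                                     type = 7))
  }
  out <- iki < bounds[1L] | iki > bounds[2L]
  n_tr <- nrow(om$melody)
  per_trial <- rowSums(out[seq_len(n_tr), , drop = FALSE]) +
    rowSums(out[n_tr + seq_len(n_tr), , drop = FALSE])
  list(flags = data.frame(trial_id = om$trial_id,
                          iki_outlier = per_trial > 0L),
       bounds = bounds, n_pooled = n_pooled)
}

#' Run the full trial exclusion pipeline
#'
#' Applies, in order: wrong-note exclusion, second-phrase tempo
#' goodness-of-fit exclusion (per player, MSE against the three tempo
#' templates), the optional technical-error column of `meta`, and pooled
#' first-phrase IKI outlier trimming on the survivors.
#'
#' @param events Event table.
#' @param meta Trial metadata.
#' @param scores List of [score_spec()] objects named by piece id.
#' @param iki_bounds Optional frozen outlier bounds (ms); when supplied
#'   the percentile estimation is skipped, making the pipeline idempotent
#'   on its own output.
#' @param lower_pct,upper_pct Outlier percentile cuts.
#' @return A `duet_qc` list: `events` (retained keystrokes), `trials`
#'   (per-trial flags and `retained`), `condition_counts` (retained trials
#'   per condition), `iki_bounds`, `n_pooled_ikis`.
#' @export
run_qc <- function(events, meta, scores = default_scores(),
                   iki_bounds = NULL, lower_pct = 1, upper_pct = 99) {
  wn <- flag_wrong_notes(events, meta, scores)

  om2 <- .onset_matrices(events, phrase = 2L)
  idx <- match(om2$trial_id, meta$trial_id)
  instr_m <- ifelse(meta$cue_melody[idx] == "up", "fast", "slow")
  instr_b <- ifelse(meta$cue_bass[idx] == "up", "fast", "slow")
  cls_m <- .classify_tempo_rows(.iki_matrix(om2$melody), instr_m)
  cls_b <- .classify_tempo_rows(.iki_matrix(om2$bass), instr_b)

  trials <- data.frame(trial_id = om2$trial_id, stringsAsFactors = FALSE)
  trials$wrong_note <- wn$wrong_note[match(trials$trial_id, wn$trial_id)]
  trials$mistempo_melody <- cls_m != instr_m
  trials$mistempo_bass <- cls_b != instr_b
  trials$technical_error <- if ("technical_error" %in% names(meta)) {
    isTRUE_v(meta$technical_error[match(trials$trial_id, meta$trial_id)])
  } else FALSE

  pre <- !(trials$wrong_note | trials$mistempo_melody |
             trials$mistempo_bass | trials$technical_error)
  surv_ev <- events[events$trial_id %in% trials$trial_id[pre], ]
  tio <- trim_iki_outliers(surv_ev, lower_pct, upper_pct,
                           bounds = iki_bounds)
  trials$iki_outlier <- FALSE
  hit <- match(tio$flags$trial_id, trials$trial_id)
  trials$iki_outlier[hit] <- tio$flags$iki_outlier
  trials$retained <- pre & !trials$iki_outlier

  keep <- trials$trial_id[trials$retained]
  cond <- meta$condition[match(keep, meta$trial_id)]
  counts <- as.data.frame(table(condition = factor(
    cond, levels = c("FC", "FI", "UC", "UI"))), stringsAsFactors = FALSE)
  names(counts)[2L] <- "retained"

  structure(list(events = events[events$trial_id %in% keep, ],
                 trials = trials, condition_counts = counts,
                 iki_bounds = tio$bounds,
                 n_pooled_ikis = tio$n_pooled),
            class = "duet_qc")
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' @export
print.duet_qc <- function(x, ...) {
  n <- nrow(x$trials)
  cat("Duet trial QC:", sum(x$trials$retained), "of", n,
      "trials retained\n")
  cat("  wrong note:", sum(x$trials$wrong_note),
      "| wrong tempo:", sum(x$trials$mistempo_melody |
                              x$trials$mistempo_bass),
      "| technical:", sum(x$trials$technical_error),
      "| IKI outlier:", sum(x$trials$iki_outlier), "\n")
  if (!anyNA(x$iki_bounds))
    cat(sprintf("  pooled IKI bounds: [%.1f, %.1f] ms (n = %d)\n",
                x$iki_bounds[1L], x$iki_bounds[2L], x$n_pooled_ikis))
  print(x$condition_counts, row.names = FALSE)
  invisible(x)
}
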