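# Synchronization accuracy, stability and adaptation metrics from
# retained first-phrase keystrokes.

#' Signed keystroke asynchronies per trial
#'
#' For every retained trial, the asynchrony at keystroke position n is
#' the melody (MR-pianist) onset minus the bass (accompanist) onset;
#' positive values mean the melody player struck later. Trials with
#' missing positions are skipped with a warning.
#'
#' @param events Event table.
#' @param phrase Phrase to analyze (default 1, where players hear each
#'   other).
#' @return Data frame `trial_id`, `position`, `asynchrony` (ms).
#' @export
compute_asynchronies <- function(events, phrase = 1L) {
  om <- .onset_matrices(events, phrase = phrase)
  a <- om$melody - om$bass
  data.frame(trial_id = rep(om$trial_id, each = om$npp),
             position = rep(seq_len(om$npp), length(om$trial_id)),
             asynchrony = as.vector(t(a)))
}

#' Mean-center asynchronies by piece and keystroke position
#'
#' Removes piece- and position-specific difficulty by subtracting, within
#' each centering cell, the mean asynchrony across all retained trials of
#' that cell (all instruction types pooled). The default scope forms
#' cells per participant-session x piece x position, which removes
#' nuisance structure without leaking information between dyads.
#'
#' @param asyn Output of [compute_asynchronies()].
#' @param meta Trial metadata (supplies pair, session and piece).
#' @param scope `"participant_session"` (default) or `"global"` (cells
#'   pooled across all sessions).
#' @return `asyn` with columns `centered` (centered asynchrony) and
#'   `single_trial_cell` (TRUE where a cell held only one trial, whose
#'   centered value is exactly 0).
#' @export
mean_center <- function(asyn, meta,
                        scope = c("participant_session", "global")) {
  scope <- match.arg(scope)
  idx <- match(asyn$trial_id, meta$trial_id)
  if (anyNA(idx))
    stop("asynchronies reference trials absent from `meta`", call. = FALSE)
  cell <- if (scope == "participant_session") {
    paste(meta$pair_id[idx], meta$session[idx], meta$piece_id[idx],
          asyn$position, sep = "\r")
  } else {
    paste(meta$piece_id[idx], asyn$position, sep = "\r")
  }
  f <- factor(cell)
  asyn$centered <- asyn$asynchrony - ave(asyn$asynchrony, f, FUN = mean)
  asyn$single_trial_cell <- ave(asyn$asynchrony, f,
                                FUN = length) == 1
  asyn
}

# long asynchrony frame -> trials x npp matrix plus aligned meta index
.asyn_matrix <- function(asyn) {
  o <- order(asyn$trial_id, asyn$position)
  a <- asyn[o, ]
  npp <- max(a$position)
  list(trial_id = a$trial_id[seq(1L, nrow(a), by = npp)],
       m = matrix(a[[if ("centered" %in% names(a)) "centered" else
         "asynchrony"]], ncol = npp, byrow = TRUE))
}

#' Synchronization accuracy per participant and condition
#'
#' Signed (centered) asynchronies are averaged over keystrokes 1-7 and
#' all retained trials separately for each of the four tempo instruction
#' types (UU, DD, UD, DU); the absolute values of these instruction-type
#' means are then averaged into the condition cells (congruent from
#' UU/DD, incongruent from UD/DU, separately per familiarity level).
#'
#' @param asyn Centered asynchronies ([mean_center()] output).
#' @param meta Trial metadata.
#' @param trial_means_first If `TRUE`, average per-trial means across
#'   trials instead of pooling keystrokes (identical for balanced
#'   retention; provided for sensitivity analysis).
#' @return Data frame `participant`, `condition`, `mean_abs_async` (ms).
#' @export
accuracy_summary <- function(asyn, meta, trial_means_first = FALSE) {
  idx <- match(asyn$trial_id, meta$trial_id)
  part <- .participant_id(meta$pair_id[idx], meta$session[idx])
  val <- if ("centered" %in% names(asyn)) asyn$centered else
    asyn$asynchrony
  instr <- meta$instruction_type[idx]
  fam <- meta$familiarity[idx]

  if (trial_means_first) {
    key_t <- paste(part, fam, instr, asyn$trial_id, sep = "\r")
    tm_s <- rowsum(val, key_t)
    tm_n <- rowsum(rep(1, length(val)), key_t)
    tm <- tm_s[, 1L] / tm_n[, 1L]
    # collapse trial means within participant x familiarity x instruction
    lab <- do.call(rbind, strsplit(rownames(tm_s), "\r", fixed = TRUE))
    key <- paste(lab[, 1L], lab[, 2L], lab[, 3L], sep = "\r")
    agg_s <- rowsum(tm, key)
    agg_n <- rowsum(rep(1, length(tm)), key)
    instr_means <- data.frame(key = rownames(agg_s),
                              mean = agg_s[, 1L] / agg_n[, 1L],
                              row.names = NULL)
  } else {
    key <- paste(part, fam, instr, sep = "\r")
    s <- rowsum(val, key)
    n <- rowsum(rep(1, length(val)), key)
    instr_means <- data.frame(key = rownames(s), mean = s[, 1L] / n[, 1L],
                              row.names = NULL)
  }
  lab <- do.call(rbind, strsplit(instr_means$key, "\r", fixed = TRUE))
  congr <- ifelse(lab[, 3L] %in% c("UU", "DD"), "C", "I")
  ckey <- paste(lab[, 1L], paste0(lab[, 2L], congr), sep = "\r")
  absmean <- rowsum(abs(instr_means$mean), ckey)
  cnt <- rowsum(rep(1, nrow(instr_means)), ckey)
  lab2 <- do.call(rbind, strsplit(rownames(absmean), "\r", fixed = TRUE))
  val_out <- absmean[, 1L] / cnt[, 1L]
  val_out[cnt[, 1L] < 2L] <- NA_real_  # an instruction type is missing
  out <- data.frame(participant = lab2[, 1L], condition = lab2[, 2L],
                    mean_abs_async = val_out,
                    row.names = NULL)
  out[order(out$participant, out$condition), ]
}

#' Synchronization stability per participant and condition
#'
#' Per-trial standard deviation (n-1 denominator) of the signed
#' (centered) asynchronies across keystrokes 1-7, averaged across the
#' condition's retained trials.
#'
#' @inheritParams accuracy_summary
#' @return Data frame `participant`, `condition`, `mean_sd_async` (ms).
#' @export
stability_summary <- function(asyn, meta) {
  am <- .asyn_matrix(asyn)
  npp <- ncol(am$m)
  sds <- sqrt(rowSums((am$m - rowMeans(am$m))^2) / (npp - 1))
  idx <- match(am$trial_id, meta$trial_id)
  key <- paste(.participant_id(meta$pair_id[idx], meta$session[idx]),
               meta$condition[idx], sep = "\r")
  s <- rowsum(sds, key)
  n <- rowsum(rep(1, length(sds)), key)
  lab <- do.call(rbind, strsplit(rownames(s), "\r", fixed = TRUE))
  out <- data.frame(participant = lab[, 1L], condition = lab[, 2L],
                    mean_sd_async = s[, 1L] / n[, 1L], row.names = NULL)
  out[order(out$participant, out$condition), ]
}

#' Lagged cross-correlation of the two players' IKIs
#'
#' Pearson correlation between the MR-pianist's (melody) inter-keystroke
#' intervals and the partner's (bass) intervals, with the partner's
#' series shifted relative to the reference: lag 0 pairs
#' `(melody_n, bass_n)` for n = 1..6; lag -1 ("the MR-pianist adapts to
#' the partner") pairs `(melody_n, bass_{n-1})` for n = 2..6; lag +1
#' ("the partner adapts to the MR-pianist") pairs `(melody_n,
#' bass_{n+1})` for n = 1..5. The Fisher z transform `atanh(r)` is
#' returned alongside, with r clipped to +/-(1 - 1e-12) first.
#'
#' @param iki_melody,iki_bass Numeric vectors of exactly 6 finite
#'   intervals (ms).
#' @param lag -1, 0 or +1.
#' @return List with `r` and `z`; both `NA` when either member of the
#'   paired sub-series has zero variance.
#' @export
#' @examples
#' lag_crosscorr(1:6 * 100, 1:6 * 100, lag = 0)$r  # 1
lag_crosscorr <- function(iki_melody, iki_bass, lag = 0L) {
  stopifnot(length(iki_melody) == 6L, length(iki_bass) == 6L,
            all(is.finite(iki_melody)), all(is.finite(iki_bass)))
  if (!lag %in% c(-1L, 0L, 1L)) stop("lag must be -1, 0 or +1",
                                     call. = FALSE)
  idx <- switch(as.character(lag),
                `0` = list(m = 1:6, b = 1:6),
                `-1` = list(m = 2:6, b = 1:5),
                `1` = list(m = 1:5, b = 2:6))
  x <- iki_melody[idx$m]
  y <- iki_bass[idx$b]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, z = NA_real_))
  r <- stats::cor(x, y)
  list(r = r, z = atanh(max(min(r, 1 - 1e-12), -(1 - 1e-12))))
}

# vectorized per-trial Pearson over matrix rows; zero variance -> NA
.row_pearson <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- ifelse(den > 0, rowSums(xc * yc) / den, NA_real_)
  ifelse(is.finite(r), r, NA_real_)
}

# per-trial lag correlations for all trials at once
.trial_lag_z <- function(events, meta, phrase = 1L) {
  om <- .onset_matrices(events, phrase = phrase)
  M <- .iki_matrix(om$melody)
  B <- .iki_matrix(om$bass)
  k <- ncol(M)
  r0 <- .row_pearson(M, B)
  rm1 <- .row_pearson(M[, -1L, drop = FALSE], B[, -k, drop = FALSE])
  rp1 <- .row_pearson(M[, -k, drop = FALSE], B[, -1L, drop = FALSE])
  clip <- function(r) atanh(pmax(pmin(r, 1 - 1e-12), -(1 - 1e-12)))
  data.frame(trial_id = om$trial_id,
             r_lag0 = r0, r_lagm1 = rm1, r_lagp1 = rp1,
             z_lag0 = clip(r0), z_lagm1 = clip(rm1), z_lagp1 = clip(rp1))
}

#' Interpersonal adaptation per participant, condition and lag
#'
#' Per-trial lagged IKI cross-correlations (see [lag_crosscorr()]) are
#' Fisher z-transformed and averaged across a condition's retained
#' trials; trials with undefined coefficients (zero IKI variance) are
#' excluded from that lag's average rather than treated as zero.
#'
#' @param events Retained event table.
#' @param meta Trial metadata.
#' @param phrase Phrase to analyze (default 1).
#' @return Data frame `participant`, `condition`, `lag` (one of
#'   `"lag-1"`, `"lag0"`, `"lag+1"`), `mean_z`.
#' @export
adaptation_summary <- function(events, meta, phrase = 1L) {
  tz <- .trial_lag_z(events, meta, phrase)
  idx <- match(tz$trial_id, meta$trial_id)
  part <- .participant_id(meta$pair_id[idx], meta$session[idx])
  cond <- meta$condition[idx]
  mean_by <- function(z) {
    ok <- !is.na(z)
    key <- paste(part[ok], cond[ok], sep = "\r")
    s <- rowsum(z[ok], key)
    n <- rowsum(rep(1, sum(ok)), key)
    lab <- do.call(rbind, strsplit(rownames(s), "\r", fixed = TRUE))
    data.frame(participant = lab[, 1L], condition = lab[, 2L],
               mean_z = s[, 1L] / n[, 1L], row.names = NULL)
  }
  out <- rbind(cbind(mean_by(tz$z_lagm1), lag = "lag-1"),
               cbind(mean_by(tz$z_lag0), lag = "lag0"),
               cbind(mean_by(tz$z_lagp1), lag = "lag+1"))
  out <- out[, c("participant", "condition", "lag", "mean_z")]
  out[order(out$participant, out$condition, out$lag), ]
}

#' Full per-participant condition summary
#'
#' Combines [accuracy_summary()], [stability_summary()] and
#' [adaptation_summary()] into the per-participant-per-condition table
#' used by the inferential layer: one row per participant x condition
#' with mean absolute asynchrony, mean asynchrony SD, and mean Fisher z
#' at lags -1, 0 and +1.
#'
#' @param events Retained event table (QC survivors).
#' @param meta Trial metadata.
#' @param scope Centering scope passed to [mean_center()].
#' @param trial_means_first Passed to [accuracy_summary()].
#' @return Data frame `participant`, `condition`, `mean_abs_async`,
#'   `mean_sd_async`, `z_lagm1`, `z_lag0`, `z_lagp1`.
#' @export
condition_summary <- function(events, meta,
                              scope = "participant_session",
                              trial_means_first = FALSE) {
  asyn <- mean_center(compute_asynchronies(events, phrase = 1L), meta,
                      scope = scope)
  acc <- accuracy_summary(asyn, meta, trial_means_first)
  sta <- stability_summary(asyn, meta)
  ada <- adaptation_summary(events, meta)
  wide <- stats::reshape(ada, idvar = c("participant", "condition"),
                         timevar = "lag", direction = "wide")
  names(wide) <- sub("mean_z.lag-1", "z_lagm1",
                     sub("mean_z.lag0", "z_lag0",
                         sub("mean_z.lag\\+1", "z_lagp1", names(wide))))
  out <- merge(merge(acc, sta, by = c("participant", "condition")),
               wide, by = c("participant", "condition"))
  out <- out[order(out$participant, out$condition), ]
  rownames(out) <- NULL
  out
}
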