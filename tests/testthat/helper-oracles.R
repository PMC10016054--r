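# Independent oracles and fixture builders used across the suite.

# Brute-force Pearson correlation via explicit double loops; deliberately
# naive and independent of the package's vectorized implementation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Lagged cross-correlation oracle following the reference convention:
# melody IKIs fixed, bass shifted.
oracle_lag_r <- function(m, b, lag) {
  if (lag == 0L) oracle_pearson(m, b)
  else if (lag == -1L) oracle_pearson(m[2:6], b[1:5])
  else oracle_pearson(m[1:5], b[2:6])
}

# Full sum-of-squares rmANOVA decomposition through stats::aov with an
# Error() stratum per within factor combination -- the standard textbook
# route, independent of the contrast-based implementation.
oracle_rm_anova <- function(data, dv, within, id) {
  for (w in c(within, id)) data[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = " * ")
  err <- sprintf("Error(%s/(%s))", id, rhs)
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- rownames(tab)
    for (i in seq_along(terms)) {
      nm <- gsub(" ", "", terms[i])
      if (nm == "Residuals") next
      out[[nm]] <- c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    }
  }
  out
}

# Random fully-crossed balanced within-participant dataset
make_balanced_data <- function(n_id, factors, sd_id = 1, sd_noise = 1) {
  lev <- lapply(factors, function(f) paste0(f, 1:2))
  names(lev) <- factors
  g <- expand.grid(c(list(id = paste0("s", seq_len(n_id))), lev),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(n_id)[match(g$id, unique(g$id))] * sd_id +
    rnorm(nrow(g), sd = sd_noise)
  g
}

# Small hand-built event table: one row per keystroke from onset matrices
make_events <- function(onsets_melody, onsets_bass, npp = ncol(onsets_melody),
                        pitch_melody = NULL, pitch_bass = NULL,
                        pair_id = 1L, session = 1L, phrase = 1L) {
  n_tr <- nrow(onsets_melody)
  if (is.null(pitch_melody))
    pitch_melody <- matrix(60L, n_tr, npp)
  if (is.null(pitch_bass))
    pitch_bass <- matrix(48L, n_tr, npp)
  data.frame(
    pair_id = pair_id, session = session,
    trial_id = rep(seq_len(n_tr), each = 2L * npp),
    player_role = rep(rep(c("melody", "bass"), each = npp), n_tr),
    phrase = phrase,
    position = rep(rep(seq_len(npp), 2L), n_tr),
    pitch = as.vector(t(cbind(pitch_melody, pitch_bass))),
    onset_ms = as.vector(t(cbind(onsets_melody, onsets_bass))),
    stringsAsFactors = FALSE)
}

# Matching minimal metadata table
make_meta <- function(n_tr, piece_id = "1", familiarity = "U",
                      cue_melody = "up", cue_bass = "up",
                      pair_id = 1L, session = 1L) {
  derive_condition(data.frame(
    pair_id = pair_id, session = session, trial_id = seq_len(n_tr),
    piece_id = piece_id, familiarity = familiarity,
    cue_melody = cue_melody, cue_bass = cue_bass,
    stringsAsFactors = FALSE))
}

# Noise-free parameter set (deterministic generator)
quiet_params <- function(...) {
  dyad_params(sigma_timekeeper = 0, sigma_motor = 0, sigma_fam = 0,
              sigma_start = 0, kappa = 0, lambda_seg = 0,
              p_wrong_note = 0, p_mistempo = 0, p_outlier = 0, ...)
}

# Construct a pair of length-n vectors whose sample correlation is
# exactly r (Gram-Schmidt construction).
vectors_with_cor <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  xs <- scale(x)[, 1L]
  es <- scale(e)[, 1L]
  list(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}
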