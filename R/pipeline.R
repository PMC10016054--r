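# End-to-end orchestration: simulate -> validate -> QC -> metrics ->
# inference -> report bundle, reproducible from a persisted config + seed.

#' Default run configuration
#'
#' A fully serializable description of one analysis run: simulator
#' parameters, design, analysis switches, and seed. Saved alongside every
#' report bundle so a run can be reproduced exactly.
#'
#' @param seed Root seed; overrides the seed stored in `params`.
#' @param params A [dyad_params()].
#' @param design A [design_spec()].
#' @param scope Mean-centering scope (see [mean_center()]).
#' @param trial_means_first Accuracy aggregation switch (see
#'   [accuracy_summary()]).
#' @param lower_pct,upper_pct IKI outlier percentile cuts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, params = dyad_params(seed = seed),
                       design = design_spec(),
                       scope = "participant_session",
                       trial_means_first = FALSE,
                       lower_pct = 1, upper_pct = 99) {
  params$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), params = params,
                 design = design, scope = scope,
                 trial_means_first = trial_means_first,
                 lower_pct = lower_pct, upper_pct = upper_pct),
            class = "run_config")
}

#' Persist / restore a run configuration as YAML
#'
#' Scores are stored as pitch vectors and rebuilt with [score_spec()].
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns the restored [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- list(
    seed = config$seed,
    params = unclass(config$params),
    design = c(unclass(config$design)[setdiff(names(config$design),
                                              "pieces")],
               list(pieces = lapply(config$design$pieces, unclass))),
    scope = config$scope,
    trial_means_first = config$trial_means_first,
    lower_pct = config$lower_pct, upper_pct = config$upper_pct)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ser <- yaml::read_yaml(path)
  pieces <- lapply(ser$design$pieces, function(p)
    score_spec(p$piece_id, p$melody_pitches, p$bass_pitches))
  names(pieces) <- vapply(pieces, function(s) as.character(s$piece_id), "")
  design <- do.call(design_spec,
                    c(ser$design[setdiff(names(ser$design), "pieces")],
                      list(pieces = pieces)))
  params <- do.call(dyad_params, ser$params)
  run_config(seed = ser$seed, params = params, design = design,
             scope = ser$scope,
             trial_means_first = ser$trial_means_first,
             lower_pct = ser$lower_pct, upper_pct = ser$upper_pct)
}

# the three rmANOVAs of the behavioral analysis, from a condition summary
.behavioral_anovas <- function(cs) {
  cs$familiarity <- substr(cs$condition, 1L, 1L)
  cs$tempo <- substr(cs$condition, 2L, 2L)
  long <- rbind(
    data.frame(cs[c("participant", "familiarity", "tempo")],
               lag = "m1", z = cs$z_lagm1),
    data.frame(cs[c("participant", "familiarity", "tempo")],
               lag = "p1", z = cs$z_lagp1))
  list(
    abs_async = rm_anova(cs, "mean_abs_async",
                         c("familiarity", "tempo"), "participant"),
    sd_async = rm_anova(cs, "mean_sd_async",
                        c("familiarity", "tempo"), "participant"),
    lag0 = rm_anova(cs, "z_lag0", c("familiarity", "tempo"),
                    "participant"),
    lag_3way = rm_anova(long, "z", c("familiarity", "tempo", "lag"),
                        "participant"),
    lag_m1 = rm_anova(cs, "z_lagm1", c("familiarity", "tempo"),
                      "participant"),
    lag_p1 = rm_anova(cs, "z_lagp1", c("familiarity", "tempo"),
                      "participant"))
}

# paired follow-up tests splitting the lag -1 interaction by familiarity;
# participants lacking either condition are dropped pairwise
.followup_tests <- function(cs) {
  pair_test <- function(c1, c2) {
    a <- cs[cs$condition == c1, c("participant", "z_lagm1")]
    b <- cs[cs$condition == c2, c("participant", "z_lagm1")]
    m <- merge(a, b, by = "participant")
    m <- m[stats::complete.cases(m), ]
    paired_t(m$z_lagm1.x, m$z_lagm1.y)
  }
  list(FC_vs_FI = pair_test("FC", "FI"),
       UC_vs_UI = pair_test("UC", "UI"))
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset, validates it, applies trial QC, computes the
#' per-participant condition summary, and runs the behavioral inference
#' (2x2 rmANOVAs on mean absolute asynchrony, asynchrony SD and lag-0
#' adaptation; the 2x2x2 rmANOVA over lags -1/+1; per-lag 2x2 ANOVAs;
#' and the paired follow-up tests on lag -1). When `out_dir` is given,
#' writes the event/meta CSVs, QC report, condition summary, ANOVA and
#' t-test tables, the persisted config, and a run log.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `events`, `meta`, `qc`,
#'   `condition_summary`, `anovas`, `followups`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_dataset(config$params, config$design)
  validate_events(sim$events)
  qc <- run_qc(sim$events, sim$meta, config$design$pieces,
               lower_pct = config$lower_pct,
               upper_pct = config$upper_pct)
  cs <- condition_summary(qc$events, sim$meta, scope = config$scope,
                          trial_means_first = config$trial_means_first)
  anovas <- .behavioral_anovas(cs)
  followups <- .followup_tests(cs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(sim$events, file.path(out_dir, "events.csv"))
    write_trial_meta(sim$meta, file.path(out_dir, "trial_meta.csv"))
    utils::write.csv(qc$trials, file.path(out_dir, "qc_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$condition_counts,
                     file.path(out_dir, "qc_condition_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(cs, file.path(out_dir, "condition_summary.csv"),
                     row.names = FALSE)
    an_tab <- do.call(rbind, lapply(names(anovas), function(nm)
      cbind(analysis = nm, as.data.frame(anovas[[nm]]))))
    utils::write.csv(an_tab, file.path(out_dir, "anova_tables.csv"),
                     row.names = FALSE)
    ft <- do.call(rbind, lapply(names(followups), function(nm)
      data.frame(contrast = nm, followups[[nm]])))
    utils::write.csv(ft, file.path(out_dir, "followup_tests.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
    writeLines(c(
      sprintf("duetsync %s | R %s", as.character(
        utils::packageVersion("duetsync")),
        paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", config$seed),
      sprintf("trials simulated: %d, retained: %d", nrow(sim$meta),
              sum(qc$trials$retained)),
      sprintf("retained per condition: %s",
              paste(qc$condition_counts$condition,
                    qc$condition_counts$retained, sep = "=",
                    collapse = " "))),
      file.path(out_dir, "run_log.txt"))
  }
  invisible(list(events = sim$events, meta = sim$meta, qc = qc,
                 condition_summary = cs, anovas = anovas,
                 followups = followups, config = config))
}
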