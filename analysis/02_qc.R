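#!/usr/bin/env Rscript
# Stage 2: behavioral trial quality control.
#
# Applies the three-stage exclusion pipeline to the simulated experiment:
# (1) trials with any wrong key, (2) trials whose second-phrase IKIs fit a
# tempo template other than the instructed one better (MSE against 400 /
# 625 / 500 ms), and (3) trials containing a first-phrase IKI beyond the
# pooled 1st/99th percentile. Writes the retained events, the per-trial
# flags and the per-condition retention counts.

library(duetsync)

events <- read_events("results/events.csv")
meta <- read_trial_meta("results/trial_meta.csv")

qc <- run_qc(events, meta)
print(qc)

write_events(qc$events, "results/retained_events.csv")
write.csv(qc$trials, "results/qc_trials.csv", row.names = FALSE)
write.csv(qc$condition_counts, "results/qc_condition_counts.csv",
          row.names = FALSE)

# cross-check against the simulator's injection log
inj <- read.csv("results/injection_log.csv")
flagged <- qc$trials$trial_id[qc$trials$wrong_note]
injected <- inj$trial_id[inj$wrong_note]
cat(sprintf("Wrong-note flags vs injection log: %d flagged, %d injected.\n",
            length(flagged), length(injected)))
cat(sprintf("Mean retained trials per pair per condition: %s\n",
            paste(qc$condition_counts$condition,
                  round(qc$condition_counts$retained / 19, 2),
                  sep = "=", collapse = ", ")))
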