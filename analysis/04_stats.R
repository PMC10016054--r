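#!/usr/bin/env Rscript
# Stage 4: repeated-measures inference.
#
# Mirrors the behavioral analysis tables: 2x2 rmANOVAs (FAMILIARITY x
# TEMPO) on mean absolute asynchrony and asynchrony SD; the 2x2x2 rmANOVA
# adding LAG (-1 / +1) on the Fisher-z cross-correlations; per-lag 2x2
# ANOVAs; and paired follow-up t tests (with Cohen's d) splitting the
# lag -1 interaction by familiarity.

library(duetsync)

cs <- read.csv("results/condition_summary.csv")
cs$familiarity <- substr(cs$condition, 1, 1)
cs$tempo <- substr(cs$condition, 2, 2)

long <- rbind(
  data.frame(cs[c("participant", "familiarity", "tempo")], lag = "m1",
             z = cs$z_lagm1),
  data.frame(cs[c("participant", "familiarity", "tempo")], lag = "p1",
             z = cs$z_lagp1))

anovas <- list(
  abs_async = rm_anova(cs, "mean_abs_async", c("familiarity", "tempo"),
                       "participant"),
  sd_async = rm_anova(cs, "mean_sd_async", c("familiarity", "tempo"),
                      "participant"),
  lag_3way = rm_anova(long, "z", c("familiarity", "tempo", "lag"),
                      "participant"),
  lag_m1 = rm_anova(cs, "z_lagm1", c("familiarity", "tempo"),
                    "participant"),
  lag_0 = rm_anova(cs, "z_lag0", c("familiarity", "tempo"),
                   "participant"),
  lag_p1 = rm_anova(cs, "z_lagp1", c("familiarity", "tempo"),
                    "participant"))

for (nm in names(anovas)) {
  cat("\n==", nm, "==\n")
  print(anovas[[nm]])
}

tab <- do.call(rbind, lapply(names(anovas), function(nm)
  cbind(analysis = nm, as.data.frame(anovas[[nm]]))))
write.csv(tab, "results/anova_tables.csv", row.names = FALSE)

# follow-up: does the TEMPO effect on lag -1 adaptation depend on
# familiarity, as in the self-other segregation account?
pairs_of <- function(c1, c2) {
  m <- merge(cs[cs$condition == c1, c("participant", "z_lagm1")],
             cs[cs$condition == c2, c("participant", "z_lagm1")],
             by = "participant")
  m[complete.cases(m), ]
}
ft <- lapply(list(FC_vs_FI = pairs_of("FC", "FI"),
                  UC_vs_UI = pairs_of("UC", "UI")),
             function(m) paired_t(m$z_lagm1.x, m$z_lagm1.y))
for (nm in names(ft))
  cat(sprintf("%s: t(%d) = %.2f, p = %.3f, d = %.2f\n", nm, ft[[nm]]$df,
              ft[[nm]]$t, ft[[nm]]$p, ft[[nm]]$d))
write.csv(do.call(rbind, lapply(names(ft), function(nm)
  data.frame(contrast = nm, ft[[nm]]))),
  "results/followup_tests.csv", row.names = FALSE)
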