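# The ME assessment: hierarchical Procrustes ANOVA (is individual variation
# larger than total digitization error?), the ME ANOVA separating systematic
# from random error with SNR permutation tests (all sessions and excluding
# the oldest), the EV ordination of the bias subspace, and the planned
# pairwise comparisons of the first session against every later one.

source("analysis/00_common.R")

ds <- study_dataset()
sh <- gpa(ds)

pa <- procrustes_anova(sh)
print(pa)
write.csv(pa$table, file.path(OUT, "procrustes_anova.csv"), row.names = FALSE)

me <- me_anova(sh, n_perm = N_PERM, seed = SEED + 1L)
print(me)
write.csv(me$table, file.path(OUT, "me_anova.csv"), row.names = FALSE)

oldest <- ds$meta$rep_label[which.max(ds$meta$day_offset)]
no_old <- subset_reps(ds, setdiff(unique(ds$meta$rep_label), oldest))
me2 <- me_anova(gpa(no_old), n_perm = N_PERM, seed = SEED + 2L)
cat("\nexcluding", oldest, ": systME Rsq",
    sprintf("%.1f%%", 100 * me2$table$Rsq[me2$table$effect == "systME"]), "\n")
write.csv(me2$table, file.path(OUT, "me_anova_no_oldest.csv"),
          row.names = FALSE)

ev <- ev_ordination(me, sh)
cat("EV axis variance fractions:",
    paste(sprintf("%.1f%%", 100 * ev$axis_variance_fraction), collapse = " "),
    "\n")
write.csv(data.frame(rep = ev$rep_label, ev$scores),
          file.path(OUT, "ev_scores.csv"), row.names = FALSE)

ts <- pairwise_timelag_series(ds, n_perm = N_PERM, seed = SEED + 10L)
syst <- ts$comparisons[ts$comparisons$effect == "systME", ]
cat("\nsystematic ME vs time lag (reference", ts$reference, "):\n")
print(syst[, c("rep", "lag_days", "SNR", "p", "Rsq")], row.names = FALSE)
write.csv(ts$comparisons, file.path(OUT, "timelag_series.csv"),
          row.names = FALSE)
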