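# Robustness of biological signal across sessions: within each REP, the
# permutation tests of sexual dimorphism and static allometry, the
# cross-validated bgPCA hit rate for sex, and the congruence of PC1 scores
# and shape distance matrices between REPs.

source("analysis/00_common.R")

ds <- study_dataset()
shapes <- per_rep_shapes(ds)

rows <- lapply(seq_along(shapes), function(k) {
  s <- shapes[[k]]
  sx <- permutation_regression(s, s$meta$sex, n_perm = N_PERM,
                               seed = SEED + 20L + k)
  al <- permutation_regression(s, s$cs, n_perm = N_PERM,
                               seed = SEED + 40L + k)
  hr <- bgpca_crossval(s, s$meta$sex)
  data.frame(rep = names(shapes)[k],
             sex_Rsq = sx$Rsq, sex_p = sx$p, HR = hr$average_hr,
             allometry_Rsq = al$Rsq, allometry_p = al$p)
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE, digits = 3)
write.csv(tab, file.path(OUT, "signal_per_rep.csv"), row.names = FALSE)

pc <- pc1_congruence(shapes)
dmc <- distance_matrix_congruence(shapes)
print(pc); print(dmc)
cong <- rbind(
  data.frame(kind = pc$kind, n = nrow(pc$pairs), median = pc$median,
             p10 = pc$p10, p90 = pc$p90),
  data.frame(kind = dmc$kind, n = nrow(dmc$pairs), median = dmc$median,
             p10 = dmc$p10, p90 = dmc$p90))
write.csv(cong, file.path(OUT, "congruence.csv"), row.names = FALSE)
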