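# Procrustes superimposition and its diagnostics: unit-size scaling, GPA,
# the tangent-space check (r and slope ~ 1 mean the flat approximation is
# excellent), the ranked outlier report, and a UPGMA phenogram of all
# records from pairwise Procrustes shape distances.

source("analysis/00_common.R")

ds <- study_dataset()
sh <- gpa(ds)
print(sh)

td <- tangent_diagnostic(sh)
cat(sprintf("tangent-space check: r = %.6f, slope = %.6f\n", td$r, td$slope))

out <- flag_outliers(sh)
cat("largest shape distances to the consensus (kept, not excluded):\n")
print(head(out, 5), row.names = FALSE)
write.csv(out, file.path(OUT, "outliers.csv"), row.names = FALSE)

dm <- procrustes_distance_matrix(sh)
tr <- cluster_phenogram(dm, "UPGMA")
ape::write.tree(tr, file.path(OUT, "phenogram_upgma.nwk"))
cat("phenogram written to", file.path(OUT, "phenogram_upgma.nwk"), "\n")
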