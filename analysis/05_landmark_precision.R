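# Absolute per-landmark imprecision in the raw coordinates: X+Y variance
# across sessions per individual and landmark, summary statistics
# standardized by their medians, the combined imprecision index, the
# threshold-based "precise" / "most precise" configurations, and the
# deviation-cloud data for plotting digitization scatter.

source("analysis/00_common.R")

ds <- study_dataset()
V <- per_landmark_variances(ds)
prec <- standardize_and_combine(summarize_precision(V))
print(prec[order(prec$median), c("landmark", "median", "p90", "std_median",
                                 "std_p90", "combined")],
      row.names = FALSE, digits = 3)
write.csv(prec, file.path(OUT, "precision.csv"), row.names = FALSE)

sel <- select_precise_configurations(prec)
cat("precise configuration:", length(sel$precise), "landmarks\n")
cat("most precise configuration:", length(sel$most_precise), "landmarks\n")
writeLines(c(paste("precise:", paste(sel$precise, collapse = " ")),
             paste("most_precise:", paste(sel$most_precise, collapse = " "))),
           file.path(OUT, "configurations.txt"))

cloud <- deviation_cloud(ds, ds$meta$individual_id[1])
write.csv(cloud, file.path(OUT, "deviation_cloud.csv"), row.names = FALSE)
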