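# Orchestration of the full repeated-digitization study: one call runs the
# ME assessment (R1), the signal-robustness battery (R2), the per-landmark
# precision analysis (R3), the reruns on reduced configurations (R4) and the
# biased-design simulation, from either input files or synthetic parameters.

#' Study configuration
#'
#' @param tps_path,meta_path Input TPS file and metadata CSV; leave `NULL` to
#'   run on synthetic data.
#' @param params A `synth_params` object used when no input files are given.
#' @param n_perm Permutations for all permutation tests (>= 99).
#' @param alpha Reporting significance threshold (default 0.005; all p-values
#'   are emitted raw).
#' @param reference Reference REP for the time-lag series (default: earliest
#'   day offset).
#' @param thresholds Numeric `c(precise = 1.5, most_precise = 1.0)` for the
#'   configuration reduction.
#' @param seed Master seed; every stage derives a fixed sub-seed from it.
#' @param outdir Output directory for CSV tables and the JSON report
#'   (`NULL` = return the report only).
#' @return A `study_config` list.
#' @export
study_config <- function(tps_path = NULL, meta_path = NULL,
                         params = synth_params(), n_perm = 999L,
                         alpha = 0.005, reference = NULL,
                         thresholds = c(precise = 1.5, most_precise = 1.0),
                         seed = 1L, outdir = NULL) {
  stopifnot(n_perm >= 99L, all(thresholds > 0))
  structure(list(tps_path = tps_path, meta_path = meta_path, params = params,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 reference = reference, thresholds = thresholds,
                 seed = as.integer(seed), outdir = outdir,
                 schema_version = 1L),
            class = "study_config")
}

# ME assessment block on one configuration of one dataset
.me_block <- function(dataset, n_perm, seed, reference) {
  shape <- gpa(dataset)
  proc <- procrustes_anova(shape)
  me <- me_anova(shape, n_perm = n_perm, seed = seed)
  ev <- ev_ordination(me, shape)
  series <- pairwise_timelag_series(dataset, reference = reference,
                                    n_perm = n_perm, seed = seed + 100L)
  oldest <- dataset$meta$rep_label[which.max(dataset$meta$day_offset)]
  no_old <- subset_reps(dataset,
                        setdiff(unique(dataset$meta$rep_label), oldest))
  me_no_old <- me_anova(gpa(no_old), n_perm = n_perm, seed = seed + 200L)
  list(procrustes_anova = proc$table, me_anova = me$table,
       me_anova_no_oldest = me_no_old$table, oldest_rep = oldest,
       ev_variance_fraction = ev$axis_variance_fraction,
       timelag = series$comparisons,
       shape = shape, me = me, ev = ev)
}

# per-REP signal tests + congruence block
.signal_block <- function(dataset, n_perm, seed) {
  shapes <- per_rep_shapes(dataset)
  per_rep <- lapply(seq_along(shapes), function(k) {
    s <- shapes[[k]]
    sex <- permutation_regression(s, s$meta$sex, n_perm = n_perm,
                                  seed = seed + 10L * k)
    allo <- permutation_regression(s, s$cs, n_perm = n_perm,
                                   seed = seed + 10L * k + 1L)
    hr <- bgpca_crossval(s, s$meta$sex)
    data.frame(rep = names(shapes)[k], sex_Rsq = sex$Rsq, sex_p = sex$p,
               hr = hr$average_hr, allometry_Rsq = allo$Rsq,
               allometry_p = allo$p, stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, per_rep)
  list(per_rep = per_rep,
       pc1_congruence = pc1_congruence(shapes),
       distance_congruence = distance_matrix_congruence(shapes))
}

#' Run the full repeated-digitization study
#'
#' Executes, in order: data assembly (or synthesis), GPA, outlier report,
#' tangent-space diagnostic, Procrustes ANOVA and ME ANOVA (including the
#' variant excluding the oldest REP), EV ordination, the pairwise time-lag
#' series, per-REP sex/allometry/classification tests with congruence
#' summaries, the per-landmark precision analysis, configuration reduction,
#' full reruns on the reduced configurations, the mixed-REP biased-design
#' simulation, and centroid-size checks. Deterministic given `config$seed`.
#'
#' @param config A `study_config`.
#' @return A `study_report` list; if `config$outdir` is set, CSV tables and a
#'   JSON report are written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  if (!is.null(config$tps_path)) {
    metadata <- utils::read.csv(config$meta_path,
                                stringsAsFactors = FALSE)
    configs <- read_tps(config$tps_path, apply_scale = TRUE)
    if (length(configs) != nrow(metadata)) {
      stop("TPS block count does not match metadata rows")
    }
    # blocks and metadata rows are in the same record order (the convention
    # of write_dataset); re-key each block by its metadata individual ID
    for (i in seq_along(configs)) {
      configs[[i]]$id <- metadata$individual_id[i]
    }
    by_rep <- split(configs, metadata$rep_label)
    dataset <- assemble_dataset(by_rep, metadata)
    truth <- NULL
  } else {
    p <- config$params
    p$seed <- seed
    sim <- generate_dataset(p)
    dataset <- sim$dataset
    truth <- sim$truth
  }
  reps <- unique(dataset$meta$rep_label)

  full <- .me_block(dataset, config$n_perm, seed + 1L, config$reference)
  outliers <- utils::head(flag_outliers(full$shape), 10L)
  tangent <- tangent_diagnostic(full$shape)
  signal_full <- .signal_block(dataset, config$n_perm, seed + 2L)

  V <- per_landmark_variances(dataset)
  prec <- standardize_and_combine(summarize_precision(V))
  selection <- select_precise_configurations(prec)
  cloud_ref <- dataset$meta$individual_id[1L]

  reruns <- list()
  for (cfg_name in c("precise", "most_precise")) {
    keep <- selection[[cfg_name]]
    if (length(keep) < dataset$n_landmarks && length(keep) >= 3L) {
      sub <- subset_landmarks(dataset, keep)
      reruns[[cfg_name]] <- list(
        n_landmarks = length(keep),
        me = .me_block(sub, config$n_perm, seed + 3L, config$reference),
        signal = .signal_block(sub, config$n_perm, seed + 4L))
    }
  }

  oldest <- full$oldest_rep
  recent <- setdiff(reps, oldest)
  mixed_small <- mixed_design_test(dataset,
                                   list(F = reps[1L], M = reps[2L]),
                                   n_perm = config$n_perm, seed = seed + 5L)
  mixed_large <- mixed_design_test(dataset,
                                   list(F = oldest, M = recent),
                                   n_perm = config$n_perm, seed = seed + 6L)
  cs_check <- cs_repeated_measures(dataset)

  report <- list(
    config = list(seed = seed, n_perm = config$n_perm, alpha = config$alpha,
                  thresholds = config$thresholds,
                  schema_version = config$schema_version),
    design = list(n_individuals = dataset$n_individuals,
                  n_reps = dataset$n_reps,
                  n_landmarks = dataset$n_landmarks,
                  n_records = nrow(dataset$meta),
                  reps = reps),
    tangent_diagnostic = tangent,
    outliers = outliers,
    R1 = full[c("procrustes_anova", "me_anova", "me_anova_no_oldest",
                "oldest_rep", "ev_variance_fraction", "timelag")],
    R2 = signal_full[c("per_rep")],
    R2_congruence = list(
      pc1 = signal_full$pc1_congruence[c("median", "p10", "p90")],
      pc1_n = nrow(signal_full$pc1_congruence$pairs),
      dist = signal_full$distance_congruence[c("median", "p10", "p90")],
      dist_n = nrow(signal_full$distance_congruence$pairs)),
    R3 = list(precision = as.data.frame(prec), selection = selection,
              cloud_reference = cloud_ref),
    R4 = lapply(reruns, function(rr) {
      list(n_landmarks = rr$n_landmarks,
           me_anova = rr$me$me_anova,
           timelag = rr$me$timelag,
           per_rep = rr$signal$per_rep)
    }),
    S = list(mixed_small = lapply(mixed_small[c("sex", "allometry")],
                                  function(t) t[c("Rsq", "F", "p")]),
             mixed_small_hr = mixed_small$bgpca$average_hr,
             mixed_large = lapply(mixed_large[c("sex", "allometry")],
                                  function(t) t[c("Rsq", "F", "p")]),
             mixed_large_hr = mixed_large$bgpca$average_hr,
             cs_anova = cs_check$anova,
             cs_sex_median_diff = cs_check$sex_median_diff))
  if (!is.null(truth)) report$ground_truth_available <- TRUE
  class(report) <- "study_report"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(full$procrustes_anova,
                     file.path(config$outdir, "procrustes_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(full$me_anova,
                     file.path(config$outdir, "me_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(full$timelag,
                     file.path(config$outdir, "timelag_series.csv"),
                     row.names = FALSE)
    utils::write.csv(signal_full$per_rep,
                     file.path(config$outdir, "signal_per_rep.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(prec),
                     file.path(config$outdir, "precision.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns")
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Repeated-digitization study report\n")
  cat("  design:", x$design$n_individuals, "individuals x",
      x$design$n_reps, "REPs,", x$design$n_landmarks, "landmarks\n")
  cat("  tangent diagnostic: r =", format(x$tangent_diagnostic$r, digits = 6),
      ", slope =", format(x$tangent_diagnostic$slope, digits = 6), "\n")
  me <- x$R1$me_anova
  cat("  ME ANOVA Rsq: individual",
      sprintf("%.1f%%", 100 * me$Rsq[me$effect == "individual"]),
      ", systME", sprintf("%.1f%%", 100 * me$Rsq[me$effect == "systME"]),
      ", randME", sprintf("%.1f%%", 100 * me$Rsq[me$effect == "randME"]),
      "\n")
  invisible(x)
}
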