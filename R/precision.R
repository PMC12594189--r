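# Per-landmark absolute imprecision in raw coordinates: variances across
# REPs, summary standardization, combined index, threshold-based
# configuration selection and the deviation-cloud plot data.
#
# These analyses act on raw (not superimposed) coordinates and rely on the
# same-photograph design: all REPs of an individual share one pose, so raw
# coordinates are directly comparable across REPs.

#' Per-landmark raw-coordinate variances across REPs
#'
#' For every individual and landmark, the sample variance (denominator R - 1)
#' of the X coordinates across the REPs plus that of the Y coordinates, in
#' mm^2.
#'
#' @param dataset A `digit_dataset` with >= 2 REPs.
#' @return n_individuals x L matrix `V`, rownames individual IDs, colnames
#'   landmark labels.
#' @export
per_landmark_variances <- function(dataset) {
  stopifnot(inherits(dataset, "digit_dataset"))
  if (dataset$n_reps < 2L) stop("variance undefined with a single REP")
  ind <- unique(dataset$meta$individual_id)
  L <- dataset$n_landmarks
  V <- matrix(NA_real_, length(ind), L,
              dimnames = list(ind, dataset$labels))
  for (i in seq_along(ind)) {
    sel <- dataset$meta$individual_id == ind[i]
    xs <- dataset$coords[, 1L, sel]  # L x R
    ys <- dataset$coords[, 2L, sel]
    V[i, ] <- apply(xs, 1L, stats::var) + apply(ys, 1L, stats::var)
  }
  V
}

#' Summary statistics of per-landmark variances
#'
#' Median, 90th percentile, mean and SD of the per-individual variances of
#' each landmark (mm^2). Landmarks are conventionally ordered by increasing
#' median for profile plots; the returned table keeps input order and adds a
#' `rank_median` column.
#'
#' @param V Matrix from [per_landmark_variances()].
#' @param p90_type Quantile interpolation type passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A `precision_summary` data frame: landmark, median, p90, mean, sd,
#'   rank_median.
#' @export
summarize_precision <- function(V, p90_type = 7L) {
  stopifnot(is.matrix(V))
  out <- data.frame(
    landmark = colnames(V),
    median = apply(V, 2L, stats::median),
    p90 = apply(V, 2L, stats::quantile, probs = 0.9, type = p90_type,
                names = FALSE),
    mean = colMeans(V),
    sd = apply(V, 2L, stats::sd),
    stringsAsFactors = FALSE)
  out$rank_median <- rank(out$median, ties.method = "first")
  rownames(out) <- NULL
  class(out) <- c("precision_summary", "data.frame")
  out
}

#' Standardize precision summaries and combine them
#'
#' Divides each landmark's median and 90th percentile by the median over
#' landmarks of the respective statistic, so a standardized median of 0.5
#' means the landmark is half as imprecise as the average landmark. The
#' combined index is the sum of the two standardized statistics, and flags
#' mark landmarks exceeding 1.0 or 1.5 on both axes (strict inequalities).
#'
#' @param summary A `precision_summary` from [summarize_precision()].
#' @return The same data frame with `std_median`, `std_p90`, `combined`,
#'   `above_1_0` and `above_1_5` columns filled.
#' @export
standardize_and_combine <- function(summary) {
  stopifnot(inherits(summary, "precision_summary"))
  mm <- stats::median(summary$median)
  mp <- stats::median(summary$p90)
  if (mm == 0 || mp == 0) stop("no imprecision to standardize (all-zero variances)")
  summary$std_median <- summary$median / mm
  summary$std_p90 <- summary$p90 / mp
  summary$combined <- summary$std_median + summary$std_p90
  summary$above_1_0 <- summary$std_median > 1 & summary$std_p90 > 1
  summary$above_1_5 <- summary$std_median > 1.5 & summary$std_p90 > 1.5
  summary
}

#' Select precise and most-precise landmark configurations
#'
#' The "precise" configuration drops landmarks whose standardized median and
#' standardized 90th percentile both exceed 1.5; the "most precise" one drops
#' all landmarks exceeding 1.0 on both axes. Comparisons are strict, so
#' boundary landmarks are retained, and most_precise is always a subset of
#' precise.
#'
#' @param summary A standardized `precision_summary` (see
#'   [standardize_and_combine()]).
#' @return List with `precise` and `most_precise` character vectors of
#'   retained landmark labels.
#' @export
select_precise_configurations <- function(summary) {
  stopifnot(inherits(summary, "precision_summary"))
  if (is.null(summary$std_median)) summary <- standardize_and_combine(summary)
  precise <- summary$landmark[!summary$above_1_5]
  most_precise <- summary$landmark[!summary$above_1_0]
  if (length(precise) == 0L || length(most_precise) == 0L) {
    stop("selection empty: every landmark exceeds the thresholds; ",
         "consider raising them")
  }
  list(precise = precise, most_precise = most_precise)
}

#' Deviation cloud of raw landmark coordinates
#'
#' For every record and landmark, the deviation of the raw coordinates from
#' the mean of that individual's REPs, anchored at the reference individual's
#' mean landmark positions. Plotting `anchored_x`/`anchored_y` shows the
#' digitization scatter around one configuration; the choice of reference
#' individual shifts the anchors but not the per-landmark scatter.
#'
#' @param dataset A `digit_dataset`.
#' @param reference_id Individual whose mean configuration anchors the cloud.
#' @return Data frame: landmark, individual_id, rep_label, dx, dy,
#'   anchored_x, anchored_y.
#' @export
deviation_cloud <- function(dataset, reference_id) {
  stopifnot(inherits(dataset, "digit_dataset"))
  ids <- dataset$meta$individual_id
  if (!reference_id %in% ids) stop("unknown reference individual ", reference_id)
  L <- dataset$n_landmarks
  n <- dim(dataset$coords)[3L]
  # per-individual mean configuration across REPs
  means <- new.env()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    assign(id, apply(dataset$coords[, , sel, drop = FALSE], c(1L, 2L), mean),
           envir = means)
  }
  ref <- get(reference_id, envir = means)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dev <- dataset$coords[, , i] - get(ids[i], envir = means)
    rows[[i]] <- data.frame(landmark = dataset$labels,
                            individual_id = ids[i],
                            rep_label = dataset$meta$rep_label[i],
                            dx = dev[, 1L], dy = dev[, 2L],
                            anchored_x = ref[, 1L] + dev[, 1L],
                            anchored_y = ref[, 2L] + dev[, 2L],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
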