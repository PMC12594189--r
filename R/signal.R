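# Robustness of biological signal across REPs: permutation regression of
# shape on sex or size, cross-validated bgPCA classification, REP averaging,
# the mixed-REP biased-design ("visiting scientist") simulation, congruence
# correlations between REPs, and centroid-size bias checks.

#' Permutational multivariate regression of shape on one predictor
#'
#' Least-squares fit of all tangent coordinates on a single predictor (sex
#' dummy with F = 0, M = 1, or centroid size for static allometry).
#' Rsq = SS(model)/SS(total); the pseudo-F statistic is
#' (SS(model)/1) / (SS(residual)/(n-2)); significance is assessed by
#' permuting the predictor over individuals, p = (b + 1)/(m + 1).
#'
#' @param shape A `shape_data` with one record per individual (a single REP or
#'   composite), or an n x p numeric matrix of shape variables.
#' @param predictor Numeric vector of length n (constant predictors are
#'   rejected). Factors with two levels are dummy-coded 0/1.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `Rsq`, `F`, `p`, `n`, `n_perm`, `seed`.
#' @export
permutation_regression <- function(shape, predictor, n_perm = 999L,
                                   seed = NULL) {
  Y <- if (inherits(shape, "shape_data")) shape$tangent else as.matrix(shape)
  if (is.factor(predictor) || is.character(predictor)) {
    predictor <- as.numeric(factor(predictor)) - 1
  }
  n <- nrow(Y)
  stopifnot(length(predictor) == n)
  if (stats::var(predictor) == 0) stop("constant predictor")
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_tot <- sum(Yc * Yc)
  model_ss <- function(x) {
    xc <- x - mean(x)
    sum(crossprod(xc, Yc)^2) / sum(xc * xc)
  }
  ss_mod <- model_ss(predictor)
  f_obs <- ss_mod / ((ss_tot - ss_mod) / (n - 2L))
  p <- NA_real_
  if (n_perm > 0L) {
    exceed <- 0L
    .with_seed(seed, {
      for (b in seq_len(n_perm)) {
        ssp <- model_ss(predictor[sample(n)])
        fp <- ssp / ((ss_tot - ssp) / (n - 2L))
        if (fp >= f_obs) exceed <- exceed + 1L
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(Rsq = ss_mod / ss_tot, F = f_obs, p = p, n = n, n_perm = n_perm,
       seed = seed)
}

#' Leave-one-out cross-validated bgPCA classification
#'
#' Nearest-group-mean classification in the full tangent space (equivalent to
#' classifying on all between-group PC axes): for each record the group means
#' are recomputed without it and the record is assigned to the closest mean by
#' Euclidean distance. Ties are broken toward the first group and flagged.
#'
#' @param shape A `shape_data` with one record per individual, or an n x p
#'   matrix.
#' @param groups Vector of group labels (>= 2 groups, each with >= 2 members).
#' @return List with `hit_rate` (per group, %), `average_hr` (%, mean of the
#'   per-group rates), `assigned`, `n_ties`.
#' @export
bgpca_crossval <- function(shape, groups) {
  Y <- if (inherits(shape, "shape_data")) shape$tangent else as.matrix(shape)
  groups <- as.character(groups)
  n <- nrow(Y)
  stopifnot(length(groups) == n)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  cnt <- table(factor(groups, levels = lev))
  if (any(cnt < 2L)) stop("every group needs >= 2 members for leave-one-out")
  sums <- rowsum(Y, factor(groups, levels = lev), reorder = FALSE)
  assigned <- character(n)
  n_ties <- 0L
  for (i in seq_len(n)) {
    d2 <- vapply(seq_along(lev), function(g) {
      s <- sums[g, ]
      m <- if (groups[i] == lev[g]) (s - Y[i, ]) / (cnt[g] - 1L) else s / cnt[g]
      sum((Y[i, ] - m)^2)
    }, numeric(1))
    win <- which(d2 <= min(d2) + 1e-12)
    if (length(win) > 1L) n_ties <- n_ties + 1L
    assigned[i] <- lev[win[1L]]
  }
  hr <- vapply(lev, function(g) {
    100 * mean(assigned[groups == g] == g)
  }, numeric(1))
  list(hit_rate = hr, average_hr = mean(hr), assigned = assigned,
       n_ties = n_ties)
}

#' Average GPA-aligned records over a set of REPs
#'
#' Per-individual arithmetic mean of the aligned coordinates over the listed
#' REPs, returned as a one-record-per-individual `digit_dataset` flagged
#' composite. Downstream shape analyses must re-superimpose it (the mean of
#' aligned shapes is treated as a raw configuration).
#'
#' @param shape A `shape_data` from [gpa()] on the full dataset.
#' @param reps Non-empty character vector of REP labels to average.
#' @param label REP label given to the composite records (default
#'   "composite").
#' @return A `digit_dataset` with one record per individual; `cs` carries over
#'   as the per-individual mean centroid size of the averaged REPs.
#' @export
average_reps <- function(shape, reps, label = "composite") {
  stopifnot(inherits(shape, "shape_data"))
  if (length(reps) == 0L) stop("empty REP set")
  meta <- shape$meta
  if (!all(reps %in% meta$rep_label)) {
    stop("unknown REP labels: ", paste(setdiff(reps, meta$rep_label),
                                       collapse = ", "))
  }
  sel <- which(meta$rep_label %in% reps)
  ids <- unique(meta$individual_id[sel])
  L <- dim(shape$aligned)[1L]
  coords <- array(NA_real_, c(L, 2L, length(ids)))
  cs <- numeric(length(ids))
  for (j in seq_along(ids)) {
    rows <- sel[meta$individual_id[sel] == ids[j]]
    coords[, , j] <- apply(shape$aligned[, , rows, drop = FALSE],
                           c(1L, 2L), mean)
    cs[j] <- mean(shape$cs[rows])
  }
  m1 <- meta[match(ids, meta$individual_id), c("individual_id", "sex"),
             drop = FALSE]
  new_meta <- data.frame(individual_id = ids, sex = m1$sex,
                         rep_label = label,
                         day_offset = round(mean(meta$day_offset[sel])),
                         stringsAsFactors = FALSE)
  structure(list(coords = coords, labels = shape$labels, meta = new_meta,
                 n_individuals = length(ids), n_reps = 1L, n_landmarks = L,
                 composite = TRUE, cs = cs),
            class = "digit_dataset")
}

# one-record-per-individual dataset for one sex from a source spec: a single
# REP label (raw coordinates) or a set of labels (averaged aligned
# coordinates, requiring `full_shape`)
.compose_source <- function(dataset, full_shape, source, sex_keep) {
  if (length(source) == 1L) {
    sub <- subset_reps(dataset, source)
    sel <- sub$meta$sex == sex_keep
    cs <- apply(sub$coords[, , sel, drop = FALSE], 3L, centroid_size)
    list(coords = sub$coords[, , sel, drop = FALSE],
         meta = sub$meta[sel, , drop = FALSE], cs = cs)
  } else {
    avg <- average_reps(full_shape, source)
    sel <- avg$meta$sex == sex_keep
    list(coords = avg$coords[, , sel, drop = FALSE],
         meta = avg$meta[sel, , drop = FALSE], cs = avg$cs[sel])
  }
}

#' Mixed-REP biased-design ("visiting scientist") test
#'
#' Simulates a flawed data-collection design in which each sex is digitized in
#' a different session: females are drawn from one REP (or an average of
#' several) and males from another. The composite sample is re-superimposed
#' and the standard tests are run: permutation regression of shape on sex and
#' on centroid size, and cross-validated bgPCA classification.
#'
#' @param dataset A `digit_dataset`.
#' @param assignment Named list `list(F = ..., M = ...)`; each element a
#'   single REP label or a character vector of labels to average.
#' @param n_perm Permutations for the regression tests.
#' @param seed Integer seed (sex test uses `seed`, allometry `seed + 1`).
#' @return List with `sex` and `allometry` permutation-regression results,
#'   `bgpca`, and `assignment`.
#' @export
mixed_design_test <- function(dataset, assignment, n_perm = 999L,
                              seed = NULL) {
  stopifnot(inherits(dataset, "digit_dataset"),
            all(c("F", "M") %in% names(assignment)))
  needs_avg <- any(lengths(assignment) > 1L)
  full_shape <- if (needs_avg) gpa(dataset) else NULL
  fpart <- .compose_source(dataset, full_shape, assignment$F, "F")
  mpart <- .compose_source(dataset, full_shape, assignment$M, "M")
  L <- dataset$n_landmarks
  coords <- array(c(fpart$coords, mpart$coords),
                  c(L, 2L, dim(fpart$coords)[3L] + dim(mpart$coords)[3L]))
  meta <- rbind(fpart$meta, mpart$meta)
  rownames(meta) <- NULL
  comp <- structure(list(coords = coords, labels = dataset$labels,
                         meta = meta, n_individuals = nrow(meta),
                         n_reps = 1L, n_landmarks = L),
                    class = "digit_dataset")
  shape <- gpa(comp)
  cs <- c(fpart$cs, mpart$cs)
  sex_test <- permutation_regression(shape, meta$sex, n_perm = n_perm,
                                     seed = seed)
  allo_test <- permutation_regression(shape, cs, n_perm = n_perm,
                                      seed = if (is.null(seed)) NULL
                                             else seed + 1L)
  bg <- bgpca_crossval(shape, meta$sex)
  list(sex = sex_test, allometry = allo_test, bgpca = bg,
       assignment = assignment)
}

#' Per-REP GPA fits
#'
#' Convenience wrapper: superimposes each REP separately (individuals in a
#' fixed common order) for congruence analyses.
#'
#' @param dataset A `digit_dataset`.
#' @return Named list of `shape_data`, one per REP, ordered by day offset.
#' @export
per_rep_shapes <- function(dataset) {
  rep_info <- unique(dataset$meta[, c("rep_label", "day_offset")])
  rep_info <- rep_info[order(rep_info$day_offset, rep_info$rep_label), ]
  out <- lapply(rep_info$rep_label, function(r) gpa(subset_reps(dataset, r)))
  names(out) <- rep_info$rep_label
  out
}

.congruence_summary <- function(df, kind) {
  structure(list(kind = kind, pairs = df,
                 median = stats::median(df$r),
                 p10 = stats::quantile(df$r, 0.1, names = FALSE),
                 p90 = stats::quantile(df$r, 0.9, names = FALSE)),
            class = "congruence_summary")
}

#' @export
print.congruence_summary <- function(x, ...) {
  cat("Congruence (", x$kind, "): ", nrow(x$pairs), " REP pairs; median ",
      round(x$median, 3), ", p10 ", round(x$p10, 3), ", p90 ",
      round(x$p90, 3), "\n", sep = "")
  invisible(x)
}

#' PC1 congruence between REPs
#'
#' Within-REP PCA, then the absolute Pearson correlation of PC1 scores for
#' every pair of REPs (absolute because the sign of a PC is arbitrary),
#' summarized by median, 10th and 90th percentile.
#'
#' @param shapes Named list of per-REP `shape_data` with the same individuals
#'   in the same order (see [per_rep_shapes()]).
#' @return A `congruence_summary`; `pairs` has rep_a, rep_b, r (= |Pearson|).
#' @export
pc1_congruence <- function(shapes) {
  R <- length(shapes)
  if (R < 2L) stop("need at least 2 REPs")
  n <- length(shapes[[1L]]$cs)
  if (n < 3L) stop("need at least 3 individuals")
  ids <- shapes[[1L]]$meta$individual_id
  pc1 <- vapply(shapes, function(s) {
    stopifnot(identical(s$meta$individual_id, ids))
    shape_pca(s$tangent)$scores[, 1L]
  }, numeric(n))
  pr <- t(utils::combn(R, 2L))
  df <- data.frame(rep_a = names(shapes)[pr[, 1L]],
                   rep_b = names(shapes)[pr[, 2L]],
                   r = abs(stats::cor(pc1)[pr]),
                   stringsAsFactors = FALSE)
  .congruence_summary(df, "PC1_abs_pearson")
}

#' Distance-matrix congruence between REPs
#'
#' Pearson correlation of the vectorized lower triangles (diagonal excluded)
#' of the within-REP Procrustes shape distance matrices, for every pair of
#' REPs, summarized by median, 10th and 90th percentile.
#'
#' @param shapes Named list of per-REP `shape_data` with the same individuals
#'   in the same order.
#' @return A `congruence_summary`; `pairs` has rep_a, rep_b, r.
#' @export
distance_matrix_congruence <- function(shapes) {
  R <- length(shapes)
  if (R < 2L) stop("need at least 2 REPs")
  n <- length(shapes[[1L]]$cs)
  if (n < 3L) stop("need at least 3 individuals")
  ids <- shapes[[1L]]$meta$individual_id
  lt <- vapply(shapes, function(s) {
    stopifnot(identical(s$meta$individual_id, ids))
    d <- procrustes_distance_matrix(s)$d
    d[lower.tri(d)]
  }, numeric(n * (n - 1L) / 2L))
  pr <- t(utils::combn(R, 2L))
  df <- data.frame(rep_a = names(shapes)[pr[, 1L]],
                   rep_b = names(shapes)[pr[, 2L]],
                   r = stats::cor(lt)[pr],
                   stringsAsFactors = FALSE)
  .congruence_summary(df, "distance_matrix_pearson")
}

#' Repeated-measures ANOVA of centroid size across REPs
#'
#' Within each sex, a one-way repeated-measures ANOVA of centroid size with
#' REP as the within-subject factor: F = MS(REP)/MS(residual) on (R - 1) and
#' (R - 1)(n - 1) degrees of freedom (uncorrected for sphericity). Also
#' reports per-REP per-sex centroid-size medians and the between-sex median
#' differences, the yardstick against which REP differences are judged.
#'
#' @param dataset A `digit_dataset` with >= 2 REPs.
#' @return List with `anova` (per sex: F, df, p), `medians` (REP x sex, mm),
#'   `sex_median_diff` (per REP, mm).
#' @export
cs_repeated_measures <- function(dataset) {
  stopifnot(inherits(dataset, "digit_dataset"))
  if (dataset$n_reps < 2L) stop("need at least 2 REPs")
  cs <- apply(dataset$coords, 3L, centroid_size)
  meta <- dataset$meta
  res <- lapply(c("F", "M"), function(s) {
    sel <- meta$sex == s
    d <- data.frame(cs = cs[sel],
                    rep = factor(meta$rep_label[sel]),
                    ind = factor(meta$individual_id[sel]))
    fit <- stats::aov(cs ~ rep + ind, data = d)
    tab <- summary(fit)[[1L]]
    rn <- trimws(rownames(tab))
    ms_rep <- tab[rn == "rep", "Mean Sq"]
    ms_res <- tab[rn == "Residuals", "Mean Sq"]
    df1 <- tab[rn == "rep", "Df"]
    df2 <- tab[rn == "Residuals", "Df"]
    f <- ms_rep / ms_res
    data.frame(sex = s, F = f, df1 = df1, df2 = df2,
               p = stats::pf(f, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  med <- tapply(cs, list(meta$rep_label, meta$sex), stats::median)
  list(anova = do.call(rbind, res),
       medians = med,
       sex_median_diff = med[, "M"] - med[, "F"])
}
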