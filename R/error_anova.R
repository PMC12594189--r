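# Hierarchical Procrustes ANOVA and the measurement-error (ME) ANOVA
# separating systematic from random digitization error, with SNR permutation
# tests, EV ordination and the pairwise time-lag series.

# stack aligned coordinates as an n x 2L matrix (x block then y block)
.flat_tangent <- function(shape) shape$tangent

# sum of squared entries
.ssq <- function(m) sum(m * m)

# group-mean SS: sum over groups of n_g * ||mean_g||^2, computed via rowsum
.group_ss <- function(z, g) {
  s <- rowsum(z, g, reorder = FALSE)
  n_g <- tabulate(factor(g, levels = unique(g)))
  sum(s * s / n_g)
}

#' Hierarchical (type I) Procrustes ANOVA
#'
#' Sequential decomposition of the stacked tangent coordinates into sex,
#' individual-within-sex, and residual (= total measurement error, the
#' variation among REPs of the same individual). Degrees of freedom are
#' multiplied by the shape dimensionality 2L - 4, and Goodall-type F
#' statistics test each level against the hierarchically lower one (sex over
#' individual; individual over total ME), with parametric p-values from the F
#' distribution.
#'
#' @param shape A `shape_data` from [gpa()] on a complete individual x REP
#'   grid.
#' @return A `procrustes_anova` object: list with `table` (effect, df, SS, MS,
#'   F, p, Rsq rows for sex, individual, totME, total) and `shape_dim`.
#' @export
procrustes_anova <- function(shape) {
  Y <- .flat_tangent(shape)
  meta <- shape$meta
  n <- nrow(Y)
  L <- dim(shape$aligned)[1L]
  m <- 2L * L - 4L
  ind <- meta$individual_id
  sex <- meta$sex
  n_ind <- length(unique(ind))
  G <- length(unique(sex))
  if (n == n_ind) stop("a single REP per individual: total ME is undefined")
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- .ssq(Yc)
  ss_sex <- .group_ss(Yc, sex)
  # individual within sex: individual SS minus the sex-mean part
  ss_ind_raw <- .group_ss(Yc, ind)
  ss_ind <- ss_ind_raw - ss_sex
  ss_totme <- ss_total - ss_ind_raw
  df_sex <- (G - 1L) * m
  df_ind <- (n_ind - G) * m
  df_totme <- (n - n_ind) * m
  ms <- c(ss_sex / df_sex, ss_ind / df_ind, ss_totme / df_totme)
  f_sex <- ms[1L] / ms[2L]
  f_ind <- ms[2L] / ms[3L]
  tab <- data.frame(
    effect = c("sex", "individual", "totME", "total"),
    df = c(df_sex, df_ind, df_totme, df_sex + df_ind + df_totme),
    SS = c(ss_sex, ss_ind, ss_totme, ss_total),
    MS = c(ms, NA),
    F = c(f_sex, f_ind, NA, NA),
    p = c(stats::pf(f_sex, df_sex, df_ind, lower.tail = FALSE),
          stats::pf(f_ind, df_ind, df_totme, lower.tail = FALSE), NA, NA),
    Rsq = c(ss_sex, ss_ind, ss_totme, ss_total) / ss_total,
    stringsAsFactors = FALSE)
  structure(list(table = tab, shape_dim = m, ss_type = "I"),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (type I, Goodall-type F; shape dimension ",
      x$shape_dim, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# observed ME-ANOVA sums of squares given centered data and factors.
# Returns c(syst, interaction, rand).
.me_ss <- function(Z, rep_f, cell_f) {
  ss_syst <- .group_ss(Z, rep_f)
  ss_cells <- .group_ss(Z, cell_f)
  ss_int <- ss_cells - ss_syst
  ss_rand <- .ssq(Z) - ss_cells
  c(ss_syst, ss_int, ss_rand)
}

#' Measurement-error ANOVA with SNR permutation tests
#'
#' Separates systematic from random digitization error. Each individual's REP
#' records are centered on the individual's own mean; the centered data are
#' decomposed into a REP main effect (systematic ME, the average difference
#' between REPs), a REP x group interaction (does the bias differ between
#' groups?), and a residual (random ME), using type II sums of squares. The
#' individual effect is computed from the uncentered data. Each effect is
#' tested by its signal-to-noise ratio SNR = SS(effect) / SS(randME), with a
#' permutation p-value obtained by shuffling REP labels within each
#' individual's centered records (for systematic ME and the interaction) or
#' individual labels across records (for the individual effect), p = (count of
#' permuted SNR >= observed + 1) / (n_perm + 1). Rsq = SS(effect) / SS(total).
#'
#' @param shape A `shape_data` on a complete grid with >= 2 REPs.
#' @param n_perm Number of permutations (>= 99, or 0 to skip the tests).
#' @param seed Integer seed for the permutations.
#' @return A `me_anova` object: list with `table` (effect, df, SS, MS, SNR, p,
#'   Rsq for individual, systME, systME:sex, randME, total), `n_perm`, `seed`,
#'   and internal components reused by [ev_ordination()].
#' @export
me_anova <- function(shape, n_perm = 999L, seed = NULL) {
  Y <- .flat_tangent(shape)
  meta <- shape$meta
  n <- nrow(Y)
  ind <- factor(meta$individual_id, levels = unique(meta$individual_id))
  rep_f <- factor(meta$rep_label, levels = unique(meta$rep_label))
  sex <- factor(meta$sex)
  R <- nlevels(rep_f)
  G <- nlevels(sex)
  n_ind <- nlevels(ind)
  if (R < 2L) stop("at least 2 REPs are required")
  if (n_perm != 0L && n_perm < 99L) stop("n_perm must be >= 99 (or 0 to skip)")
  counts <- table(ind, rep_f)
  if (any(counts != 1L)) {
    warning("unbalanced individual x REP grid: results are experimental")
  }
  drop_int <- G < 2L
  if (drop_int) warning("group constant: systME x group interaction dropped")

  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- .ssq(Yc)
  ind_means <- rowsum(Y, ind, reorder = FALSE) / as.vector(table(ind))
  Z <- Y - ind_means[as.integer(ind), , drop = FALSE]
  ss_ind <- .group_ss(Yc, ind)

  cell_f <- if (drop_int) rep_f else interaction(rep_f, sex, drop = TRUE)
  ss <- .me_ss(Z, rep_f, cell_f)
  ss_syst <- ss[1L]; ss_int <- ss[2L]; ss_rand <- ss[3L]

  df_syst <- R - 1L
  df_int <- if (drop_int) 0L else (R - 1L) * (G - 1L)
  df_rand <- n - 1L - (n_ind - 1L) - df_syst - df_int
  df_ind <- n_ind - 1L

  snr <- c(ss_ind, ss_syst, if (!drop_int) ss_int) / ss_rand
  p <- rep(NA_real_, length(snr))
  if (n_perm > 0L) {
    exceed <- numeric(length(snr))
    .with_seed(seed, {
      idx_by_ind <- split(seq_len(n), ind)
      for (b in seq_len(n_perm)) {
        # within-individual shuffle of REP labels for systME / interaction
        pi_w <- unlist(lapply(idx_by_ind, sample), use.names = FALSE)
        Zp <- Z[pi_w, , drop = FALSE]
        ssp <- .me_ss(Zp, rep_f, cell_f)
        if (isTRUE(ssp[1L] / ssp[3L] >= snr[2L])) exceed[2L] <- exceed[2L] + 1
        if (!drop_int && isTRUE(ssp[2L] / ssp[3L] >= snr[3L])) {
          exceed[3L] <- exceed[3L] + 1
        }
        # free shuffle of records over individuals for the individual effect
        pi_f <- sample(n)
        Yp <- Y[pi_f, , drop = FALSE]
        im <- rowsum(Yp, ind, reorder = FALSE) / as.vector(table(ind))
        Zf <- Yp - im[as.integer(ind), , drop = FALSE]
        ss_ind_p <- .group_ss(sweep(Yp, 2L, colMeans(Yp)), ind)
        ssf <- .me_ss(Zf, rep_f, cell_f)
        if (isTRUE(ss_ind_p / ssf[3L] >= snr[1L])) exceed[1L] <- exceed[1L] + 1
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }

  eff <- c("individual", "systME", if (!drop_int) "systME:sex", "randME")
  df <- c(df_ind, df_syst, if (!drop_int) df_int, df_rand)
  SS <- c(ss_ind, ss_syst, if (!drop_int) ss_int, ss_rand)
  tab <- data.frame(
    effect = c(eff, "total"),
    df = c(df, n - 1L),
    SS = c(SS, ss_total),
    MS = c(SS / df, NA),
    SNR = c(snr, NA, NA)[seq_len(length(eff) + 1L)],
    p = c(p, NA, NA)[seq_len(length(eff) + 1L)],
    Rsq = c(SS, ss_total) / ss_total,
    stringsAsFactors = FALSE)
  tab$SNR[tab$effect == "randME"] <- NA
  tab$p[tab$effect == "randME"] <- NA
  structure(list(table = tab, n_perm = n_perm, seed = seed, ss_type = "II",
                 centered = Z, rep_f = rep_f, cell_f = cell_f,
                 ss_rand = ss_rand, ss_syst = ss_syst),
            class = "me_anova")
}

#' @export
print.me_anova <- function(x, ...) {
  cat("ME ANOVA (type II SS; SNR = SS(effect)/SS(randME); ",
      x$n_perm, " permutations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' EV ordination of systematic measurement error
#'
#' Generalized eigenvectors of the systematic-ME cross-product matrix relative
#' to the random-ME cross-product matrix: the axes maximizing systematic
#' relative to random ME variance. Individual-mean-centered records of all
#' REPs are projected onto the leading R - 1 axes; axis variance fractions are
#' relative eigenvalues within the systematic-ME subspace only.
#'
#' The random-ME scatter must be inverted in a high-dimensional, rank-
#' deficient shape space. The computation is restricted to the principal
#' subspace of the centered data; within it, the default `regularize = "lw"`
#' applies Ledoit-Wolf shrinkage of the random-ME covariance toward a scaled
#' identity before whitening. The shrinkage intensity is estimated from the
#' residuals themselves: with near-isotropic random ME it approaches 1,
#' protecting the leading axis from the eigenvalue noise of a plain inverted
#' sample covariance, while clearly anisotropic random ME keeps its structure.
#' `regularize = "none"` uses the tolerance-thresholded pseudo-inverse
#' instead.
#'
#' @param me A `me_anova` object.
#' @param shape The `shape_data` the ME ANOVA was computed from.
#' @param regularize `"lw"` (Ledoit-Wolf shrinkage, default) or `"none"`
#'   (plain pseudo-inverse).
#' @param tol Relative eigenvalue tolerance defining the usable subspace;
#'   default 1e-10.
#' @return List with `scores` (n x (R-1)), `axes` (2L x (R-1), unit norm),
#'   `axis_variance_fraction` (length R-1, non-increasing, sums to 1),
#'   `shrinkage` (intensity used, NA for "none") and `rep_label`.
#' @export
ev_ordination <- function(me, shape, regularize = c("lw", "none"),
                          tol = 1e-10) {
  stopifnot(inherits(me, "me_anova"))
  regularize <- match.arg(regularize)
  Z <- me$centered
  rep_f <- me$rep_f
  R <- nlevels(rep_f)
  n_ax <- R - 1L
  # restrict to the principal subspace actually spanned by the centered data
  et <- eigen(crossprod(Z), symmetric = TRUE)
  keep <- et$values > tol * max(et$values)
  if (!any(keep)) stop("centered data have no usable rank")
  B <- et$vectors[, keep, drop = FALSE]
  Ze <- Z %*% B
  s <- rowsum(Ze, rep_f, reorder = FALSE)
  n_r <- tabulate(factor(rep_f, levels = unique(rep_f)))
  rep_means <- s / n_r
  S_syst <- crossprod(rep_means * sqrt(n_r))
  cell_app <- unique(me$cell_f)
  cell_means <- rowsum(Ze, me$cell_f, reorder = FALSE) /
    tabulate(factor(me$cell_f, levels = cell_app))
  E <- Ze - cell_means[match(me$cell_f, cell_app), , drop = FALSE]
  r <- ncol(Ze)
  n <- nrow(Ze)
  shrink <- NA_real_
  if (regularize == "lw") {
    S <- crossprod(E) / n
    mu <- sum(diag(S)) / r
    d2 <- sum((S - diag(mu, r))^2)
    if (d2 < .Machine$double.eps * mu^2) {
      S_rand <- diag(mu, r)
      shrink <- 1
    } else {
      b2 <- (sum(rowSums(E^2)^2) / n - sum(S^2)) / n
      shrink <- min(1, max(0, b2 / d2))
      S_rand <- shrink * diag(mu, r) + (1 - shrink) * S
    }
    er <- eigen(S_rand, symmetric = TRUE)
    usable <- er$values > tol * max(er$values)
  } else {
    S_rand <- crossprod(E)
    er <- eigen(S_rand, symmetric = TRUE)
    usable <- er$values > tol * max(er$values)
  }
  if (!any(usable)) stop("random-ME cross-product has no usable rank")
  W <- er$vectors[, usable, drop = FALSE] %*%
    diag(1 / sqrt(er$values[usable]), sum(usable))
  M <- crossprod(W, S_syst %*% W)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(n_ax, ncol(W))
  axes <- B %*% (W %*% em$vectors[, seq_len(k), drop = FALSE])
  axes <- sweep(axes, 2L, sqrt(colSums(axes^2)), "/")
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  lambda <- pmax(em$values[seq_len(k)], 0)
  list(scores = Z %*% axes, axes = axes,
       axis_variance_fraction = lambda / sum(lambda),
       shrinkage = shrink, rep_label = as.character(rep_f))
}

#' Pairwise time-lag series of ME ANOVAs
#'
#' For every non-reference REP, rebuilds a 2-REP dataset (reference + that
#' REP), re-runs GPA on that subset, runs the ME ANOVA, and reports Rsq, SNR
#' and p per effect, ordered by increasing day lag. This is the planned
#' comparison series probing whether systematic ME grows with the time lag
#' between digitization sessions.
#'
#' @param dataset A `digit_dataset` (raw coordinates).
#' @param reference Reference REP label (default the first by day offset).
#' @param n_perm Permutations per comparison.
#' @param seed Integer seed; comparison k uses seed + k.
#' @return A `timelag_series` object: list with `reference` and `comparisons`
#'   (data frame: rep, lag_days, effect, df, SS, SNR, p, Rsq).
#' @export
pairwise_timelag_series <- function(dataset, reference = NULL, n_perm = 999L,
                                    seed = NULL) {
  stopifnot(inherits(dataset, "digit_dataset"))
  meta <- dataset$meta
  rep_info <- unique(meta[, c("rep_label", "day_offset")])
  rep_info <- rep_info[order(rep_info$day_offset, rep_info$rep_label), ]
  if (is.null(reference)) reference <- rep_info$rep_label[1L]
  if (!reference %in% rep_info$rep_label) {
    stop("reference REP ", reference, " not present")
  }
  others <- rep_info[rep_info$rep_label != reference, , drop = FALSE]
  ref_day <- rep_info$day_offset[rep_info$rep_label == reference]
  rows <- vector("list", nrow(others))
  for (k in seq_len(nrow(others))) {
    sub <- subset_reps(dataset, c(reference, others$rep_label[k]))
    me <- me_anova(gpa(sub), n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else seed + k)
    tb <- me$table[me$table$effect != "total", , drop = FALSE]
    rows[[k]] <- data.frame(rep = others$rep_label[k],
                            lag_days = others$day_offset[k] - ref_day,
                            tb, stringsAsFactors = FALSE)
  }
  structure(list(reference = reference,
                 comparisons = do.call(rbind, rows)),
            class = "timelag_series")
}

#' @export
print.timelag_series <- function(x, ...) {
  cat("Pairwise ME-ANOVA time-lag series (reference ", x$reference, ")\n",
      sep = "")
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}
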