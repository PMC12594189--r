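# helper: explicit least-squares oracle for sums of squares via per-column lm
.rss <- function(formula, data, Y) {
  sum(vapply(seq_len(ncol(Y)), function(j) {
    d <- data
    d$y <- Y[, j]
    sum(stats::resid(stats::lm(formula, data = d))^2)
  }, numeric(1)))
}

test_that("study-design degrees of freedom match the analytic identities", {
  sim <- generate_dataset(synth_params(seed = 3))
  sh <- gpa(sim$dataset)
  pa <- procrustes_anova(sh)
  expect_identical(pa$table$df[pa$table$effect == "sex"], 48L)
  expect_identical(pa$table$df[pa$table$effect == "individual"], 2688L)
  expect_identical(pa$table$df[pa$table$effect == "totME"], 19488L)
  me <- me_anova(sh, n_perm = 0L)
  expect_identical(me$table$df[me$table$effect == "systME"], 7L)
  expect_identical(me$table$df[me$table$effect == "systME:sex"], 7L)
  expect_identical(me$table$df[me$table$effect == "randME"], 392L)
  expect_identical(me$table$df[me$table$effect == "individual"], 57L)
  # type I rows sum to the total
  expect_equal(sum(pa$table$SS[1:3]), pa$table$SS[4],
               tolerance = 1e-9 * pa$table$SS[4])
})

test_that("tiny-instance decompositions equal design-matrix oracles", {
  p <- tiny_params(n_individuals = 3L, n_reps = 2L, n_landmarks = 4L,
                   seed = 5)
  sim <- generate_dataset(p)
  sh <- gpa(sim$dataset)
  Y <- sh$tangent
  meta <- sh$meta
  d <- data.frame(sex = factor(meta$sex),
                  ind = factor(meta$individual_id),
                  rep = factor(meta$rep_label))
  # type I: sequential projections sex -> individual -> residual
  rss0 <- .rss(y ~ 1, d, Y)
  rss_sex <- .rss(y ~ sex, d, Y)
  rss_ind <- .rss(y ~ sex + ind, d, Y)
  pa <- procrustes_anova(sh)
  expect_equal(pa$table$SS[pa$table$effect == "sex"], rss0 - rss_sex,
               tolerance = 1e-10)
  expect_equal(pa$table$SS[pa$table$effect == "individual"],
               rss_sex - rss_ind, tolerance = 1e-10)
  expect_equal(pa$table$SS[pa$table$effect == "totME"], rss_ind,
               tolerance = 1e-10)
  # type II on individual-centered data: full-vs-reduced model comparisons
  me <- me_anova(sh, n_perm = 0L)
  ind_means <- rowsum(Y, d$ind) / as.vector(table(d$ind))
  Z <- Y - ind_means[as.integer(d$ind), ]
  rss_sex_only <- .rss(y ~ sex, d, Z)
  rss_sex_rep <- .rss(y ~ sex + rep, d, Z)
  rss_full <- .rss(y ~ sex * rep, d, Z)
  expect_equal(me$table$SS[me$table$effect == "systME"],
               rss_sex_only - rss_sex_rep, tolerance = 1e-10)
  expect_equal(me$table$SS[me$table$effect == "systME:sex"],
               rss_sex_rep - rss_full, tolerance = 1e-10)
  expect_equal(me$table$SS[me$table$effect == "randME"], rss_full,
               tolerance = 1e-10)
  # individual SS from the uncentered data
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(me$table$SS[me$table$effect == "individual"],
               sum(vapply(levels(d$ind), function(i) {
                 sum(colMeans(Yc[d$ind == i, , drop = FALSE])^2) *
                   sum(d$ind == i)
               }, numeric(1))), tolerance = 1e-10)
})

test_that("type II sums of squares do not depend on effect-entry order", {
  p <- tiny_params(n_individuals = 5L, n_reps = 3L, n_landmarks = 5L,
                   seed = 15)
  sim <- generate_dataset(p)
  sh <- gpa(sim$dataset)
  me <- me_anova(sh, n_perm = 0L)
  # reorder records and recompute: SS unchanged
  perm <- order(sh$meta$rep_label, sh$meta$individual_id)
  sh2 <- sh
  sh2$tangent <- sh$tangent[perm, ]
  sh2$aligned <- sh$aligned[, , perm]
  sh2$cs <- sh$cs[perm]
  sh2$meta <- sh$meta[perm, ]
  me2 <- me_anova(sh2, n_perm = 0L)
  for (e in c("individual", "systME", "systME:sex", "randME")) {
    expect_equal(me$table$SS[me$table$effect == e],
                 me2$table$SS[me2$table$effect == e], tolerance = 1e-10)
    expect_gte(me$table$SS[me$table$effect == e], 0)
  }
})

test_that("exactly null REP means give SNR 0 with p = 1", {
  # build a shape_data whose within-individual REP structure is removed
  p <- tiny_params(n_individuals = 8L, n_reps = 4L, seed = 25)
  sh <- gpa(generate_dataset(p)$dataset)
  ind <- factor(sh$meta$individual_id, levels = unique(sh$meta$individual_id))
  rep_f <- factor(sh$meta$rep_label, levels = unique(sh$meta$rep_label))
  ind_means <- rowsum(sh$tangent, ind) / as.vector(table(ind))
  Z <- sh$tangent - ind_means[as.integer(ind), ]
  rep_means <- rowsum(Z, rep_f) / as.vector(table(rep_f))
  sh$tangent <- sh$tangent - rep_means[as.integer(rep_f), ]
  me <- me_anova(sh, n_perm = 199L, seed = 1L)
  expect_lt(me$table$SNR[me$table$effect == "systME"], 1e-20)
  expect_gt(me$table$p[me$table$effect == "systME"], 0.99)
})

test_that("SNR and Rsq are invariant to rigid motion and global rescaling", {
  p <- tiny_params(seed = 35)
  sim <- generate_dataset(p)
  me1 <- me_anova(gpa(sim$dataset), n_perm = 0L)
  ds <- sim$dataset
  for (i in seq_len(nrow(ds$meta))) {
    ds <- transform_record(ds, i, angle_deg = 33, scale = 2.5,
                           shift = c(-7, 19))
  }
  me2 <- me_anova(gpa(ds), n_perm = 0L)
  expect_equal(me1$table$SNR, me2$table$SNR, tolerance = 1e-8)
  expect_equal(me1$table$Rsq, me2$table$Rsq, tolerance = 1e-8)
})

test_that("permutation p-values are deterministic given the seed", {
  p <- tiny_params(seed = 45)
  sh <- gpa(generate_dataset(p)$dataset)
  m1 <- me_anova(sh, n_perm = 99L, seed = 7L)
  m2 <- me_anova(sh, n_perm = 99L, seed = 7L)
  expect_identical(m1$table$p, m2$table$p)
  expect_error(me_anova(sh, n_perm = 50L), ">= 99")
})

test_that("EV ordination spans R-1 axes and finds an injected bias", {
  p <- tiny_params(n_individuals = 10L, n_reps = 4L, seed = 55)
  sh <- gpa(generate_dataset(p)$dataset)
  me <- me_anova(sh, n_perm = 0L)
  ev <- ev_ordination(me, sh)
  expect_identical(ncol(ev$axes), 3L)
  expect_equal(sum(ev$axis_variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(ev$axis_variance_fraction) <= 1e-12))
  # two REPs: a single axis carrying all systematic-ME variance
  two <- subset_reps(generate_dataset(p)$dataset,
                     unique(sh$meta$rep_label)[1:2])
  sh2 <- gpa(two)
  ev2 <- ev_ordination(me_anova(sh2, n_perm = 0L), sh2)
  expect_identical(ncol(ev2$axes), 1L)
  expect_equal(ev2$axis_variance_fraction, 1)
  # a single injected bias direction dominates EV1
  pb <- null_params(n_individuals = 40L, n_reps = 4L, n_landmarks = 10L,
                    seed = 56, rotation_sd_deg = 0,
                    sigma_landmark = rep(0.1, 10L))
  dir <- digitME:::.shape_direction(pb$template, tag = 77L)
  pb$rep_bias[[3]] <- 3 * dir
  simb <- generate_dataset(pb)
  shb <- gpa(simb$dataset)
  meb <- me_anova(shb, n_perm = 0L)
  evb <- ev_ordination(meb, shb)
  # reference direction: the injected bias expressed at the fitted consensus
  cons <- shb$consensus
  biased <- cons + 3 * dir / mean(shb$cs)
  biased <- sweep(biased, 2, colMeans(biased))
  biased <- biased / centroid_size(biased)
  ref <- c(biased - cons)
  ref <- ref / sqrt(sum(ref^2))
  expect_gt(abs(sum(evb$axes[, 1] * ref)), 0.99)
})

test_that("the time-lag series orders comparisons and finds the biased REP", {
  p <- null_params(n_individuals = 12L, n_reps = 5L, n_landmarks = 8L,
                   seed = 65)
  dir <- digitME:::.shape_direction(p$template, tag = 88L)
  p$rep_bias[[5]] <- 2.5 * dir          # bias only in the largest-lag REP
  sim <- generate_dataset(p)
  ts <- pairwise_timelag_series(sim$dataset, n_perm = 0L)
  syst <- ts$comparisons[ts$comparisons$effect == "systME", ]
  expect_identical(nrow(syst), 4L)
  expect_false(is.unsorted(syst$lag_days))
  expect_identical(syst$rep[which.max(syst$Rsq)],
                   names(p$day_offsets)[5])
  expect_error(pairwise_timelag_series(sim$dataset, reference = "zz"),
               "not present")
  # a REP that duplicates the reference shows zero systematic ME
  ds <- sim$dataset
  ref_rows <- which(ds$meta$rep_label == names(p$day_offsets)[1])
  dup_rows <- which(ds$meta$rep_label == names(p$day_offsets)[2])
  ds$coords[, , dup_rows] <- ds$coords[, , ref_rows]
  ts2 <- pairwise_timelag_series(ds, n_perm = 0L)
  s2 <- ts2$comparisons
  expect_lt(s2$SS[s2$effect == "systME" & s2$rep == names(p$day_offsets)[2]],
            1e-18)
})

test_that("eight REPs yield seven planned comparisons", {
  sim <- generate_dataset(synth_params(seed = 66))
  ts <- pairwise_timelag_series(sim$dataset, n_perm = 0L)
  expect_identical(length(unique(ts$comparisons$rep)), 7L)
  expect_false(ts$reference %in% ts$comparisons$rep)
})
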