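test_that("centroid size matches hand computation and a direct oracle", {
  sq <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(matrix(5, 7, 2)), 0)
  set.seed(3)
  for (k in 1:5) {
    cf <- random_config(26L)
    # brute-force oracle: explicit loop over landmark-centroid distances
    ctr <- c(mean(cf[, 1]), mean(cf[, 2]))
    acc <- 0
    for (l in seq_len(nrow(cf))) {
      acc <- acc + (cf[l, 1] - ctr[1])^2 + (cf[l, 2] - ctr[2])^2
    }
    expect_equal(centroid_size(cf), sqrt(acc), tolerance = 1e-12)
  }
})

test_that("GPA aligns identical and similarity-transformed configurations", {
  set.seed(4)
  base <- random_config(10L)
  coords <- array(rep(base, 4), c(10L, 2L, 4L))
  meta <- data.frame(individual_id = paste0("i", 1:4), sex = "F",
                     rep_label = "r1", day_offset = 1L)
  ds <- list(coords = coords, labels = paste0("L", 1:10), meta = meta)
  sh <- gpa(ds)
  dm <- procrustes_distance_matrix(sh)$d
  expect_lt(max(dm), 1e-10)
  # consensus equals the shared shape up to similarity: distance 0
  expect_equal(unname(sh$aligned[, , 1]), unname(sh$consensus),
               tolerance = 1e-9)
  # rotated / translated / rescaled copy aligns to distance < 1e-10
  ds2 <- ds
  ds2 <- transform_record(ds2, 2, angle_deg = 117, scale = 3.7,
                          shift = c(40, -13))
  sh2 <- gpa(ds2)
  expect_lt(procrustes_distance_matrix(sh2)$d[1, 2], 1e-10)
})

test_that("GPA output is invariant to similarity transforms of records", {
  sim <- generate_dataset(tiny_params(seed = 9))
  sh <- gpa(sim$dataset)
  set.seed(10)
  for (k in 1:5) {
    ds <- sim$dataset
    i <- sample(nrow(ds$meta), 1)
    ds <- transform_record(ds, i, angle_deg = stats::runif(1, -180, 180),
                           scale = stats::runif(1, 0.2, 5),
                           shift = stats::rnorm(2, sd = 50))
    sh2 <- gpa(ds)
    expect_equal(sh2$aligned, sh$aligned, tolerance = 1e-9)
  }
  # per-record centroid at origin and unit centroid size
  for (i in seq_len(dim(sh$aligned)[3])) {
    expect_lt(max(abs(colMeans(sh$aligned[, , i]))), 1e-9)
    expect_equal(centroid_size(sh$aligned[, , i]), 1, tolerance = 1e-9)
  }
})

test_that("two-configuration fit matches a brute-force rotation grid", {
  t1 <- matrix(c(0, 4, 1, 0, 0, 3), 3, 2)
  t2 <- matrix(c(0, 5, -1, 0, 1, 2.5), 3, 2)
  ds <- list(coords = array(c(t1, t2), c(3L, 2L, 2L)),
             labels = paste0("L", 1:3),
             meta = data.frame(individual_id = c("a", "b"), sex = "F",
                               rep_label = "r1", day_offset = 1L))
  sh <- gpa(ds)
  fitted_d <- procrustes_distance_matrix(sh)$d[1, 2]
  # oracle: center, scale to unit CS, search rotations on a 0.001 degree grid
  norm1 <- sweep(t1, 2, colMeans(t1)); norm1 <- norm1 / centroid_size(t1)
  norm2 <- sweep(t2, 2, colMeans(t2)); norm2 <- norm2 / centroid_size(t2)
  resid_at <- function(deg) {
    th <- deg * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((norm1 %*% t(rot) - norm2)^2))
  }
  coarse <- seq(0, 360, by = 0.1)
  r0 <- vapply(coarse, resid_at, numeric(1))
  fine <- seq(coarse[which.min(r0)] - 0.1, coarse[which.min(r0)] + 0.1,
              by = 0.001)
  best <- min(vapply(fine, resid_at, numeric(1)))
  expect_equal(fitted_d, best, tolerance = 1e-6)
})

test_that("distance matrix matches per-pair recomputation", {
  sim <- generate_dataset(tiny_params(seed = 12))
  sh <- gpa(sim$dataset)
  dm <- procrustes_distance_matrix(sh)
  expect_equal(dm$d, t(dm$d), tolerance = 1e-12)
  expect_true(all(diag(dm$d) == 0))
  set.seed(13)
  for (k in 1:10) {
    ij <- sample(nrow(sh$meta), 2)
    direct <- sqrt(sum((sh$aligned[, , ij[1]] - sh$aligned[, , ij[2]])^2))
    expect_equal(dm$d[ij[1], ij[2]], direct, tolerance = 1e-12)
  }
})

test_that("tangent diagnostic tracks the geodesic metric", {
  # low dispersion: flat-space approximation nearly exact
  p <- tiny_params(n_individuals = 10L, seed = 21,
                   sigma_individual = 0.001)
  p$sigma_landmark <- rep(0.135, p$n_landmarks)  # ~1e-3 of CS
  sh <- gpa(generate_dataset(p)$dataset)
  td <- tangent_diagnostic(sh)
  expect_gt(td$r, 0.999)
  expect_lt(abs(td$slope - 1), 0.01)
  # wide dispersion: slope < 1 (chord shorter than arc), matches per-pair oracle
  set.seed(22)
  coords <- array(stats::rnorm(6 * 2 * 12, sd = 1), c(6, 2, 12))
  ds <- list(coords = coords, labels = paste0("L", 1:6),
             meta = data.frame(individual_id = paste0("i", 1:12), sex = "F",
                               rep_label = "r1", day_offset = 1L))
  shw <- gpa(ds)
  tdw <- tangent_diagnostic(shw)
  expect_lt(tdw$slope, 1)
  expect_lt(tdw$r, 1)
  # chord never exceeds the geodesic arc, pairwise
  n <- 12
  for (k in 1:10) {
    ij <- sample(n, 2)
    a <- shw$aligned[, , ij[1]]; b <- shw$aligned[, , ij[2]]
    chord <- sqrt(sum((a - b)^2))
    ip <- min(1, sum(a * b))
    expect_lte(chord, acos(ip) + 1e-12)
  }
})

test_that("PCA reproduces covariance with deterministic signs", {
  set.seed(31)
  x <- matrix(stats::rnorm(200 * 6), 200, 6) %*% diag(c(3, 2, 1, 1, 0.5, 0.1))
  pc <- shape_pca(x)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-12)
  # scores' covariance is diagonal with the eigenvalues on the diagonal
  cv <- crossprod(sweep(pc$scores, 2, colMeans(pc$scores))) / (nrow(x) - 1)
  expect_equal(unname(cv), diag(pc$eigenvalues), tolerance = 1e-8)
  # covariance reconstruction from scores and vectors
  rec <- pc$vectors %*% diag(pc$eigenvalues) %*% t(pc$vectors)
  expect_equal(rec, stats::cov(x), tolerance = 1e-8)
  # sign convention: flipping input signs yields identical axes
  pc2 <- shape_pca(-x)
  expect_equal(abs(pc2$vectors), abs(pc$vectors), tolerance = 1e-8)
  for (j in seq_along(pc$eigenvalues)) {
    expect_gte(pc$vectors[which.max(abs(pc$vectors[, j])), j], 0)
  }
  # isotropic 2D cloud: two comparable eigenvalues
  y <- matrix(stats::rnorm(4000), 2000, 2)
  pcy <- shape_pca(y)
  expect_lt(pcy$eigenvalues[1] / pcy$eigenvalues[2], 1.2)
})

test_that("shape space of the full design has 2L-4 informative dimensions", {
  sim <- generate_dataset(synth_params(seed = 2))
  sh <- gpa(sim$dataset)
  pc <- shape_pca(sh$tangent, tol = 1e-8)
  expect_identical(length(pc$eigenvalues), 48L)
})

test_that("outlier ranking responds to an injected displacement", {
  p <- tiny_params(n_individuals = 8L, seed = 41)
  sim <- generate_dataset(p)
  ds <- sim$dataset
  # displace one landmark of one record far beyond the digitization noise
  ds$coords[3, , 7] <- ds$coords[3, , 7] + 30 * 0.4
  sh <- gpa(ds)
  out <- flag_outliers(sh)
  expect_identical(paste(out$individual_id[1], out$rep_label[1]),
                   paste(ds$meta$individual_id[7], ds$meta$rep_label[7]))
  # ranking invariant to record order
  perm <- rev(seq_len(nrow(ds$meta)))
  ds2 <- ds
  ds2$coords <- ds2$coords[, , perm]
  ds2$meta <- ds2$meta[perm, ]
  out2 <- flag_outliers(gpa(ds2))
  expect_equal(out$distance, out2$distance, tolerance = 1e-9)
  expect_identical(out$individual_id, out2$individual_id)
})

test_that("phenograms agglomerate like the hand-computed linkage", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3)
  dm <- list(d = d, labels = c("A", "B", "C"))
  tr <- cluster_phenogram(dm, "UPGMA")
  cop <- ape::cophenetic.phylo(tr)
  # first merge (A,B) at height 1; C joins at average distance 4
  expect_equal(cop["A", "B"], 1)
  expect_equal(cop["A", "C"], 4)
  expect_equal(cop["B", "C"], 4)
  tn <- cluster_phenogram(dm, "NN")
  expect_equal(ape::cophenetic.phylo(tn)["A", "B"], 1)
  # two tight, well-separated groups: first bipartition separates them
  set.seed(51)
  g1 <- matrix(stats::rnorm(5 * 2, sd = 0.05), 5, 2)
  g2 <- matrix(stats::rnorm(5 * 2, sd = 0.05) + 10, 5, 2)
  pts <- rbind(g1, g2)
  dd <- as.matrix(stats::dist(pts))
  labs <- c(paste0("a", 1:5), paste0("b", 1:5))
  tr2 <- cluster_phenogram(list(d = dd, labels = labs), "UPGMA")
  # the root splits the tips exactly into the two groups
  sub <- ape::extract.clade(tr2, ape::getMRCA(tr2, paste0("a", 1:5)))
  expect_setequal(sub$tip.label, paste0("a", 1:5))
})
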