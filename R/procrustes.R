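# Centroid size, generalized Procrustes superimposition (2D), tangent-space
# diagnostics, shape distances, PCA, outlier ranking and phenograms.
#
# 2D configurations are handled internally as complex vectors (x + iy): the
# rotation of z that best fits w in the least-squares sense is multiplication
# by the unit complex number conj(sum(Conj(z) * w)) normalized, which never
# reflects. This gives a closed-form rotation step in the GPA loop.

#' Centroid size of a landmark configuration
#'
#' The square root of the sum of squared distances between the landmarks and
#' their centroid (the mean point of the configuration).
#'
#' @param coords L x 2 numeric matrix of landmark coordinates (mm).
#' @return Non-negative scalar; zero iff all landmarks coincide.
#' @export
centroid_size <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L, all(is.finite(coords)))
  ctr <- colMeans(coords)
  sqrt(sum((coords[, 1L] - ctr[1L])^2 + (coords[, 2L] - ctr[2L])^2))
}

# dataset coords array -> n x L complex matrix (rows = records)
.as_complex <- function(coords) {
  L <- dim(coords)[1L]
  n <- dim(coords)[3L]
  z <- matrix(complex(real = coords[, 1L, ], imaginary = coords[, 2L, ]), L, n)
  t(z)
}

# n x L complex matrix -> L x 2 x n array
.as_array <- function(z) {
  n <- nrow(z); L <- ncol(z)
  a <- array(NA_real_, c(L, 2L, n))
  a[, 1L, ] <- t(Re(z)); a[, 2L, ] <- t(Im(z))
  a
}

#' Generalized Procrustes superimposition (2D)
#'
#' Centers each configuration, scales it to unit centroid size, and rotates it
#' (rotation only, no reflection) to minimize the summed squared distance to an
#' iteratively updated consensus, itself kept at unit centroid size. Iteration
#' stops when the consensus changes by less than `tol` (Frobenius norm) or
#' after `max_iter` sweeps. Tangent-plane coordinates are the aligned
#' coordinates projected orthogonally to the consensus direction.
#'
#' @param dataset A `digit_dataset` (or any list with an L x 2 x n `coords`
#'   array and a `meta` data frame).
#' @param tol Convergence tolerance on the consensus change; default 1e-10.
#' @param max_iter Maximum iterations; default 100.
#' @return A `shape_data`: list with `aligned` (L x 2 x n array, unit centroid
#'   size), `consensus` (L x 2, unit centroid size), `cs` (n centroid sizes,
#'   mm), `tangent` (n x 2L matrix of tangent coordinates), `labels`, `meta`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  coords <- dataset$coords
  n <- dim(coords)[3L]
  L <- dim(coords)[1L]
  if (L < 3L) stop("at least 3 landmarks are required for shape analysis")
  z <- .as_complex(coords)
  z <- z - rowMeans(z)                      # center
  cs <- sqrt(rowSums(Mod(z)^2))             # centroid size
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    stop("degenerate configuration(s) with zero centroid size at record(s) ",
         paste(bad, collapse = ", "))
  }
  z <- z / cs                               # unit centroid size
  consensus <- z[1L, ]                      # init: first record
  consensus <- consensus / sqrt(sum(Mod(consensus)^2))
  it <- 0L
  repeat {
    it <- it + 1L
    # optimal rotation of each row onto the consensus
    inner <- z %*% Conj(consensus)          # n x 1
    rot <- Conj(inner) / Mod(inner)
    z <- z * as.vector(rot)
    new_cons <- colMeans(z)
    new_cons <- new_cons - mean(new_cons)
    new_cons <- new_cons / sqrt(sum(Mod(new_cons)^2))
    delta <- sqrt(sum(Mod(new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
    if (it >= max_iter) {
      stop("GPA did not converge in ", max_iter,
           " iterations (last consensus change ", format(delta), ")")
    }
  }
  # final rotation pass onto the converged consensus
  inner <- z %*% Conj(consensus)
  z <- z * as.vector(Conj(inner) / Mod(inner))
  # canonical frame, so the fit does not depend on the record used to
  # initialize: principal axis of the consensus along x, then the pi
  # ambiguity resolved by the sign of the first landmark's x coordinate
  mu <- sum(consensus^2)
  if (Mod(mu) > 1e-12) {
    spin <- exp(complex(imaginary = -Arg(mu) / 2))
    consensus <- consensus * spin
    z <- z * spin
  }
  if (Re(consensus[1L]) < 0) {
    consensus <- -consensus
    z <- -z
  }
  aligned <- .as_array(z)
  cons_m <- cbind(Re(consensus), Im(consensus))
  tangent <- .tangent_coords(z, consensus)
  labels <- dataset$labels
  if (is.null(labels)) labels <- paste0("L", seq_len(L))
  dimnames(aligned) <- list(labels, c("x", "y"), NULL)
  rownames(cons_m) <- labels
  structure(list(aligned = aligned, consensus = cons_m, cs = cs,
                 tangent = tangent, labels = labels, meta = dataset$meta,
                 iterations = it),
            class = "shape_data")
}

# orthogonal projection of aligned shapes onto the tangent plane at the
# consensus: t_i = z_i - <z_i, c> c, returned as n x 2L real matrix (x then y)
.tangent_coords <- function(z, consensus) {
  # real inner product of flattened (x, y) vectors = Re(<z, conj pairing>)
  ip <- Re(z %*% Conj(consensus))           # n x 1 real inner products
  zt <- z - ip %*% t(consensus)
  cbind(Re(zt), Im(zt))
}

#' @export
print.shape_data <- function(x, ...) {
  cat("Procrustes shape data:", length(x$cs), "records,",
      nrow(x$consensus), "landmarks; GPA converged in", x$iterations,
      "iterations\n")
  invisible(x)
}

#' Pairwise Procrustes shape distance matrix
#'
#' Euclidean distances between GPA-aligned coordinate vectors (the standard
#' tangent/partial-Procrustes proxy for the Procrustes distance, which is
#' near-identical to the geodesic metric in low-dispersion data; see
#' [tangent_diagnostic()]).
#'
#' @param shape A `shape_data` from [gpa()].
#' @return List with `d` (n x n symmetric matrix, zero diagonal) and `labels`
#'   (record keys "individual:rep").
#' @export
procrustes_distance_matrix <- function(shape) {
  flat <- cbind(matrix(shape$aligned[, 1L, ], ncol = dim(shape$aligned)[1L],
                       byrow = TRUE),
                matrix(shape$aligned[, 2L, ], ncol = dim(shape$aligned)[1L],
                       byrow = TRUE))
  d <- as.matrix(stats::dist(flat))
  labs <- paste(shape$meta$individual_id, shape$meta$rep_label, sep = ":")
  dimnames(d) <- list(labs, labs)
  list(d = d, labels = labs)
}

#' Tangent-space approximation diagnostic
#'
#' Correlates pairwise Euclidean distances in the tangent plane with the
#' corresponding Procrustes geodesic distances (rho = arccos of the inner
#' product of aligned unit-size shapes) and reports the origin-centered
#' regression slope of tangent on geodesic distances. Values of r ~ 1 and
#' slope ~ 1 indicate an excellent flat approximation of shape space.
#'
#' @param shape A `shape_data`.
#' @return List with `r` (Pearson correlation) and `slope` (sum(xy)/sum(xx)).
#' @export
tangent_diagnostic <- function(shape) {
  n <- length(shape$cs)
  if (n < 3L) stop("need at least 3 records")
  z <- matrix(complex(real = t(matrix(shape$aligned[, 1L, ],
                                      nrow = dim(shape$aligned)[1L])),
                      imaginary = t(matrix(shape$aligned[, 2L, ],
                                           nrow = dim(shape$aligned)[1L]))),
              nrow = n)
  tang <- as.matrix(stats::dist(cbind(Re(z), Im(z))))
  # geodesic: rho = acos(|<z_i, z_j>|) on aligned unit-size shapes
  g <- Mod(z %*% Conj(t(z)))
  g[g > 1] <- 1
  geo <- acos(g)
  lt <- lower.tri(tang)
  x <- geo[lt]; y <- tang[lt]
  if (all(x < 1e-14)) stop("no shape variation: all shapes identical")
  r <- if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) 1 else
    stats::cor(x, y)
  list(r = r, slope = sum(x * y) / sum(x * x))
}

#' Principal component analysis of shape coordinates
#'
#' Eigendecomposition of the sample covariance matrix of the input rows, with
#' a deterministic sign convention: each eigenvector's largest-magnitude
#' loading is made positive. Variance fractions are computed over the positive
#' eigenvalues only (shape data lose 4 dimensions in superimposition).
#'
#' @param x n x p numeric matrix (rows = observations), e.g. `shape$tangent`.
#' @param tol Relative eigenvalue threshold below which dimensions are treated
#'   as null; default 1e-10.
#' @return List with `scores` (n x k), `eigenvalues` (k, non-increasing),
#'   `vectors` (p x k), `variance_fraction` (k, sums to 1), `center`.
#' @export
shape_pca <- function(x, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  cv <- crossprod(xc) / (n - 1L)
  e <- eigen(cv, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("no variation in input")
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  # sign convention: largest-|loading| positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(scores = xc %*% vecs, eigenvalues = vals, vectors = vecs,
       variance_fraction = vals / sum(vals), center = ctr)
}

#' Rank records by Procrustes distance to the consensus
#'
#' Mirrors the usual "find outliers" check: records are sorted by decreasing
#' distance to the sample average shape. No record is excluded automatically;
#' the ranking is a report for the analyst.
#'
#' @param shape A `shape_data`.
#' @return Data frame with `individual_id`, `rep_label`, `distance`, sorted
#'   decreasing.
#' @export
flag_outliers <- function(shape) {
  L <- dim(shape$aligned)[1L]
  n <- length(shape$cs)
  cons <- c(shape$consensus[, 1L], shape$consensus[, 2L])
  flat <- cbind(matrix(shape$aligned[, 1L, ], ncol = L, byrow = TRUE),
                matrix(shape$aligned[, 2L, ], ncol = L, byrow = TRUE))
  d <- sqrt(rowSums(sweep(flat, 2L, cons)^2))
  out <- data.frame(individual_id = shape$meta$individual_id,
                    rep_label = shape$meta$rep_label,
                    distance = d)
  out[order(-d, out$individual_id, out$rep_label), , drop = FALSE]
}

#' Agglomerative phenogram from a shape distance matrix
#'
#' UPGMA (average linkage) or NN (nearest neighbor, single linkage) clustering
#' of the pairwise Procrustes shape distances, returned as an `ape` tree with
#' branch lengths.
#'
#' @param dm Output of [procrustes_distance_matrix()] (or a list with a
#'   symmetric `d` matrix and `labels`).
#' @param linkage `"UPGMA"` (default) or `"NN"`.
#' @return An object of class `phylo`.
#' @export
cluster_phenogram <- function(dm, linkage = c("UPGMA", "NN")) {
  linkage <- match.arg(linkage)
  d <- dm$d
  if (nrow(d) < 2L) stop("need at least 2 records")
  dimnames(d) <- list(dm$labels, dm$labels)
  hc <- stats::hclust(stats::as.dist(d),
                      method = if (linkage == "UPGMA") "average" else "single")
  ape::as.phylo(hc)
}
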