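# Synthetic digitization generator: complete individual x REP grids with known
# individual shape variation, sex effect, static allometry, heterogeneous
# per-landmark digitization noise and per-REP systematic bias, plus ground
# truth for parameter-recovery studies.

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic cranium-like template configuration
#'
#' An elongated, bilaterally symmetric 2D configuration standing in for a
#' ventral-cranium landmark scheme: midline points along the long axis plus
#' paired lateral points on an elliptical outline. Centered, unit centroid
#' size, deterministic for a given L.
#'
#' @param L Number of landmarks (>= 4); default 26.
#' @return L x 2 matrix, rownames "L1".."LL".
#' @export
template_shape <- function(L = 26L) {
  stopifnot(L >= 4L)
  n_mid <- max(2L, round(L / 4))
  n_side <- L - n_mid
  mid <- cbind(seq(-1, 1, length.out = n_mid), rep(0, n_mid))
  th <- seq(0.15, pi - 0.15, length.out = n_side)
  side <- cbind(1.6 * cos(th), 0.9 * sin(th) * rep(c(1, -1), length.out = n_side))
  xy <- rbind(mid, side)
  xy <- sweep(xy, 2L, colMeans(xy))
  xy <- xy / centroid_size(xy)
  rownames(xy) <- paste0("L", seq_len(L))
  colnames(xy) <- c("x", "y")
  xy
}

# deterministic unit direction in the 2L shape space, orthogonal to the
# similarity directions (translations, scaling, rotation) at `template` and to
# any columns of `ortho_to`; `tag` selects the direction reproducibly
.shape_direction <- function(template, tag, ortho_to = NULL) {
  L <- nrow(template)
  v <- .with_seed(90000L + tag, stats::rnorm(2L * L))
  flat <- c(template[, 1L], template[, 2L])
  basis <- cbind(c(rep(1, L), rep(0, L)),        # x translation
                 c(rep(0, L), rep(1, L)),        # y translation
                 flat,                           # scaling
                 c(-template[, 2L], template[, 1L]))  # rotation
  if (!is.null(ortho_to)) basis <- cbind(basis, ortho_to)
  q <- qr.Q(qr(basis))
  v <- v - q %*% crossprod(q, v)
  v <- v / sqrt(sum(v^2))
  matrix(v, L, 2L, dimnames = dimnames(template))
}

#' Parameters for the synthetic digitization generator
#'
#' The defaults describe a "marmot-like" regime: 58 adult individuals (32
#' females, 26 males), 26 landmarks, 8 digitization REPs at day offsets
#' 1, 1, 2, 4, 11, 41, 121 and 7300, individual shape variation much larger
#' than random digitization noise, which in turn is much larger than per-REP
#' systematic bias; heterogeneous per-landmark noise (about five-fold range in
#' per-landmark variance); a small sex effect (shape Rsq ~2%); static
#' allometric shape-size covariation (Rsq ~11% within a REP); and per-sex
#' lognormal centroid sizes with medians near 133.5 (F) and 136.5 (M) mm.
#'
#' @param n_individuals Number of individuals.
#' @param sex_counts Named integer vector `c(F=, M=)` summing to
#'   `n_individuals`.
#' @param n_landmarks Number of landmarks L.
#' @param template L x 2 mean shape, unit centroid size.
#' @param sigma_individual SD of individual shape deviations per coordinate
#'   (shape units).
#' @param sex_effect L x 2 shape-space displacement added to males (F = 0
#'   baseline).
#' @param allometry_slope L x 2 shape change per unit log centroid size.
#' @param cs_median Named vector `c(F=, M=)`, per-sex lognormal medians (mm).
#' @param cs_sdlog Lognormal dispersion of centroid size.
#' @param sigma_landmark Length-L vector of per-landmark digitization noise
#'   SDs (mm, per coordinate, raw image scale).
#' @param rep_bias Named list: REP label -> L x 2 bias matrix (mm, raw image
#'   scale) added to every digitization of that REP. Zero matrices allowed.
#' @param sex_specific_bias Optional named list "rep:sex" -> L x 2 extra bias.
#' @param day_offsets Named integer vector: REP label -> day offset.
#' @param rotation_sd_deg SD of the per-individual photographic pose rotation
#'   (degrees); drawn once per individual and shared by all its REPs.
#' @param translation_sd SD of the per-individual pose translation (mm).
#' @param seed Integer seed making the generated dataset reproducible.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_individuals = 58L,
                         sex_counts = c(F = 32L, M = 26L),
                         n_landmarks = 26L,
                         template = template_shape(n_landmarks),
                         sigma_individual = 0.0085,
                         sex_effect = NULL,
                         allometry_slope = NULL,
                         cs_median = c(F = 133.5, M = 137),
                         cs_sdlog = 0.03,
                         sigma_landmark = sqrt(seq(0.10, 0.45,
                                                   length.out = n_landmarks)),
                         rep_bias = NULL,
                         sex_specific_bias = NULL,
                         day_offsets = c(d0001a = 1L, d0001b = 1L, d0002 = 2L,
                                         d0004 = 4L, d0011 = 11L, d0041 = 41L,
                                         d0121 = 121L, d7300 = 7300L),
                         rotation_sd_deg = 3,
                         translation_sd = 20,
                         seed = 1L) {
  L <- n_landmarks
  stopifnot(nrow(template) == L, sum(sex_counts) == n_individuals,
            length(sigma_landmark) == L, all(sigma_landmark >= 0),
            sigma_individual >= 0, cs_sdlog >= 0)
  sex_dir <- .shape_direction(template, tag = 1L)
  if (is.null(sex_effect)) sex_effect <- 0.010 * sex_dir
  if (is.null(allometry_slope)) {
    allometry_slope <- 0.78 * .shape_direction(template, tag = 2L,
                                               ortho_to = c(sex_dir))
  }
  reps <- names(day_offsets)
  if (is.null(rep_bias)) {
    # shape-space bias magnitude (mm, 2L-norm) and centroid-size offset (mm)
    # per REP; both drift with the time lag, with the oldest session largest
    mags <- c(d0001a = 0, d0001b = 0.10, d0002 = 1.45, d0004 = 1.10,
              d0011 = 1.15, d0041 = 1.20, d0121 = 1.25, d7300 = 2.60)
    cs_off <- c(d0001a = 0, d0001b = -0.1, d0002 = 0.5, d0004 = -0.4,
                d0011 = 0.45, d0041 = -0.5, d0121 = 0.4, d7300 = 1.0)
    if (!setequal(reps, names(mags))) {
      mags <- stats::setNames(rep(0, length(reps)), reps)
      cs_off <- mags
    }
    rep_bias <- lapply(seq_along(reps), function(k) {
      mags[[reps[k]]] * .shape_direction(template, tag = 10L + k,
                                         ortho_to = cbind(c(sex_dir),
                                                          c(allometry_slope))) +
        cs_off[[reps[k]]] * template
    })
    names(rep_bias) <- reps
  }
  if (!setequal(names(rep_bias), reps)) {
    stop("rep_bias must be defined for every REP in day_offsets")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 sex_counts = sex_counts, n_landmarks = L,
                 template = template, sigma_individual = sigma_individual,
                 sex_effect = sex_effect, allometry_slope = allometry_slope,
                 cs_median = cs_median, cs_sdlog = cs_sdlog,
                 sigma_landmark = sigma_landmark, rep_bias = rep_bias,
                 sex_specific_bias = sex_specific_bias,
                 day_offsets = day_offsets,
                 rotation_sd_deg = rotation_sd_deg,
                 translation_sd = translation_sd, seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic digitization dataset with ground truth
#'
#' For each individual i a true shape is drawn once: template + sex effect +
#' allometric deviation proportional to (log CS_i - mean log CS) + iid normal
#' individual deviation per coordinate. One pose (rotation + translation) per
#' individual is drawn once and reused for every REP, emulating repeated
#' digitization of the same photograph. Each raw record is
#' CS_i * R_i(S_i) + t_i + rep bias (+ optional sex-specific bias) + iid
#' per-landmark noise on the raw mm scale. Deterministic given
#' `params$seed`.
#'
#' @param params A `synth_params` object.
#' @return List with `dataset` (a `digit_dataset`) and `truth` (list: true
#'   shapes, centroid sizes, poses, bias vectors, noise draws, params).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  .with_seed(params$seed, {
    L <- params$n_landmarks
    nI <- params$n_individuals
    reps <- names(params$day_offsets)[order(params$day_offsets,
                                            names(params$day_offsets))]
    R <- length(reps)
    sex <- rep(c("F", "M"), times = c(params$sex_counts[["F"]],
                                      params$sex_counts[["M"]]))
    ids <- sprintf("ind%02d", seq_len(nI))
    cs <- exp(stats::rnorm(nI,
                           mean = log(params$cs_median[sex]),
                           sd = params$cs_sdlog))
    lcs <- log(cs) - mean(log(cs))
    true_shapes <- array(NA_real_, c(L, 2L, nI))
    for (i in seq_len(nI)) {
      dev <- matrix(stats::rnorm(2L * L, sd = params$sigma_individual), L, 2L)
      true_shapes[, , i] <- params$template +
        (sex[i] == "M") * params$sex_effect +
        lcs[i] * params$allometry_slope + dev
    }
    theta <- stats::rnorm(nI, sd = params$rotation_sd_deg * pi / 180)
    trans <- matrix(stats::rnorm(2L * nI, sd = params$translation_sd), nI, 2L)
    n <- nI * R
    coords <- array(NA_real_, c(L, 2L, n))
    noise <- array(stats::rnorm(L * 2L * n,
                                sd = rep(params$sigma_landmark, times = 2L * n)),
                   c(L, 2L, n))
    meta <- data.frame(individual_id = rep(ids, each = R),
                       sex = rep(sex, each = R),
                       rep_label = rep(reps, times = nI),
                       day_offset = rep(unname(params$day_offsets[reps]),
                                        times = nI),
                       stringsAsFactors = FALSE)
    for (i in seq_len(nI)) {
      rot <- matrix(c(cos(theta[i]), sin(theta[i]),
                      -sin(theta[i]), cos(theta[i])), 2L, 2L)
      posed <- (cs[i] * true_shapes[, , i]) %*% t(rot)
      posed <- sweep(posed, 2L, -trans[i, ])
      for (k in seq_len(R)) {
        rec <- (i - 1L) * R + k
        b <- params$rep_bias[[reps[k]]]
        sb <- params$sex_specific_bias[[paste(reps[k], sex[i], sep = ":")]]
        coords[, , rec] <- posed + b + (if (is.null(sb)) 0 else sb) +
          noise[, , rec]
      }
    }
    labels <- rownames(params$template)
    if (is.null(labels)) labels <- paste0("L", seq_len(L))
    dataset <- structure(list(coords = coords, labels = labels, meta = meta,
                              n_individuals = nI, n_reps = R, n_landmarks = L),
                         class = "digit_dataset")
    truth <- list(ids = ids, sex = sex, cs = cs, log_cs_centered = lcs,
                  true_shapes = true_shapes, theta = theta, trans = trans,
                  rep_bias = params$rep_bias,
                  sex_effect = params$sex_effect,
                  allometry_slope = params$allometry_slope,
                  noise = noise, params = params)
    list(dataset = dataset, truth = truth)
  })
}

#' Monte-Carlo expectation of the ME-ANOVA variance decomposition
#'
#' Generates `n_sim` fresh datasets under `params` (seeds derived from
#' `params$seed`), runs GPA and the ME ANOVA on each (permutation tests
#' skipped), and returns the mean and SD of the Rsq of each effect. Used to
#' size generator effects to a target variance regime.
#'
#' @param params A `synth_params` object.
#' @param n_sim Number of simulated datasets (>= 2; >= 50 recommended).
#' @return List with `mean`, `sd` (named by effect) and `rsq` (n_sim x 4
#'   matrix).
#' @export
expected_variance_components <- function(params, n_sim = 50L) {
  stopifnot(inherits(params, "synth_params"), n_sim >= 2L)
  if (params$sigma_individual == 0 && all(params$sigma_landmark == 0)) {
    stop("degenerate parameters: no individual variation and no noise")
  }
  effects <- c("individual", "systME", "systME:sex", "randME")
  rsq <- matrix(NA_real_, n_sim, 4L, dimnames = list(NULL, effects))
  for (s in seq_len(n_sim)) {
    p <- params
    p$seed <- params$seed + 1000L + s
    sim <- generate_dataset(p)
    me <- me_anova(gpa(sim$dataset), n_perm = 0L)
    rsq[s, ] <- me$table$Rsq[match(effects, me$table$effect)]
  }
  list(mean = colMeans(rsq), sd = apply(rsq, 2L, stats::sd), rsq = rsq)
}
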