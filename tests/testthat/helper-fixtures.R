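# shared fixtures: all built in code at test time

# small study design for fast tests
tiny_params <- function(n_individuals = 6L, n_reps = 3L, n_landmarks = 6L,
                        seed = 42L,
                        sigma_landmark = rep(0.4, n_landmarks), ...) {
  nF <- ceiling(n_individuals / 2)
  days <- c(1L, 2L, 4L, 11L, 41L, 121L, 7300L)[seq_len(n_reps)]
  names(days) <- sprintf("d%04d", days)
  synth_params(n_individuals = n_individuals,
               sex_counts = c(F = nF, M = n_individuals - nF),
               n_landmarks = n_landmarks,
               sigma_landmark = sigma_landmark,
               day_offsets = days, seed = seed, ...)
}

# zero-signal variant: no bias, no sex effect, equal CS medians
null_params <- function(..., seed = 42L) {
  p <- tiny_params(..., seed = seed)
  p$rep_bias <- lapply(p$rep_bias, function(b) b * 0)
  p$sex_effect <- p$sex_effect * 0
  p$cs_median <- c(F = 135, M = 135)
  p
}

random_config <- function(L = 8L, scale = 100) {
  matrix(stats::rnorm(2L * L, sd = scale), L, 2L,
         dimnames = list(paste0("L", seq_len(L)), c("x", "y")))
}

# configs_by_rep + metadata for assemble_dataset tests
grid_fixture <- function(n_ind = 3L, reps = c(a = 1L, b = 2L), L = 5L,
                         seed = 1L) {
  set.seed(seed)
  ids <- sprintf("sp%02d", seq_len(n_ind))
  sex <- rep(c("F", "M"), length.out = n_ind)
  configs_by_rep <- lapply(names(reps), function(r) {
    lapply(seq_len(n_ind), function(i) {
      list(coords = random_config(L), id = ids[i], image = "", scale = 1,
           scale_applied = TRUE)
    })
  })
  names(configs_by_rep) <- names(reps)
  metadata <- data.frame(
    individual_id = rep(ids, times = length(reps)),
    sex = rep(sex, times = length(reps)),
    rep_label = rep(names(reps), each = n_ind),
    day_offset = rep(unname(reps), each = n_ind),
    stringsAsFactors = FALSE)
  list(configs_by_rep = configs_by_rep, metadata = metadata)
}

# apply one similarity transform (rotation deg, scale, translation) to a
# record of a dataset
transform_record <- function(dataset, i, angle_deg = 0, scale = 1,
                             shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  dataset$coords[, , i] <- scale * dataset$coords[, , i] %*% t(rot) +
    rep(shift, each = dim(dataset$coords)[1L])
  dataset
}
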