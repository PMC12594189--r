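# TPS landmark file input/output and assembly of the individual x REP
# digitization grid.

#' Read a TPS landmark file
#'
#' Parses the plain-text TPS interchange format produced by the TPS software
#' family: one block per specimen, each starting with an `LM=` line giving the
#' number of 2D landmarks, followed by that many "x y" coordinate lines and
#' optional `ID=`, `IMAGE=` and `SCALE=` records. Only 2D blocks are accepted;
#' `LM3=` (3D) blocks are rejected.
#'
#' @param path Path to a TPS file.
#' @param apply_scale If `TRUE` (default) and a `SCALE=` record is present,
#'   coordinates are multiplied by the scale factor (pixels to mm). Blocks
#'   without `SCALE=` are returned unscaled with `scale_applied = FALSE`.
#' @return A list of landmark configurations. Each element is a list with
#'   `coords` (L x 2 numeric matrix, landmark labels as rownames), `id`,
#'   `image`, `scale` and `scale_applied`.
#' @export
read_tps <- function(path, apply_scale = TRUE) {
  stopifnot(length(path) == 1L, file.exists(path))
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  lm_at <- grep("^LM\\s*=", trimmed, ignore.case = TRUE)
  if (any(grepl("^LM3\\s*=", trimmed, ignore.case = TRUE))) {
    stop("3D blocks (LM3=) are not supported; this package handles 2D landmark data only")
  }
  if (length(lm_at) == 0L) stop("no LM= blocks found in ", path)
  bounds <- c(lm_at, length(trimmed) + 1L)
  configs <- vector("list", length(lm_at))
  for (b in seq_along(lm_at)) {
    block <- trimmed[lm_at[b]:(bounds[b + 1L] - 1L)]
    block_line0 <- lm_at[b] - 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L], ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1L) {
      stop("block ", b, ": invalid LM= count at line ", block_line0 + 1L)
    }
    # coordinate lines are the contiguous run immediately following LM=
    looks_coord <- grepl("^[-+0-9.]", block[-1L])
    run <- if (!length(looks_coord) || !looks_coord[1L]) 0L else {
      stops <- which(!looks_coord)
      if (length(stops) == 0L) length(looks_coord) else stops[1L] - 1L
    }
    if (run != n_lm) {
      stop("block ", b, ": LM=", n_lm, " but found ", run, " coordinate lines")
    }
    coord_idx <- seq_len(n_lm) + 1L
    coords <- matrix(NA_real_, n_lm, 2L)
    for (i in seq_len(n_lm)) {
      parts <- strsplit(block[coord_idx[i]], "\\s+")[[1L]]
      xy <- suppressWarnings(as.numeric(parts))
      if (length(xy) != 2L || anyNA(xy)) {
        stop("block ", b, ": non-numeric or malformed coordinate at line ",
             block_line0 + coord_idx[i])
      }
      coords[i, ] <- xy
    }
    rest <- block[-seq_len(n_lm + 1L)]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), rest, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0L) NULL else sub(paste0("^", key, "\\s*=\\s*"), "", hit[1L],
                                           ignore.case = TRUE)
    }
    id <- get_field("ID")
    image <- get_field("IMAGE")
    scale_chr <- get_field("SCALE")
    scale <- if (is.null(scale_chr)) NA_real_ else suppressWarnings(as.numeric(scale_chr))
    scale_applied <- FALSE
    if (apply_scale && !is.na(scale)) {
      coords <- coords * scale
      scale_applied <- TRUE
    }
    rownames(coords) <- paste0("L", seq_len(n_lm))
    configs[[b]] <- list(coords = coords,
                         id = if (is.null(id)) as.character(b) else id,
                         image = if (is.null(image)) "" else image,
                         scale = scale,
                         scale_applied = scale_applied)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: emits one `LM=` block per configuration with
#' coordinate lines, `ID=`, `IMAGE=` and `SCALE=1.0` records (coordinates are
#' written on the mm scale, so the scale factor is unity).
#'
#' @param configs Non-empty list of configurations as returned by [read_tps()],
#'   or any list whose elements have a `coords` L x 2 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stop("cannot write an empty configuration list")
  nl <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(nl)) != 1L) stop("configurations have inconsistent landmark counts")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (b in seq_along(configs)) {
    cf <- configs[[b]]
    writeLines(paste0("LM=", nrow(cf$coords)), con)
    writeLines(sprintf("%.17g %.17g", cf$coords[, 1L], cf$coords[, 2L]), con)
    writeLines(paste0("ID=", if (is.null(cf$id)) b else cf$id), con)
    if (!is.null(cf$image) && nzchar(cf$image)) writeLines(paste0("IMAGE=", cf$image), con)
    writeLines("SCALE=1.0", con)
  }
  invisible(path)
}

#' Assemble the individual x REP digitization grid
#'
#' Joins per-REP configuration lists with a metadata table and validates the
#' complete-grid design: every individual must appear in every REP exactly
#' once. Records are re-keyed by individual ID (digitization order is
#' randomized between sessions, so file order is not meaningful) and sorted by
#' (individual, day offset).
#'
#' @param configs_by_rep Named list: REP label -> list of configurations, each
#'   carrying the individual ID in its `id` field.
#' @param metadata Data frame with columns `individual_id`, `sex` (F/M,
#'   case-insensitive), `rep_label`, `day_offset`.
#' @return A `digit_dataset`: list with `coords` (L x 2 x n array), `labels`
#'   (landmark labels), `meta` (data frame, one row per record), and counts
#'   `n_individuals`, `n_reps`, `n_landmarks`.
#' @export
assemble_dataset <- function(configs_by_rep, metadata) {
  req <- c("individual_id", "sex", "rep_label", "day_offset")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns ", paste(req, collapse = ", "))
  }
  metadata$individual_id <- as.character(metadata$individual_id)
  metadata$rep_label <- as.character(metadata$rep_label)
  sex <- toupper(trimws(as.character(metadata$sex)))
  if (!all(sex %in% c("F", "M"))) {
    bad <- unique(metadata$sex[!sex %in% c("F", "M")])
    stop("sex codes must be F or M; found: ", paste(bad, collapse = ", "))
  }
  metadata$sex <- sex
  # rep_label <-> day_offset must be a consistent 1:1 mapping
  map <- unique(metadata[, c("rep_label", "day_offset")])
  if (anyDuplicated(map$rep_label)) {
    stop("inconsistent rep_label/day_offset mapping")
  }
  ind <- sort(unique(metadata$individual_id))
  reps <- map$rep_label[order(map$day_offset)]
  key <- paste(metadata$individual_id, metadata$rep_label, sep = "\r")
  want <- as.vector(outer(ind, reps, paste, sep = "\r"))
  if (anyDuplicated(key) || !setequal(key, want) || length(key) != length(want)) {
    missing <- setdiff(want, key)
    dup <- key[duplicated(key)]
    bad <- c(if (length(missing)) paste("missing:", gsub("\r", " x ", missing)),
             if (length(dup)) paste("duplicated:", gsub("\r", " x ", dup)))
    stop("incomplete individual x REP grid; ", paste(bad, collapse = "; "))
  }
  if (!setequal(names(configs_by_rep), reps)) {
    stop("configs_by_rep names must match metadata rep labels")
  }
  L <- nrow(configs_by_rep[[1L]][[1L]]$coords)
  labels <- rownames(configs_by_rep[[1L]][[1L]]$coords)
  if (is.null(labels)) labels <- paste0("L", seq_len(L))
  n <- length(ind) * length(reps)
  coords <- array(NA_real_, dim = c(L, 2L, n))
  # order records individual-major, REP (by day offset) minor
  meta <- metadata[order(match(metadata$individual_id, ind), metadata$day_offset),
                   req, drop = FALSE]
  rownames(meta) <- NULL
  for (r in reps) {
    cfs <- configs_by_rep[[r]]
    ids <- vapply(cfs, function(cf) as.character(cf$id), character(1))
    if (!setequal(ids, ind) || anyDuplicated(ids)) {
      stop("REP ", r, ": configuration IDs do not match the individual set")
    }
    for (cf in cfs) {
      if (nrow(cf$coords) != L) {
        stop("REP ", r, ", individual ", cf$id, ": landmark count ",
             nrow(cf$coords), " != ", L)
      }
      row <- which(meta$individual_id == cf$id & meta$rep_label == r)
      coords[, , row] <- cf$coords
    }
  }
  if (anyNA(coords) || any(!is.finite(coords))) stop("non-finite coordinates in dataset")
  structure(list(coords = coords, labels = labels, meta = meta,
                 n_individuals = length(ind), n_reps = length(reps),
                 n_landmarks = L),
            class = "digit_dataset")
}

#' @export
print.digit_dataset <- function(x, ...) {
  cat("Digitization dataset:", x$n_individuals, "individuals x", x$n_reps,
      "REPs,", x$n_landmarks, "landmarks (", nrow(x$meta), "records)\n")
  cat("REPs:", paste(unique(x$meta$rep_label), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset to named landmarks
#'
#' Returns a new dataset restricted to the kept landmarks, preserving the
#' grid. Subsetting operates on raw coordinates; downstream shape analyses
#' must re-superimpose the reduced configurations.
#'
#' @param dataset A `digit_dataset`.
#' @param keep Character vector of landmark labels to retain (non-empty, no
#'   duplicates, all present).
#' @return A `digit_dataset` with `length(keep)` landmarks.
#' @export
subset_landmarks <- function(dataset, keep) {
  stopifnot(inherits(dataset, "digit_dataset"))
  if (length(keep) == 0L) stop("keep must be non-empty")
  if (anyDuplicated(keep)) stop("duplicated landmark labels in keep")
  idx <- match(keep, dataset$labels)
  if (anyNA(idx)) stop("unknown landmark labels: ",
                       paste(keep[is.na(idx)], collapse = ", "))
  dataset$coords <- dataset$coords[idx, , , drop = FALSE]
  dataset$labels <- dataset$labels[idx]
  dataset$n_landmarks <- length(idx)
  dataset
}

#' Subset a dataset to named REPs
#'
#' @param dataset A `digit_dataset`.
#' @param reps Character vector of REP labels to retain.
#' @return A `digit_dataset` restricted to those REPs.
#' @export
subset_reps <- function(dataset, reps) {
  stopifnot(inherits(dataset, "digit_dataset"))
  if (length(reps) == 0L) stop("reps must be non-empty")
  if (!all(reps %in% dataset$meta$rep_label)) {
    stop("unknown REP labels: ",
         paste(setdiff(reps, dataset$meta$rep_label), collapse = ", "))
  }
  sel <- dataset$meta$rep_label %in% reps
  dataset$coords <- dataset$coords[, , sel, drop = FALSE]
  dataset$meta <- dataset$meta[sel, , drop = FALSE]
  rownames(dataset$meta) <- NULL
  dataset$n_reps <- length(unique(reps))
  dataset
}

#' Write a dataset as TPS plus metadata CSV
#'
#' @param dataset A `digit_dataset`.
#' @param tps_path Output TPS file (records in dataset order).
#' @param meta_path Output CSV with `individual_id`, `sex`, `rep_label`,
#'   `day_offset`.
#' @return Invisibly, `c(tps_path, meta_path)`.
#' @export
write_dataset <- function(dataset, tps_path, meta_path) {
  stopifnot(inherits(dataset, "digit_dataset"))
  n <- dim(dataset$coords)[3L]
  configs <- lapply(seq_len(n), function(i) {
    cm <- dataset$coords[, , i]
    rownames(cm) <- dataset$labels
    list(coords = cm, id = dataset$meta$individual_id[i],
         image = paste0(dataset$meta$individual_id[i], ".jpg"),
         scale = 1, scale_applied = TRUE)
  })
  write_tps(configs, tps_path)
  utils::write.csv(dataset$meta, meta_path, row.names = FALSE)
  invisible(c(tps_path, meta_path))
}
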