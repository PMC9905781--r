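#' Construct a hypnogram
#'
#' A hypnogram is one stage label per epoch for a single scorer of a single
#' PSG. Epoch indices are 0-based and the lights interval is half-open:
#' `[lights_off_epoch, lights_on_epoch)`.
#'
#' @param stages Character vector of stage labels in `sleep_stages()`.
#' @param epoch_duration Epoch length in seconds (default 30).
#' @param scorer_id,psg_id Identifiers (free text).
#' @param lights_off_epoch,lights_on_epoch Optional 0-based epoch indices
#'   delimiting the in-bed interval; `lights_on_epoch` is exclusive.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_duration = 30, scorer_id = "scorer",
                      psg_id = "psg", lights_off_epoch = NULL,
                      lights_on_epoch = NULL) {
  stages <- as.character(stages)
  if (length(stages) < 1L) stop("hypnogram must contain at least one epoch")
  stage_index(stages)  # validates
  if (!is.numeric(epoch_duration) || length(epoch_duration) != 1L ||
      epoch_duration <= 0)
    stop("`epoch_duration` must be a single positive number")
  n <- length(stages)
  if (!is.null(lights_off_epoch) || !is.null(lights_on_epoch)) {
    if (is.null(lights_off_epoch) || is.null(lights_on_epoch))
      stop("provide both lights_off_epoch and lights_on_epoch, or neither")
    if (!(lights_off_epoch >= 0 && lights_off_epoch < lights_on_epoch &&
          lights_on_epoch <= n))
      stop("lights interval must satisfy 0 <= off < on <= n_epochs")
  }
  structure(
    list(stages = stages, epoch_duration = as.numeric(epoch_duration),
         scorer_id = as.character(scorer_id), psg_id = as.character(psg_id),
         lights_off_epoch = lights_off_epoch,
         lights_on_epoch = lights_on_epoch),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> psg=%s scorer=%s: %d epochs x %gs\n",
              x$psg_id, x$scorer_id, length(x$stages), x$epoch_duration))
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat("  epochs per stage:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Construct a hypnodensity
#'
#' A hypnodensity is an epoch-by-5 matrix of sleep stage probabilities with
#' columns in the fixed order `W, N1, N2, N3, R`. Every entry must lie in
#' \[0, 1\] and every row must sum to 1 within `1e-9`.
#'
#' @param probabilities Numeric matrix, one row per epoch, 5 columns.
#' @param epoch_duration Epoch length in seconds.
#' @param source One of `"scorers"`, `"autoscorer"`, `"latent_truth"`.
#' @param psg_id PSG identifier.
#' @return An object of class `hypnodensity`.
#' @export
hypnodensity <- function(probabilities, epoch_duration = 30,
                         source = c("scorers", "autoscorer", "latent_truth"),
                         psg_id = "psg") {
  source <- match.arg(source)
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 5L)
    stop("hypnodensity needs exactly 5 probability columns (W,N1,N2,N3,R)")
  if (nrow(probabilities) < 1L) stop("hypnodensity must have >= 1 epoch")
  if (any(probabilities < 0) || any(probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  rs <- rowSums(probabilities)
  if (any(abs(rs - 1) > 1e-9)) {
    bad <- which(abs(rs - 1) > 1e-9)[1L]
    stop(sprintf("hypnodensity row %d sums to %.12g, not 1", bad, rs[bad]))
  }
  dimnames(probabilities) <- list(NULL, sleep_stages())
  structure(
    list(probabilities = probabilities,
         epoch_duration = as.numeric(epoch_duration),
         source = source, psg_id = as.character(psg_id)),
    class = "hypnodensity"
  )
}

#' @export
length.hypnodensity <- function(x) nrow(x$probabilities)

#' @export
print.hypnodensity <- function(x, ...) {
  cat(sprintf("<hypnodensity> psg=%s source=%s: %d epochs x %gs\n",
              x$psg_id, x$source, nrow(x$probabilities), x$epoch_duration))
  cat("  mean stage probability:",
      paste(sprintf("%s=%.3f", sleep_stages(), colMeans(x$probabilities)),
            collapse = " "), "\n")
  invisible(x)
}

#' Assemble aligned hypnograms into a scoring set
#'
#' A scoring set holds the stagings of one PSG by several scorers, aligned
#' epoch for epoch. Hypnograms of unequal length are rejected outright:
#' silent truncation would corrupt every agreement statistic downstream.
#'
#' @param hypnograms List of at least two [hypnogram()] objects with a
#'   common `psg_id`, equal length and equal `epoch_duration`.
#' @param psg_id Optional override; defaults to the shared `psg_id`.
#' @return An object of class `scoring_set`.
#' @export
assemble_scoring_set <- function(hypnograms, psg_id = NULL) {
  if (!is.list(hypnograms) || length(hypnograms) < 2L)
    stop("a scoring set needs at least two hypnograms")
  if (!all(vapply(hypnograms, inherits, logical(1), "hypnogram")))
    stop("all elements must be hypnogram objects")
  lens <- vapply(hypnograms, function(h) length(h$stages), integer(1))
  ids <- vapply(hypnograms, `[[`, character(1), "scorer_id")
  if (length(unique(lens)) != 1L)
    stop("hypnogram lengths differ: ",
         paste(sprintf("%s=%d", ids, lens), collapse = ", "))
  durs <- vapply(hypnograms, `[[`, numeric(1), "epoch_duration")
  if (length(unique(durs)) != 1L)
    stop("epoch durations differ across scorers")
  if (anyDuplicated(ids))
    stop("duplicate scorer_id: ", ids[duplicated(ids)][1L])
  psgs <- unique(vapply(hypnograms, `[[`, character(1), "psg_id"))
  if (is.null(psg_id)) {
    if (length(psgs) != 1L)
      stop("hypnograms belong to different PSGs: ",
           paste(psgs, collapse = ", "))
    psg_id <- psgs
  }
  structure(list(psg_id = psg_id, hypnograms = hypnograms),
            class = "scoring_set")
}

#' @export
print.scoring_set <- function(x, ...) {
  cat(sprintf("<scoring_set> psg=%s: %d scorers x %d epochs\n", x$psg_id,
              length(x$hypnograms), length(x$hypnograms[[1]]$stages)))
  invisible(x)
}

n_scorers <- function(s) length(s$hypnograms)
scorer_ids <- function(s) vapply(s$hypnograms, `[[`, character(1), "scorer_id")

# epochs x scorers label matrix (character), or integer codes 1..5
label_matrix <- function(s, as_integer = FALSE) {
  m <- vapply(s$hypnograms, function(h) h$stages,
              character(length(s$hypnograms[[1]]$stages)))
  m <- matrix(m, ncol = length(s$hypnograms),
              dimnames = list(NULL, scorer_ids(s)))
  if (as_integer) {
    m <- matrix(stage_index(m), nrow = nrow(m), dimnames = dimnames(m))
  }
  m
}

#' Read a hypnogram from a delimited text file
#'
#' Expects a header row and columns `epoch,stage`; any extra columns are
#' ignored. Stage codes are translated through `dialect`; unknown codes are
#' rejected with the offending code and row number.
#'
#' @param path File path.
#' @param dialect Dialect name or named mapping (see [stage_dialects()]).
#' @inheritParams hypnogram
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = "aasm", epoch_duration = 30,
                           scorer_id = NULL, psg_id = "psg",
                           lights_off_epoch = NULL, lights_on_epoch = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) stop("empty hypnogram file: ", path)
  if (!"stage" %in% names(df))
    stop("hypnogram file must have a `stage` column: ", path)
  stages <- map_stage_codes(df$stage, dialect)
  if (is.null(scorer_id))
    scorer_id <- sub("\\.[^.]*$", "", basename(path))
  hypnogram(stages, epoch_duration = epoch_duration, scorer_id = scorer_id,
            psg_id = psg_id, lights_off_epoch = lights_off_epoch,
            lights_on_epoch = lights_on_epoch)
}

#' Write a hypnogram to CSV
#'
#' Columns `epoch` (0-based) and `stage` (AASM text codes).
#'
#' @param x A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(x, path) {
  stopifnot(inherits(x, "hypnogram"))
  utils::write.csv(
    data.frame(epoch = seq_along(x$stages) - 1L, stage = x$stages),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnodensity from CSV
#'
#' Expects columns `epoch,pW,pN1,pN2,pN3,pR`. Rows whose sum deviates from 1
#' by at most `1e-6` are renormalized (tolerating decimal rounding in the
#' file); larger deviations or negative entries are rejected with the row
#' index.
#'
#' @param path File path.
#' @inheritParams hypnodensity
#' @return A [hypnodensity()].
#' @export
read_hypnodensity <- function(path, epoch_duration = 30,
                              source = "autoscorer", psg_id = "psg") {
  df <- utils::read.csv(path)
  cols <- paste0("p", sleep_stages())
  if (!all(cols %in% names(df)))
    stop("hypnodensity file must have columns ", paste(cols, collapse = ","))
  p <- as.matrix(df[cols])
  if (nrow(p) == 0L) stop("empty hypnodensity file: ", path)
  if (any(p < 0)) {
    bad <- which(rowSums(p < 0) > 0)[1L]
    stop(sprintf("negative probability at row %d", bad))
  }
  rs <- rowSums(p)
  off <- abs(rs - 1)
  if (any(off > 1e-6)) {
    bad <- which(off > 1e-6)[1L]
    stop(sprintf("row %d probabilities sum to %.8g (off by > 1e-6)",
                 bad, rs[bad]))
  }
  p <- p / rs
  hypnodensity(p, epoch_duration = epoch_duration, source = source,
               psg_id = psg_id)
}

#' Write a hypnodensity to CSV
#'
#' Probabilities are written with 12 decimal places so that a read/write
#' round trip is exact to that precision.
#'
#' @param x A [hypnodensity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnodensity <- function(x, path) {
  stopifnot(inherits(x, "hypnodensity"))
  p <- x$probabilities
  df <- data.frame(epoch = seq_len(nrow(p)) - 1L)
  for (j in seq_len(5L))
    df[[paste0("p", sleep_stages()[j])]] <- sprintf("%.12f", p[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scoring set as a directory of per-scorer CSVs plus a manifest
#'
#' The manifest (`manifest.json`) records `psg_id`, scorer order,
#' `epoch_duration`, the lights interval, and one hypnogram CSV per scorer.
#'
#' @param s A scoring set.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scoring_set <- function(s, dir) {
  stopifnot(inherits(s, "scoring_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.csv", scorer_ids(s))
  for (i in seq_along(s$hypnograms))
    write_hypnogram(s$hypnograms[[i]], file.path(dir, files[i]))
  h1 <- s$hypnograms[[1]]
  manifest <- list(
    psg_id = s$psg_id,
    epoch_duration = h1$epoch_duration,
    scorers = scorer_ids(s),
    files = files,
    lights_off_epoch = h1$lights_off_epoch,
    lights_on_epoch = h1$lights_on_epoch
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a scoring set from a manifest directory
#'
#' @param dir Directory written by [write_scoring_set()].
#' @param dialect Stage-code dialect for the per-scorer CSVs.
#' @return A `scoring_set`.
#' @export
read_scoring_set <- function(dir, dialect = "aasm") {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  hgs <- lapply(seq_along(mf$files), function(i) {
    read_hypnogram(file.path(dir, mf$files[i]), dialect = dialect,
                   epoch_duration = mf$epoch_duration,
                   scorer_id = mf$scorers[i], psg_id = mf$psg_id,
                   lights_off_epoch = mf$lights_off_epoch,
                   lights_on_epoch = mf$lights_on_epoch)
  })
  assemble_scoring_set(hgs, psg_id = mf$psg_id)
}
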