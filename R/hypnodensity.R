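#' Build a hypnodensity from a panel of manual scorings
#'
#' The probability of stage `s` at epoch `e` is the fraction of scorers who
#' assigned `s` at `e`. With `n` scorers every entry is a multiple of `1/n`
#' and rows sum to 1 exactly (integer counts divided by `n`).
#'
#' @param s A scoring set.
#' @return A [hypnodensity()] with `source = "scorers"`.
#' @export
hypnodensity_from_scorings <- function(s) {
  stopifnot(inherits(s, "scoring_set"))
  m <- label_matrix(s, as_integer = TRUE)
  n <- ncol(m)
  counts <- vapply(1:5, function(k) rowSums(m == k), numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  hypnodensity(counts / n, epoch_duration = s$hypnograms[[1]]$epoch_duration,
               source = "scorers", psg_id = s$psg_id)
}

#' One-hot hypnodensity encoding of a hypnogram
#'
#' @param hg A [hypnogram()].
#' @param source Source tag for the resulting hypnodensity.
#' @return A [hypnodensity()] whose rows are indicator vectors.
#' @export
one_hot_hypnodensity <- function(hg, source = "scorers") {
  stopifnot(inherits(hg, "hypnogram"))
  idx <- stage_index(hg$stages)
  p <- matrix(0, nrow = length(idx), ncol = 5L)
  p[cbind(seq_along(idx), idx)] <- 1
  hypnodensity(p, epoch_duration = hg$epoch_duration, source = source,
               psg_id = hg$psg_id)
}

#' Collapse a hypnodensity to a single-stage hypnogram
#'
#' Each epoch receives its maximal-probability stage; exact ties are broken
#' by the fixed stage priority (default `N3 > N2 > N1 > R > W`), making the
#' collapse deterministic. This realizes the "majority rule" reading of a
#' scorer-derived hypnodensity: the plurality stage wins.
#'
#' @param h A [hypnodensity()].
#' @param priority Permutation of the five stages; earlier wins ties.
#' @param scorer_id Identifier of the derived hypnogram.
#' @return A [hypnogram()].
#' @export
hypnodensity_to_hypnogram <- function(h, priority = stage_priority(),
                                      scorer_id = "majority") {
  stopifnot(inherits(h, "hypnodensity"))
  rank <- priority_rank(priority)
  p <- h$probabilities
  # order columns by priority so the first max hit is the tie-winner
  ord <- order(rank)
  winner <- ord[max.col(p[, ord, drop = FALSE], ties.method = "first")]
  hypnogram(sleep_stages()[winner], epoch_duration = h$epoch_duration,
            scorer_id = scorer_id, psg_id = h$psg_id)
}

#' Sleep report parameters from a hypnodensity
#'
#' Derives the standard sleep report directly from stage probabilities over
#' the half-open lights interval `[lights_off, lights_on)`:
#' \itemize{
#'   \item time in stage `s` = area under the stage-`s` probability curve,
#'     `sum(p_s) * epoch_duration / 60` minutes. For a scorer-derived
#'     hypnodensity this equals the across-scorer mean of per-scorer stage
#'     times exactly.
#'   \item sleep probability of an epoch = `1 - p_W`; sleep onset is the
#'     first epoch with sleep probability strictly greater than 0.5.
#'   \item sleep latency = minutes from lights-off to sleep onset;
#'     REM latency = minutes from sleep onset to the first epoch at or
#'     after onset with `p_R > 0.5`. Either is `NA` when no epoch
#'     qualifies.
#'   \item total sleep time = summed non-wake stage time; sleep efficiency
#'     = `100 * TST / time-in-bed`.
#' }
#' Latencies use the epoch-start convention: an onset at the first in-bed
#' epoch has latency 0.
#'
#' @param h A [hypnodensity()].
#' @param lights_off,lights_on 0-based epoch indices, `lights_on` exclusive.
#'   Defaults cover the whole recording.
#' @return An object of class `sleep_parameters`: a list with
#'   `time_in_bed`, `total_sleep_time`, `sleep_efficiency`, `time_in_stage`
#'   (named minutes per stage), `sleep_latency`, `rem_latency`,
#'   `sleep_onset_epoch` (0-based absolute index or `NA`).
#' @export
sleep_parameters_from_hypnodensity <- function(h, lights_off = 0,
                                               lights_on = length(h)) {
  stopifnot(inherits(h, "hypnodensity"))
  n <- nrow(h$probabilities)
  if (!(lights_off >= 0 && lights_off < lights_on && lights_on <= n))
    stop("lights interval must satisfy 0 <= off < on <= n_epochs")
  idx <- seq.int(lights_off + 1L, lights_on)  # 1-based rows in window
  p <- h$probabilities[idx, , drop = FALSE]
  min_per_epoch <- h$epoch_duration / 60

  time_in_stage <- colSums(p) * min_per_epoch
  names(time_in_stage) <- sleep_stages()
  tst <- sum(time_in_stage[c("N1", "N2", "N3", "R")])
  tib <- length(idx) * min_per_epoch

  p_sleep <- 1 - p[, "W"]
  onset_rel <- which(p_sleep > 0.5)[1L]  # NA if none
  if (is.na(onset_rel)) {
    sleep_latency <- NA_real_
    rem_latency <- NA_real_
    onset_abs <- NA_integer_
  } else {
    sleep_latency <- (onset_rel - 1L) * min_per_epoch
    onset_abs <- lights_off + onset_rel - 1L
    rem_rel <- which(p[, "R"] > 0.5 & seq_along(idx) >= onset_rel)[1L]
    rem_latency <- if (is.na(rem_rel)) NA_real_ else
      (rem_rel - onset_rel) * min_per_epoch
  }

  structure(
    list(time_in_bed = tib, total_sleep_time = tst,
         sleep_efficiency = 100 * tst / tib,
         time_in_stage = time_in_stage,
         sleep_latency = sleep_latency, rem_latency = rem_latency,
         sleep_onset_epoch = onset_abs),
    class = "sleep_parameters"
  )
}

#' Sleep report parameters from a single hypnogram
#'
#' Identical contract to [sleep_parameters_from_hypnodensity()] applied to
#' the one-hot probability encoding of the hypnogram, so single-scorer
#' reports and probability-based reports share one definition.
#'
#' @param hg A [hypnogram()].
#' @inheritParams sleep_parameters_from_hypnodensity
#' @return A `sleep_parameters` object.
#' @export
sleep_parameters_from_hypnogram <- function(hg, lights_off = 0,
                                            lights_on = length(hg)) {
  sleep_parameters_from_hypnodensity(one_hot_hypnodensity(hg),
                                     lights_off = lights_off,
                                     lights_on = lights_on)
}

#' @export
print.sleep_parameters <- function(x, ...) {
  cat(sprintf("<sleep_parameters> TIB %.1f min, TST %.1f min, SE %.1f%%\n",
              x$time_in_bed, x$total_sleep_time, x$sleep_efficiency))
  cat("  time in stage (min):",
      paste(sprintf("%s=%.1f", names(x$time_in_stage), x$time_in_stage),
            collapse = " "), "\n")
  cat(sprintf("  sleep latency %s min, REM latency %s min\n",
              format(x$sleep_latency), format(x$rem_latency)))
  invisible(x)
}

#' Serialize sleep parameters as flat JSON
#'
#' @param x A `sleep_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_parameters <- function(x, path) {
  stopifnot(inherits(x, "sleep_parameters"))
  flat <- c(
    list(time_in_bed = x$time_in_bed,
         total_sleep_time = x$total_sleep_time,
         sleep_efficiency = x$sleep_efficiency),
    as.list(stats::setNames(as.numeric(x$time_in_stage),
                            paste0("time_in_", names(x$time_in_stage)))),
    list(sleep_latency = x$sleep_latency, rem_latency = x$rem_latency,
         sleep_onset_epoch = x$sleep_onset_epoch)
  )
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
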