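#' Reliability weight of each scorer in a panel
#'
#' A scorer's reliability is their mean pairwise Cohen's kappa with every
#' other scorer in the panel, computed once over all epochs. Used to weight
#' votes when a consensus plurality is tied: more reliable scorers count
#' more. Undefined pairwise kappas (constant sequences) are dropped from
#' the mean.
#'
#' @param s A scoring set.
#' @return Named numeric vector of weights, one per scorer.
#' @export
scorer_reliability <- function(s) {
  stopifnot(inherits(s, "scoring_set"))
  m <- label_matrix(s)
  n <- ncol(m)
  km <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      km[i, j] <- km[j, i] <- cohen_kappa(m[, i], m[, j])
    }
  }
  w <- rowMeans(km, na.rm = TRUE)
  w[is.nan(w)] <- 0
  stats::setNames(w, scorer_ids(s))
}

#' Unbiased majority-vote consensus of a scorer panel
#'
#' The consensus staging of the panel, excluding one scorer when that
#' scorer is itself being evaluated ("unbiased" leave-one-out consensus).
#' Per epoch the plurality stage of the remaining scorers wins; ties are
#' resolved by summing the tied candidates' voter reliability weights
#' (mean pairwise kappa among the remaining scorers, see
#' [scorer_reliability()]); a tie that survives weighting falls back to the
#' fixed stage priority. The construction is deterministic and invariant to
#' scorer ordering.
#'
#' @param s A scoring set.
#' @param excluded_scorer A `scorer_id` to leave out, or `NULL` for the
#'   full-panel consensus.
#' @param priority Stage priority for final tie-breaks.
#' @return A [hypnogram()] with `scorer_id = "consensus"`.
#' @export
unbiased_consensus <- function(s, excluded_scorer = NULL,
                               priority = stage_priority()) {
  stopifnot(inherits(s, "scoring_set"))
  ids <- scorer_ids(s)
  keep <- seq_along(ids)
  if (!is.null(excluded_scorer)) {
    if (!excluded_scorer %in% ids)
      stop("unknown scorer_id: ", excluded_scorer)
    keep <- keep[ids != excluded_scorer]
  }
  if (length(keep) < 2L)
    stop("need at least two remaining scorers for a consensus")
  sub <- assemble_scoring_set(s$hypnograms[keep], psg_id = s$psg_id)
  m <- label_matrix(sub, as_integer = TRUE)
  w <- unname(scorer_reliability(sub))
  rank <- priority_rank(priority)

  counts <- vapply(1:5, function(k) rowSums(m == k), numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  maxc <- counts == matrixStats_rowMax(counts)

  winner <- integer(nrow(m))
  n_tied <- rowSums(maxc)
  simple <- n_tied == 1L
  winner[simple] <- max.col(maxc[simple, , drop = FALSE])

  for (e in which(!simple)) {
    cand <- which(maxc[e, ])
    wsum <- vapply(cand, function(k) sum(w[m[e, ] == k]), numeric(1))
    best <- cand[wsum == max(wsum)]
    winner[e] <- if (length(best) == 1L) best else
      best[which.min(rank[best])]
  }
  hypnogram(sleep_stages()[winner],
            epoch_duration = s$hypnograms[[1]]$epoch_duration,
            scorer_id = "consensus", psg_id = s$psg_id)
}

matrixStats_rowMax <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Cohen's kappa of every scorer (and the auto-scorer) against three comparators
#'
#' Evaluates each scorer of the panel -- and optionally an auto-scored
#' hypnogram aligned to the same PSG -- against:
#' \describe{
#'   \item{`individual`}{each remaining scorer pairwise; the kappas are
#'     averaged per test scorer.}
#'   \item{`unbiased_consensus`}{the leave-one-out majority consensus of
#'     the remaining scorers ([unbiased_consensus()]). The auto-scorer is
#'     compared against the same leave-one-out consensus for every scorer
#'     and the kappas averaged, so manual and auto face identical
#'     comparators.}
#'   \item{`any_scorer`}{agreement counts whenever at least one remaining
#'     scorer matches the test label. Kappa needs a concrete reference
#'     sequence, so the reference carries the test label where some
#'     remaining scorer agrees and the leave-one-out consensus label
#'     elsewhere.}
#' }
#' Kappas are computed for the five-stage comparison (`stage = "all"`) and
#' for each stage one-vs-rest. Undefined kappas are excluded from averages;
#' the number excluded is recorded in `attr(, "n_undefined")`.
#'
#' @param s A scoring set.
#' @param auto Optional [hypnogram()] from the auto-scorer, aligned to `s`.
#' @param priority Stage priority for consensus tie-breaks.
#' @param stages Which comparisons to compute: `"all"` for the five-stage
#'   kappa and/or individual stage labels for one-vs-rest kappas. Default
#'   computes everything.
#' @return A data.frame with columns `psg_id, comparator, stage, scorer,
#'   kappa`, where `scorer` is a manual `scorer_id` or `"auto"` (auto rows
#'   are already averaged over leave-one-out panels).
#' @export
kappa_vs_comparators <- function(s, auto = NULL,
                                 priority = stage_priority(),
                                 stages = c("all", sleep_stages())) {
  stopifnot(inherits(s, "scoring_set"))
  if (!is.null(auto)) {
    stopifnot(inherits(auto, "hypnogram"))
    if (length(auto$stages) != length(s$hypnograms[[1]]$stages))
      stop("auto-scored hypnogram is not aligned to the scoring set")
  }
  m <- label_matrix(s)
  ids <- scorer_ids(s)
  n <- ncol(m)
  if (!all(stages %in% c("all", sleep_stages())))
    stop("`stages` must be \"all\" and/or stage labels")
  n_undefined <- 0L

  kap <- function(a, b, stage) {
    k <- if (stage == "all") cohen_kappa(a, b) else per_stage_kappa(a, b, stage)
    if (is.na(k)) n_undefined <<- n_undefined + 1L
    k
  }
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

  # leave-one-out consensus per test scorer, shared by all comparators
  loo_cons <- lapply(ids, function(id)
    unbiased_consensus(s, excluded_scorer = id, priority = priority)$stages)

  rows <- list()
  add <- function(comparator, stage, scorer, kappa) {
    rows[[length(rows) + 1L]] <<- data.frame(
      psg_id = s$psg_id, comparator = comparator, stage = stage,
      scorer = scorer, kappa = kappa)
  }

  any_reference <- function(test_labels, rest) {
    hit <- rowSums(rest == test_labels) > 0L
    hit
  }

  for (stg in stages) {
    # --- manual scorers ---
    auto_ind <- auto_con <- auto_any <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      test <- m[, i]
      rest <- m[, -i, drop = FALSE]
      cons <- loo_cons[[i]]

      add("individual", stg, ids[i],
          mean_def(vapply(seq_len(ncol(rest)),
                          function(j) kap(test, rest[, j], stg), numeric(1))))
      add("unbiased_consensus", stg, ids[i], kap(test, cons, stg))
      ref <- ifelse(any_reference(test, rest), test, cons)
      add("any_scorer", stg, ids[i], kap(test, ref, stg))

      if (!is.null(auto)) {
        a <- auto$stages
        auto_ind[i] <- mean_def(vapply(seq_len(ncol(rest)), function(j)
          kap(a, rest[, j], stg), numeric(1)))
        auto_con[i] <- kap(a, cons, stg)
        ref_a <- ifelse(any_reference(a, rest), a, cons)
        auto_any[i] <- kap(a, ref_a, stg)
      }
    }
    if (!is.null(auto)) {
      add("individual", stg, "auto", mean_def(auto_ind))
      add("unbiased_consensus", stg, "auto", mean_def(auto_con))
      add("any_scorer", stg, "auto", mean_def(auto_any))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_undefined") <- n_undefined
  out
}

#' Aggregate a per-PSG kappa table into a mean +/- SD summary
#'
#' Kappas are computed per PSG and aggregated across PSGs: manual scorers
#' are first averaged within each PSG, then summarized across PSGs, and the
#' auto-scorer rows are summarized across PSGs directly. With
#' `pooling = "pooled_scorers"` manual scorer rows enter the across-PSG
#' pool individually instead of being averaged per PSG first.
#'
#' @param tbl A kappa table from [kappa_vs_comparators()] (rows from one or
#'   several PSGs bound together).
#' @param pooling `"per_psg_mean"` (default) or `"pooled_scorers"`.
#' @return A data.frame `comparator, stage, who, mean, sd, n` where `who`
#'   is `"manual"` or `"auto"`.
#' @export
kappa_summary <- function(tbl, pooling = c("per_psg_mean", "pooled_scorers")) {
  pooling <- match.arg(pooling)
  tbl$who <- ifelse(tbl$scorer == "auto", "auto", "manual")
  if (pooling == "per_psg_mean") {
    agg <- stats::aggregate(kappa ~ psg_id + comparator + stage + who,
                            data = tbl, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
  } else {
    agg <- tbl
  }
  out <- stats::aggregate(
    kappa ~ comparator + stage + who, data = agg,
    FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                        sd = if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0,
                        n = sum(!is.na(x))),
    na.action = stats::na.pass)
  data.frame(comparator = out$comparator, stage = out$stage, who = out$who,
             mean = out$kappa[, "mean"], sd = out$kappa[, "sd"],
             n = out$kappa[, "n"])
}
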