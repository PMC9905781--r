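#' Percentage of epochs with complete agreement
#'
#' The fraction (as a percentage) of epochs at which every sequence carries
#' the identical stage label.
#'
#' @param labels A character matrix (epochs x scorers), or a list of
#'   equal-length label vectors, or a scoring set.
#' @return Percentage in \[0, 100\].
#' @export
complete_agreement <- function(labels) {
  m <- as_label_mat(labels)
  if (ncol(m) == 1L) return(100)
  eq <- m == m[, 1L]
  100 * mean(rowSums(eq) == ncol(m))
}

as_label_mat <- function(labels) {
  if (inherits(labels, "scoring_set")) return(label_matrix(labels))
  if (is.matrix(labels)) {
    if (nrow(labels) < 1L) stop("need at least one epoch")
    return(labels)
  }
  if (is.list(labels)) {
    lens <- lengths(labels)
    if (length(unique(lens)) != 1L)
      stop("label sequences have unequal lengths: ",
           paste(lens, collapse = ", "))
    if (lens[1] < 1L) stop("need at least one epoch")
    return(matrix(unlist(labels), ncol = length(labels)))
  }
  stop("`labels` must be a matrix, list of vectors, or scoring_set")
}

#' Complete-agreement decay across panel sizes
#'
#' For each panel size `k`, evaluates [complete_agreement()] on every
#' size-`k` subset of the scorer panel and averages across subsets.
#' Averaging over unordered subsets (combinations) equals averaging over all
#' ordered permutations, because complete agreement is invariant to scorer
#' order; combinations are enumerated for efficiency.
#'
#' With `pooling = "pooled_epochs"` the epochs of all PSGs are concatenated
#' before agreement is computed (scorer columns aligned by panel position);
#' with `"per_psg_mean"` agreement is computed per PSG and averaged across
#' PSGs for each subset.
#'
#' `stage_condition` restricts the epoch set to epochs whose full-panel
#' consensus label (plurality over all scorers, priority tie-break) equals
#' the given stage, yielding per-stage decay curves.
#'
#' @param sets A scoring set or list of scoring sets sharing a scorer count.
#' @param k_range Integer vector of panel sizes, each in `[2, n]`. Default
#'   `2:n`.
#' @param pooling `"pooled_epochs"` (default) or `"per_psg_mean"`.
#' @param stage_condition `"all"` (default) or one stage label.
#' @param max_subsets If the number of size-`k` subsets exceeds this, a
#'   deterministic random sample of subsets of this size is used (seeded
#'   internally, so results are reproducible). Default `Inf` (exhaustive).
#' @return An object of class `agreement_curve`: list with `summary`
#'   (data.frame `k, mean_agreement, sd_agreement, n_subsets`),
#'   `per_subset` (list mapping `k` to the subset agreement percentages),
#'   `pooling`, `stage_condition`, `n_scorers`.
#' @export
agreement_curve <- function(sets, k_range = NULL,
                            pooling = c("pooled_epochs", "per_psg_mean"),
                            stage_condition = "all", max_subsets = Inf) {
  pooling <- match.arg(pooling)
  if (inherits(sets, "scoring_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "scoring_set")))
  ns <- vapply(sets, n_scorers, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all scoring sets must share the same number of scorers")
  n <- ns[1]
  if (is.null(k_range)) k_range <- 2:n
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > n))
    stop(sprintf("k must lie in [2, %d]", n))

  mats <- lapply(sets, label_matrix, as_integer = TRUE)
  if (!identical(stage_condition, "all")) {
    stage_index(stage_condition)  # validates
    mats <- lapply(seq_along(mats), function(i) {
      cons <- hypnodensity_to_hypnogram(hypnodensity_from_scorings(sets[[i]]))
      mats[[i]][cons$stages == stage_condition, , drop = FALSE]
    })
    mats <- mats[vapply(mats, nrow, integer(1)) > 0L]
    if (length(mats) == 0L)
      stop("no epochs with consensus stage ", stage_condition)
  }
  pooled <- if (pooling == "pooled_epochs") do.call(rbind, mats) else NULL

  per_subset <- list()
  rows <- lapply(k_range, function(k) {
    subsets <- enumerate_subsets(n, k, max_subsets)
    ag <- vapply(subsets, function(cols) {
      if (pooling == "pooled_epochs") {
        subset_agreement(pooled, cols)
      } else {
        mean(vapply(mats, subset_agreement, numeric(1), cols = cols))
      }
    }, numeric(1))
    per_subset[[as.character(k)]] <<- ag
    data.frame(k = k, mean_agreement = mean(ag),
               sd_agreement = if (length(ag) > 1L) stats::sd(ag) else 0,
               n_subsets = length(ag))
  })

  structure(
    list(summary = do.call(rbind, rows), per_subset = per_subset,
         pooling = pooling, stage_condition = stage_condition,
         n_scorers = n),
    class = "agreement_curve"
  )
}

# integer label matrix, columns cols: % epochs where all selected agree
subset_agreement <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  100 * mean(rowSums(sub == sub[, 1L]) == length(cols))
}

enumerate_subsets <- function(n, k, max_subsets) {
  n_comb <- choose(n, k)
  if (n_comb <= max_subsets) {
    cmb <- utils::combn(n, k)
    return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  # deterministic subsample of distinct subsets
  withr::with_seed(k * 10007L + n, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", max_subsets)
    i <- 0L
    while (i < max_subsets) {
      cand <- sort(sample.int(n, k))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        i <- i + 1L
        out[[i]] <- cand
      }
    }
    out
  })
}

#' @export
print.agreement_curve <- function(x, ...) {
  cat(sprintf("<agreement_curve> %s, stage=%s, n_scorers=%d\n",
              x$pooling, x$stage_condition, x$n_scorers))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit the power model y = a * x^b to an agreement curve
#'
#' `y` is the mean complete-agreement percentage and `x` the panel size.
#' The default estimator is ordinary least squares on `log(y) ~ log(x)`
#' (exact for data lying on a power curve); `method = "nls"` refines that
#' fit by nonlinear least squares in the original percent space.
#' `r_squared` is always reported in the original space as
#' `1 - SS_res / SS_tot`, with the convention that perfectly reproduced
#' constant data (both sums of squares zero) gives 1.
#'
#' @param curve An `agreement_curve`, or a numeric vector of agreements
#'   (percent) with `k` supplied.
#' @param k Panel sizes when `curve` is a plain vector.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return An object of class `power_fit`: list with `a`, `b`, `r_squared`,
#'   `k`, `y`, `method`.
#' @export
fit_power_law <- function(curve, k = NULL, method = c("loglog", "nls")) {
  method <- match.arg(method)
  if (inherits(curve, "agreement_curve")) {
    y <- curve$summary$mean_agreement
    k <- curve$summary$k
  } else {
    y <- as.numeric(curve)
    if (is.null(k)) stop("supply `k` when `curve` is a plain vector")
  }
  if (length(y) != length(k)) stop("k and y lengths differ")
  if (length(unique(k)) < 2L)
    stop("need at least two distinct panel sizes to fit")
  if (any(y <= 0))
    stop("power-law fit undefined for zero or negative agreement values")

  fit <- stats::lm(log(y) ~ log(k))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0  # constant x cannot occur (distinct k enforced)

  if (method == "nls") {
    nl <- try(stats::nls(y ~ a * k^b, start = list(a = a, b = b)),
              silent = TRUE)
    if (!inherits(nl, "try-error")) {
      a <- unname(stats::coef(nl)["a"])
      b <- unname(stats::coef(nl)["b"])
    }
  }

  yhat <- a * k^b
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-20) 1 else NA_real_
  } else 1 - ss_res / ss_tot

  structure(list(a = a, b = b, r_squared = r2, k = k, y = y,
                 method = method),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> y = %.4g * x^%.4g, R^2 = %.6f (%s)\n",
              x$a, x$b, x$r_squared, x$method))
  invisible(x)
}

#' Predict complete agreement for a given panel size
#'
#' Evaluates the fitted power model `a * x^b` and clips the result to
#' \[0, 100\] percent.
#'
#' @param fit A `power_fit`, or a list with elements `a` and `b`.
#' @param x Panel size(s), each >= 1.
#' @return Predicted agreement percentage(s).
#' @export
predict_agreement <- function(fit, x) {
  if (any(x < 1)) stop("panel size must be >= 1")
  pmin(100, pmax(0, fit$a * x^fit$b))
}
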