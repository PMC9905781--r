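#' ICC(2,1): single-measure absolute-agreement intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC for two
#' raters (here: two probability series over the same epochs). With `n`
#' targets and `k = 2` raters, the mean squares of the two-way ANOVA
#' decomposition (rows = targets, columns = raters) give
#' \deqn{ICC = (MSR - MSE) / (MSR + MSE + (2/n)(MSC - MSE)).}
#' The 95% confidence interval follows the F-based construction of McGraw &
#' Wong for ICC(A,1) (Satterthwaite degrees of freedom for the rater term).
#'
#' @param x,y Equal-length numeric series (the two raters), `n >= 3`.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `icc`, `ci_low`, `ci_high`, `n`; `icc` is `NA` (with
#'   NA bounds) when the between-target variance is zero so agreement is
#'   undefined.
#' @export
icc_2_1 <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("series have unequal lengths")
  n <- length(x)
  if (n < 3L) stop("need at least 3 targets")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sst <- sum((dat - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  mse <- max(mse, 0)

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= .Machine$double.eps * max(1, abs(msr)) || msr == 0) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  ci <- c(NA_real_, NA_real_)
  if (is.finite(a) && is.finite(b) && mse > 0) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, lower), min(1, upper))
  } else if (mse == 0) {
    ci <- c(icc, icc)  # perfect agreement: interval degenerates
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Compare two hypnodensities with per-stage and overall ICC(2,1)
#'
#' Treats the two probability sources (e.g. scorer-derived vs auto-scored)
#' as two raters of the same epochs. Per stage, the ICC is computed on the
#' two probability series of that stage; the overall ICC stacks the five
#' per-stage series into one pair of length `5 * n_epochs`, reproducing a
#' single reliability value for the whole hypnodensity. Stages with less
#' than `low_support_minutes` of area under the reference probability curve
#' are flagged: their ICCs rest on too little of the stage to be
#' statistically meaningful.
#'
#' @param manual Reference [hypnodensity()] (typically scorer-derived).
#' @param auto Comparison [hypnodensity()] (typically auto-scored).
#' @param low_support_minutes Flagging threshold in minutes, default 3.5.
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `icc_report`: list with `per_stage`
#'   (data.frame `stage, icc, ci_low, ci_high, reference_minutes,
#'   low_support`), `all_stage` (list `icc, ci_low, ci_high`),
#'   `n_epochs`, `low_support_stages`.
#' @export
compare_hypnodensities <- function(manual, auto, low_support_minutes = 3.5,
                                   conf_level = 0.95) {
  stopifnot(inherits(manual, "hypnodensity"), inherits(auto, "hypnodensity"))
  pm <- manual$probabilities
  pa <- auto$probabilities
  if (nrow(pm) != nrow(pa))
    stop("hypnodensities have different epoch counts")
  mins <- colSums(pm) * manual$epoch_duration / 60

  per_stage <- lapply(1:5, function(j) {
    r <- icc_2_1(pm[, j], pa[, j], conf_level = conf_level)
    data.frame(stage = sleep_stages()[j], icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, reference_minutes = mins[j],
               low_support = mins[j] < low_support_minutes)
  })
  per_stage <- do.call(rbind, per_stage)
  overall <- icc_2_1(as.vector(pm), as.vector(pa), conf_level = conf_level)

  structure(
    list(per_stage = per_stage,
         all_stage = list(icc = overall$icc, ci_low = overall$ci_low,
                          ci_high = overall$ci_high),
         n_epochs = nrow(pm),
         low_support_stages = per_stage$stage[per_stage$low_support]),
    class = "icc_report"
  )
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("<icc_report> %d epochs; overall ICC %.3f [%.3f, %.3f]\n",
              x$n_epochs, x$all_stage$icc, x$all_stage$ci_low,
              x$all_stage$ci_high))
  print(x$per_stage, row.names = FALSE, digits = 3)
  if (length(x$low_support_stages))
    cat("  low-support stages:",
        paste(x$low_support_stages, collapse = ", "), "\n")
  invisible(x)
}
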