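#' Cohen's kappa between two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` computed from the marginal label frequencies of each
#' sequence. When both sequences are constant on the same label, `p_e = 1`
#' and kappa is undefined; `NA` is returned and callers exclude it from
#' aggregation (with a count of exclusions where reported).
#'
#' @param a,b Equal-length character vectors of stage labels (any label
#'   vocabulary; the two sequences define their own categories).
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  if (length(a) < 1L) stop("need at least one epoch")
  n <- length(a)
  p_o <- mean(a == b)
  labs <- union(unique(a), unique(b))
  pa <- tabulate(match(a, labs), nbins = length(labs)) / n
  pb <- tabulate(match(b, labs), nbins = length(labs)) / n
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < .Machine$double.eps * 8) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Per-stage (one-vs-rest) Cohen's kappa
#'
#' Collapses both sequences to binary `stage` / `other` and applies
#' [cohen_kappa()]. Undefined (NA) when the stage is absent from both
#' sequences (both collapse to the constant `other`).
#'
#' @inheritParams cohen_kappa
#' @param stage One of the five stage labels.
#' @return Kappa or `NA`.
#' @export
per_stage_kappa <- function(a, b, stage) {
  stage_index(stage)
  cohen_kappa(ifelse(a == stage, stage, "other"),
              ifelse(b == stage, stage, "other"))
}

#' Paired t-test on per-PSG kappa values
#'
#' Two-sided paired-samples t-test on the per-PSG differences
#' `auto - manual`. Zero-variance differences are degenerate: the test
#' statistic is reported as 0 (all differences zero) or signed infinity,
#' with `degenerate = TRUE`.
#'
#' @param manual_kappas,auto_kappas Numeric vectors paired by PSG.
#' @return List with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_kappa_test <- function(manual_kappas, auto_kappas) {
  if (length(manual_kappas) != length(auto_kappas))
    stop("kappa vectors must be paired by PSG (equal length)")
  if (length(manual_kappas) < 2L) stop("need at least two PSGs")
  d <- auto_kappas - manual_kappas
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                p_value = if (md == 0) 1 else 0,
                df = length(d) - 1L, mean_difference = md,
                degenerate = TRUE))
  }
  tt <- stats::t.test(auto_kappas, manual_kappas, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d),
       degenerate = FALSE)
}
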