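#' Run the full multi-scorer analysis over a dataset
#'
#' Orchestrates every dataset-level analysis on a collection of PSGs, each
#' scored by the same number of scorers and optionally accompanied by an
#' auto-scored hypnodensity:
#' \enumerate{
#'   \item pooled complete-agreement curve across panel sizes and its
#'     power-model fit (plus per-PSG full-panel agreement);
#'   \item per-PSG Cohen's kappa of every scorer and the auto-scorer
#'     against the three comparators, with the mean +/- SD summary;
#'   \item per-PSG ICC(2,1) between the scorer-derived and auto-scored
#'     hypnodensities, per stage and overall, with the across-PSG summary;
#'   \item a paired t-test of per-PSG auto vs manual consensus kappas.
#' }
#' Every summary cell is reproducible from the per-PSG tables by the
#' documented aggregation, and the whole report is deterministic for a
#' fixed input dataset.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()], or a list in
#'   which each element has `$scorings` (a scoring set) and optionally
#'   `$auto` (an aligned auto-scorer [hypnodensity()]).
#' @param k_range Panel sizes for the agreement curve (default `2:n`).
#' @param low_support_minutes ICC low-support flag threshold (minutes).
#' @param max_subsets Subset cap passed to [agreement_curve()].
#' @param kappa_stages Passed to [kappa_vs_comparators()]; restrict to
#'   `"all"` to skip the per-stage kappa breakdown.
#' @return An object of class `dataset_report`: list with elements
#'   `agreement` (curve summary + `power_fit`), `kappa` (`per_psg` table,
#'   `summary`), `icc` (`per_psg` table, `summary`), `paired_test`,
#'   `provenance`.
#' @export
run_dataset_analysis <- function(dataset, k_range = NULL,
                                 low_support_minutes = 3.5,
                                 max_subsets = Inf,
                                 kappa_stages = c("all", sleep_stages())) {
  psgs <- unclass(dataset)
  attributes(psgs) <- attributes(psgs)["names"]
  stopifnot(length(psgs) >= 1L)
  sets <- lapply(psgs, `[[`, "scorings")
  autos <- lapply(psgs, `[[`, "auto")
  has_auto <- !vapply(autos, is.null, logical(1))

  # --- agreement decay + power model (pooled epochs) ---
  curve <- agreement_curve(sets, k_range = k_range,
                           pooling = "pooled_epochs",
                           max_subsets = max_subsets)
  fit <- fit_power_law(curve)
  per_psg_agreement <- data.frame(
    psg_id = vapply(sets, `[[`, character(1), "psg_id"),
    full_panel_agreement = vapply(sets, complete_agreement, numeric(1)),
    row.names = NULL
  )

  # --- kappa vs the three comparators, per PSG ---
  kappa_per_psg <- do.call(rbind, lapply(seq_along(sets), function(i) {
    auto_hg <- if (has_auto[i])
      hypnodensity_to_hypnogram(autos[[i]], scorer_id = "auto") else NULL
    kappa_vs_comparators(sets[[i]], auto = auto_hg, stages = kappa_stages)
  }))
  rownames(kappa_per_psg) <- NULL
  kappa_sum <- kappa_summary(kappa_per_psg)

  # --- ICC manual- vs auto-scored probabilities, per PSG ---
  icc_per_psg <- NULL
  icc_sum <- NULL
  if (any(has_auto)) {
    icc_per_psg <- do.call(rbind, lapply(which(has_auto), function(i) {
      manual <- hypnodensity_from_scorings(sets[[i]])
      rep_i <- compare_hypnodensities(manual, autos[[i]],
                                      low_support_minutes = low_support_minutes)
      rbind(
        data.frame(psg_id = sets[[i]]$psg_id, stage = "all",
                   icc = rep_i$all_stage$icc, ci_low = rep_i$all_stage$ci_low,
                   ci_high = rep_i$all_stage$ci_high,
                   reference_minutes = NA_real_, low_support = FALSE),
        cbind(psg_id = sets[[i]]$psg_id, rep_i$per_stage)
      )
    }))
    rownames(icc_per_psg) <- NULL
    ok <- !icc_per_psg$low_support & !is.na(icc_per_psg$icc)
    icc_sum <- stats::aggregate(
      cbind(icc, ci_low, ci_high) ~ stage, data = icc_per_psg[ok, ],
      FUN = mean)
    icc_sum$n_psg <- stats::aggregate(icc ~ stage, data = icc_per_psg[ok, ],
                                      FUN = length)$icc
  }

  # --- paired test: auto vs manual consensus kappa per PSG ---
  paired <- NULL
  if (any(has_auto)) {
    cons <- kappa_per_psg[kappa_per_psg$comparator == "unbiased_consensus" &
                            kappa_per_psg$stage == "all", ]
    manual_k <- stats::aggregate(
      kappa ~ psg_id, data = cons[cons$scorer != "auto", ], FUN = mean)
    auto_k <- cons[cons$scorer == "auto", c("psg_id", "kappa")]
    merged <- merge(manual_k, auto_k, by = "psg_id",
                    suffixes = c("_manual", "_auto"))
    if (nrow(merged) >= 2L) {
      paired <- paired_kappa_test(merged$kappa_manual, merged$kappa_auto)
      paired$per_psg <- merged
    }
  }

  structure(
    list(
      agreement = list(curve = curve$summary, power_fit = fit[c("a", "b", "r_squared")],
                       per_psg = per_psg_agreement),
      kappa = list(per_psg = kappa_per_psg, summary = kappa_sum),
      icc = list(per_psg = icc_per_psg, summary = icc_sum),
      paired_test = paired,
      provenance = list(
        n_psg = length(sets),
        n_scorers = n_scorers(sets[[1]]),
        n_epochs = length(sets[[1]]$hypnograms[[1]]$stages),
        seed = attr(dataset, "base_seed"),
        package_version = as.character(utils::packageVersion("hypnoagree"))
      )
    ),
    class = "dataset_report"
  )
}

#' @export
print.dataset_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<dataset_report> %d PSGs x %d scorers x %d epochs\n",
              p$n_psg, p$n_scorers, p$n_epochs))
  f <- x$agreement$power_fit
  cat(sprintf("  agreement decay: y = %.1f * x^%.3f (R^2 = %.4f)\n",
              f$a, f$b, f$r_squared))
  ks <- x$kappa$summary
  all5 <- ks[ks$stage == "all", ]
  for (i in seq_len(nrow(all5)))
    cat(sprintf("  kappa[%s, %s] = %.3f +/- %.3f\n", all5$comparator[i],
                all5$who[i], all5$mean[i], all5$sd[i]))
  if (!is.null(x$icc$summary)) {
    o <- x$icc$summary[x$icc$summary$stage == "all", ]
    cat(sprintf("  overall ICC (mean across PSGs) = %.3f\n", o$icc))
  }
  if (!is.null(x$paired_test))
    cat(sprintf("  paired t-test auto vs manual consensus kappa: t = %.3f, p = %.3g\n",
                x$paired_test$statistic, x$paired_test$p_value))
  invisible(x)
}

#' Write a dataset report as deterministic CSV/JSON artifacts
#'
#' Writes `agreement_curve.csv`, `power_fit.csv`, `kappa_per_psg.csv`,
#' `kappa_summary.csv`, `icc_per_psg.csv`, `icc_summary.csv` and a single
#' `report.json` holding every block. No timestamps are embedded: a report
#' built from the same dataset is byte-identical across runs.
#'
#' @param report A `dataset_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_report <- function(report, dir) {
  stopifnot(inherits(report, "dataset_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wcsv(report$agreement$curve, "agreement_curve.csv")
  wcsv(data.frame(a = report$agreement$power_fit$a,
                  b = report$agreement$power_fit$b,
                  r_squared = report$agreement$power_fit$r_squared),
       "power_fit.csv")
  wcsv(report$kappa$per_psg, "kappa_per_psg.csv")
  wcsv(report$kappa$summary, "kappa_summary.csv")
  wcsv(report$icc$per_psg, "icc_per_psg.csv")
  wcsv(report$icc$summary, "icc_summary.csv")
  payload <- report
  class(payload) <- NULL
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}
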