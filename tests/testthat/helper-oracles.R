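# Independent oracles and small builders shared across test files.

STAGES <- c("W", "N1", "N2", "N3", "R")

make_hg <- function(stages, id = "s1", psg = "p1", dur = 30) {
  hypnogram(stages, epoch_duration = dur, scorer_id = id, psg_id = psg)
}

make_set <- function(..., psg = "p1") {
  seqs <- list(...)
  assemble_scoring_set(
    lapply(seq_along(seqs), function(i)
      make_hg(seqs[[i]], id = paste0("s", i), psg = psg)),
    psg_id = psg)
}

random_set <- function(n_scorers, n_epochs, psg = "p1") {
  hgs <- lapply(seq_len(n_scorers), function(i)
    make_hg(sample(STAGES, n_epochs, replace = TRUE),
            id = paste0("s", i), psg = psg))
  assemble_scoring_set(hgs, psg_id = psg)
}

# Cohen's kappa from the contingency table, independent of the package's
# marginal-frequency route (cross-checked against e1071 where available).
kappa_oracle <- function(a, b) {
  labs <- union(unique(a), unique(b))
  tab <- table(factor(a, levels = labs), factor(b, levels = labs))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# ICC(2,1) via a two-way ANOVA fit with aov(): an independent route to the
# mean squares used by icc_2_1().
icc_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(score = c(x, y),
                   target = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(c("x", "y"), each = n)))
  ms <- anova(aov(score ~ target + rater, data = df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

label_matrix_of <- function(s)
  vapply(s$hypnograms, `[[`, character(length(s$hypnograms[[1]]$stages)),
         "stages")

# exhaustive ordered k-permutations of 1..n
ordered_permutations <- function(n, k) {
  if (k == 1L) return(lapply(seq_len(n), identity))
  out <- list()
  for (p in ordered_permutations(n, k - 1L)) {
    for (j in setdiff(seq_len(n), p)) out[[length(out) + 1L]] <- c(p, j)
  }
  out
}
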