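#' Default stage transition matrix of the latent sleep architecture
#'
#' First-order, time-homogeneous Markov chain over `W,N1,N2,N3,R` tuned to
#' produce a plausible whole-night occupancy (N2-dominant, modest N3 and R,
#' intermittent wake). Early-night N3 clustering and ultradian REM cycling
#' are deliberately not modeled: a homogeneous chain suffices to exercise
#' the agreement statistics.
#'
#' @return 5x5 row-stochastic matrix with stage dimnames.
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    W  = c(0.86, 0.10, 0.02, 0.00, 0.02),
    N1 = c(0.09, 0.58, 0.29, 0.00, 0.04),
    N2 = c(0.03, 0.07, 0.81, 0.05, 0.04),
    N3 = c(0.02, 0.01, 0.22, 0.75, 0.00),
    R  = c(0.05, 0.05, 0.06, 0.00, 0.84)
  )
  colnames(m) <- sleep_stages()
  m
}

#' Default stage confusability (adjacency) mass
#'
#' Nonnegative mass that ambiguous epochs spread onto stages confusable
#' with the latent stage. Mass is concentrated along the AASM-adjacent
#' pairs where human scorers disagree most (W-N1, N1-N2, N2-N3, N1-R), so
#' N1 and N3 epochs are the most ambiguous and W/R the least -- the
#' qualitative pattern reported for multi-scorer panels. Magnitudes are
#' free simulator parameters, not measured quantities.
#'
#' @return 5x5 nonnegative matrix, zero diagonal, stage dimnames.
#' @export
default_stage_adjacency <- function() {
  m <- rbind(
    W  = c(0.0, 2.0, 0.3, 0.0, 0.2),
    N1 = c(1.2, 0.0, 1.8, 0.1, 0.9),
    N2 = c(0.2, 1.3, 0.0, 1.3, 0.3),
    N3 = c(0.1, 0.2, 3.0, 0.0, 0.0),
    R  = c(0.4, 1.3, 0.4, 0.0, 0.0)
  )
  colnames(m) <- sleep_stages()
  m
}

#' Mildly biased per-scorer confusion matrices
#'
#' Each scorer misreads a label with a small scorer-specific probability,
#' leaking it onto stages in proportion to the adjacency mass. Scorers
#' sharing a `center` index share a confusion matrix, emulating
#' within-center alignment of scoring habits.
#'
#' @param n_scorers Number of scorers.
#' @param eps Per-scorer misread probabilities, recycled; default cycles
#'   through 0.01--0.04.
#' @param centers Optional integer vector assigning scorers to centers;
#'   scorers in one center share a matrix.
#' @param adjacency Confusability mass used for the leak direction.
#' @return List of 5x5 row-stochastic matrices, one per scorer.
#' @export
biased_scorer_confusions <- function(n_scorers,
                                     eps = c(0.01, 0.02, 0.03, 0.04),
                                     centers = NULL,
                                     adjacency = default_stage_adjacency()) {
  eps <- rep_len(eps, n_scorers)
  if (!is.null(centers)) {
    stopifnot(length(centers) == n_scorers)
    eps <- eps[match(centers, unique(centers))]  # one eps per center
  }
  leak <- adjacency / pmax(rowSums(adjacency), .Machine$double.eps)
  lapply(seq_len(n_scorers), function(i) {
    cm <- (1 - eps[i]) * diag(5) + eps[i] * leak
    dimnames(cm) <- list(sleep_stages(), sleep_stages())
    cm
  })
}

identity_confusions <- function(n_scorers) {
  cm <- diag(5)
  dimnames(cm) <- list(sleep_stages(), sleep_stages())
  rep(list(cm), n_scorers)
}

#' Simulation configuration for a synthetic multi-scorer PSG
#'
#' Defaults emulate the staging conditions of a 12-scorer whole-night panel
#' (~900 thirty-second epochs, i.e. 7.5 h in bed): about 30% of epochs are
#' unequivocal (one-hot truth), the rest carry Dirichlet-distributed
#' stage-probability rows concentrated on the latent stage
#' (`ambiguity_concentration = 8`) with confusable mass spread by
#' `stage_adjacency`, and scorers carry mild individual confusion bias.
#' Under these defaults the pooled complete-agreement curve declines from
#' roughly 70% at 2 scorers to roughly a third of epochs at 12 scorers,
#' the decay pattern reported for real multi-scorer panels.
#'
#' @param n_epochs Number of 30-s epochs per night (default 900).
#' @param n_scorers Panel size (default 12).
#' @param epoch_duration Epoch length in seconds (default 30).
#' @param transition_matrix 5x5 row-stochastic latent-architecture chain.
#' @param initial_stage Stage of the first epoch (default `"W"`).
#' @param unequivocal_fraction Probability that an epoch's truth row is
#'   one-hot on the latent stage (default 0.30).
#' @param ambiguity_concentration Dirichlet mass placed on the latent stage
#'   of an ambiguous epoch (default 8).
#' @param stage_adjacency 5x5 nonnegative confusability mass.
#' @param scorer_confusions List of per-scorer 5x5 row-stochastic confusion
#'   matrices, or `NULL` for identity (unbiased scorers). The default adds
#'   mild bias via [biased_scorer_confusions()].
#' @param autoscorer_noise_sd SD of additive log-space noise for the
#'   simulated auto-scorer (default 1.0).
#' @param seed Integer seed; every sampling operation derives its stream
#'   from it, so identical configs reproduce bit-identical outputs.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_epochs = 900L, n_scorers = 12L,
                       epoch_duration = 30,
                       transition_matrix = default_transition_matrix(),
                       initial_stage = "W",
                       unequivocal_fraction = 0.30,
                       ambiguity_concentration = 8,
                       stage_adjacency = default_stage_adjacency(),
                       scorer_confusions = biased_scorer_confusions(n_scorers),
                       autoscorer_noise_sd = 1.0,
                       seed = 1L) {
  check_stochastic <- function(m, what) {
    if (!is.matrix(m) || any(dim(m) != 5L) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9))
      stop(what, " must be a 5x5 row-stochastic matrix")
  }
  check_stochastic(transition_matrix, "transition_matrix")
  if (is.null(scorer_confusions))
    scorer_confusions <- identity_confusions(n_scorers)
  if (length(scorer_confusions) != n_scorers)
    stop("need one confusion matrix per scorer")
  for (cm in scorer_confusions) check_stochastic(cm, "scorer confusion")
  if (unequivocal_fraction < 0 || unequivocal_fraction > 1)
    stop("unequivocal_fraction must lie in [0, 1]")
  if (ambiguity_concentration <= 0)
    stop("ambiguity_concentration must be > 0")
  if (any(stage_adjacency < 0) || any(dim(stage_adjacency) != 5L))
    stop("stage_adjacency must be a 5x5 nonnegative matrix")
  stage_index(initial_stage)
  if (n_epochs < 1L || n_scorers < 2L)
    stop("need n_epochs >= 1 and n_scorers >= 2")
  structure(
    list(n_epochs = as.integer(n_epochs), n_scorers = as.integer(n_scorers),
         epoch_duration = epoch_duration,
         transition_matrix = transition_matrix,
         initial_stage = initial_stage,
         unequivocal_fraction = unequivocal_fraction,
         ambiguity_concentration = ambiguity_concentration,
         stage_adjacency = stage_adjacency,
         scorer_confusions = scorer_confusions,
         autoscorer_noise_sd = autoscorer_noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {          # numerically degenerate; fall back to argmax
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Generate the latent staging truth of one synthetic PSG
#'
#' Samples the latent stage path from the first-order chain, then builds
#' the per-epoch truth probability row: with probability
#' `unequivocal_fraction` the row is one-hot on the latent stage, otherwise
#' it is Dirichlet-distributed with parameter
#' `ambiguity_concentration * onehot(latent) + stage_adjacency[latent, ]`,
#' i.e. mean mass mostly on the latent stage and the rest on its
#' confusable neighbours.
#'
#' @param cfg A [sim_config()].
#' @param psg_id Identifier for the generated PSG.
#' @return List with `latent` (a [hypnogram()]) and `truth` (a
#'   [hypnodensity()] with `source = "latent_truth"`).
#' @export
generate_truth <- function(cfg, psg_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_epochs
    tm <- cfg$transition_matrix
    path <- integer(n)
    path[1] <- stage_index(cfg$initial_stage)
    if (n > 1L) {
      for (e in 2:n)
        path[e] <- sample.int(5L, 1L, prob = tm[path[e - 1L], ])
    }
    p <- matrix(0, nrow = n, ncol = 5L)
    ambiguous <- stats::runif(n) >= cfg$unequivocal_fraction
    for (e in seq_len(n)) {
      if (!ambiguous[e]) {
        p[e, path[e]] <- 1
      } else {
        alpha <- cfg$stage_adjacency[path[e], ]
        alpha[path[e]] <- alpha[path[e]] + cfg$ambiguity_concentration
        p[e, ] <- rdirichlet(alpha)
      }
    }
    list(
      latent = hypnogram(sleep_stages()[path],
                         epoch_duration = cfg$epoch_duration,
                         scorer_id = "latent", psg_id = psg_id),
      truth = hypnodensity(p, epoch_duration = cfg$epoch_duration,
                           source = "latent_truth", psg_id = psg_id)
    )
  })
}

#' Sample a panel of scorers from a truth hypnodensity
#'
#' Each scorer at each epoch draws a stage from the truth probability row,
#' then passes it through that scorer's confusion matrix (bias). Scorers
#' are conditionally independent given the truth.
#'
#' @param truth A [hypnodensity()] (usually from [generate_truth()]).
#' @param cfg A [sim_config()].
#' @return A `scoring_set` with `cfg$n_scorers` hypnograms.
#' @export
sample_scorers <- function(truth, cfg) {
  stopifnot(inherits(truth, "hypnodensity"), inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(truth$probabilities)
    hgs <- lapply(seq_len(cfg$n_scorers), function(i) {
      cm <- cfg$scorer_confusions[[i]]
      labels <- integer(n)
      for (e in seq_len(n)) {
        drawn <- sample.int(5L, 1L, prob = truth$probabilities[e, ])
        labels[e] <- sample.int(5L, 1L, prob = cm[drawn, ])
      }
      hypnogram(sleep_stages()[labels], epoch_duration = truth$epoch_duration,
                scorer_id = sprintf("scorer%02d", i), psg_id = truth$psg_id)
    })
    assemble_scoring_set(hgs, psg_id = truth$psg_id)
  })
}

#' Simulate a probability-emitting auto-scorer
#'
#' Perturbs the truth hypnodensity with additive zero-mean Gaussian noise
#' of SD `autoscorer_noise_sd` in log-probability space, then renormalizes
#' each row onto the simplex. Zero probabilities stay zero (log-space noise
#' cannot create mass), and `autoscorer_noise_sd = 0` returns the truth
#' unchanged.
#'
#' @param truth A [hypnodensity()].
#' @param cfg A [sim_config()].
#' @return A [hypnodensity()] with `source = "autoscorer"`.
#' @export
simulate_autoscorer <- function(truth, cfg) {
  stopifnot(inherits(truth, "hypnodensity"), inherits(cfg, "sim_config"))
  if (cfg$autoscorer_noise_sd == 0) {
    return(hypnodensity(truth$probabilities,
                        epoch_duration = truth$epoch_duration,
                        source = "autoscorer", psg_id = truth$psg_id))
  }
  withr::with_seed(cfg$seed + 2L, {
    p <- truth$probabilities
    lg <- log(p)  # -Inf for zero entries, preserved by additive noise
    noise <- matrix(stats::rnorm(length(p), sd = cfg$autoscorer_noise_sd),
                    nrow = nrow(p))
    q <- exp(lg + noise)
    q <- q / rowSums(q)
    hypnodensity(q, epoch_duration = truth$epoch_duration,
                 source = "autoscorer", psg_id = truth$psg_id)
  })
}

#' Simulate one complete synthetic PSG
#'
#' Convenience wrapper chaining [generate_truth()], [sample_scorers()] and
#' [simulate_autoscorer()].
#'
#' @param cfg A [sim_config()].
#' @param psg_id Identifier.
#' @return List with `latent`, `truth`, `scorings` (scoring set), `auto`
#'   (auto-scorer hypnodensity), and `config`.
#' @export
simulate_psg <- function(cfg, psg_id = "sim") {
  tr <- generate_truth(cfg, psg_id = psg_id)
  scorings <- sample_scorers(tr$truth, cfg)
  auto <- simulate_autoscorer(tr$truth, cfg)
  list(latent = tr$latent, truth = tr$truth, scorings = scorings,
       auto = auto, config = cfg)
}

#' Simulate a dataset of synthetic multi-scorer PSGs
#'
#' Each PSG gets its own seed derived deterministically from `seed`
#' (`seed + 1000 * i`), so datasets are reproducible PSG by PSG.
#'
#' @param n_psg Number of PSGs (default 10, a 12-scorer panel dataset).
#' @param cfg Base [sim_config()]; its `seed` is overridden per PSG.
#' @param seed Dataset-level seed.
#' @return An object of class `sim_dataset`: list of [simulate_psg()]
#'   results named `psg01 ...`, with the base config and seed attached as
#'   attributes.
#' @export
simulate_dataset <- function(n_psg = 10L, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_psg >= 1L)
  psgs <- lapply(seq_len(n_psg), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed + 1000L * i)
    simulate_psg(cfg_i, psg_id = sprintf("psg%02d", i))
  })
  names(psgs) <- vapply(psgs, function(p) p$scorings$psg_id, character(1))
  structure(psgs, class = "sim_dataset", base_seed = as.integer(seed),
            base_config = cfg)
}
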