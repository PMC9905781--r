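# builds a 4-scorer set where scorers 1-2 track a base staging closely and
# scorers 3-4 are noisier, so 1-2 carry the larger reliability weights
weighted_tie_set <- function(high_pair_stage, low_pair_stage) {
  withr::with_seed(101, {
    base <- sample(STAGES, 60, replace = TRUE)
    noisy <- function(p_err) ifelse(runif(60) < p_err,
                                    sample(STAGES, 60, replace = TRUE), base)
    s1 <- c(base, high_pair_stage)
    s2 <- c(base, high_pair_stage)
    s3 <- c(noisy(0.5), low_pair_stage)
    s4 <- c(noisy(0.5), low_pair_stage)
  })
  make_set(s1, s2, s3, s4)
}

test_that("consensus takes the plurality and respects exclusion", {
  s <- make_set(c("N2", "W"), c("N2", "W"), c("N2", "N1"), c("N1", "W"),
                c("N2", "W"))
  cons <- unbiased_consensus(s)
  expect_equal(cons$stages, c("N2", "W"))
  # excluding a scorer removes their vote
  cons_ex <- unbiased_consensus(s, excluded_scorer = "s4")
  expect_equal(cons_ex$stages, c("N2", "W"))
  expect_error(unbiased_consensus(s, excluded_scorer = "nope"), "unknown")
  s2 <- make_set(c("W", "N1"), c("N1", "W"))
  expect_error(unbiased_consensus(s2, excluded_scorer = "s1"),
               "at least two")
})

test_that("all scorers identical: consensus reproduces them", {
  withr::with_seed(55, {
    stages <- sample(STAGES, 50, replace = TRUE)
  })
  s <- make_set(stages, stages, stages)
  expect_identical(unbiased_consensus(s)$stages, stages)
})

test_that("vote ties go to the summed reliability weights", {
  # high-weight pair votes N1, low-weight pair votes N2: weight beats
  # the N2-over-N1 stage priority
  s <- weighted_tie_set("N1", "N2")
  w <- scorer_reliability(s)
  expect_true(w["s1"] + w["s2"] > w["s3"] + w["s4"])
  expect_equal(unbiased_consensus(s)$stages[61], "N1")
  # swap the pairs: the tie now resolves the other way
  s_swap <- weighted_tie_set("N2", "N1")
  expect_equal(unbiased_consensus(s_swap)$stages[61], "N2")
})

test_that("ties with equal weights fall back to the stage priority", {
  s <- make_set(c("W", "N1", "N2"), c("W", "N1", "N3"))
  cons <- unbiased_consensus(s)
  expect_equal(cons$stages[3], "N3")  # N3 > N2 in the default priority
  cons2 <- unbiased_consensus(s, priority = c("N2", "N3", "N1", "R", "W"))
  expect_equal(cons2$stages[3], "N2")
})

test_that("consensus is invariant to scorer ordering", {
  withr::with_seed(61, {
    s <- random_set(5, 80)
  })
  perm <- c(3, 1, 5, 2, 4)
  s_perm <- assemble_scoring_set(s$hypnograms[perm], psg_id = s$psg_id)
  expect_identical(unbiased_consensus(s)$stages,
                   unbiased_consensus(s_perm)$stages)
  expect_identical(unbiased_consensus(s, excluded_scorer = "s2")$stages,
                   unbiased_consensus(s_perm, excluded_scorer = "s2")$stages)
})

test_that("identical scorers yield kappa 1 under all three comparators", {
  withr::with_seed(71, {
    stages <- sample(STAGES, 60, replace = TRUE)
  })
  s <- make_set(stages, stages, stages, stages)
  tbl <- kappa_vs_comparators(s, stages = "all")
  expect_true(all(tbl$kappa == 1))
})

test_that("comparator table is wired to the documented constructions", {
  withr::with_seed(73, {
    s <- random_set(4, 120)
  })
  m <- vapply(s$hypnograms, `[[`, character(120), "stages")
  tbl <- kappa_vs_comparators(s, stages = "all")

  # individual comparator: mean pairwise kappa, checked against the oracle
  ind_s1 <- tbl$kappa[tbl$comparator == "individual" & tbl$scorer == "s1"]
  expect_equal(ind_s1, mean(sapply(2:4, function(j)
    kappa_oracle(m[, 1], m[, j]))), tolerance = 1e-12)

  # consensus comparator: kappa against the leave-one-out consensus
  cons1 <- unbiased_consensus(s, excluded_scorer = "s1")$stages
  con_s1 <- tbl$kappa[tbl$comparator == "unbiased_consensus" &
                        tbl$scorer == "s1"]
  expect_equal(con_s1, kappa_oracle(m[, 1], cons1), tolerance = 1e-12)

  # any-scorer comparator: reference carries the test label wherever some
  # remaining scorer matches, else the consensus label
  hit <- rowSums(m[, 2:4] == m[, 1]) > 0
  ref <- ifelse(hit, m[, 1], cons1)
  any_s1 <- tbl$kappa[tbl$comparator == "any_scorer" & tbl$scorer == "s1"]
  expect_equal(any_s1, kappa_oracle(m[, 1], ref), tolerance = 1e-12)
})

test_that("auto rows average the per-panel comparisons against manual panels", {
  withr::with_seed(79, {
    s <- random_set(4, 100)
  })
  m <- vapply(s$hypnograms, `[[`, character(100), "stages")
  auto <- make_hg(m[, 1], id = "auto")  # auto identical to scorer 1
  tbl <- kappa_vs_comparators(s, auto = auto, stages = "all")

  ind_auto <- tbl$kappa[tbl$comparator == "individual" & tbl$scorer == "auto"]
  expected <- mean(sapply(1:4, function(i)
    mean(sapply(setdiff(1:4, i), function(j) kappa_oracle(m[, 1], m[, j])))))
  expect_equal(ind_auto, expected, tolerance = 1e-12)

  # within scorer 1's own panel the comparison sets coincide exactly, so
  # auto (== scorer 1) can never average below scorer 1
  ind_s1 <- tbl$kappa[tbl$comparator == "individual" & tbl$scorer == "s1"]
  expect_gte(ind_auto, ind_s1)

  # auto faces the same leave-one-out consensus as each scorer
  con_auto <- tbl$kappa[tbl$comparator == "unbiased_consensus" &
                          tbl$scorer == "auto"]
  expected_con <- mean(sapply(paste0("s", 1:4), function(id)
    kappa_oracle(m[, 1], unbiased_consensus(s, excluded_scorer = id)$stages)))
  expect_equal(con_auto, expected_con, tolerance = 1e-12)
})

test_that("any-scorer kappa is at least the individual-comparator mean", {
  withr::with_seed(83, {
    for (i in 1:15) {
      cfg <- sim_config(n_epochs = 120, n_scorers = 5, seed = 9000 + i)
      s <- simulate_psg(cfg)$scorings
      tbl <- kappa_vs_comparators(s, stages = "all")
      for (id in paste0("scorer0", 1:5)) {
        any_k <- tbl$kappa[tbl$comparator == "any_scorer" & tbl$scorer == id]
        ind_k <- tbl$kappa[tbl$comparator == "individual" & tbl$scorer == id]
        expect_gte(any_k, ind_k)
      }
    }
  })
})

test_that("undefined kappas are excluded and counted", {
  s <- make_set(rep("W", 10), rep("W", 10), rep("W", 10))
  tbl <- kappa_vs_comparators(s, stages = "all")
  expect_true(all(is.na(tbl$kappa)))
  expect_gt(attr(tbl, "n_undefined"), 0)
})
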