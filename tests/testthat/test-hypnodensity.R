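test_that("hypnodensity_from_scorings counts votes into exact fractions", {
  s <- make_set(c("N3", "W", "W", "N1", "N2"),
                c("N3", "W", "N1", "N2", "N2"),
                c("N2", "W", "N2", "N3", "N2"),
                c("N2", "W", "N3", "R",  "N2"))
  h <- hypnodensity_from_scorings(s)
  # epoch 1: N3 x2, N2 x2 of 4 scorers
  expect_equal(unname(h$probabilities[1, ]), c(0, 0, 0.5, 0.5, 0))
  expect_equal(unname(h$probabilities[2, ]), c(1, 0, 0, 0, 0))
  # five distinct labels from 5 scorers -> uniform row
  s5 <- make_set("W", "N1", "N2", "N3", "R")
  expect_equal(unname(hypnodensity_from_scorings(s5)$probabilities[1, ]),
               rep(0.2, 5))
  # rows sum to 1 exactly (rational counts), entries multiples of 1/n
  withr::with_seed(3, {
    sr <- random_set(7, 120)
  })
  hr <- hypnodensity_from_scorings(sr)
  expect_identical(rowSums(hr$probabilities), rep(1, 120))
  expect_true(all(abs(hr$probabilities * 7 -
                        round(hr$probabilities * 7)) < 1e-12))
})

test_that("majority collapse takes argmax with the documented tie priority", {
  h <- hypnodensity(rbind(c(0, 0, 0.4, 0.6, 0),    # clear N3 majority
                          c(1, 0, 0, 0, 0),
                          c(0, 0, 0.5, 0.5, 0),    # N3 beats N2 on ties
                          c(0.5, 0.5, 0, 0, 0),    # N1 beats W
                          c(0, 0.5, 0, 0, 0.5)))   # N1 beats R
  hg <- hypnodensity_to_hypnogram(h)
  expect_equal(hg$stages, c("N3", "W", "N3", "N1", "N1"))
  # a different priority flips the tie, not the argmax
  hg2 <- hypnodensity_to_hypnogram(h, priority = c("W", "N1", "N2", "N3", "R"))
  expect_equal(hg2$stages, c("N3", "W", "N2", "W", "N1"))
  expect_error(hypnodensity_to_hypnogram(h, priority = c("W", "W", "N1", "N2", "N3")),
               "permutation")
})

test_that("one-hot encoding and majority collapse are mutually inverse", {
  withr::with_seed(5, {
    hg <- make_hg(sample(STAGES, 80, replace = TRUE))
  })
  h <- one_hot_hypnodensity(hg)
  expect_equal(rowSums(h$probabilities), rep(1, 80))
  expect_identical(hypnodensity_to_hypnogram(h)$stages, hg$stages)
})

test_that("sleep parameters follow the probability definitions", {
  # all wake: TST 0, no onset
  hw <- hypnodensity(matrix(rep(c(1, 0, 0, 0, 0), 10), ncol = 5,
                            byrow = TRUE))
  pw <- sleep_parameters_from_hypnodensity(hw)
  expect_equal(pw$total_sleep_time, 0)
  expect_equal(pw$sleep_efficiency, 0)
  expect_true(is.na(pw$sleep_latency))
  expect_true(is.na(pw$rem_latency))

  # one wake epoch then three pure N2 -> latency 0.5 min, TST 1.5 min
  h <- hypnodensity(rbind(c(1, 0, 0, 0, 0),
                          c(0, 0, 1, 0, 0),
                          c(0, 0, 1, 0, 0),
                          c(0, 0, 1, 0, 0)))
  p <- sleep_parameters_from_hypnodensity(h)
  expect_equal(p$sleep_latency, 0.5)
  expect_equal(p$total_sleep_time, 1.5)
  expect_equal(unname(p$time_in_stage["N2"]), 1.5)
  expect_equal(p$sleep_onset_epoch, 1L)
  expect_equal(p$time_in_bed, 2)
  expect_equal(p$sleep_efficiency, 75)

  # sleep probability ties at exactly 0.5 do not count as asleep
  h2 <- hypnodensity(rbind(c(0.5, 0.5, 0, 0, 0), c(0.4, 0.6, 0, 0, 0)))
  expect_equal(sleep_parameters_from_hypnodensity(h2)$sleep_latency, 0.5)

  # REM latency measured from sleep onset
  h3 <- hypnodensity(rbind(c(1, 0, 0, 0, 0),
                           c(0, 0, 1, 0, 0),
                           c(0, 0, 0.4, 0, 0.6)))
  expect_equal(sleep_parameters_from_hypnodensity(h3)$rem_latency, 0.5)
})

test_that("lights interval restricts the report window", {
  hg <- make_hg(c("W", "W", "N1", "N2", "N2", "W"))
  p <- sleep_parameters_from_hypnogram(hg, lights_off = 1, lights_on = 5)
  expect_equal(p$time_in_bed, 2)
  expect_equal(p$sleep_latency, 0.5)
  expect_equal(p$total_sleep_time, 1.5)
  expect_equal(p$sleep_onset_epoch, 2L)
  expect_error(sleep_parameters_from_hypnogram(hg, lights_off = 5,
                                               lights_on = 3), "off < on")
})

test_that("hypnogram parameters equal one-hot hypnodensity parameters", {
  withr::with_seed(9, {
    for (i in 1:100) {
      hg <- make_hg(sample(STAGES, sample(20:60, 1), replace = TRUE))
      a <- sleep_parameters_from_hypnogram(hg)
      b <- sleep_parameters_from_hypnodensity(one_hot_hypnodensity(hg))
      expect_equal(a, b)
    }
  })
})

test_that("stage times from probabilities equal mean per-scorer stage times", {
  # the exact area-under-curve identity, and the TST consistency invariant
  withr::with_seed(21, {
    for (i in 1:25) {
      s <- random_set(sample(3:9, 1), sample(30:90, 1))
      h <- hypnodensity_from_scorings(s)
      hp <- sleep_parameters_from_hypnodensity(h)
      per_scorer <- sapply(s$hypnograms, function(hg)
        sleep_parameters_from_hypnogram(hg)$time_in_stage)
      expect_equal(unname(hp$time_in_stage), unname(rowMeans(per_scorer)),
                   tolerance = 1e-12)
      expect_equal(hp$total_sleep_time,
                   sum(hp$time_in_stage[c("N1", "N2", "N3", "R")]),
                   tolerance = 1e-12)
    }
  })
})

test_that("identical scorers give a one-hot hypnodensity and the same report", {
  withr::with_seed(13, {
    stages <- sample(STAGES, 100, replace = TRUE)
  })
  s <- make_set(stages, stages, stages, stages)
  h <- hypnodensity_from_scorings(s)
  expect_true(all(h$probabilities %in% c(0, 1)))
  expect_equal(sleep_parameters_from_hypnodensity(h),
               sleep_parameters_from_hypnogram(s$hypnograms[[1]]))
})

test_that("sleep parameters serialize to flat JSON", {
  hg <- make_hg(c("W", "N1", "N2", "R"))
  p <- sleep_parameters_from_hypnogram(hg)
  path <- withr::local_tempfile(fileext = ".json")
  write_sleep_parameters(p, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$total_sleep_time, p$total_sleep_time)
  expect_equal(back$time_in_N2, unname(p$time_in_stage["N2"]))
})
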