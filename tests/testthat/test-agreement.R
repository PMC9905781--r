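test_that("complete agreement counts epochs where every scorer concurs", {
  expect_equal(complete_agreement(list(c("W", "N2"), c("W", "N2"))), 100)
  expect_equal(complete_agreement(list(c("W", "W", "N2", "N2"),
                                       c("W", "N1", "N2", "N3"))), 50)
  # three scorers agreeing on exactly 1 of 4 epochs
  expect_equal(complete_agreement(list(c("W", "N1", "N2", "N3"),
                                       c("W", "N1", "N1", "N2"),
                                       c("W", "N2", "N2", "N3"))), 25)
  # a sequence against itself
  expect_equal(complete_agreement(list(c("W", "R", "N3"))), 100)
  expect_error(complete_agreement(list(c("W", "W"), "W")), "unequal")
})

test_that("agreement curve averages every subset and matches hand averages", {
  s <- make_set(c("W", "N1", "N2", "N3"),
                c("W", "N1", "N1", "N3"),
                c("W", "N2", "N2", "N3"))
  cv <- agreement_curve(s)
  m <- vapply(s$hypnograms, `[[`, character(4), "stages")
  pair_means <- mean(c(complete_agreement(list(m[, 1], m[, 2])),
                       complete_agreement(list(m[, 1], m[, 3])),
                       complete_agreement(list(m[, 2], m[, 3]))))
  expect_equal(cv$summary$mean_agreement[cv$summary$k == 2], pair_means)
  expect_equal(cv$summary$n_subsets, c(3L, 1L))
  expect_equal(cv$summary$mean_agreement[cv$summary$k == 3],
               complete_agreement(s))

  # identical scorers: flat 100 at every k
  s_id <- make_set(rep("N2", 6), rep("N2", 6), rep("N2", 6), rep("N2", 6))
  expect_true(all(agreement_curve(s_id)$summary$mean_agreement == 100))
  expect_error(agreement_curve(s, k_range = 4), "k must lie")
})

test_that("subset averaging over combinations equals ordered permutations", {
  withr::with_seed(31, {
    for (n in 3:5) {
      s <- random_set(n, 25)
      m <- vapply(s$hypnograms, `[[`, character(25), "stages")
      cv <- agreement_curve(s)
      for (k in 2:n) {
        perms <- ordered_permutations(n, k)
        perm_mean <- mean(vapply(perms, function(p)
          complete_agreement(m[, p, drop = FALSE]), numeric(1)))
        expect_equal(cv$summary$mean_agreement[cv$summary$k == k], perm_mean,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("mean agreement is non-increasing in the number of scorers", {
  withr::with_seed(17, {
    for (i in 1:10) {
      s <- random_set(sample(4:8, 1), 60)
      ag <- agreement_curve(s)$summary$mean_agreement
      expect_true(all(diff(ag) <= 1e-12))
    }
  })
})

test_that("per-PSG-mean pooling averages PSGs for each subset", {
  s1 <- make_set(rep("N2", 4), rep("N2", 4), psg = "a")          # 100%
  s2 <- make_set(c("W", "W", "N1", "N1"), c("W", "N2", "N1", "R"),
                 psg = "b")                                       # 50%
  cv <- agreement_curve(list(s1, s2), pooling = "per_psg_mean")
  expect_equal(cv$summary$mean_agreement, 75)
  pooled <- agreement_curve(list(s1, s2), pooling = "pooled_epochs")
  expect_equal(pooled$summary$mean_agreement, 75)  # equal epoch counts here
})

test_that("stage-conditioned curves restrict to consensus-stage epochs", {
  s <- make_set(c("N2", "N2", "W", "W"),
                c("N2", "N2", "W", "N1"),
                c("N2", "N1", "W", "N1"))
  cv <- agreement_curve(s, stage_condition = "N2")  # consensus N2: epochs 1,2
  m <- vapply(s$hypnograms, `[[`, character(4), "stages")[1:2, ]
  expect_equal(cv$summary$mean_agreement[cv$summary$k == 3],
               complete_agreement(m))
  expect_error(agreement_curve(s, stage_condition = "N3"), "no epochs")
})

test_that("power fit recovers exact power data and flags degenerate input", {
  k <- 2:12
  y <- 98 * k^(-0.44)
  fit <- fit_power_law(y, k = k)
  expect_equal(fit$a, 98, tolerance = 1e-6)
  expect_equal(fit$b, -0.44, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # nls refinement agrees on exact data
  fit_nls <- fit_power_law(y, k = k, method = "nls")
  expect_equal(fit_nls$a, 98, tolerance = 1e-6)
  expect_equal(fit_nls$b, -0.44, tolerance = 1e-6)

  # constant 100%: b = 0, a = 100, R^2 = 1 by the degenerate convention
  fc <- fit_power_law(rep(100, 5), k = 2:6)
  expect_equal(fc$a, 100)
  expect_equal(fc$b, 0)
  expect_equal(fc$r_squared, 1)

  expect_error(fit_power_law(c(50, 0), k = 2:3), "zero or negative")
  expect_error(fit_power_law(50, k = 2), "two distinct")
})

test_that("R^2 degrades as noise grows around a power law", {
  withr::with_seed(41, {
    k <- 2:12
    clean <- 90 * k^(-0.5)
    r2 <- vapply(c(0.5, 2, 8), function(sd) {
      mean(replicate(20, {
        y <- pmax(1, clean + rnorm(length(k), sd = sd))
        fit_power_law(y, k = k)$r_squared
      }))
    }, numeric(1))
    expect_true(all(diff(r2) < 0))
    expect_lt(r2[3], 1)
  })
})

test_that("prediction evaluates a*x^b, clipped to the percent scale", {
  fit <- list(a = 98, b = 0)
  expect_equal(predict_agreement(fit, 7), 98)
  expect_equal(predict_agreement(list(a = 98, b = -0.44), 1), 98)
  expect_equal(predict_agreement(list(a = 120, b = 0), 3), 100)  # clipped
  expect_error(predict_agreement(fit, 0.5), ">= 1")
  # fit-then-predict reproduces points lying on a power curve
  k <- 2:8
  y <- 85 * k^(-0.3)
  f <- fit_power_law(y, k = k)
  expect_equal(predict_agreement(f, k), y, tolerance = 1e-9)
})
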