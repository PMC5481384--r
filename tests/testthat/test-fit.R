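# EM fitting, posterior classification, bootstrap

test_that("the mixed-looking worked example fits as published", {
  fit <- fit_mixture(example_series_2523())
  expect_equal(fit$pi_hat, 0.36, tolerance = 0.05)
  # frozen regression value of this implementation
  expect_equal(fit$pi_hat, 0.3527235, tolerance = 1e-5)
  expect_equal(fit$model$a, -130)
  expect_equal(fit$model$f, 130)
  expect_equal(fit$model$b, -103)
  expect_equal(fit$model$e, 112)
  expect_true(fit$converged)
  expect_identical(fit$selected, "mixture")
  # mixed looker: weakly long-looking, strongly neither
  cls <- classify(fit)
  expect_identical(cls$weak_label, "LL")
  expect_identical(cls$strong_label, "neither")
})

test_that("boundary-clustered series yield a degenerate long-looking fit", {
  # every score at the extremes, nothing in between
  d <- c(-130:-119, 118:130)
  fit <- fit_mixture(trial_series(d))
  expect_lt(fit$pi_hat, 1e-6)
  expect_equal(fit$model$b, -119)
  expect_equal(fit$model$e, 118)
  expect_identical(classify(fit)$strong_label, "LL")
})

test_that("band-free mid-range series yield the short-only fit", {
  set.seed(1)
  d <- sample(-50:50, 24, replace = TRUE)
  fit <- fit_mixture(trial_series(d))
  expect_identical(fit$pi_hat, 1)
  expect_identical(fit$selected, "short_only")
  expect_false(fit$identifiable)
  expect_identical(classify(fit)$strong_label, "SL")
})

test_that("degenerate and one-sided series are handled", {
  # constant series
  fit <- fit_mixture(trial_series(rep(0, 10)))
  expect_identical(fit$pi_hat, 1)
  expect_true(fit$converged)

  # no negative scores: negative band absent, lam pinned
  fit2 <- fit_mixture(trial_series(c(125:130, 126, 128, 40, 55, 60, 70)))
  expect_true(is.na(fit2$model$b))

  # too few trials refused
  expect_error(fit_mixture(trial_series(c(1, 2, 3))), "at least 4")
})

test_that("EM log-likelihood is nondecreasing across iterations", {
  set.seed(201)
  for (i in 1:100) {
    fit <- fit_mixture(random_series())
    if (length(fit$ll_trace) > 1) {
      expect_true(all(diff(fit$ll_trace) >= -1e-8))
    }
  }
})

test_that("pi_hat equals the mean per-trial posterior", {
  set.seed(202)
  for (i in 1:50) {
    fit <- fit_mixture(random_series())
    expect_equal(fit$pi_hat, mean(fit$posteriors), tolerance = 1e-8)
    expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
    expect_true(is.finite(fit$loglik))
  }
})

test_that("EM attains the brute-force grid optimum at its endpoints", {
  set.seed(203)
  for (i in 1:10) {
    s <- random_series(T = 12)
    fit <- fit_mixture(s)
    if (fit$selected != "mixture") next
    m <- fit$model
    oracle <- grid_search_loglik(s$d, m$a, m$b, m$e, m$f)
    expect_gte(fit$loglik, oracle - 1e-6)
  }
})

test_that("fits are invariant to trial order", {
  set.seed(204)
  for (i in 1:10) {
    s <- random_series(T = 20)
    perm <- trial_series(sample(s$d))
    f1 <- fit_mixture(s)
    f2 <- fit_mixture(perm)
    expect_identical(f1$pi_hat, f2$pi_hat)
    expect_identical(classify(f1)$weak_label, classify(f2)$weak_label)
  }
})

test_that("posterior_short follows the mixture algebra", {
  m <- looking_mixture(-130, -119, 118, 130, pi = 0.5, lam = 0.5)
  # gap points are certainly short whenever pi > 0
  expect_equal(posterior_short(m, c(-50, 0, 100)), c(1, 1, 1))
  # hand computation on the negative band
  expect_equal(posterior_short(m, -120),
               (0.5 / 260) / ((0.5 / 260) + 0.5 * 0.5 / 11),
               tolerance = 1e-12)
  # no short mass at all
  m0 <- looking_mixture(-130, -119, 118, 130, pi = 0, lam = 0.5)
  expect_equal(posterior_short(m0, -120), 0)
  # outside the support
  expect_error(posterior_short(m, 131), "within the model support")
})

test_that("classification thresholds follow the weak and strong criteria", {
  expect_identical(classify(1.0)$weak_label, "SL")
  expect_identical(classify(1.0)$strong_label, "SL")
  expect_identical(classify(0.36)$weak_label, "LL")
  expect_identical(classify(0.36)$strong_label, "neither")
  expect_identical(classify(0.5)$weak_label, "indeterminate")
  expect_identical(classify(1 - 1e-8)$strong_label, "SL")
  expect_identical(classify(1e-8)$strong_label, "LL")
  expect_error(classify(1.2), "probability")
})

test_that("bootstrap refuses tiny B and handles degenerate data", {
  expect_error(bootstrap_fit(example_series_2523(), B = 50), "at least 100")

  bs0 <- bootstrap_fit(trial_series(rep(0, 8)), B = 100, seed = 1)
  expect_equal(bs0$pi_hat$se, 0)
  expect_equal(bs0$d_bar$se, 0)

  # degenerate long looker: pi_hat cannot fall below 0
  d <- c(-130:-119, 118:130)
  bs <- bootstrap_fit(trial_series(d), B = 100, seed = 2)
  expect_lt(bs$pi_hat$ci[1], 1e-6)
  expect_gte(bs$pi_hat$ci[1], 0)
})

test_that("bootstrap of the worked example reproduces frozen uncertainty", {
  bs <- bootstrap_fit(example_series_2523(), B = 1000, seed = 99)
  expect_gt(bs$pi_hat$se, 0)
  expect_lt(bs$pi_hat$ci[1], 0.36)
  expect_gt(bs$pi_hat$ci[2], 0.36)
  # frozen regression values for this seed
  expect_equal(bs$pi_hat$se, 0.1587279, tolerance = 1e-6)
  expect_equal(unname(bs$pi_hat$ci), c(0.1505668, 0.7647060),
               tolerance = 1e-6)
  # seeded reproducibility
  bs2 <- bootstrap_fit(example_series_2523(), B = 1000, seed = 99)
  expect_identical(bs$pi_hat$replicates, bs2$pi_hat$replicates)
})
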