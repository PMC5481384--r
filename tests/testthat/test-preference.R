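# downstream analyses linking looking style to preference

test_that("transition probabilities count correctly on a toy cohort", {
  co <- cohort_table(data.frame(
    infant_id = rep(c("a", "b", "c", "d"), each = 2),
    occasion = rep(c(3, 6), 4),
    pi_hat = c(0.2, 0.9, 0.3, 0.8, 0.1, 0.2, 0.9, 0.95),
    d_bar = 0.5
  ))
  tt <- transition_probabilities(co, 3, 6)
  get <- function(from, to) tt$prob[tt$from == from & tt$to == to]
  expect_equal(get("LL", "SL"), 2 / 3)
  expect_equal(get("SL", "SL"), 1)
  expect_equal(get("LL", "LL"), 1 / 3)
  expect_equal(get("SL", "LL"), 0)
  # rows condition correctly: probabilities sum to one given counts > 0
  for (g in c("SL", "LL")) {
    expect_equal(sum(tt$prob[tt$from == g]), 1)
  }
})

test_that("empty conditioning sets give NA, and indeterminate rows drop", {
  co <- cohort_table(data.frame(
    infant_id = rep(c("a", "b", "c"), each = 2),
    occasion = rep(c(3, 6), 3),
    pi_hat = c(0.9, 0.9, 0.8, 0.8, 0.5, 0.9),
    d_bar = 1
  ))
  tt <- transition_probabilities(co, 3, 6)
  expect_true(all(is.na(tt$prob[tt$from == "LL"])))
  expect_equal(tt$prob[tt$from == "SL" & tt$to == "LL"], 0)
  expect_equal(attr(tt, "n_indeterminate"), 1)
})

test_that("transition estimates recover a known transition matrix", {
  set.seed(401)
  n <- 500
  sl3 <- runif(n) < 0.4
  sl6 <- ifelse(sl3, TRUE, runif(n) < 0.87)
  co <- cohort_table(data.frame(
    infant_id = rep(seq_len(n), 2),
    occasion = rep(c(3, 6), each = n),
    pi_hat = c(ifelse(sl3, 0.9, 0.1), ifelse(sl6, 0.9, 0.1)),
    d_bar = rnorm(2 * n)
  ))
  tt <- transition_probabilities(co, 3, 6)
  n_ll <- tt$n_from[tt$from == "LL"][1]
  p_hat <- tt$prob[tt$from == "LL" & tt$to == "SL"]
  se <- sqrt(0.87 * 0.13 / n_ll)
  expect_lt(abs(p_hat - 0.87), 3 * se)
  expect_equal(tt$prob[tt$from == "SL" & tt$to == "SL"], 1)
})

test_that("conditional means and Welch test follow hand calculations", {
  co <- make_cohort(
    pi_hat = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1),
    d_bar = c(0, 2, 4, 6, 8, 1, 1, 1, 1, 1)
  )
  cm <- conditional_means(co, 3)
  expect_equal(cm$SL$mean, 4)
  expect_equal(cm$LL$mean, 1)
  expect_equal(cm$unconditional$mean, 2.5)
  # Welch with one zero-variance group: t = 3/sqrt(10/5), df collapses to 4
  expect_equal(cm$welch$t, 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cm$welch$df, 4, tolerance = 1e-9)
  # LL group is constant: its one-sample test is suppressed, mean reported
  expect_false(cm$LL$test)
  expect_true(cm$SL$test)
})

test_that("single-row and empty cells are reported without tests", {
  co <- make_cohort(pi_hat = c(0.9, 0.9, 0.2), d_bar = c(-5, -7, -30.67))
  cm <- conditional_means(co, 3)
  expect_equal(cm$LL$n, 1)
  expect_equal(cm$LL$mean, -30.67)
  expect_false(cm$LL$test)
  expect_null(conditional_means(make_cohort(0.9, 1), 3)$welch)
})

test_that("delta-curve endpoints equal the unconditional mean bit-exactly", {
  set.seed(402)
  for (i in 1:5) {
    co <- make_cohort(pi_hat = runif(20), d_bar = rnorm(20, 0, 30))
    dc <- delta_curve(co, 3)
    uncond <- mean(co$d_bar)
    expect_identical(dc$mean_ge[dc$delta == 0], uncond)
    expect_identical(dc$mean_le[dc$delta == 1], uncond)
    expect_equal(dc$n_ge[1], 20L)
    expect_equal(dc$n_le[11], 20L)
  }
})

test_that("delta-curve respects monotone structure and empty cells", {
  pi_hat <- seq(0.05, 0.95, length.out = 19)
  co <- make_cohort(pi_hat = pi_hat, d_bar = 10 * pi_hat)
  dc <- delta_curve(co, 3)
  le <- dc$mean_le[!is.na(dc$mean_le)]
  expect_true(all(diff(le) >= -1e-12))

  co1 <- make_cohort(pi_hat = rep(1, 5), d_bar = 1:5)
  dc1 <- delta_curve(co1, 3)
  expect_true(all(is.na(dc1$mean_le[dc1$delta < 1])))
  expect_true(all(dc1$mean_ge == 3))
  # single-row cells suppress the SE but keep the mean
  expect_true(all(is.na(dc1$se_le[dc1$delta < 1])))
})

test_that("independence test rejects a dependent cohort and not a null one", {
  set.seed(403)
  # dependent: preference tracks looking style
  pi_hat <- runif(60)
  d_bar <- 15 * (pi_hat - 0.5) + rnorm(60, 0, 2)
  co <- make_cohort(pi_hat, d_bar)
  out <- independence_test(co, 3, B = 2000, seed = 1)
  expect_lt(out$p_le, 0.01)
  expect_lt(out$p_ge, 0.01)
  expect_gt(out$slope_le, 0)

  # independent draws: no signal at this seed
  co0 <- make_cohort(runif(200), rnorm(200, 0, 10))
  out0 <- independence_test(co0, 3, B = 1000, seed = 2)
  expect_gt(out0$p_le, 0.05)
  expect_gt(out0$p_ge, 0.05)

  # constant preference: exactly zero slopes
  coc <- make_cohort(runif(20), rep(4, 20))
  outc <- independence_test(coc, 3, B = 200, seed = 3)
  expect_equal(outc$slope_le, 0)
  expect_equal(outc$slope_ge, 0)

  expect_error(independence_test(make_cohort(runif(5), rnorm(5)), 3,
                                 B = 100, seed = 4),
               "at least 10 rows")
})

test_that("precedence counting identities hold exactly", {
  # every other-pole-preferring infant is SL; half the SL infants are not
  co <- make_cohort(
    pi_hat = c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1),
    d_bar = c(-1, -1, 1, 1, 1, 1)
  )
  pr <- precedence_test(co, 3, B = 200, seed = 5)
  expect_equal(pr$P1, 1)
  expect_equal(pr$P2, 0.5)
  expect_equal(pr$diff, 0.5)

  # structural identity P1 * #ORP = P2 * #SL = #(SL and ORP) on any cohort
  set.seed(406)
  for (i in 1:10) {
    coi <- make_cohort(runif(30), rnorm(30))
    sti <- tryCatch(precedence_test(coi, 3, B = 100, seed = i),
                    error = function(e) NULL)
    if (is.null(sti)) next
    expect_equal(sti$P1 * sti$n_orp, sti$n_joint)
    expect_equal(sti$P2 * sti$n_sl, sti$n_joint)
  }

  # all infants SL and ORP
  co2 <- make_cohort(rep(0.9, 6), rep(-2, 6))
  pr2 <- precedence_test(co2, 3, B = 200, seed = 6)
  expect_equal(pr2$P1, 1)
  expect_equal(pr2$P2, 1)
  expect_equal(pr2$diff, 0)

  # refusal names the empty conditioning set
  expect_error(precedence_test(make_cohort(c(0.9, 0.9), c(1, 2)), 3,
                               B = 100, seed = 7), "no ORP")
})

test_that("precedence bootstrap detects SL preceding other-pole preference", {
  set.seed(404)
  n <- 500
  sl <- runif(n) < 0.9
  orp <- ifelse(sl, runif(n) < 0.64, runif(n) < 0.2)
  co <- make_cohort(
    pi_hat = ifelse(sl, 0.9, 0.1),
    d_bar = ifelse(orp, -5, 5)
  )
  pr <- precedence_test(co, 3, B = 2000, seed = 8)
  expect_gt(pr$P1, pr$P2)
  expect_lt(pr$p, 0.05)
})

test_that("trajectory extrapolation matches hand OLS with clamping", {
  co <- cohort_table(data.frame(
    infant_id = rep(c("flat", "step", "ramp"), each = 3),
    occasion = rep(c(3, 6, 9), 3),
    pi_hat = c(1, 1, 1, 0, 1, 1, 0.2, 0.5, 0.8),
    d_bar = 0
  ))
  out <- trajectory_extrapolation(co, target_age = 0.25)
  pr <- out$predictions
  expect_equal(pr$prediction[pr$infant_id == "flat"], 1)
  # (0,1,1): slope 1/6, intercept -1/3, raw -0.2917 -> clamped to 0
  step <- pr[pr$infant_id == "step", ]
  expect_equal(step$slope, 1 / 6)
  expect_equal(step$intercept, -1 / 3)
  expect_equal(step$raw_prediction, -1 / 3 + 0.25 / 6)
  expect_equal(step$prediction, 0)
  # (0.2, 0.5, 0.8): slope 0.1, intercept -0.1, raw -0.075 -> clamped to 0
  ramp <- pr[pr$infant_id == "ramp", ]
  expect_equal(ramp$slope, 0.1)
  expect_equal(ramp$intercept, -0.1, tolerance = 1e-12)
  expect_equal(ramp$raw_prediction, -0.1 + 0.1 * 0.25)
  expect_equal(ramp$prediction, 0)
  expect_equal(out$n, 3)
})

test_that("infants missing an occasion are excluded with a count", {
  co <- cohort_table(data.frame(
    infant_id = c("a", "a", "a", "b", "b"),
    occasion = c(3, 6, 9, 3, 6),
    pi_hat = c(0.1, 0.5, 0.9, 0.2, 0.4),
    d_bar = 0
  ))
  out <- trajectory_extrapolation(co)
  expect_equal(out$n, 1)
  expect_equal(out$n_excluded, 1)
})

test_that("sampling calculator reproduces the published design numbers", {
  q <- sampling_probability(12, 21 / 58, 5)
  expect_equal(round(q, 2), 0.45)
  expect_equal(round(sampling_probability(12, 21 / 58, 5, 2), 2), 0.20)
  expect_equal(round(sampling_probability(12, 21 / 58, 5, 3), 2), 0.09)
  expect_equal(sampling_probability(12, 0, 1), 0)
  expect_equal(sampling_probability(12, 0.3, 0), 1)
  expect_error(sampling_probability(12, 1.5, 5), "probability")
  expect_error(sampling_probability(4, 0.5, 5), "min_sl")
})

test_that("sampling probability is monotone in its arguments", {
  p <- vapply(0:12, function(m) sampling_probability(12, 0.36, m),
              numeric(1))
  expect_true(all(diff(p) <= 0))
  p2 <- vapply(1:5, function(k) sampling_probability(12, 0.36, 5, k),
               numeric(1))
  expect_true(all(diff(p2) <= 0))
  p3 <- vapply(seq(0, 1, 0.1), function(q) sampling_probability(12, q, 5),
               numeric(1))
  expect_true(all(diff(p3) >= 0))
})

test_that("cohort_table validates and labels rows", {
  co <- make_cohort(pi_hat = c(0.6, 0.4, 0.5), d_bar = c(-1, 2, 0))
  expect_identical(co$weak_label, c("SL", "LL", "indeterminate"))
  expect_identical(co$preference_label, c("ORP", "SRP", "none"))
  expect_error(make_cohort(c(0.5, 1.2), c(0, 0)), "pi_hat")
  expect_error(cohort_table(data.frame(
    infant_id = c("a", "a"), occasion = c(3, 3),
    pi_hat = c(0.1, 0.2), d_bar = c(0, 0)
  )), "one row per infant-occasion")
})
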