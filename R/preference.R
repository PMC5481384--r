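#' Cohort summary table
#'
#' One row per infant-occasion, carrying the estimated short-look
#' probability, the mean difference score, and the derived labels that feed
#' every downstream analysis. The weak looking-style label is SL for
#' \code{pi_hat > 1/2}, LL for \code{pi_hat < 1/2}, and indeterminate at
#' exactly 1/2 (indeterminate rows are excluded from label-conditioned
#' analyses). The preference label is ORP (other-race/other-pole preference)
#' for \code{d_bar < 0}, SRP for \code{d_bar > 0}, and \code{"none"} at
#' exactly 0.
#'
#' @param x either a list of \code{"lookmix_fit"} objects or a data frame
#'   with columns \code{infant_id}, \code{occasion}, \code{pi_hat},
#'   \code{d_bar} and optionally \code{T}.
#' @return A data frame of class \code{"cohort_table"} with columns
#'   \code{infant_id}, \code{occasion}, \code{pi_hat}, \code{d_bar},
#'   \code{T}, \code{weak_label}, \code{preference_label}.
#' @export
cohort_table <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "lookmix_fit"))) {
    x <- do.call(rbind, lapply(x, function(f) {
      data.frame(
        infant_id = f$infant_id, occasion = f$occasion,
        pi_hat = f$pi_hat, d_bar = f$d_bar, T = f$T,
        stringsAsFactors = FALSE
      )
    }))
  }
  stopifnot(is.data.frame(x))
  need <- c("infant_id", "occasion", "pi_hat", "d_bar")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing cohort columns: ", paste(miss, collapse = ", "))
  }
  if (!"T" %in% names(x)) x$T <- NA_integer_
  if (any(x$pi_hat < 0 | x$pi_hat > 1, na.rm = TRUE)) {
    stop("'pi_hat' must lie in [0, 1]")
  }
  if (anyDuplicated(x[c("infant_id", "occasion")])) {
    stop("cohort table must have one row per infant-occasion")
  }
  x$weak_label <- ifelse(x$pi_hat > 0.5, "SL",
                  ifelse(x$pi_hat < 0.5, "LL", "indeterminate"))
  x$preference_label <- ifelse(x$d_bar < 0, "ORP",
                        ifelse(x$d_bar > 0, "SRP", "none"))
  class(x) <- c("cohort_table", "data.frame")
  x
}

occasion_rows <- function(cohort, occasion) {
  rows <- cohort[cohort$occasion == occasion, , drop = FALSE]
  if (!nrow(rows)) stop("no cohort rows at occasion ", occasion)
  rows
}

#' Looking-style transition probabilities between two occasions
#'
#' Estimates \eqn{\hat P(\mathrm{label}_{later} \mid \mathrm{label}_{earlier})}
#' by direct counting over infants observed at both occasions, using the
#' weak SL/LL labels. Indeterminate rows are excluded (their count is
#' reported in the \code{"n_indeterminate"} attribute). A conditioning label
#' with zero count yields \code{NA} probabilities, never 0.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param earlier,later the two occasions (earlier first).
#' @return Data frame with columns \code{from}, \code{to}, \code{n_from},
#'   \code{n}, \code{prob}; attributes \code{n_pairs} (infants at both
#'   occasions) and \code{n_indeterminate}.
#' @export
transition_probabilities <- function(cohort, earlier, later) {
  stopifnot(inherits(cohort, "cohort_table"))
  a <- cohort[cohort$occasion == earlier, c("infant_id", "weak_label")]
  b <- cohort[cohort$occasion == later, c("infant_id", "weak_label")]
  both <- merge(a, b, by = "infant_id", suffixes = c("_from", "_to"))
  if (!nrow(both)) {
    stop("no infant observed at both occasions ", earlier, " and ", later)
  }
  n_ind <- sum(both$weak_label_from == "indeterminate" |
                 both$weak_label_to == "indeterminate")
  both <- both[both$weak_label_from != "indeterminate" &
                 both$weak_label_to != "indeterminate", ]
  grid <- expand.grid(from = c("SL", "LL"), to = c("SL", "LL"),
                      stringsAsFactors = FALSE)
  grid$n_from <- vapply(grid$from, function(g) {
    sum(both$weak_label_from == g)
  }, numeric(1))
  grid$n <- mapply(function(g, h) {
    sum(both$weak_label_from == g & both$weak_label_to == h)
  }, grid$from, grid$to)
  grid$prob <- ifelse(grid$n_from > 0, grid$n / grid$n_from, NA_real_)
  attr(grid, "n_pairs") <- nrow(both)
  attr(grid, "n_indeterminate") <- n_ind
  attr(grid, "occasions") <- c(earlier = earlier, later = later)
  grid
}

one_sample_t <- function(v) {
  n <- length(v)
  out <- list(n = n, mean = if (n) mean(v) else NA_real_,
              se = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
              test = FALSE)
  if (n >= 2 && stats::sd(v) > 0) {
    tt <- stats::t.test(v, mu = 0)
    out$se <- unname(tt$stderr)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out$test <- TRUE
  } else if (n >= 2) {
    out$se <- 0 # zero variance: mean reported, test suppressed
  }
  out
}

#' Mean preference conditional on looking style at one occasion
#'
#' For one occasion: the unconditional mean of the per-infant mean
#' difference scores \code{d_bar} with a two-sided one-sample t-test against
#' 0; the same conditioned on the weak SL and LL labels; and Welch's
#' unequal-variance two-sample test comparing SL with LL
#' (Welch-Satterthwaite degrees of freedom). Cells with a single row report
#' the mean only; zero-variance cells suppress the test.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param occasion occasion to analyse.
#' @return A list of class \code{"conditional_means"}: \code{unconditional},
#'   \code{SL}, \code{LL} (each with n, mean, se, t, df, p, test flag) and
#'   \code{welch} (t, df, p or NULL if either group has < 2 rows).
#' @export
conditional_means <- function(cohort, occasion) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- occasion_rows(cohort, occasion)
  sl <- rows$d_bar[rows$weak_label == "SL"]
  ll <- rows$d_bar[rows$weak_label == "LL"]
  welch <- NULL
  if (length(sl) >= 2 && length(ll) >= 2 &&
      (stats::sd(sl) > 0 || stats::sd(ll) > 0)) {
    wt <- stats::t.test(sl, ll, var.equal = FALSE)
    welch <- list(t = unname(wt$statistic), df = unname(wt$parameter),
                  p = wt$p.value)
  }
  structure(
    list(
      occasion = occasion,
      unconditional = one_sample_t(rows$d_bar),
      SL = one_sample_t(sl),
      LL = one_sample_t(ll),
      n_indeterminate = sum(rows$weak_label == "indeterminate"),
      welch = welch
    ),
    class = "conditional_means"
  )
}

#' @export
print.conditional_means <- function(x, ...) {
  cat(sprintf("Occasion %s: mean difference score by looking style\n",
              format(x$occasion)))
  row <- function(lbl, g) {
    if (!g$n) {
      cat(sprintf("  %-14s (no rows)\n", lbl))
    } else if (g$test) {
      cat(sprintf("  %-14s n=%3d  mean %7.2f (se %.2f)  t=%.2f df=%.1f p=%.4g\n",
                  lbl, g$n, g$mean, g$se, g$t, g$df, g$p))
    } else {
      cat(sprintf("  %-14s n=%3d  mean %7.2f  (test suppressed)\n",
                  lbl, g$n, g$mean))
    }
  }
  row("unconditional", x$unconditional)
  row("SL", x$SL)
  row("LL", x$LL)
  if (!is.null(x$welch)) {
    cat(sprintf("  SL vs LL (Welch): t=%.2f df=%.1f p=%.4g\n",
                x$welch$t, x$welch$df, x$welch$p))
  }
  invisible(x)
}

#' Delta-curve: preference means conditioned on looking style thresholds
#'
#' Over the grid \code{delta = 0, 0.1, ..., 1}, computes the mean of
#' \code{d_bar} over rows with \code{pi_hat <= delta} (the "le" curve) and
#' with \code{pi_hat >= delta} (the "ge" curve), with counts and standard
#' errors (SE suppressed for n < 2). Thresholds are inclusive on both
#' curves, so the ge-curve at \code{delta = 0} and the le-curve at
#' \code{delta = 1} both equal the unconditional mean. Empty cells are
#' \code{NA}, never fabricated.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param occasion occasion to analyse.
#' @return Data frame of class \code{"delta_curve"} with columns
#'   \code{delta}, \code{mean_le}, \code{n_le}, \code{se_le},
#'   \code{mean_ge}, \code{n_ge}, \code{se_ge}.
#' @export
delta_curve <- function(cohort, occasion) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- occasion_rows(cohort, occasion)
  compute_delta_curve(rows$pi_hat, rows$d_bar)
}

# internal core so resampling tests can avoid data-frame overhead
compute_delta_curve <- function(pi_hat, d_bar, grid = (0:10) / 10) {
  cell <- function(v) {
    n <- length(v)
    c(mean = if (n) mean(v) else NA_real_, n = n,
      se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_)
  }
  le <- vapply(grid, function(dl) cell(d_bar[pi_hat <= dl]), numeric(3))
  ge <- vapply(grid, function(dl) cell(d_bar[pi_hat >= dl]), numeric(3))
  out <- data.frame(
    delta = grid,
    mean_le = le["mean", ], n_le = as.integer(le["n", ]), se_le = le["se", ],
    mean_ge = ge["mean", ], n_ge = as.integer(ge["n", ]), se_ge = ge["se", ]
  )
  class(out) <- c("delta_curve", "data.frame")
  out
}

# n-weighted OLS slope of curve means against delta over defined points
curve_slope <- function(delta, means, n) {
  ok <- !is.na(means) & n > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- delta[ok]; y <- means[ok]; w <- n[ok]
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) return(NA_real_)
  sum(w * (x - xb) * (y - yb)) / sxx
}

#' Independence test of looking style and preference
#'
#' Under independence of \code{pi_hat} and \code{d_bar}, both delta-curves
#' are flat in expectation, so their n-weighted least-squares slopes against
#' delta are zero. The observed slopes are referred to a resampling null in
#' which the pairing between \code{pi_hat} and \code{d_bar} is broken:
#' by default the \code{d_bar} values are permuted against the \code{pi_hat}
#' values (\code{null = "permutation"}); \code{null = "bootstrap"} resamples
#' infants with replacement and permutes within the resample. The curve and
#' slope are recomputed for each resample; two-sided p-values use the
#' add-one convention.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param occasion occasion to analyse (>= 10 rows required).
#' @param B number of resamples.
#' @param seed integer seed.
#' @param null \code{"permutation"} (default) or \code{"bootstrap"}.
#' @return A list: \code{slope_le}, \code{slope_ge}, \code{p_le},
#'   \code{p_ge}, \code{B}, \code{null}.
#' @export
independence_test <- function(cohort, occasion, B = 2000, seed = NULL,
                              null = c("permutation", "bootstrap")) {
  stopifnot(inherits(cohort, "cohort_table"))
  null <- match.arg(null)
  rows <- occasion_rows(cohort, occasion)
  if (nrow(rows) < 10) {
    stop("independence test requires at least 10 rows at the occasion")
  }
  pi_hat <- rows$pi_hat
  d_bar <- rows$d_bar
  slopes_of <- function(p, d) {
    cv <- compute_delta_curve(p, d)
    c(le = curve_slope(cv$delta, cv$mean_le, cv$n_le),
      ge = curve_slope(cv$delta, cv$mean_ge, cv$n_ge))
  }
  obs <- slopes_of(pi_hat, d_bar)
  if (anyNA(obs)) {
    stop("too few defined delta-curve points (need >= 3 per curve)")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- length(pi_hat)
  null_slopes <- vapply(seq_len(B), function(i) {
    if (null == "permutation") {
      slopes_of(pi_hat, sample(d_bar))
    } else {
      idx <- sample.int(n, n, replace = TRUE)
      slopes_of(pi_hat[idx], sample(d_bar[idx]))
    }
  }, numeric(2))
  pval <- function(stat, draws) {
    draws <- draws[!is.na(draws)]
    (sum(abs(draws) >= abs(stat)) + 1) / (length(draws) + 1)
  }
  list(
    slope_le = unname(obs["le"]), slope_ge = unname(obs["ge"]),
    p_le = pval(obs["le"], null_slopes["le", ]),
    p_ge = pval(obs["ge"], null_slopes["ge", ]),
    B = B, null = null
  )
}

precedence_stats <- function(weak_label, preference_label) {
  sl <- weak_label == "SL"
  orp <- preference_label == "ORP"
  n_orp <- sum(orp)
  n_sl <- sum(sl)
  if (n_orp == 0 || n_sl == 0) return(NULL)
  joint <- sum(sl & orp)
  c(P1 = joint / n_orp, P2 = joint / n_sl,
    n_orp = n_orp, n_sl = n_sl, joint = joint)
}

#' Precedence test: does short looking precede other-pole preference?
#'
#' If state B develops before state C, then among those who have reached C
#' nearly all have already reached B, so \eqn{P(B \mid C) > P(C \mid B)}.
#' Here \code{P1 = P(SL | ORP)} and \code{P2 = P(ORP | SL)}: \code{P1 > P2}
#' indicates other-pole preference is the later event. The difference
#' \code{P1 - P2} is tested against zero by resampling infants with
#' replacement; the achieved significance level is
#' \code{2 * min(P(diff* <= 0), P(diff* >= 0))} with the add-one convention,
#' capped at 1. Resamples in which a conditioning set is empty are dropped
#' (their count is reported).
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param occasion occasion to analyse; must contain at least one ORP row
#'   and one SL row.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return A list of class \code{"precedence_result"}: \code{P1}, \code{P2},
#'   \code{diff}, \code{p} (two-sided), \code{B}, \code{B_effective},
#'   \code{seed}, and the supporting counts.
#' @export
precedence_test <- function(cohort, occasion, B = 2000, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- occasion_rows(cohort, occasion)
  obs <- precedence_stats(rows$weak_label, rows$preference_label)
  if (is.null(obs)) {
    empty <- if (!sum(rows$preference_label == "ORP")) "ORP" else "SL"
    stop("precedence test refused: no ", empty, " rows at occasion ",
         occasion)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(rows)
  diffs <- vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- precedence_stats(rows$weak_label[idx], rows$preference_label[idx])
    if (is.null(st)) NA_real_ else unname(st["P1"] - st["P2"])
  }, numeric(1))
  valid <- diffs[!is.na(diffs)]
  b_eff <- length(valid)
  p <- min(1, 2 * min(
    (sum(valid <= 0) + 1) / (b_eff + 1),
    (sum(valid >= 0) + 1) / (b_eff + 1)
  ))
  structure(
    list(
      P1 = unname(obs["P1"]), P2 = unname(obs["P2"]),
      diff = unname(obs["P1"] - obs["P2"]), p = p,
      B = B, B_effective = b_eff, seed = seed,
      n_orp = unname(obs["n_orp"]), n_sl = unname(obs["n_sl"]),
      n_joint = unname(obs["joint"])
    ),
    class = "precedence_result"
  )
}

#' @export
print.precedence_result <- function(x, ...) {
  cat(sprintf(
    "Precedence: P1 = P(SL|ORP) = %.3f, P2 = P(ORP|SL) = %.3f, diff = %.3f\n",
    x$P1, x$P2, x$diff
  ))
  cat(sprintf("  bootstrap two-sided p = %.4g (B = %d, %d valid)\n",
              x$p, x$B, x$B_effective))
  invisible(x)
}

#' Extrapolate looking-style trajectories to an earlier age
#'
#' For every infant observed at all the given occasions, fits an ordinary
#' least-squares line of \code{pi_hat} on occasion (age in months) and
#' predicts the value at \code{target_age}, clamping the prediction to
#' \code{[0, 1]}. Infants missing an occasion are excluded (count reported).
#' The summary gives the mean prediction and the proportion of predictions
#' above 1/2 (the weak SL proportion at the target age).
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param target_age age in months to predict at (default 0.25, one week).
#' @param occasions occasions an infant must have (default \code{c(3,6,9)}).
#' @return A list: \code{predictions} (data frame with infant_id, intercept,
#'   slope, raw and clamped prediction), \code{mean_prediction},
#'   \code{prop_sl}, \code{n}, \code{n_excluded}, \code{target_age}.
#' @export
trajectory_extrapolation <- function(cohort, target_age = 0.25,
                                     occasions = c(3, 6, 9)) {
  stopifnot(inherits(cohort, "cohort_table"), target_age > 0)
  sub <- cohort[cohort$occasion %in% occasions, ]
  counts <- table(sub$infant_id)
  complete <- names(counts)[counts == length(occasions)]
  n_excl <- length(unique(cohort$infant_id)) - length(complete)
  if (!length(complete)) {
    stop("no infant observed at all occasions ",
         paste(occasions, collapse = ", "))
  }
  preds <- do.call(rbind, lapply(complete, function(id) {
    rows <- sub[sub$infant_id == id, ]
    fit <- stats::lm(pi_hat ~ occasion, data = rows)
    cf <- stats::coef(fit)
    raw <- unname(cf[1] + cf[2] * target_age)
    data.frame(
      infant_id = id, intercept = unname(cf[1]), slope = unname(cf[2]),
      raw_prediction = raw,
      prediction = min(1, max(0, raw)),
      stringsAsFactors = FALSE
    )
  }))
  list(
    predictions = preds,
    mean_prediction = mean(preds$prediction),
    prop_sl = mean(preds$prediction > 0.5),
    n = nrow(preds), n_excluded = n_excl,
    target_age = target_age
  )
}

#' Probability of sampling enough short-looking infants
#'
#' Treats recruitment as a Bernoulli process: each infant is weak SL with
#' probability \code{p_sl}. Returns the probability that each of
#' \code{n_samples} independent samples of size \code{n_per_sample} contains
#' at least \code{min_sl} SL infants:
#' \eqn{[P(\mathrm{Bin}(n, p) \ge m)]^{k}}.
#'
#' @param n_per_sample infants per sample.
#' @param p_sl probability an infant is weak SL, in \code{[0, 1]}.
#' @param min_sl required number of SL infants per sample
#'   (\code{<= n_per_sample}).
#' @param n_samples number of independent samples (default 1).
#' @return A probability.
#' @examples
#' sampling_probability(12, 21/58, 5)      # about 0.45
#' sampling_probability(12, 21/58, 5, 3)   # about 0.09
#' @export
sampling_probability <- function(n_per_sample, p_sl, min_sl, n_samples = 1) {
  if (!is.numeric(p_sl) || is.na(p_sl) || p_sl < 0 || p_sl > 1) {
    stop("'p_sl' must be a probability in [0, 1]")
  }
  if (min_sl < 0 || n_per_sample < 1 || min_sl > n_per_sample) {
    stop("need 0 <= min_sl <= n_per_sample with n_per_sample >= 1")
  }
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  q <- stats::pbinom(min_sl - 1, n_per_sample, p_sl, lower.tail = FALSE)
  q^n_samples
}
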