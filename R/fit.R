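#' Fitting options for the looking-style mixture
#'
#' @param cluster_gap maximum spacing (frames) between consecutive distinct
#'   same-sign values for them to belong to the same boundary cluster when
#'   seeding the long-band inner endpoints. Default 8 frames (about a third
#'   of a second at 25 frames/s), calibrated on simulated cohorts with known
#'   parameters.
#' @param tol relative log-likelihood convergence tolerance for EM.
#' @param max_iter maximum EM iterations.
#' @param select if \code{TRUE} (default), compare the full mixture against
#'   the short-only submodel by BIC and return the short-only degenerate fit
#'   (\code{pi = 1}) when the long bands are not supported by the data.
#' @param lambda_rule how the negative-band weight \code{lam} is updated:
#'   \code{"long"} (default) uses the long-look responsibility mass on the
#'   negative side; \code{"all"} pins \code{lam} at the observed fraction of
#'   negative scores among nonzero scores.
#' @param extend_tol log-likelihood improvement an inward band extension
#'   must achieve to be accepted (a decisive-support threshold; 8 log units
#'   is a likelihood ratio of about 3000:1). Extensions rescue bands that
#'   the spacing rule severed; the high bar prevents bands from creeping
#'   over genuinely short looks. Set to \code{Inf} to disable.
#' @param min_width minimum component width (frames) used in the fitting
#'   likelihood so that single-valued clusters (zero-width bands) keep a
#'   finite likelihood. Default 1 frame.
#' @return A list of class \code{"lookmix_control"}.
#' @export
fit_control <- function(cluster_gap = 8, tol = 1e-8, max_iter = 500,
                        select = TRUE, lambda_rule = c("long", "all"),
                        extend_tol = 8, min_width = 1) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(cluster_gap >= 0, tol > 0, max_iter >= 1, min_width > 0,
            extend_tol > 0)
  structure(
    list(cluster_gap = cluster_gap, tol = tol, max_iter = max_iter,
         select = select, lambda_rule = lambda_rule,
         extend_tol = extend_tol, min_width = min_width),
    class = "lookmix_control"
  )
}

# inner endpoint of a boundary cluster: walk inward from the outermost
# distinct value while consecutive spacings stay within `gap`
cluster_endpoint <- function(values, from_low, gap) {
  v <- sort(unique(values), decreasing = !from_low)
  k <- 1L
  while (k < length(v) && abs(v[k + 1L] - v[k]) <= gap) k <- k + 1L
  v[k]
}

# fitting likelihood: component width floored at `min_width` so that
# degenerate single-valued components stay finite
fit_width <- function(lo, hi, min_width) max(hi - lo, min_width)

fit_densities <- function(d, a, b, e, f, min_width) {
  us <- ifelse(d >= a & d <= f, 1 / fit_width(a, f, min_width), 0)
  ul <- numeric(length(d))
  if (!is.na(b)) {
    ul <- ul + ifelse(d >= a & d <= b, 1, 0) / fit_width(a, b, min_width)
  }
  un <- ul # negative-band indicator density (unit lambda)
  up <- numeric(length(d))
  if (!is.na(e)) {
    up <- ifelse(d >= e & d <= f, 1, 0) / fit_width(e, f, min_width)
  }
  list(short = us, neg = un, pos = up)
}

em_loglik <- function(dens, pi, lam) {
  mix <- pi * dens$short + (1 - pi) * (lam * dens$neg + (1 - lam) * dens$pos)
  if (any(mix <= 0)) return(-Inf)
  sum(log(mix))
}

# EM for (pi, lam) at fixed endpoints; returns the path of log-likelihoods
run_em <- function(d, a, b, e, f, control) {
  dens <- fit_densities(d, a, b, e, f, control$min_width)
  in_gap <- dens$short > 0 & dens$neg == 0 & dens$pos == 0
  pi <- if (any(in_gap)) max(0.5, mean(in_gap)) else 0.5
  n_neg <- sum(d < 0); n_pos <- sum(d > 0)
  lam <- if (is.na(b)) 0 else if (is.na(e)) 1 else
    if (n_neg + n_pos > 0) n_neg / (n_neg + n_pos) else 0.5
  lam_free <- control$lambda_rule == "long" && !is.na(b) && !is.na(e)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  r <- rep(NA_real_, length(d))
  for (it in seq_len(control$max_iter)) {
    u_long <- lam * dens$neg + (1 - lam) * dens$pos
    mix <- pi * dens$short + (1 - pi) * u_long
    if (any(mix <= 0)) {
      return(list(pi = pi, lam = lam, loglik = -Inf, posteriors = r,
                  n_iter = it, converged = FALSE, ll_trace = ll_trace))
    }
    r <- pi * dens$short / mix
    pi <- mean(r)
    if (lam_free) {
      long_mass <- sum(1 - r)
      if (long_mass > 0) lam <- sum((1 - r)[d < 0]) / long_mass
    }
    ll <- em_loglik(dens, pi, lam)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < control$tol * (abs(ll_old) + control$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final responsibilities at the converged parameters
  u_long <- lam * dens$neg + (1 - lam) * dens$pos
  mix <- pi * dens$short + (1 - pi) * u_long
  r <- pi * dens$short / mix
  list(pi = pi, lam = lam, loglik = em_loglik(dens, pi, lam),
       posteriors = r, n_iter = length(ll_trace), converged = converged,
       ll_trace = ll_trace)
}

#' Fit the looking-style mixture to a trial series
#'
#' Estimates one infant-occasion's looking-style mixture. The outer endpoints
#' are fixed at the observed extremes, \code{a = min(d)} and \code{f =
#' max(d)} (clamped to the frame range). The long-band inner endpoints
#' \code{b} and \code{e} are seeded at the inner edge of each boundary
#' cluster: the maximal run inward from the most extreme negative (positive)
#' value whose consecutive distinct values are no more than
#' \code{cluster_gap} frames apart. An EM algorithm then estimates the
#' short-look weight \code{pi} and the negative-band share \code{lam}:
#' the E-step computes per-trial responsibilities
#' \eqn{r_t = \pi u_s(d_t) / [\pi u_s(d_t) + (1-\pi) u_{long}(d_t)]} and the
#' M-step sets \eqn{\pi \leftarrow \mathrm{mean}(r_t)} and
#' \eqn{\lambda \leftarrow \sum_{d_t<0}(1-r_t) / \sum_t (1-r_t)}. After
#' convergence, inward band extensions (moving \code{b} or \code{e} to a
#' more central observed value and re-running EM) are accepted while the
#' best one improves the log-likelihood by more than \code{extend_tol}; this
#' rescues a band that the spacing rule severed at an internal gap, while
#' the decisive-support threshold stops bands from absorbing genuinely
#' short looks.
#'
#' Because uniform mixtures reward arbitrarily narrow bands, band support is
#' decided by model choice rather than raw likelihood: the converged mixture
#' is compared with the short-only submodel (a single uniform on
#' \code{[a, f]}) by BIC, and when the bands are not supported the
#' degenerate short-only fit \code{pi = 1} is returned. Degenerate fits
#' \code{pi = 0} and \code{pi = 1} are admissible; at \code{pi = 1} the band
#' endpoints are not identified and are reported as located, flagged via
#' \code{identifiable = FALSE}. Scores of exactly 0 always lie in the open
#' gap \code{(b, e)}, so their posterior short probability is 1 whenever
#' \code{pi > 0}. Series with no negative (or no positive) scores drop the
#' corresponding band (\code{lam} pinned to 0 or 1).
#'
#' @param series a \code{\link{trial_series}} (or bare numeric vector of
#'   difference scores) with at least 4 trials.
#' @param control a \code{\link{fit_control}} list.
#' @return An object of class \code{"lookmix_fit"}: list with \code{model}
#'   (\code{\link{looking_mixture}}), \code{posteriors} (per-trial
#'   probability the look was short), \code{pi_hat} (their mean),
#'   \code{loglik}, \code{n_iter}, \code{converged}, \code{ll_trace} (EM
#'   log-likelihood path), \code{selected} (\code{"mixture"} or
#'   \code{"short_only"}), \code{identifiable}, \code{d_bar}, and the input
#'   identifiers.
#' @examples
#' fit <- fit_mixture(example_series_2523())
#' fit$pi_hat
#' @export
fit_mixture <- function(series, control = fit_control()) {
  series <- as_trial_series(series)
  d <- series$d
  T <- series$T
  if (T < 4) {
    stop("fitting requires at least 4 trials; got ", T)
  }
  lim <- series$frame_limit
  a <- max(min(d), -lim)
  f <- min(max(d), lim)

  # fully degenerate data: every score identical
  if (a == f) {
    model <- looking_mixture(a = a, b = NA, e = NA, f = f, pi = 1, lam = 0)
    post <- rep(1, T)
    ll <- -T * log(fit_width(a, f, control$min_width))
    return(new_lookmix_fit(series, model, post, ll, 0L, TRUE, numeric(0),
                           "short_only", identifiable = FALSE))
  }

  b <- if (any(d < 0)) cluster_endpoint(d[d < 0], from_low = TRUE,
                                        control$cluster_gap) else NA_real_
  e <- if (any(d > 0)) cluster_endpoint(d[d > 0], from_low = FALSE,
                                        control$cluster_gap) else NA_real_

  em <- run_em(d, a, b, e, f, control)

  # decisively supported inward extensions of the seeded bands
  if (is.finite(control$extend_tol)) {
    repeat {
      cand <- list()
      if (!is.na(b)) {
        for (b2 in unique(d[d < 0 & d > b])) cand <- c(cand, list(c(b2, NA)))
      }
      if (!is.na(e)) {
        for (e2 in unique(d[d > 0 & d < e])) cand <- c(cand, list(c(NA, e2)))
      }
      if (!length(cand)) break
      ems <- lapply(cand, function(z) {
        run_em(d, a, if (is.na(z[1])) b else z[1],
               if (is.na(z[2])) e else z[2], f, control)
      })
      lls <- vapply(ems, `[[`, numeric(1), "loglik")
      k <- which.max(lls)
      if (lls[k] <= em$loglik + control$extend_tol) break
      if (!is.na(cand[[k]][1])) b <- cand[[k]][1] else e <- cand[[k]][2]
      em <- ems[[k]]
    }
  }

  # short-only submodel: single uniform on [a, f]
  ll_short <- -T * log(fit_width(a, f, control$min_width))
  k_extra <- sum(!is.na(c(b, e))) + 1 + as.integer(!is.na(b) && !is.na(e))
  keep_bands <- is.finite(em$loglik) &&
    (!control$select || em$loglik - ll_short > k_extra / 2 * log(T))

  if (!keep_bands) {
    model <- looking_mixture(a = a, b = b, e = e, f = f, pi = 1,
                             lam = em$lam)
    return(new_lookmix_fit(series, model, rep(1, T), ll_short, em$n_iter,
                           TRUE, em$ll_trace, "short_only",
                           identifiable = FALSE))
  }

  eps <- 1e-6
  model <- looking_mixture(a = a, b = b, e = e, f = f, pi = em$pi,
                           lam = em$lam)
  new_lookmix_fit(series, model, em$posteriors, em$loglik, em$n_iter,
                  em$converged, em$ll_trace, "mixture",
                  identifiable = em$pi < 1 - eps)
}

new_lookmix_fit <- function(series, model, posteriors, loglik, n_iter,
                            converged, ll_trace, selected, identifiable) {
  structure(
    list(
      model = model, posteriors = posteriors,
      pi_hat = mean(posteriors), loglik = loglik,
      n_iter = n_iter, converged = converged, ll_trace = ll_trace,
      selected = selected, identifiable = identifiable,
      d_bar = mean(series$d), T = series$T,
      infant_id = series$infant_id, occasion = series$occasion,
      series = series
    ),
    class = "lookmix_fit"
  )
}

#' @export
print.lookmix_fit <- function(x, ...) {
  cat(sprintf(
    "Looking-style mixture fit: infant %s, occasion %s, T = %d\n",
    format(x$infant_id), format(x$occasion), x$T
  ))
  m <- x$model
  cat(sprintf("  pi_hat = %.4f   lambda = %.4f   loglik = %.3f\n",
              x$pi_hat, m$lam, x$loglik))
  cat(sprintf("  endpoints: a = %g, b = %s, e = %s, f = %g%s\n",
              m$a, format(m$b), format(m$e), m$f,
              if (!x$identifiable) "  (bands not identified)" else ""))
  invisible(x)
}

#' Posterior probability a look was short
#'
#' \eqn{P(\mathrm{short} \mid x) = \pi u_s(x) / u_{mix}(x)}. Points in the
#' open gap \code{(b, e)} have zero long density, so their posterior is 1
#' whenever \code{pi > 0}; when \code{pi = 0} the posterior is 0 on the
#' bands (and, by the same convention, everywhere).
#'
#' @param model a \code{\link{looking_mixture}}.
#' @param x numeric vector of points within \code{[a, f]}.
#' @return Numeric vector of probabilities in \code{[0, 1]}.
#' @export
posterior_short <- function(model, x) {
  stopifnot(inherits(model, "looking_mixture"))
  if (any(x < model$a | x > model$f)) {
    stop("'x' must lie within the model support [a, f]")
  }
  if (model$pi == 0) return(rep(0, length(x)))
  num <- model$pi * unif_dens(x, model$a, model$f)
  dens <- mixture_density(model, x)
  p <- ifelse(is.infinite(dens), 0, num / dens)
  # zero-width short component: point mass entirely short where it sits
  if (model$f == model$a) p <- rep(1, length(x))
  pmin(pmax(p, 0), 1)
}

#' Classify an infant-occasion as short- or long-looking
#'
#' Weak criterion: short-looking (SL) iff \code{pi_hat > 1/2}, long-looking
#' (LL) iff \code{pi_hat < 1/2}, indeterminate at exactly 1/2. Strong
#' criterion: SL iff \code{pi_hat >= 1 - eps}, LL iff \code{pi_hat <= eps},
#' else neither (estimates rarely reach the boundary bit-exactly except in
#' fully degenerate fits, hence the tolerance).
#'
#' @param pi_hat estimated short-look probability in \code{[0, 1]}, or a
#'   \code{"lookmix_fit"}.
#' @param infant_id,occasion identifiers carried into the record (taken from
#'   the fit when one is supplied).
#' @param eps strong-criterion tolerance, default \code{1e-6}.
#' @return A one-row data frame with columns \code{infant_id},
#'   \code{occasion}, \code{pi_hat}, \code{weak_label} (SL/LL/indeterminate)
#'   and \code{strong_label} (SL/LL/neither).
#' @export
classify <- function(pi_hat, infant_id = NA, occasion = NA, eps = 1e-6) {
  if (inherits(pi_hat, "lookmix_fit")) {
    fit <- pi_hat
    if (is.na(infant_id)) infant_id <- fit$infant_id
    if (is.na(occasion)) occasion <- fit$occasion
    pi_hat <- fit$pi_hat
  }
  if (!is.numeric(pi_hat) || length(pi_hat) != 1 || is.na(pi_hat) ||
      pi_hat < 0 || pi_hat > 1) {
    stop("'pi_hat' must be a single probability in [0, 1]")
  }
  weak <- if (pi_hat > 0.5) "SL" else if (pi_hat < 0.5) "LL" else
    "indeterminate"
  strong <- if (pi_hat >= 1 - eps) "SL" else if (pi_hat <= eps) "LL" else
    "neither"
  data.frame(
    infant_id = infant_id, occasion = occasion, pi_hat = pi_hat,
    weak_label = weak, strong_label = strong,
    stringsAsFactors = FALSE
  )
}

#' Bootstrap uncertainty for a fitted series
#'
#' Resamples the trials with replacement \code{B} times, refits the mixture
#' each time, and summarises the bootstrap distributions of \code{pi_hat}
#' and the mean difference score \code{d_bar} with a standard error and a
#' 2.5--97.5 percentile interval.
#'
#' @param series a \code{\link{trial_series}} with at least 4 trials.
#' @param B number of bootstrap resamples (>= 100; fewer makes percentile
#'   intervals meaningless and is refused).
#' @param seed integer seed.
#' @param control passed to \code{\link{fit_mixture}}.
#' @return A list with \code{pi_hat} and \code{d_bar}, each holding
#'   \code{estimate}, \code{se}, \code{ci} (percentile interval) and the
#'   bootstrap \code{replicates}; plus \code{B} and \code{seed}.
#' @export
bootstrap_fit <- function(series, B = 1000, seed = NULL,
                          control = fit_control()) {
  series <- as_trial_series(series)
  if (B < 100) {
    stop("'B' must be at least 100: percentile intervals from fewer ",
         "resamples are meaningless")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  fit0 <- fit_mixture(series, control)
  reps <- vapply(seq_len(B), function(i) {
    idx <- sample.int(series$T, series$T, replace = TRUE)
    db <- series$d[idx]
    ft <- fit_mixture(
      trial_series(db, series$infant_id, series$occasion,
                   series$frame_limit),
      control
    )
    c(pi_hat = ft$pi_hat, d_bar = mean(db))
  }, numeric(2))
  summarise <- function(v, est) {
    list(estimate = est, se = stats::sd(v),
         ci = unname(stats::quantile(v, c(0.025, 0.975))),
         replicates = unname(v))
  }
  list(
    pi_hat = summarise(reps["pi_hat", ], fit0$pi_hat),
    d_bar = summarise(reps["d_bar", ], fit0$d_bar),
    B = B, seed = seed
  )
}
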