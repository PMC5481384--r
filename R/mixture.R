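#' Looking-style uniform mixture model
#'
#' Constructs the per-infant three-rectangle mixture model of looking style.
#' A trial's difference score is drawn, with probability \code{pi}, from the
#' "short look" component: a uniform over the whole response range
#' \code{[a, f]} (gaze split between the two stimuli). With probability
#' \code{1 - pi} it is a "long look", drawn from one of two narrow boundary
#' uniforms: the negative band \code{[a, b]} with weight \code{lam}, or the
#' positive band \code{[e, f]} with weight \code{1 - lam} (near-exclusive
#' gaze to one stimulus).
#'
#' The density is
#' \deqn{u_{mix}(x) = \pi\, u(a,f) + (1-\pi)\,[\lambda\, u(a,b) +
#'   (1-\lambda)\, u(e,f)]}
#' where \eqn{u(\alpha,\beta) = 1/(\beta-\alpha)} on \eqn{[\alpha,\beta]}.
#' Endpoints must satisfy \code{a <= b < 0 < e <= f}. A band may be absent
#' (\code{b = NA} with \code{lam = 0}, or \code{e = NA} with \code{lam = 1}),
#' which arises when a series has no negative (or no positive) scores.
#' Zero-width components (\code{a == b}, \code{e == f}, or \code{a == f})
#' are admitted for degenerate data and behave as point masses: the CDF
#' jumps there and the density is infinite at the point.
#'
#' @param a,f outer endpoints of the response range (frames).
#' @param b upper endpoint of the negative long band, or \code{NA} if the
#'   band is absent.
#' @param e lower endpoint of the positive long band, or \code{NA} if absent.
#' @param pi probability a look is short, in \code{[0, 1]}.
#' @param lam proportion of long-look mass on the negative band, in
#'   \code{[0, 1]}.
#'
#' @return An object of class \code{"looking_mixture"}.
#' @examples
#' m <- looking_mixture(a = -130, b = -119, e = 118, f = 130,
#'                      pi = 0.4, lam = 0.5)
#' mixture_density(m, 0)      # in the gap: only the short component
#' mixture_cdf(m, 0)
#' mixture_moments(m)
#' @export
looking_mixture <- function(a, b, e, f, pi, lam) {
  stopifnot(is.numeric(a), is.numeric(f), length(a) == 1, length(f) == 1)
  if (is.na(a) || is.na(f) || a > f) {
    stop("outer endpoints must satisfy a <= f")
  }
  if (!is.numeric(pi) || is.na(pi) || pi < 0 || pi > 1) {
    stop("'pi' must lie in [0, 1]")
  }
  if (!is.numeric(lam) || is.na(lam) || lam < 0 || lam > 1) {
    stop("'lam' must lie in [0, 1]")
  }
  has_neg <- !is.na(b)
  has_pos <- !is.na(e)
  if (has_neg && (b < a || b >= 0)) stop("need a <= b < 0")
  if (has_pos && (e > f || e <= 0)) stop("need 0 < e <= f")
  if (!has_neg && lam > 0 && pi < 1) {
    stop("negative band absent: 'lam' must be 0")
  }
  if (!has_pos && lam < 1 && pi < 1) {
    stop("positive band absent: 'lam' must be 1")
  }
  structure(
    list(a = a, b = if (has_neg) b else NA_real_,
         e = if (has_pos) e else NA_real_, f = f,
         pi = pi, lam = lam),
    class = "looking_mixture"
  )
}

#' @export
print.looking_mixture <- function(x, ...) {
  cat("Looking-style uniform mixture\n")
  cat(sprintf("  short component: u(%g, %g), weight pi = %.4g\n",
              x$a, x$f, x$pi))
  if (!is.na(x$b)) {
    cat(sprintf("  negative long band: u(%g, %g), weight (1-pi)*lam = %.4g\n",
                x$a, x$b, (1 - x$pi) * x$lam))
  }
  if (!is.na(x$e)) {
    cat(sprintf("  positive long band: u(%g, %g), weight (1-pi)*(1-lam) = %.4g\n",
                x$e, x$f, (1 - x$pi) * (1 - x$lam)))
  }
  invisible(x)
}

# component weights: short, negative band, positive band
mixture_weights <- function(model) {
  w_neg <- if (is.na(model$b)) 0 else (1 - model$pi) * model$lam
  w_pos <- if (is.na(model$e)) 0 else (1 - model$pi) * (1 - model$lam)
  c(short = model$pi, neg = w_neg, pos = w_pos)
}

# uniform density on [lo, hi]; zero-width -> Inf at the point
unif_dens <- function(x, lo, hi) {
  inside <- x >= lo & x <= hi
  if (hi > lo) ifelse(inside, 1 / (hi - lo), 0) else ifelse(inside, Inf, 0)
}

# uniform CDF on [lo, hi]; zero-width -> step at the point
unif_cdf <- function(x, lo, hi) {
  if (hi > lo) pmin(1, pmax(0, (x - lo) / (hi - lo))) else as.numeric(x >= lo)
}

#' Mixture density
#'
#' Evaluates the looking-style mixture density at \code{x}. The density is
#' zero outside \code{[a, f]}, and zero in the open gap \code{(b, e)} unless
#' the short component has weight (\code{pi > 0}). Equal-looking trials
#' (\code{x = 0}) always fall in the gap, so their long density is zero.
#'
#' @param model a \code{\link{looking_mixture}}.
#' @param x numeric vector of evaluation points (frames).
#' @return Numeric vector of densities.
#' @export
mixture_density <- function(model, x) {
  stopifnot(inherits(model, "looking_mixture"))
  w <- mixture_weights(model)
  dens <- w["short"] * unif_dens(x, model$a, model$f)
  if (w["neg"] > 0) dens <- dens + w["neg"] * unif_dens(x, model$a, model$b)
  if (w["pos"] > 0) dens <- dens + w["pos"] * unif_dens(x, model$e, model$f)
  unname(dens)
}

#' Mixture cumulative distribution function
#'
#' Piecewise-linear, nondecreasing CDF of the looking-style mixture: 0 at
#' \code{x <= a}, 1 at \code{x >= f}.
#'
#' @inheritParams mixture_density
#' @return Numeric vector of probabilities in \code{[0, 1]}.
#' @export
mixture_cdf <- function(model, x) {
  stopifnot(inherits(model, "looking_mixture"))
  w <- mixture_weights(model)
  p <- w["short"] * unif_cdf(x, model$a, model$f)
  if (w["neg"] > 0) p <- p + w["neg"] * unif_cdf(x, model$a, model$b)
  if (w["pos"] > 0) p <- p + w["pos"] * unif_cdf(x, model$e, model$f)
  unname(p)
}

#' Mixture mean and variance
#'
#' Closed-form moments from the component moments of each uniform
#' (\eqn{u(\alpha,\beta)} has mean \eqn{(\alpha+\beta)/2} and second moment
#' \eqn{(\alpha^2+\alpha\beta+\beta^2)/3}), combined with the component
#' weights \code{pi}, \code{(1-pi)*lam}, \code{(1-pi)*(1-lam)}.
#'
#' @inheritParams mixture_density
#' @return Named numeric vector \code{c(mean, variance)}.
#' @export
mixture_moments <- function(model) {
  stopifnot(inherits(model, "looking_mixture"))
  w <- mixture_weights(model)
  ends <- rbind(
    short = c(model$a, model$f),
    neg   = c(model$a, model$b),
    pos   = c(model$e, model$f)
  )
  m1 <- m2 <- 0
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    lo <- ends[k, 1]; hi <- ends[k, 2]
    m1 <- m1 + w[k] * (lo + hi) / 2
    m2 <- m2 + w[k] * (lo^2 + lo * hi + hi^2) / 3
  }
  c(mean = unname(m1), variance = unname(m2 - m1^2))
}

#' Sample trials from a looking-style mixture
#'
#' Generative counterpart of the mixture: per trial, draw a component (short
#' with probability \code{pi}, otherwise the negative band with probability
#' \code{lam}), then a uniform variate within the component interval. With
#' \code{integerize = TRUE} (the default, mimicking video-frame counts)
#' values are rounded to the nearest integer and clamped to
#' \code{[-frame_limit, frame_limit]}.
#'
#' @inheritParams mixture_density
#' @param T number of trials to draw (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param integerize round and clamp draws to integer frame counts.
#' @param infant_id,occasion passed to \code{\link{trial_series}}.
#' @param frame_limit clamping bound, default 130.
#' @return A \code{\link{trial_series}} with attribute \code{"component"}:
#'   the true generating component per trial (\code{"short"}, \code{"neg"},
#'   \code{"pos"}).
#' @export
sample_trials <- function(model, T, seed = NULL, integerize = TRUE,
                          infant_id = NA, occasion = NA, frame_limit = 130) {
  stopifnot(inherits(model, "looking_mixture"))
  if (!is.numeric(T) || length(T) != 1 || T < 1) {
    stop("'T' must be a positive trial count")
  }
  T <- as.integer(T)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  w <- mixture_weights(model)
  comp <- sample(c("short", "neg", "pos"), T, replace = TRUE, prob = w)
  ends <- list(
    short = c(model$a, model$f),
    neg   = c(model$a, model$b),
    pos   = c(model$e, model$f)
  )
  d <- vapply(comp, function(k) {
    stats::runif(1, ends[[k]][1], ends[[k]][2])
  }, numeric(1))
  if (integerize) d <- pmin(pmax(round(d), -frame_limit), frame_limit)
  out <- trial_series(d, infant_id = infant_id, occasion = occasion,
                      frame_limit = frame_limit)
  attr(out, "component") <- unname(comp)
  out
}

# save / restore the global RNG state so seeded helpers do not disturb
# the caller's random stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
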