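#' Scenario for a synthetic longitudinal cohort
#'
#' Describes a cohort with the statistical structure the downstream analyses
#' assume: per-infant looking-style trajectories rising with age, long-look
#' side imbalance inducing preference, and a longitudinal attrition pattern.
#' Defaults emulate a 74-infant cohort assessed at 3, 6 and 9 months with
#' 46 infants at all three ages, 21 at two adjacent ages (12 at 3 & 6, 9 at
#' 6 & 9) and 7 at one age, giving per-occasion sizes 58, 67 and 62.
#'
#' Per infant, the short-look probability follows a logistic curve in age,
#' \code{pi(age) = plogis((age - midpoint)/scale)}, with random midpoint and
#' scale; a fraction \code{prop_always_sl} of infants are strong SL at every
#' age (\code{pi = 1}) and a fraction \code{prop_step} jump from \code{pi =
#' 0} at the first occasion to \code{pi = 1} afterwards. Preference enters
#' through the two mechanisms the mixture offers: the long-look side share
#' \code{lam} (values above 1/2 tilt long looks toward the negative,
#' other-pole side) and an occasion-specific shift of the short component's
#' lower endpoint (a positive shift moves the short-look mean toward the
#' positive pole). The mixture mean is
#' \code{pi*(a+f)/2 + (1-pi)*[lam*(a+b)/2 + (1-lam)*(e+f)/2]}.
#'
#' @param n_infants number of infants.
#' @param occasions assessment ages in months.
#' @param T trials per session.
#' @param n_complete,n_two,n_one attrition pattern: infants observed at all,
#'   two adjacent, and one occasion (must sum to \code{n_infants}).
#' @param n_two_split how the two-adjacent infants divide over the adjacent
#'   occasion pairs, earliest pair first (must sum to \code{n_two});
#'   \code{NULL} splits evenly with the remainder on the earliest pairs.
#' @param midpoint_mean,midpoint_sd,scale_min,scale_max logistic trajectory
#'   parameters (months).
#' @param prop_always_sl,prop_step proportions of always-SL and step infants.
#' @param lambda_logit_mean,lambda_logit_sd per-infant \code{lam} drawn as
#'   \code{plogis(rnorm(., mean, sd))}.
#' @param band_inner_min,band_inner_max long-band inner endpoints are drawn
#'   uniformly on \code{[band_inner_min, band_inner_max]} in absolute value.
#' @param short_shift named numeric vector (one per occasion): frames added
#'   to the short component's lower endpoint (positive values) or subtracted
#'   from its upper endpoint (negative values).
#' @param frame_limit trial length in frames.
#' @param integerize round draws to integer frame counts.
#' @return A list of class \code{"cohort_scenario"}.
#' @export
cohort_scenario <- function(n_infants = 74,
                            occasions = c(3, 6, 9),
                            T = 24,
                            n_complete = 46, n_two = 21, n_one = 7,
                            n_two_split = if (n_two == 21 &&
                                              length(occasions) == 3)
                              c(12, 9) else NULL,
                            midpoint_mean = 3.2, midpoint_sd = 1.3,
                            scale_min = 0.5, scale_max = 1.5,
                            prop_always_sl = 0.10, prop_step = 0.05,
                            lambda_logit_mean = 0.3, lambda_logit_sd = 0.5,
                            band_inner_min = 105, band_inner_max = 120,
                            short_shift = c("3" = 13, "6" = -9, "9" = -13),
                            frame_limit = 130,
                            integerize = TRUE) {
  if (n_complete + n_two + n_one != n_infants) {
    stop("attrition counts must sum to n_infants")
  }
  stopifnot(
    T >= 4, length(occasions) >= 1, all(occasions > 0),
    prop_always_sl >= 0, prop_step >= 0, prop_always_sl + prop_step <= 1,
    band_inner_min > 0, band_inner_max >= band_inner_min,
    band_inner_max < frame_limit
  )
  if (!is.null(n_two_split)) {
    if (length(n_two_split) != length(occasions) - 1 ||
        sum(n_two_split) != n_two) {
      stop("'n_two_split' must give one count per adjacent occasion pair ",
           "and sum to n_two")
    }
  }
  if (is.null(names(short_shift)) ||
      !all(as.character(occasions) %in% names(short_shift))) {
    stop("'short_shift' must be named by occasion")
  }
  structure(
    list(
      n_infants = n_infants, occasions = sort(occasions), T = T,
      n_complete = n_complete, n_two = n_two, n_one = n_one,
      n_two_split = n_two_split,
      midpoint_mean = midpoint_mean, midpoint_sd = midpoint_sd,
      scale_min = scale_min, scale_max = scale_max,
      prop_always_sl = prop_always_sl, prop_step = prop_step,
      lambda_logit_mean = lambda_logit_mean,
      lambda_logit_sd = lambda_logit_sd,
      band_inner_min = band_inner_min, band_inner_max = band_inner_max,
      short_shift = short_shift, frame_limit = frame_limit,
      integerize = integerize
    ),
    class = "cohort_scenario"
  )
}

# deterministic attrition: complete infants first, then two-adjacent
# (earliest pair first), then singletons at the last occasion
observation_pattern <- function(scenario) {
  occ <- scenario$occasions
  k <- length(occ)
  pats <- vector("list", scenario$n_infants)
  idx <- 1L
  for (i in seq_len(scenario$n_complete)) {
    pats[[idx]] <- occ; idx <- idx + 1L
  }
  if (scenario$n_two > 0) {
    if (k < 2) stop("two-occasion infants need at least 2 occasions")
    n_pairs <- k - 1L
    counts <- scenario$n_two_split
    if (is.null(counts)) {
      base <- floor(scenario$n_two / n_pairs)
      extra <- scenario$n_two - base * n_pairs
      counts <- rep(base, n_pairs) +
        c(rep(1, extra), rep(0, n_pairs - extra))
    }
    for (p in seq_len(n_pairs)) {
      for (i in seq_len(counts[p])) {
        pats[[idx]] <- occ[c(p, p + 1L)]; idx <- idx + 1L
      }
    }
  }
  for (i in seq_len(scenario$n_one)) {
    pats[[idx]] <- occ[k]; idx <- idx + 1L
  }
  pats
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws, for each infant-occasion in the scenario's observation pattern, a
#' looking-style mixture (true \code{pi} from the infant's trajectory, long
#' bands and \code{lam} per the scenario) and then a full trial series from
#' it via \code{\link{sample_trials}}. Deterministic under \code{seed}.
#'
#' @param scenario a \code{\link{cohort_scenario}}.
#' @param seed integer seed.
#' @return A list with \code{trials} (long-format data frame: infant_id,
#'   occasion, trial, d, component) and \code{truth} (one row per
#'   infant-occasion: true pi, lam, a, b, e, f, and the infant's trajectory
#'   type).
#' @export
generate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- scenario$n_infants
  occ <- scenario$occasions
  lim <- scenario$frame_limit

  type <- sample(
    c("always_sl", "step", "logistic"), n, replace = TRUE,
    prob = c(scenario$prop_always_sl, scenario$prop_step,
             1 - scenario$prop_always_sl - scenario$prop_step)
  )
  midpoint <- stats::rnorm(n, scenario$midpoint_mean, scenario$midpoint_sd)
  scale <- stats::runif(n, scenario$scale_min, scenario$scale_max)
  lam <- stats::plogis(stats::rnorm(n, scenario$lambda_logit_mean,
                                    scenario$lambda_logit_sd))
  pats <- observation_pattern(scenario)

  true_pi <- function(i, age) {
    switch(type[i],
      always_sl = 1,
      step = as.numeric(age > min(occ)),
      logistic = stats::plogis((age - midpoint[i]) / scale[i])
    )
  }

  trials <- list()
  truth <- list()
  for (i in seq_len(n)) {
    id <- sprintf("syn%03d", i)
    for (age in pats[[i]]) {
      p <- true_pi(i, age)
      shift <- scenario$short_shift[[as.character(age)]]
      a <- -lim + max(0, shift)
      f <- lim + min(0, shift)
      b <- -round(stats::runif(1, scenario$band_inner_min,
                               scenario$band_inner_max))
      e <- round(stats::runif(1, scenario$band_inner_min,
                              scenario$band_inner_max))
      b <- max(b, a + 1)
      e <- min(e, f - 1)
      model <- looking_mixture(a = a, b = b, e = e, f = f,
                               pi = p, lam = lam[i])
      s <- sample_trials(model, scenario$T, integerize = scenario$integerize,
                         infant_id = id, occasion = age, frame_limit = lim)
      trials[[length(trials) + 1L]] <- data.frame(
        infant_id = id, occasion = age, trial = seq_len(scenario$T),
        d = s$d, component = attr(s, "component"),
        stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <- data.frame(
        infant_id = id, occasion = age, pi = p, lam = lam[i],
        a = a, b = b, e = e, f = f, type = type[i],
        stringsAsFactors = FALSE
      )
    }
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}
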