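#' Model-data agreement for one fitted series
#'
#' Compares the empirical distribution function of a series with the fitted
#' mixture CDF and the sample variance with the closed-form model variance.
#' The ECDF is right-continuous, \code{ECDF(x) = #(d <= x)/T}; the
#' discrepancy is the two-sided Kolmogorov-Smirnov statistic evaluated at
#' the observed points and their left limits. No p-value is attached: with
#' estimated parameters the KS null distribution does not apply, so the
#' statistic is descriptive.
#'
#' @param series a \code{\link{trial_series}}.
#' @param model the fitted \code{\link{looking_mixture}} for that series
#'   (or a \code{"lookmix_fit"}, from which both are taken).
#' @return A list of class \code{"fit_diagnostics"}: \code{ks_discrepancy},
#'   \code{model_variance}, \code{sample_variance} (denominator T - 1) and
#'   \code{variance_ratio} (model / sample).
#' @export
ecdf_vs_model <- function(series, model = NULL) {
  if (inherits(series, "lookmix_fit")) {
    model <- series$model
    series <- series$series
  }
  series <- as_trial_series(series)
  stopifnot(inherits(model, "looking_mixture"))
  d <- sort(series$d)
  T <- length(d)
  if (model$f == model$a) {
    stop("degenerate model (zero-width support): ECDF comparison refused")
  }
  Fm <- mixture_cdf(model, d)
  upper <- seq_len(T) / T      # ECDF at the point (right-continuous)
  lower <- (seq_len(T) - 1) / T # ECDF just left of the point
  ks <- max(abs(upper - Fm), abs(lower - Fm))
  mv <- unname(mixture_moments(model)["variance"])
  sv <- stats::var(series$d)
  structure(
    list(ks_discrepancy = ks, model_variance = mv, sample_variance = sv,
         variance_ratio = mv / sv),
    class = "fit_diagnostics"
  )
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf(
    "KS discrepancy %.4f | model var %.1f | sample var %.1f | ratio %.3f\n",
    x$ks_discrepancy, x$model_variance, x$sample_variance, x$variance_ratio
  ))
  invisible(x)
}

#' Cohort-level variance ratio per occasion
#'
#' For each occasion, the mean over infants of the model variance divided by
#' the mean over infants of the sample variance. Ratios near 1 indicate the
#' fitted mixtures carry the right amount of spread on average; below 1,
#' under-fitting (more variation in the data than the models account for).
#'
#' @param fits a list of \code{"lookmix_fit"} objects.
#' @return Data frame with one row per occasion: \code{occasion}, \code{n},
#'   \code{mean_model_variance}, \code{mean_sample_variance}, \code{ratio}.
#'   Occasions with no usable fits are skipped with a warning.
#' @export
cohort_variance_ratio <- function(fits) {
  stopifnot(length(fits) >= 1)
  occ <- vapply(fits, function(f) as.numeric(f$occasion), numeric(1))
  mv <- vapply(fits, function(f) {
    unname(mixture_moments(f$model)["variance"])
  }, numeric(1))
  sv <- vapply(fits, function(f) stats::var(f$series$d), numeric(1))
  out <- lapply(sort(unique(occ)), function(o) {
    i <- which(occ == o & is.finite(mv) & is.finite(sv))
    if (!length(i)) {
      warning("occasion ", o, " has no usable fits; skipped")
      return(NULL)
    }
    data.frame(
      occasion = o, n = length(i),
      mean_model_variance = mean(mv[i]),
      mean_sample_variance = mean(sv[i]),
      ratio = mean(mv[i]) / mean(sv[i])
    )
  })
  do.call(rbind, out)
}

#' Serial-correlation check of the within-infant sampling assumption
#'
#' The model treats an infant's trials as a random sample from that infant's
#' own response distribution, which implies trial order is irrelevant. This
#' checks the Pearson correlation of the pairs \code{(d_t, t)} against a
#' resampling null. The default null permutes the trial order (the sharp
#' null for "order is irrelevant"); \code{null = "bootstrap"} resamples the
#' scores with replacement instead. Two-sided p-values use the add-one
#' convention \code{(k + 1)/(B + 1)}.
#'
#' @param series a \code{\link{trial_series}} with at least 4 trials.
#' @param B number of resamples.
#' @param seed integer seed.
#' @param null \code{"permutation"} (default) or \code{"bootstrap"}.
#' @return A list: \code{r} (Pearson correlation, \code{NA} with
#'   \code{constant = TRUE} when the series has zero variance), \code{p}
#'   (two-sided), \code{B}, \code{null}.
#' @export
serial_correlation_check <- function(series, B = 2000, seed = NULL,
                                     null = c("permutation", "bootstrap")) {
  series <- as_trial_series(series)
  null <- match.arg(null)
  d <- series$d
  T <- series$T
  if (T < 4) stop("serial-correlation check requires at least 4 trials")
  t_idx <- seq_len(T)
  if (stats::var(d) == 0) {
    return(list(r = NA_real_, p = 1, B = B, null = null, constant = TRUE))
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  r_obs <- stats::cor(d, t_idx)
  r_null <- vapply(seq_len(B), function(i) {
    db <- if (null == "permutation") sample(d) else
      sample(d, T, replace = TRUE)
    if (stats::var(db) == 0) 0 else stats::cor(db, t_idx)
  }, numeric(1))
  p <- (sum(abs(r_null) >= abs(r_obs)) + 1) / (B + 1)
  list(r = r_obs, p = p, B = B, null = null, constant = FALSE)
}
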