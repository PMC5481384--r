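#' Trial series of difference scores
#'
#' A trial series holds one infant-occasion's ordered per-trial difference
#' scores from a paired-stimulus preferential looking session. Each score
#' \code{d} is the number of video frames spent on the positive-pole stimulus
#' minus the frames on the other stimulus; with 130 frames per trial,
#' \code{d} lies in \code{[-130, 130]}. Negative scores mean the infant
#' looked longer at the other-pole stimulus on that trial.
#'
#' @param d integer-valued vector of difference scores in \code{[-130, 130]}.
#' @param infant_id identifier for the infant (any scalar, kept as given).
#' @param occasion assessment age in months (positive number, e.g. 3, 6, 9).
#' @param frame_limit maximum trial length in frames; scores must lie in
#'   \code{[-frame_limit, frame_limit]}. Default 130.
#'
#' @return An object of class \code{"trial_series"}: a list with elements
#'   \code{d}, \code{infant_id}, \code{occasion}, \code{T} (number of
#'   trials) and \code{frame_limit}.
#' @examples
#' s <- trial_series(c(-130, 0, 64, 130), infant_id = "demo", occasion = 3)
#' s$T
#' @export
trial_series <- function(d, infant_id = NA, occasion = NA, frame_limit = 130) {
  if (!is.numeric(d) || length(d) < 1) {
    stop("'d' must be a non-empty numeric vector of difference scores")
  }
  if (anyNA(d)) stop("'d' must not contain missing values")
  bad <- which(abs(d) > frame_limit)
  if (length(bad)) {
    stop(sprintf(
      "difference scores out of [-%d, %d] at positions: %s",
      frame_limit, frame_limit, paste(bad, collapse = ", ")
    ))
  }
  if (!is.na(occasion) && (!is.numeric(occasion) || occasion <= 0)) {
    stop("'occasion' must be a positive age in months")
  }
  structure(
    list(
      d = as.numeric(d), infant_id = infant_id, occasion = occasion,
      T = length(d), frame_limit = frame_limit
    ),
    class = "trial_series"
  )
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf(
    "Trial series: infant %s, occasion %s months, T = %d\n",
    format(x$infant_id), format(x$occasion), x$T
  ))
  cat(sprintf(
    "  d: mean %.2f, var %.1f, range [%g, %g]\n",
    mean(x$d), stats::var(x$d), min(x$d), max(x$d)
  ))
  invisible(x)
}

as_trial_series <- function(x, ...) {
  if (inherits(x, "trial_series")) x else trial_series(x, ...)
}
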