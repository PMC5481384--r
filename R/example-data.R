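#' Worked-example trial series (infant 2523, 3 months)
#'
#' The 24 per-trial difference scores of the mixed-looking example infant
#' used throughout the documentation: a 3-month paired-stimulus session with
#' 130-frame trials. Scores near the boundary (|d| close to 130) are
#' near-exclusive looks to one face; scores near 0 split gaze between the
#' two faces. The series mixes both, so neither the all-short nor the
#' all-long model describes it: the fitted short-look probability is about
#' 0.35. Mean 1.67, sample variance about 11784.
#'
#' The same data ship as a CSV fixture at
#' \code{system.file("extdata", "example_trials.csv", package = "lookmix")}.
#'
#' @return A \code{\link{trial_series}} with \code{T = 24}.
#' @examples
#' s <- example_series_2523()
#' mean(s$d)
#' @export
example_series_2523 <- function() {
  trial_series(
    c(-117, 120, -124, 130, 97, 112, -108, 126, -130, -34, -122, 129,
      129, -76, 103, -103, 0, 0, -117, 130, -112, -108, 115, 0),
    infant_id = "2523", occasion = 3
  )
}
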