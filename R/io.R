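#' Difference scores from raw per-trial frame counts
#'
#' Computes \code{d = frames on the positive-pole stimulus minus frames on
#' the other stimulus} for each trial. The tool is stimulus-agnostic: which
#' column is the positive pole is a required choice, recorded in the
#' output's \code{"positive_pole"} attribute.
#'
#' @param raw data frame with columns \code{infant_id}, \code{occasion},
#'   \code{trial} and the two frame-count columns.
#' @param positive,negative names of the frame-count columns mapped to the
#'   positive and negative pole of \code{d}.
#' @param frame_limit frames per trial; per-trial counts must be
#'   nonnegative and sum to at most this (looking away accounts for the
#'   remainder). Default 130.
#' @return The input with a \code{d} column appended (frame columns kept),
#'   with attribute \code{"positive_pole"}.
#' @examples
#' raw <- data.frame(infant_id = "a", occasion = 3, trial = 1:2,
#'                   frames_c = c(70, 65), frames_a = c(50, 65))
#' compute_differences(raw, positive = "frames_c", negative = "frames_a")$d
#' @export
compute_differences <- function(raw, positive, negative,
                                frame_limit = 130) {
  stopifnot(is.data.frame(raw))
  for (col in c(positive, negative)) {
    if (!col %in% names(raw)) stop("missing frame-count column: ", col)
  }
  fp <- raw[[positive]]
  fn <- raw[[negative]]
  bad <- which(is.na(fp) | is.na(fn) | fp < 0 | fn < 0 |
                 fp + fn > frame_limit)
  if (length(bad)) {
    stop(sprintf(
      "invalid frame counts (negative, missing, or summing over %d) at rows: %s",
      frame_limit, paste(bad, collapse = ", ")
    ))
  }
  raw$d <- fp - fn
  attr(raw, "positive_pole") <- positive
  raw
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read trial data into validated trial series
#'
#' Reads a long-format delimited file with header and columns
#' \code{infant_id}, \code{occasion}, \code{trial}, \code{d} (or raw frame
#' columns, converted via \code{\link{compute_differences}} when
#' \code{positive}/\code{negative} are given), validates every row, and
#' groups rows into one \code{\link{trial_series}} per infant-occasion,
#' sorted by trial index. Validation failures name the offending rows;
#' nothing is silently dropped.
#'
#' @param path CSV or TSV file (delimiter auto-detected unless \code{sep}
#'   is given).
#' @param sep optional field delimiter.
#' @param positive,negative optional frame-count column names for raw input.
#' @param frame_limit frames per trial, default 130.
#' @return A named list of \code{\link{trial_series}} (names
#'   \code{"<infant>:<occasion>"}), with the validated long-format data
#'   frame as attribute \code{"table"}.
#' @export
read_trials <- function(path, sep = NULL, positive = NULL, negative = NULL,
                        frame_limit = 130) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(positive) || !is.null(negative)) {
    if (is.null(positive) || is.null(negative)) {
      stop("both 'positive' and 'negative' must be given for raw input")
    }
    df <- compute_differences(df, positive, negative, frame_limit)
  }
  need <- c("infant_id", "occasion", "trial", "d")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(df$d) | df$d != round(df$d) | abs(df$d) > frame_limit)
  if (length(bad)) {
    stop(sprintf(
      "invalid difference scores (non-integer, missing, or outside [-%d, %d]) at rows: %s",
      frame_limit, frame_limit, paste(bad, collapse = ", ")
    ))
  }
  if (any(is.na(df$occasion) | df$occasion <= 0)) {
    stop("'occasion' must be a positive age in months")
  }
  key <- paste(df$infant_id, df$occasion, sep = ":")
  dup <- duplicated(data.frame(key, df$trial))
  if (any(dup)) {
    stop("duplicate trial index within an infant-occasion at rows: ",
         paste(which(dup), collapse = ", "))
  }
  groups <- split(df, key)
  series <- lapply(groups, function(g) {
    g <- g[order(g$trial), ]
    trial_series(g$d, infant_id = g$infant_id[1], occasion = g$occasion[1],
                 frame_limit = frame_limit)
  })
  attr(series, "table") <- df
  series
}

#' Write fit, classification and analysis results
#'
#' Emits the standard output files: a parameter table (one row per
#' infant-occasion with endpoints, \code{lam}, \code{pi_hat}, log-likelihood
#' and flags), a posterior table (one row per trial with its short-look
#' posterior), optional analysis tables, and a run-level JSON report with
#' the configuration and seed. Numeric fields are written with 12
#' significant digits so that a write/read round trip is lossless at that
#' precision.
#'
#' @param fits list of \code{"lookmix_fit"} objects.
#' @param dir output directory (created if absent).
#' @param classifications optional data frame (e.g. stacked
#'   \code{\link{classify}} rows).
#' @param analyses optional named list of data frames, each written as
#'   \code{analysis_<name>.csv}.
#' @param config optional list stored in the JSON report.
#' @param seed optional seed recorded in the report.
#' @return Invisibly, the named vector of written paths.
#' @export
write_results <- function(fits, dir, classifications = NULL, analyses = NULL,
                          config = NULL, seed = NULL) {
  stopifnot(length(fits) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 12))
    df
  }
  params <- do.call(rbind, lapply(fits, function(f) {
    m <- f$model
    data.frame(
      infant_id = f$infant_id, occasion = f$occasion, T = f$T,
      a = m$a, b = m$b, e = m$e, f = m$f, lam = m$lam,
      pi_hat = f$pi_hat, d_bar = f$d_bar, loglik = f$loglik,
      n_iter = f$n_iter, converged = f$converged,
      selected = f$selected, identifiable = f$identifiable,
      stringsAsFactors = FALSE
    )
  }))
  posteriors <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      infant_id = f$infant_id, occasion = f$occasion,
      trial = seq_len(f$T), d = f$series$d, p_short = f$posteriors,
      stringsAsFactors = FALSE
    )
  }))
  paths <- c(
    params = file.path(dir, "params.csv"),
    posteriors = file.path(dir, "posteriors.csv"),
    report = file.path(dir, "report.json")
  )
  utils::write.csv(fmt(params), paths["params"], row.names = FALSE)
  utils::write.csv(fmt(posteriors), paths["posteriors"], row.names = FALSE)
  if (!is.null(classifications)) {
    paths["classifications"] <- file.path(dir, "classifications.csv")
    utils::write.csv(fmt(classifications), paths["classifications"],
                     row.names = FALSE)
  }
  for (nm in names(analyses)) {
    key <- paste0("analysis_", nm)
    paths[key] <- file.path(dir, paste0(key, ".csv"))
    utils::write.csv(fmt(as.data.frame(analyses[[nm]])), paths[key],
                     row.names = FALSE)
  }
  report <- list(
    package = "lookmix",
    version = as.character(utils::packageVersion("lookmix")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = if (is.null(config)) list() else config,
    n_fits = length(fits),
    files = as.list(unname(paths[names(paths) != "report"])),
    analyses = if (is.null(analyses)) list() else as.list(names(analyses))
  )
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
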