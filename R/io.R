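#' Read a beat stream from disk
#'
#' Two plain-text formats are supported:
#'
#' * `"csv"` — headered CSV with a required `rr_ms` column and optional
#'   `label` (`AF`/`NONAF`) and `time_s` columns.
#' * `"rdann"` — whitespace-delimited beat-annotation text as produced by
#'   WFDB's `rdann`, one beat per line starting with the elapsed time in
#'   seconds (further columns such as sample number and annotation code are
#'   ignored here). RR intervals are the successive beat-time differences;
#'   the first beat has no RR and is dropped with a message.
#'
#' @param path file path.
#' @param format `"csv"` or `"rdann"`.
#' @param record_id record identifier; defaults to the file name without
#'   extension.
#' @return a [beat_stream()].
#' @export
read_beats <- function(path, format = c("csv", "rdann"),
                       record_id = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop(sprintf("no beats in %s", path), call. = FALSE)
    if (!"rr_ms" %in% names(df)) {
      stop(sprintf("missing required column `rr_ms` in %s", path), call. = FALSE)
    }
    rr <- suppressWarnings(as.numeric(df$rr_ms))
    bad <- which(is.na(rr))
    if (length(bad) > 0L) {
      stop(sprintf("malformed rr_ms value %s at line %d of %s",
                   dQuote(df$rr_ms[bad[1L]]), bad[1L] + 1L, path), call. = FALSE)
    }
    labels <- if ("label" %in% names(df)) df$label else NULL
    beat_stream(rr, labels = labels, record_id = record_id)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop(sprintf("no beats in %s", path), call. = FALSE)
    times <- suppressWarnings(
      as.numeric(vapply(strsplit(trimws(lines), "[[:space:]]+"), `[[`, "", 1L)))
    bad <- which(is.na(times))
    if (length(bad) > 0L) {
      stop(sprintf("malformed beat time at line %d of %s", bad[1L], path),
           call. = FALSE)
    }
    if (length(times) < 2L) {
      stop(sprintf("need at least 2 beat times to form an RR interval: %s", path),
           call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop(sprintf("non-monotone beat times at line %d of %s",
                   which(diff(times) <= 0)[1L] + 1L, path), call. = FALSE)
    }
    message(sprintf("read_beats: first beat of %s has no RR interval and was dropped",
                    basename(path)))
    beat_stream(diff(times) * 1000, record_id = record_id)
  }
}

#' Write a beat stream to CSV
#'
#' Writes the standard headered beat CSV (`rr_ms` plus `label` when labels
#' are present). RR intervals are written with full precision so a
#' write/read round trip reproduces them to well below 1e-6 ms.
#'
#' @param stream a [beat_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(stream, path) {
  stopifnot(inherits(stream, "beat_stream"))
  df <- data.frame(rr_ms = format(stream$rr, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  if (!is.null(stream$labels)) df$label <- stream$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read interval rhythm annotations
#'
#' Parses rdann-style rhythm-annotation text: whitespace-delimited lines
#' carrying an onset (elapsed time in seconds, or a beat index) and a
#' rhythm code such as `"(AFIB"` or `"(N"`. Lines with two columns are read
#' as (onset, rhythm); lines with three or more as (time, sample, rhythm),
#' the rdann column order.
#'
#' @param path file path.
#' @return data frame with columns `onset` (numeric) and `rhythm`
#'   (character), onsets strictly increasing.
#' @seealso [expand_rhythm_labels()]
#' @export
read_rhythm_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("no annotations in %s", path), call. = FALSE)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  onset <- numeric(length(parts)); rhythm <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) {
      stop(sprintf("malformed annotation at line %d of %s", i, path), call. = FALSE)
    }
    onset[i] <- suppressWarnings(as.numeric(p[1L]))
    rhythm[i] <- if (length(p) >= 3L) p[3L] else p[2L]
    if (is.na(onset[i])) {
      stop(sprintf("malformed onset at line %d of %s", i, path), call. = FALSE)
    }
  }
  if (any(diff(onset) <= 0)) {
    stop(sprintf("annotation onsets must be strictly increasing (line %d of %s)",
                 which(diff(onset) <= 0)[1L] + 1L, path), call. = FALSE)
  }
  data.frame(onset = onset, rhythm = rhythm, stringsAsFactors = FALSE)
}

#' Expand interval rhythm annotations to per-beat labels
#'
#' A rhythm annotation governs every beat from its onset until the next
#' annotation (half-open intervals `[onset_j, onset_{j+1})`), the standard
#' rdann semantics. Onsets are beat indices (0-based) by default; when
#' `beat_times` is supplied, onsets are times in seconds and each beat is
#' assigned the annotation last seen at or before its time.
#'
#' Codes in `af_codes` map to `"AF"`; every other rhythm code (including
#' atrial flutter `"(AFL"` by default) maps to `"NONAF"`.
#'
#' @param annotations data frame with columns `onset` and `rhythm`, as from
#'   [read_rhythm_annotations()].
#' @param n_beats number of beats to label.
#' @param beat_times optional numeric vector of beat times (s), length
#'   `n_beats`; when given, onsets are interpreted as times.
#' @param af_codes rhythm codes classed as AF. Default `"(AFIB"`.
#' @return character vector of `"AF"` / `"NONAF"`, length `n_beats`.
#' @examples
#' ann <- data.frame(onset = c(0, 10, 20), rhythm = c("(N", "(AFIB", "(N"))
#' table(expand_rhythm_labels(ann, 30))
#' @export
expand_rhythm_labels <- function(annotations, n_beats, beat_times = NULL,
                                 af_codes = "(AFIB") {
  stopifnot(is.data.frame(annotations),
            all(c("onset", "rhythm") %in% names(annotations)))
  if (nrow(annotations) == 0L) stop("no annotations supplied", call. = FALSE)
  if (any(diff(annotations$onset) <= 0)) {
    stop("annotation onsets must be strictly increasing", call. = FALSE)
  }
  pos <- if (is.null(beat_times)) seq_len(n_beats) - 1L else {
    if (length(beat_times) != n_beats) {
      stop("`beat_times` length must equal `n_beats`", call. = FALSE)
    }
    beat_times
  }
  idx <- findInterval(pos, annotations$onset)
  if (any(idx == 0L)) {
    stop(sprintf("beat %d (0-based) precedes the first rhythm annotation",
                 which(idx == 0L)[1L] - 1L), call. = FALSE)
  }
  ifelse(annotations$rhythm[idx] %in% af_codes, "AF", "NONAF")
}

#' Write per-beat decisions to CSV
#'
#' Columns `record_id`, `beat_index`, `h` (6 decimals, empty before the
#' first word) and `label`.
#'
#' @param decisions a `beat_decisions` data frame from [detect_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  stopifnot(is.data.frame(decisions))
  out <- decisions
  out$h <- ifelse(is.na(out$h), "", sprintf("%.6f", out$h))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-beat decisions from CSV
#'
#' @param path a CSV written by [write_decisions()].
#' @return a `beat_decisions` data frame.
#' @export
read_decisions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  needed <- c("record_id", "beat_index", "h", "label")
  if (!all(needed %in% names(df))) {
    stop(sprintf("decisions file %s must have columns %s", path,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  df$h <- suppressWarnings(as.numeric(df$h))
  class(df) <- c("beat_decisions", "data.frame")
  df
}

#' Write an ROC sweep to CSV
#'
#' The per-threshold table, preceded by comment lines recording the AUC
#' and the optimal operating point.
#'
#' @param roc a [roc_sweep()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# auc=%.6f", roc$auc),
               sprintf("# best_threshold=%.3f", roc$best_threshold),
               sprintf("# best_distance=%.6f", roc$best_distance)), con)
  utils::write.csv(roc$points, con, row.names = FALSE)
  invisible(path)
}

#' Read a detector configuration file
#'
#' Accepts either JSON (`{"threshold": 0.639, ...}`) or simple
#' `key=value` lines; recognized keys are `threshold`, `N`, `hr_cap`,
#' `bin_width` and `warmup_policy`. Unspecified keys keep their defaults.
#'
#' @param path configuration file path.
#' @return a [detector_config()].
#' @export
read_detector_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  vals <- if (any(grepl("^\\s*\\{", txt))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    kv <- strsplit(txt[nzchar(trimws(txt))], "=")
    stats::setNames(
      lapply(kv, function(p) {
        v <- trimws(p[2L])
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) v else num
      }),
      vapply(kv, function(p) trimws(p[1L]), ""))
  }
  args <- vals[names(vals) %in% c("threshold", "N", "hr_cap", "bin_width",
                                  "warmup_policy")]
  do.call(detector_config, args)
}
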