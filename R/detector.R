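#' Detector configuration
#'
#' Bundles the tunable parameters of the beat-by-beat AF detector.
#'
#' `threshold` defaults to 0.639, the operating point selected on a large
#' long-term AF training corpus by minimizing the ROC distance to the ideal
#' classifier. `N` is the entropy window length in words; `hr_cap` and
#' `bin_width` shape the symbol alphabet. `warmup_policy` controls the label
#' given to the first `N + 1` beats, before a full window of `N` words
#' exists (two beats to form the first word plus `N - 1` more words):
#' `"mark"` labels them `WARMUP` (excluded from evaluation), `"nonaf"`
#' labels them `NONAF`, `"drop"` removes them from the output.
#'
#' @param threshold decision threshold in `[0, 1]`; entropy at or above it
#'   is called AF. Default 0.639.
#' @param N entropy window size in words. Default 127.
#' @param hr_cap,bin_width symbol-alphabet parameters, see [symbolize()].
#' @param warmup_policy one of `"mark"`, `"nonaf"`, `"drop"`.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(threshold = 0.639, N = 127L,
                            hr_cap = 315, bin_width = 5,
                            warmup_policy = c("mark", "nonaf", "drop")) {
  warmup_policy <- match.arg(warmup_policy)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("`N` must be an integer >= 2", call. = FALSE)
  if (hr_cap <= 0 || bin_width <= 0) {
    stop("`hr_cap` and `bin_width` must be positive", call. = FALSE)
  }
  structure(list(threshold = threshold, N = N, hr_cap = hr_cap,
                 bin_width = bin_width, warmup_policy = warmup_policy),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> threshold %.3f, N = %d, alphabet %d x %g bpm, warmup '%s'\n",
    x$threshold, x$N, as.integer(x$hr_cap %/% x$bin_width) + 1L,
    x$bin_width, x$warmup_policy))
  invisible(x)
}

#' Threshold decision rule
#'
#' AF is called when the entropy *meets or exceeds* the threshold (a tie is
#' AF); otherwise non-AF. Comparison is at full floating-point precision.
#'
#' @param h numeric vector of entropy values in `[0, 1]` (`NA` allowed).
#' @param threshold decision threshold.
#' @return character vector of `"AF"` / `"NONAF"` (`NA` where `h` is `NA`).
#' @examples
#' decide(c(0.639, 0.638), 0.639)
#' @export
decide <- function(h, threshold) {
  ifelse(is.na(h), NA_character_, ifelse(h >= threshold, "AF", "NONAF"))
}

#' Beat-by-beat AF detection over a beat stream
#'
#' The streaming classifier: each beat's RR interval is converted to heart
#' rate, symbolized, combined with the two preceding symbols into a word,
#' the word is pushed through the recursive sliding-window entropy, and the
#' entropy is compared with the threshold. The decision for beat `n` is
#' causal — it depends only on beats `0..n` (the word ending at beat `n`
#' and the `N - 1` words before it). Detector state never leaks across
#' records: each stream starts from an all-zero state.
#'
#' Beats `0:(N + 1 - 1)` precede the first full window; they are handled
#' per `config$warmup_policy`. The first fully-windowed decision is at beat
#' index `N + 1` (128 with defaults). Decisions are attached to the current
#' beat; the intrinsic detection latency of roughly half a window plus the
#' word length (about 65 beats with defaults) is a property of the sliding
#' window, not an output shift.
#'
#' @param stream a [beat_stream()].
#' @param config a [detector_config()].
#' @return data frame of class `beat_decisions` with columns `record_id`,
#'   `beat_index` (0-based), `h` (entropy, `NA` before the first word) and
#'   `label` (`"AF"`, `"NONAF"` or `"WARMUP"`).
#' @examples
#' bs <- beat_stream(rep(800, 200))
#' head(detect_stream(bs)[129:132, ])
#' @export
detect_stream <- function(stream, config = detector_config()) {
  stopifnot(inherits(stream, "beat_stream"), inherits(config, "detector_config"))
  n <- length(stream$rr)
  sw <- symbolize_stream(stream, hr_cap = config$hr_cap,
                         bin_width = config$bin_width)
  pm <- build_pimap(config$N)
  h_words <- entropy_stream(sw$words, pm)
  # word ending at beat n (0-based) is word index n - 2
  h <- rep(NA_real_, n)
  if (length(h_words) > 0L) h[seq_along(h_words) + 2L] <- h_words
  label <- decide(h, config$threshold)
  warm <- seq_len(min(n, config$N + 1L))  # beat indices 0 .. N (0-based)
  if (config$warmup_policy == "mark") {
    label[warm] <- "WARMUP"
  } else if (config$warmup_policy == "nonaf") {
    label[warm] <- "NONAF"
  }
  out <- data.frame(record_id = stream$record_id,
                    beat_index = 0:(n - 1L),
                    h = h, label = label,
                    stringsAsFactors = FALSE)
  if (config$warmup_policy == "drop") out <- out[-warm, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("beat_decisions", "data.frame")
  out
}
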