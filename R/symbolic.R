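#' Convert RR intervals to instantaneous heart rates
#'
#' Instantaneous heart rate in beats per minute is the reciprocal of the
#' RR interval: `hr = 60000 / rr_ms`. The value is kept real-valued; flooring
#' happens only inside [symbolize()], so no precision is lost before the
#' coarse-graining step.
#'
#' @param rr_ms numeric vector of RR intervals in milliseconds; all entries
#'   must be finite and strictly positive.
#' @return numeric vector of heart rates in bpm, same length as `rr_ms`.
#' @examples
#' rr_to_hr(c(1000, 500, 857.14))
#' @seealso [symbolize()], [symbolize_stream()]
#' @export
rr_to_hr <- function(rr_ms) {
  if (length(rr_ms) == 0L) return(numeric(0))
  if (!is.numeric(rr_ms)) stop("`rr_ms` must be numeric", call. = FALSE)
  bad <- which(!is.finite(rr_ms) | rr_ms <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid RR interval at beat index %d (0-based): %s ms",
                 bad[1L] - 1L, format(rr_ms[bad[1L]])), call. = FALSE)
  }
  60000 / rr_ms
}

#' Map heart rates to instantaneous-state symbols
#'
#' Coarse-grains heart rate into `bin_width`-bpm instantaneous states:
#' `floor(hr / bin_width)`, capped at the top symbol for `hr >= hr_cap`.
#' With the defaults (5 bpm bins, 315 bpm cap) the alphabet is
#' `{0, 1, ..., 63}` — 64 states, so a symbol fits in 6 bits.
#'
#' A heart rate exactly on a bin edge falls in the upper bin (floor
#' semantics); values within floating-point error of an edge follow IEEE
#' floor, no epsilon adjustment is applied.
#'
#' @param hr numeric vector of heart rates in bpm; finite and non-negative.
#' @param hr_cap heart rate (bpm) at and above which the top symbol is
#'   emitted. Default 315.
#' @param bin_width width of each heart-rate state in bpm. Default 5.
#' @return integer vector of symbols in `0:(hr_cap %/% bin_width)`.
#' @examples
#' symbolize(c(60, 314.9, 315, 1000))  # 12, 62, 63, 63
#' @export
symbolize <- function(hr, hr_cap = 315, bin_width = 5) {
  if (length(hr) == 0L) return(integer(0))
  if (!is.numeric(hr)) stop("`hr` must be numeric", call. = FALSE)
  bad <- which(!is.finite(hr) | hr < 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid heart rate at beat index %d (0-based): %s bpm",
                 bad[1L] - 1L, format(hr[bad[1L]])), call. = FALSE)
  }
  s_max <- as.integer(hr_cap %/% bin_width)
  as.integer(pmin(floor(hr / bin_width), s_max))
}

#' Encode three successive symbols into a word value
#'
#' Packs a triple of 6-bit symbols into a single 18-bit integer:
#' `w = s2 * 2^12 + s1 * 2^6 + s0`, where `s2` is the oldest symbol. The
#' encoding is a bijection between symbol triples and `0:262143`
#' (`262143 = 63*4096 + 63*64 + 63`); [decode_word()] inverts it.
#'
#' @param s2,s1,s0 integer vectors of symbols in `0:63` (oldest first);
#'   recycled to a common length.
#' @return integer vector of word values in `0:262143`.
#' @examples
#' encode_word(0, 1, 3)     # 67
#' encode_word(63, 63, 63)  # 262143
#' @export
encode_word <- function(s2, s1, s0) {
  n <- max(length(s2), length(s1), length(s0))
  if (n == 0L) return(integer(0))
  s2 <- as.integer(rep_len(s2, n))
  s1 <- as.integer(rep_len(s1, n))
  s0 <- as.integer(rep_len(s0, n))
  for (s in list(s2, s1, s0)) {
    bad <- which(is.na(s) | s < 0L | s > 63L)
    if (length(bad) > 0L) {
      stop(sprintf("symbol out of range [0, 63] at position %d", bad[1L]),
           call. = FALSE)
    }
  }
  bitwShiftL(s2, 12L) + bitwShiftL(s1, 6L) + s0
}

#' Decode a word value back into its symbol triple
#'
#' @param w integer vector of word values in `0:262143`.
#' @return integer matrix with columns `s2`, `s1`, `s0` (oldest first).
#' @examples
#' decode_word(67)  # 0, 1, 3
#' @export
decode_word <- function(w) {
  w <- as.integer(w)
  bad <- which(is.na(w) | w < 0L | w > 262143L)
  if (length(bad) > 0L) {
    stop(sprintf("word value out of range [0, 262143] at position %d", bad[1L]),
         call. = FALSE)
  }
  cbind(s2 = bitwShiftR(w, 12L),
        s1 = bitwAnd(bitwShiftR(w, 6L), 63L),
        s0 = bitwAnd(w, 63L))
}

#' Construct a validated beat stream
#'
#' A beat stream holds the ordered RR intervals of one record, the derived
#' heart rates, and optional per-beat reference rhythm labels
#' (`"AF"` / `"NONAF"`). Beat indices are 0-based throughout the package;
#' RR intervals are in milliseconds, times in seconds.
#'
#' @param rr_ms numeric vector of RR intervals (ms), strictly positive.
#' @param labels optional character vector of per-beat reference labels,
#'   values `"AF"` or `"NONAF"`, same length as `rr_ms`.
#' @param record_id record identifier string.
#' @return an object of class `beat_stream`: a list with elements `record_id`,
#'   `rr` (ms), `hr` (bpm) and `labels` (or `NULL`).
#' @examples
#' bs <- beat_stream(c(800, 790, 810), labels = rep("NONAF", 3))
#' bs$hr
#' @export
beat_stream <- function(rr_ms, labels = NULL, record_id = "record") {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) == 0L) stop("beat stream must contain at least one beat", call. = FALSE)
  hr <- rr_to_hr(rr_ms)  # validates positivity/finiteness
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(rr_ms)) {
      stop(sprintf("labels length (%d) differs from rr length (%d)",
                   length(labels), length(rr_ms)), call. = FALSE)
    }
    bad <- which(!labels %in% c("AF", "NONAF"))
    if (length(bad) > 0L) {
      stop(sprintf("unknown rhythm label %s at beat index %d (0-based)",
                   dQuote(labels[bad[1L]]), bad[1L] - 1L), call. = FALSE)
    }
  }
  structure(list(record_id = as.character(record_id)[1L],
                 rr = rr_ms, hr = hr, labels = labels),
            class = "beat_stream")
}

#' @export
print.beat_stream <- function(x, ...) {
  cat(sprintf("<beat_stream> record %s: %d beats, HR %.1f-%.1f bpm%s\n",
              x$record_id, length(x$rr), min(x$hr), max(x$hr),
              if (is.null(x$labels)) "" else
                sprintf(", %d AF / %d non-AF labelled",
                        sum(x$labels == "AF"), sum(x$labels == "NONAF"))))
  invisible(x)
}

#' Symbolize a whole beat stream
#'
#' Vectorized composition of [rr_to_hr()], [symbolize()] and [encode_word()]:
#' yields the symbol sequence (one per beat) and the word sequence (one per
#' beat from the third beat on). Word `j` (0-based) encodes the symbols of
#' beats `j`, `j+1`, `j+2`, so `length(words) == length(symbols) - 2`.
#'
#' @param stream a [beat_stream()].
#' @param hr_cap,bin_width passed to [symbolize()].
#' @return list with integer vectors `symbols` and `words`.
#' @examples
#' symbolize_stream(beat_stream(rep(1000, 3)))  # symbols 12,12,12; word 49932
#' @export
symbolize_stream <- function(stream, hr_cap = 315, bin_width = 5) {
  stopifnot(inherits(stream, "beat_stream"))
  sy <- symbolize(stream$hr, hr_cap = hr_cap, bin_width = bin_width)
  n <- length(sy)
  words <- if (n < 3L) integer(0) else
    encode_word(sy[1:(n - 2L)], sy[2:(n - 1L)], sy[3:n])
  list(symbols = sy, words = words)
}
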