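#' Precompute the integer entropy lookup table
#'
#' For a sliding window of nominal size `N`, every word count `i` in
#' `0:N` corresponds to a probability `p_i = i/N`. The table stores
#' `floor((Cons / log2(N)) * (-p_i * log2(p_i)))` for each count, with the
#' entries at counts 0 and `N` fixed to 0 (`-p log2 p` is 0 at both ends).
#' Scaling by the integer constant `Cons` turns the per-count entropy terms
#' into integers, so the sliding-window entropy can be maintained with pure
#' integer addition and subtraction; the quantization error per entry is
#' below 1/`Cons` on the unscaled value.
#'
#' With the defaults `N = 127`, `Cons = 1e6` the first entry (count 1) is
#' 7874 and the entries at counts 63 and 64 are 71790 and 71291.
#'
#' @param N window size (number of words in the sliding window), integer
#'   `>= 2`. Default 127.
#' @param Cons integer scale constant converting entropy terms to integers.
#'   Default 1e6.
#' @return an object of class `pimap`: list with `N`, `Cons` and `values`,
#'   an integer vector of length `N + 1` where `values[i + 1]` is the table
#'   entry for count `i`.
#' @examples
#' pm <- build_pimap()
#' pm$values[c(1, 2, 64, 65, 128)]  # counts 0, 1, 63, 64, 127
#' @export
build_pimap <- function(N = 127L, Cons = 1000000L) {
  N <- as.integer(N); Cons <- as.integer(Cons)
  if (is.na(N) || N < 2L) stop("`N` must be an integer >= 2", call. = FALSE)
  if (is.na(Cons) || Cons < 1L) stop("`Cons` must be a positive integer", call. = FALSE)
  i <- seq_len(N - 1L)
  p <- i / N
  vals <- c(0L, as.integer(floor((Cons / log2(N)) * (-p * log2(p)))), 0L)
  structure(list(N = N, Cons = Cons, values = vals), class = "pimap")
}

#' @export
print.pimap <- function(x, ...) {
  cat(sprintf("<pimap> N = %d, Cons = %d, max entry %d at count %d\n",
              x$N, x$Cons, max(x$values), which.max(x$values) - 1L))
  invisible(x)
}

#' Write a pimap table to a plain-text integer list
#'
#' One entry per line, count order 0..N; a two-line header records N and Cons.
#'
#' @param pimap a [build_pimap()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pimap <- function(pimap, path) {
  stopifnot(inherits(pimap, "pimap"))
  writeLines(c(sprintf("# N=%d", pimap$N), sprintf("# Cons=%d", pimap$Cons),
               as.character(pimap$values)), path)
  invisible(path)
}

#' Direct coarse Shannon entropy of a word window
#'
#' Floating-point reference evaluation of the normalized entropy
#' \deqn{H'' = -\frac{k}{N \log_2 N} \sum_{i=1}^{k} p_i \log_2 p_i,}
#' where the sum runs over the `k` distinct words in the window,
#' `p_i = N_i / N` with `N_i` the count of word `i`, and `N` is the
#' *nominal* window size — the denominator stays fixed at `N` even when the
#' window holds fewer than `N` words, matching the recursive engine, whose
#' lookup table is indexed by raw counts. `H''` lies in `[0, 1]`: 0 when the
#' window holds a single repeated word, 1 when all `N` words are distinct.
#'
#' This function recomputes the entropy from scratch and serves as the
#' oracle against which the O(1)-per-beat recursion ([push_word()],
#' [entropy_stream()]) is validated; it applies no integer quantization.
#'
#' @param window integer vector of word values currently in the window
#'   (1 to `N` of them).
#' @param N nominal window size. Default 127.
#' @return entropy value in `[0, 1]`.
#' @examples
#' entropy_direct(rep(7L, 127))   # 0
#' entropy_direct(1:127)          # 1
#' @export
entropy_direct <- function(window, N = 127L) {
  if (length(window) == 0L) stop("window must contain at least one word", call. = FALSE)
  N <- as.integer(N)
  if (length(window) > N) stop("window larger than nominal size N", call. = FALSE)
  cnt <- tabulate(match(window, unique(window)))
  p <- cnt / N
  -(length(cnt) / (N * log2(N))) * sum(p * log2(p))
}

#' Create (or reset) the recursive entropy state
#'
#' The detector's rolling state: a circular buffer of the last `N` word
#' values, a dense count buffer over the full 0..262143 word space, the
#' number `k` of distinct words present, and the integer entropy accumulator
#' `acc` = sum of lookup-table entries at the live counts. Implemented as an
#' environment so that [push_word()] updates it in place, mirroring the
#' constant-memory embedded formulation.
#'
#' @param pimap a [build_pimap()] table.
#' @return an environment of class `entropy_state` with fields `window`,
#'   `pos`, `occ`, `counts`, `k`, `acc`, `n_seen` and the `pimap` itself.
#' @seealso [push_word()], [reset_state()]
#' @export
entropy_state <- function(pimap = build_pimap()) {
  stopifnot(inherits(pimap, "pimap"))
  st <- new.env(parent = emptyenv())
  st$pimap <- pimap
  reset_state(st)
  class(st) <- "entropy_state"
  st
}

#' Reset an entropy state to its initial (all-zero) condition
#'
#' All counts, the distinct-word tally `k`, the integer accumulator and the
#' window occupancy return to zero, as at detector start-up; pushing words
#' after a reset is indistinguishable from pushing them into a fresh state.
#'
#' @param state an [entropy_state()].
#' @return `state`, invisibly (modified in place).
#' @export
reset_state <- function(state) {
  N <- state$pimap$N
  state$window <- integer(N)
  state$pos <- 0L        # next write slot (0-based); oldest element when full
  state$occ <- 0L        # current occupancy, <= N
  state$counts <- integer(262144L)
  state$k <- 0L
  state$acc <- 0L
  state$n_seen <- 0L
  invisible(state)
}

#' @export
print.entropy_state <- function(x, ...) {
  cat(sprintf("<entropy_state> N = %d: %d/%d words, k = %d, acc = %d\n",
              x$pimap$N, x$occ, x$pimap$N, x$k, x$acc))
  invisible(x)
}

#' Push one word through the recursive entropy update
#'
#' Performs the O(1) sliding-window update. When the window is full the
#' oldest word slides out: its lookup-table term at the old count is
#' subtracted from the accumulator, the count is decremented, the term at
#' the new count added back, and `k` decremented if the count reached zero.
#' Then the new word slides in symmetrically (`k` incremented if the word is
#' new). The returned entropy is `k * acc / (N * Cons)` — one integer
#' multiply and one divide per beat; everything else is integer
#' add/subtract/compare plus table lookups.
#'
#' @param state an [entropy_state()] (updated in place).
#' @param w word value in `0:262143`.
#' @return the entropy value in `[0, 1]` after consuming `w`.
#' @examples
#' st <- entropy_state()
#' push_word(st, 67L)  # k = 1, acc = 7874 -> 7874 / 127e6
#' @export
push_word <- function(state, w) {
  w <- as.integer(w)
  if (is.na(w) || w < 0L || w > 262143L) {
    stop("word value out of range [0, 262143]", call. = FALSE)
  }
  pv <- state$pimap$values
  N <- state$pimap$N
  if (state$occ == N) {
    old <- state$window[state$pos + 1L]
    c_old <- state$counts[old + 1L]
    state$acc <- state$acc - pv[c_old + 1L]
    c_old <- c_old - 1L
    state$counts[old + 1L] <- c_old
    state$acc <- state$acc + pv[c_old + 1L]
    if (c_old == 0L) state$k <- state$k - 1L
  } else {
    state$occ <- state$occ + 1L
  }
  cw <- state$counts[w + 1L]
  if (cw == 0L) state$k <- state$k + 1L
  state$acc <- state$acc - pv[cw + 1L]
  cw <- cw + 1L
  state$counts[w + 1L] <- cw
  state$acc <- state$acc + pv[cw + 1L]
  state$window[state$pos + 1L] <- w
  state$pos <- (state$pos + 1L) %% N
  state$n_seen <- state$n_seen + 1L
  as.numeric(state$k) * state$acc / (as.numeric(N) * state$pimap$Cons)
}

#' Recursive entropy over a whole word sequence
#'
#' Runs the sliding-window recursion of [push_word()] over `words` in a
#' single pass and returns the entropy after each word. Identical output to
#' repeated [push_word()] calls on a fresh [entropy_state()], in one
#' tight loop.
#'
#' @param words integer vector of word values in `0:262143`.
#' @param pimap a [build_pimap()] table.
#' @return numeric vector of entropies, one per word.
#' @export
entropy_stream <- function(words, pimap = build_pimap()) {
  stopifnot(inherits(pimap, "pimap"))
  words <- as.integer(words)
  if (length(words) == 0L) return(numeric(0))
  if (anyNA(words) || any(words < 0L | words > 262143L)) {
    stop("word values out of range [0, 262143]", call. = FALSE)
  }
  pv <- pimap$values
  N <- pimap$N
  Cons <- as.numeric(pimap$Cons)
  counts <- integer(262144L)
  win <- integer(N)
  pos <- 0L; occ <- 0L; k <- 0L; acc <- 0L
  h <- numeric(length(words))
  for (j in seq_along(words)) {
    if (occ == N) {
      old <- win[pos + 1L]
      c_old <- counts[old + 1L]
      acc <- acc - pv[c_old + 1L]
      c_old <- c_old - 1L
      counts[old + 1L] <- c_old
      acc <- acc + pv[c_old + 1L]
      if (c_old == 0L) k <- k - 1L
    } else {
      occ <- occ + 1L
    }
    w <- words[j]
    cw <- counts[w + 1L]
    if (cw == 0L) k <- k + 1L
    acc <- acc - pv[cw + 1L]
    cw <- cw + 1L
    counts[w + 1L] <- cw
    acc <- acc + pv[cw + 1L]
    win[pos + 1L] <- w
    pos <- (pos + 1L) %% N
    h[j] <- as.numeric(k) * acc / (N * Cons)
  }
  h
}
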