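# Shared fixtures: all synthetic, built in code at test time.

# RR sequence whose symbol stream guarantees that every 127 consecutive
# words are pairwise distinct (maximal-entropy window, h = 1). Built by
# rejection: a candidate symbol is redrawn if the word it completes is
# already among the last 126 words.
make_max_entropy_rr <- function(n, seed = 99) {
  set.seed(seed)
  s <- integer(n)
  s[1:2] <- sample(0:63, 2, replace = TRUE)
  recent <- integer(0)
  for (i in 3:n) {
    repeat {
      cand <- sample(0:63, 1)
      w <- s[i - 2] * 4096L + s[i - 1] * 64L + cand
      if (!w %in% utils::tail(recent, 126L)) break
    }
    s[i] <- cand
    recent <- c(recent, s[i - 2] * 4096L + s[i - 1] * 64L + s[i])
  }
  60000 / (5 * s + 2.5)  # hr in the middle of each symbol bin
}

# Independent sliding-window entropy oracle: recomputes the coarse Shannon
# entropy from a fresh count table at each position (no recursion, no
# integer quantization). `words` may be any integers.
direct_entropy_trace <- function(words, N = 127L) {
  alpha <- unique(words)
  wid <- match(words, alpha)
  vapply(seq_along(words), function(j) {
    cnt <- tabulate(wid[max(1L, j - N + 1L):j], nbins = length(alpha))
    cnt <- cnt[cnt > 0L]
    p <- cnt / N
    -(length(cnt) / (N * log2(N))) * sum(p * log2(p))
  }, numeric(1))
}

# Pairwise-concordance (Mann-Whitney) AUC oracle.
concordance_auc <- function(h, labels) {
  h_af <- h[labels == "AF"]
  h_non <- h[labels == "NONAF"]
  cmp <- outer(h_af, h_non, ">") + 0.5 * outer(h_af, h_non, "==")
  mean(cmp)
}
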