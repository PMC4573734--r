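test_that("pimap table matches its closed form and fixed endpoints", {
  pm <- build_pimap(127L, 1000000L)
  expect_identical(pm$values[0 + 1], 0L)
  expect_identical(pm$values[1 + 1], 7874L)
  expect_identical(pm$values[63 + 1], 71790L)
  expect_identical(pm$values[64 + 1], 71291L)
  expect_identical(pm$values[127 + 1], 0L)
  expect_true(all(pm$values >= 0L))
  i <- 1:126
  expect_identical(pm$values[i + 1],
                   as.integer(floor(1e6 / log2(127) * (-(i / 127) * log2(i / 127)))))
  # accumulator headroom: worst case fits comfortably in a 32-bit integer
  expect_lt(127 * max(as.numeric(pm$values)), 2^31)
  expect_error(build_pimap(1L), "N")
})

test_that("direct entropy hits its closed-form extremes", {
  expect_equal(entropy_direct(rep(5L, 127)), 0)
  expect_equal(entropy_direct(0:126), 1)
  # two-word window, counts 64 + 63
  p1 <- 64 / 127; p2 <- 63 / 127
  expected <- -(2 / (127 * log2(127))) * (p1 * log2(p1) + p2 * log2(p2))
  expect_equal(entropy_direct(c(rep(1L, 64), rep(2L, 63))), expected)
  expect_equal(expected, 0.0022533, tolerance = 1e-4)
  expect_error(entropy_direct(integer(0)), "at least one")
  expect_error(entropy_direct(rep(1L, 128)), "larger than")
})

test_that("a single pushed word yields the first lookup-table term", {
  st <- entropy_state()
  h <- push_word(st, 4242L)
  expect_identical(st$k, 1L)
  expect_identical(st$acc, 7874L)
  expect_equal(h, 7874 / 127e6)
})

test_that("a saturated single-word window has zero entropy", {
  st <- entropy_state()
  for (i in 1:127) h <- push_word(st, 7L)
  expect_identical(st$counts[7 + 1], 127L)
  expect_identical(st$k, 1L)
  expect_equal(h, 0)
  # and it stays zero as the same word keeps sliding
  expect_equal(push_word(st, 7L), 0)
})

test_that("recursive update matches the direct oracle over random streams", {
  pm <- build_pimap()
  set.seed(2024)
  worst <- 0
  for (rep in 1:60) {
    m <- sample(1:300, 1)
    alpha <- sample(0:262143, m)
    words <- sample(alpha, 500, replace = TRUE)
    h_rec <- entropy_stream(words, pm)
    h_dir <- direct_entropy_trace(words)
    worst <- max(worst, max(abs(h_rec - h_dir)))
  }
  expect_lt(worst, 2e-4)  # integer quantization bound k^2/(N*Cons)
})

test_that("entropy_stream and repeated push_word agree exactly", {
  pm <- build_pimap()
  set.seed(5)
  words <- sample(0:500, 400, replace = TRUE)
  st <- entropy_state(pm)
  h_push <- vapply(words, function(w) push_word(st, w), numeric(1))
  expect_identical(entropy_stream(words, pm), h_push)
})

test_that("entropy depends only on the window multiset", {
  pm <- build_pimap()
  set.seed(8)
  win <- sample(0:50, 127, replace = TRUE)
  h_vals <- vapply(1:20, function(i) {
    shuffled <- sample(win)
    utils::tail(entropy_stream(shuffled, pm), 1)
  }, numeric(1))
  expect_equal(diff(range(h_vals)), 0)
  expect_equal(h_vals[1], utils::tail(entropy_stream(win, pm), 1))
})

test_that("state bookkeeping survives long push sequences", {
  pm <- build_pimap()
  set.seed(31)
  st <- entropy_state(pm)
  words <- sample(0:40, 500, replace = TRUE)
  for (j in seq_along(words)) {
    push_word(st, words[j])
    if (j %% 50 == 0) {
      live <- words[max(1, j - 126):j]
      tab <- table(live)
      expect_identical(sum(st$counts), min(j, 127L))        # occupancy
      expect_identical(st$k, length(tab))                   # distinct words
      expect_identical(st$counts[as.integer(names(tab)) + 1],
                       as.integer(tab))                     # per-word counts
      expect_identical(st$acc,                              # accumulator
                       sum(pm$values[as.integer(tab) + 1]))
    }
  }
})

test_that("entropy stays in [0, 1]; zero iff one distinct word", {
  pm <- build_pimap()
  set.seed(77)
  # h = 0 exactly when the (saturated) window holds one repeated word:
  # only then is every live count 0 or 127, both zero table entries.
  for (m in c(1, 2, 10, 262144)) {
    words <- sample(0:(m - 1), 300, replace = TRUE)
    h <- entropy_stream(words, pm)
    expect_true(all(h >= 0 & h <= 1))
    sat <- seq_along(words) >= 127L
    one_distinct <- vapply(seq_along(words), function(j)
      length(unique(words[max(1, j - 126):j])) == 1L, logical(1))
    expect_identical(h == 0, one_distinct & sat)
  }
})

test_that("reset restores the all-zero start state exactly", {
  pm <- build_pimap()
  set.seed(3)
  words1 <- sample(0:99, 300, replace = TRUE)
  words2 <- sample(0:99, 300, replace = TRUE)
  st <- entropy_state(pm)
  for (w in words1) push_word(st, w)
  reset_state(st)
  expect_identical(st$occ, 0L)
  expect_identical(st$k, 0L)
  expect_identical(st$acc, 0L)
  expect_true(all(st$counts == 0L))
  h_after_reset <- vapply(words2, function(w) push_word(st, w), numeric(1))
  expect_identical(h_after_reset, entropy_stream(words2, pm))
})
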