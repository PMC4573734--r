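test_that("confusion counts match enumeration and a brute-force recount", {
  cm <- confusion(rep("AF", 10), rep("AF", 10))
  expect_identical(cm$tp, 10L)
  expect_identical(cm$tn + cm$fp + cm$fn, 0L)

  cm <- confusion(c("AF", "NONAF", "AF", "NONAF"),
                  c("AF", "AF", "NONAF", "NONAF"))
  expect_identical(unlist(cm[c("tp", "fn", "fp", "tn")]),
                   c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  set.seed(40)
  pred <- sample(c("AF", "NONAF", "WARMUP"), 1000, replace = TRUE)
  ref <- sample(c("AF", "NONAF"), 1000, replace = TRUE)
  cm <- confusion(pred, ref)
  keep <- pred != "WARMUP"
  expect_identical(cm$tp, sum(pred[keep] == "AF" & ref[keep] == "AF"))
  expect_identical(cm$tn, sum(pred[keep] == "NONAF" & ref[keep] == "NONAF"))
  expect_identical(cm$fp, sum(pred[keep] == "AF" & ref[keep] == "NONAF"))
  expect_identical(cm$fn, sum(pred[keep] == "NONAF" & ref[keep] == "AF"))
  expect_identical(cm$total, sum(keep))
  expect_error(confusion(pred, ref[-1]), "lengths differ")
})

test_that("metrics follow their definitions, NA on empty denominators", {
  m <- classification_metrics(
    structure(list(tp = 3L, fn = 1L, tn = 0L, fp = 0L, total = 4L),
              class = "confusion_counts"))
  expect_equal(m[["se"]], 0.75)
  expect_true(is.na(m[["sp"]]))
  expect_equal(m[["ppv"]], 1)
  expect_equal(m[["acc"]], 0.75)

  m <- classification_metrics(
    structure(list(tp = 50L, fn = 0L, tn = 50L, fp = 0L, total = 100L),
              class = "confusion_counts"))
  expect_equal(unname(m), c(1, 1, 1, 1))

  # a record with no AF reference beats: Se and PPV not applicable
  pred <- rep("NONAF", 20)
  ref <- rep("NONAF", 20)
  m <- classification_metrics(confusion(pred, ref))
  expect_true(is.na(m[["se"]]))
  expect_true(is.na(m[["ppv"]]))
  expect_equal(m[["sp"]], 1)
  expect_equal(m[["acc"]], 1)
})

test_that("ROC sweep is exact on separable and uninformative scores", {
  h <- c(rep(0.9, 40), rep(0.1, 60))
  lab <- c(rep("AF", 40), rep("NONAF", 60))
  r <- roc_sweep(h, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$best_distance, 0)
  expect_true(r$best_threshold > 0.1 && r$best_threshold <= 0.9)
  at <- r$points[r$points$threshold == 0.5, ]
  expect_equal(at$se, 1); expect_equal(at$sp, 1)

  # constant score: degenerate two-point curve, AUC 1/2
  r0 <- roc_sweep(rep(0.4, 100), lab)
  expect_equal(r0$auc, 0.5)

  expect_error(roc_sweep(runif(5), rep("AF", 5)), "both AF and NONAF")
  expect_error(roc_sweep(c(0.5, 1.2), c("AF", "NONAF")), "\\[0, 1\\]")
})

test_that("trapezoidal AUC agrees with pairwise concordance", {
  set.seed(300)
  n <- 200
  lab <- sample(c("AF", "NONAF"), n, replace = TRUE, prob = c(0.45, 0.55))
  h <- ifelse(lab == "AF", rbeta(n, 4, 2), rbeta(n, 2, 4))
  r <- roc_sweep(h, lab)
  expect_equal(r$auc, concordance_auc(h, lab), tolerance = 0.01)
})

test_that("sweep is monotone at every grid point and ACC is consistent", {
  set.seed(301)
  n <- 500
  lab <- sample(c("AF", "NONAF"), n, replace = TRUE)
  h <- ifelse(lab == "AF", rbeta(n, 3, 2), rbeta(n, 2, 3))
  r <- roc_sweep(h, lab)
  expect_true(all(diff(r$points$se) <= 0))
  expect_true(all(diff(r$points$one_minus_sp) <= 0))
  n_af <- sum(lab == "AF"); n_non <- n - n_af
  acc_check <- (r$points$se * n_af + r$points$sp * n_non) / n
  expect_equal(r$points$acc, acc_check)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(302)
  n <- 300
  lab <- sample(c("AF", "NONAF"), n, replace = TRUE)
  h <- ifelse(lab == "AF", rbeta(n, 4, 2), rbeta(n, 2, 4))
  r1 <- roc_sweep(h, lab)
  r2 <- roc_sweep(h^2, lab)
  expect_equal(r1$auc, r2$auc, tolerance = 0.002)  # grid discretization only
})

test_that("best threshold is the smallest among distance ties", {
  h <- c(rep(0.8, 10), rep(0.2, 10))
  lab <- rep(c("AF", "NONAF"), each = 10)
  r <- roc_sweep(h, lab)
  # every threshold in (0.2, 0.8] is perfect; the sweep reports the smallest
  expect_equal(r$best_threshold, 0.201)
})
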