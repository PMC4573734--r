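#' Beat-level confusion counts
#'
#' Tallies predicted against reference rhythm labels per beat. AF is the
#' positive class: AF/AF is a true positive, NONAF/NONAF a true negative,
#' a predicted AF on a NONAF reference a false positive, and a missed AF a
#' false negative. Beats whose prediction is `"WARMUP"` or `NA` are
#' excluded from the tally (their reference labels are ignored too).
#'
#' @param predicted character vector of `"AF"` / `"NONAF"` / `"WARMUP"`
#'   predictions, or a `beat_decisions` data frame from [detect_stream()].
#' @param reference character vector of `"AF"` / `"NONAF"` reference labels,
#'   same length as `predicted`.
#' @return an object of class `confusion_counts`: list with integer
#'   `tp`, `tn`, `fp`, `fn` and `total`.
#' @examples
#' confusion(c("AF", "NONAF", "AF", "NONAF"), c("AF", "AF", "NONAF", "NONAF"))
#' @export
confusion <- function(predicted, reference) {
  if (inherits(predicted, "beat_decisions") || is.data.frame(predicted)) {
    predicted <- predicted$label
  }
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (length(predicted) != length(reference)) {
    stop(sprintf("predicted (%d) and reference (%d) lengths differ",
                 length(predicted), length(reference)), call. = FALSE)
  }
  keep <- !is.na(predicted) & predicted != "WARMUP"
  predicted <- predicted[keep]; reference <- reference[keep]
  if (anyNA(reference)) stop("reference labels contain NA on evaluated beats", call. = FALSE)
  bad <- which(!reference %in% c("AF", "NONAF"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown reference label %s", dQuote(reference[bad[1L]])), call. = FALSE)
  }
  structure(list(
    tp = sum(predicted == "AF" & reference == "AF"),
    tn = sum(predicted == "NONAF" & reference == "NONAF"),
    fp = sum(predicted == "AF" & reference == "NONAF"),
    fn = sum(predicted == "NONAF" & reference == "AF"),
    total = length(predicted)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  FP %d  TN %d (%d beats)\n",
              x$tp, x$fn, x$fp, x$tn, x$total))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive
#' predictive value `PPV = TP/(TP+FP)` and accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`. A metric whose denominator is zero is
#' reported as `NA` (not applicable — e.g. Se on a record with no AF
#' reference beats), never as 0.
#'
#' @param counts a [confusion()] result.
#' @return named numeric vector with elements `se`, `sp`, `ppv`, `acc`.
#' @examples
#' classification_metrics(confusion(rep("AF", 4), c("AF", "AF", "AF", "NONAF")))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0L) stop("no evaluated beats", call. = FALSE)
  safe_div <- function(num, den) if (den == 0L) NA_real_ else num / den
  c(se  = safe_div(counts$tp, counts$tp + counts$fn),
    sp  = safe_div(counts$tn, counts$tn + counts$fp),
    ppv = safe_div(counts$tp, counts$tp + counts$fp),
    acc = safe_div(counts$tp + counts$tn, counts$total))
}

#' ROC threshold sweep with AUC and optimal operating point
#'
#' Evaluates the threshold rule `AF iff h >= t` for every threshold on the
#' grid `seq(lo, hi, by = step)` (default 0.0 to 1.0 in increments of
#' 0.001), computing Se, Sp, 1-Sp, PPV and ACC at each point. The area
#' under the ROC curve is obtained by trapezoidal integration of Se over
#' 1-Sp after sorting, with the `(0, 0)` and `(1, 1)` corners appended if
#' the grid does not reach them. The optimal operating point is the
#' threshold whose ROC point lies closest (Euclidean distance) to the ideal
#' classifier `(0, 1)`; among ties the smallest threshold is reported.
#'
#' @param h numeric vector of per-beat entropy values in `[0, 1]`.
#' @param reference per-beat reference labels `"AF"` / `"NONAF"`. Both
#'   classes must be present.
#' @param lo,hi,step threshold grid. Defaults 0, 1, 0.001.
#' @return an object of class `roc_curve`: list with `points` (data frame
#'   with columns `threshold`, `se`, `sp`, `one_minus_sp`, `ppv`, `acc`),
#'   `auc`, `best_threshold` and `best_distance`.
#' @examples
#' set.seed(1)
#' h <- c(runif(50, 0.7, 1), runif(50, 0, 0.3))
#' roc_sweep(h, rep(c("AF", "NONAF"), each = 50))$auc
#' @export
roc_sweep <- function(h, reference, lo = 0, hi = 1, step = 0.001) {
  h <- as.numeric(h); reference <- as.character(reference)
  if (length(h) != length(reference)) {
    stop("`h` and `reference` lengths differ", call. = FALSE)
  }
  if (anyNA(h) || any(h < 0 | h > 1)) {
    stop("`h` must be finite values in [0, 1]", call. = FALSE)
  }
  is_af <- reference == "AF"
  n_af <- sum(is_af); n_non <- sum(!is_af)
  if (n_af == 0L || n_non == 0L) {
    stop("ROC undefined: reference must contain both AF and NONAF beats",
         call. = FALSE)
  }
  thr <- seq(lo, hi, by = step)
  h_af <- sort(h[is_af]); h_non <- sort(h[!is_af])
  # count of values >= t via binary search on the sorted vectors
  tp <- n_af - findInterval(thr, h_af, left.open = TRUE)
  fp <- n_non - findInterval(thr, h_non, left.open = TRUE)
  fn <- n_af - tp; tn <- n_non - fp
  se <- tp / n_af
  sp <- tn / n_non
  ppv <- ifelse(tp + fp == 0L, NA_real_, tp / (tp + fp))
  acc <- (tp + tn) / (n_af + n_non)
  pts <- data.frame(threshold = thr, se = se, sp = sp,
                    one_minus_sp = 1 - sp, ppv = ppv, acc = acc)
  # trapezoidal AUC over (1-sp, se), corners appended if absent
  x <- pts$one_minus_sp; y <- pts$se
  if (!any(x == 0 & y == 0)) { x <- c(x, 0); y <- c(y, 0) }
  if (!any(x == 1 & y == 1)) { x <- c(x, 1); y <- c(y, 1) }
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  auc <- sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
  dist <- sqrt(pts$one_minus_sp^2 + (1 - pts$se)^2)
  best <- which(dist == min(dist))[1L]  # smallest threshold among ties
  structure(list(points = pts, auc = auc,
                 best_threshold = pts$threshold[best],
                 best_distance = dist[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d thresholds, AUC %.4f; best threshold %.3f (distance %.4f to ideal)\n",
    nrow(x$points), x$auc, x$best_threshold, x$best_distance))
  invisible(x)
}
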