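#' Per-group distribution of composite FCD scores
#'
#' Container for the counts of composite scores 0..6 within one surgical
#' group (dehiscent "FCD" group or intact "control" group).
#'
#' @param x either a vector of per-ear composite scores in 0..6, or a
#'   length-7 vector of counts over scores 0..6 (use `counts = TRUE`).
#' @param group group label, conventionally `"FCD"` or `"control"`.
#' @param counts if `TRUE`, `x` is already a count vector over 0..6.
#' @return object of class `"score_dist"`: list with `group`, `counts`
#'   (named integer vector over `"0"`..`"6"`) and `n`.
#' @export
score_distribution <- function(x, group = "FCD", counts = FALSE) {
  if (counts) {
    if (length(x) != 7L || any(x < 0) || any(x != floor(x))) {
      fcd_stop("count form requires 7 non-negative integer counts (scores 0..6)")
    }
    cts <- as.integer(x)
  } else {
    if (length(x) == 0L || anyNA(x) || any(x < 0) || any(x > 6) ||
        any(x != floor(x))) {
      fcd_stop("'x' must contain composite scores in 0..6")
    }
    cts <- as.integer(tabulate(x + 1L, nbins = 7L))
  }
  if (sum(cts) == 0L) fcd_stop("score distribution must contain at least one ear")
  names(cts) <- as.character(0:6)
  structure(list(group = group, counts = cts, n = sum(cts)),
            class = "score_dist")
}

#' @export
print.score_dist <- function(x, ...) {
  cat(sprintf("FCD score distribution, group '%s' (n = %d)\n", x$group, x$n))
  print(x$counts)
  invisible(x)
}

cum_below <- function(dist, cutoff) {
  if (cutoff <= 0L) 0L else sum(dist$counts[seq_len(min(cutoff, 7L))])
}

#' Confusion counts at a strict score cutoff
#'
#' With dehiscent as the positive class, an ear is test-positive when its
#' composite score is strictly below the cutoff. True positives are
#' dehiscent ears below the cutoff; true negatives intact ears at or
#' above it.
#'
#' @param dist_pos `score_dist` of the surgically dehiscent group.
#' @param dist_neg `score_dist` of the surgically intact group.
#' @param cutoff single integer in 0..7.
#' @return object of class `"fcd_confusion"`: list with `tp`, `fp`,
#'   `tn`, `fn`, `cutoff`, `positive`.
#' @export
confusion_at_cutoff <- function(dist_pos, dist_neg, cutoff) {
  stopifnot(inherits(dist_pos, "score_dist"), inherits(dist_neg, "score_dist"))
  cutoff <- check_cutoff(cutoff)
  tp <- cum_below(dist_pos, cutoff)
  fp <- cum_below(dist_neg, cutoff)
  structure(list(tp = tp, fn = dist_pos$n - tp,
                 fp = fp, tn = dist_neg$n - fp,
                 cutoff = cutoff, positive = "dehiscent"),
            class = "fcd_confusion")
}

#' @export
print.fcd_confusion <- function(x, ...) {
  cat(sprintf("Confusion at cutoff < %d (positive = %s)\n", x$cutoff, x$positive))
  cat(sprintf("  tp = %d  fn = %d  fp = %d  tn = %d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and Youden's index per cutoff
#'
#' One row per strict cutoff `< k`, k = 0..6, under the dehiscent-positive
#' convention (`sensitivity` = fraction of dehiscent ears with score
#' below k). Because published tables of this design sometimes label the
#' columns under the opposite (intact-positive) orientation, the swapped
#' rendering is included as `sensitivity_intact_pos` /
#' `specificity_intact_pos`; Youden's index is orientation-invariant.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs integer vector of strict cutoffs to tabulate.
#' @return data.frame with columns `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `sensitivity_intact_pos`,
#'   `specificity_intact_pos`.
#' @export
metrics_table <- function(dist_pos, dist_neg, cutoffs = 0:6) {
  rows <- lapply(cutoffs, function(k) {
    cf <- confusion_at_cutoff(dist_pos, dist_neg, k)
    sens <- cf$tp / dist_pos$n
    spec <- cf$tn / dist_neg$n
    data.frame(cutoff = k, sensitivity = sens, specificity = spec,
               youden = sens + spec - 1,
               sensitivity_intact_pos = spec, specificity_intact_pos = sens)
  })
  do.call(rbind, rows)
}

#' ROC points for an ordinal score
#'
#' Operating points for strict cutoffs 0..7, anchored at (0, 0) and
#' (1, 1), ordered by false-positive rate then true-positive rate. Both
#' coordinates are non-decreasing along the list (a monotone staircase).
#'
#' @inheritParams confusion_at_cutoff
#' @return data.frame with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(dist_pos, dist_neg) {
  pts <- do.call(rbind, lapply(0:7, function(k) {
    cf <- confusion_at_cutoff(dist_pos, dist_neg, k)
    data.frame(cutoff = k, fpr = cf$fp / dist_neg$n, tpr = cf$tp / dist_pos$n)
  }))
  pts[order(pts$fpr, pts$tpr), , drop = FALSE]
}

#' Area under the ROC curve for an ordinal score
#'
#' Computed two ways and asserted equal to 1e-10: (a) trapezoidal
#' integration of [roc_points()]; (b) the tie-corrected rank form
#' \eqn{P(S_{pos} < S_{neg}) + \tfrac12 P(S_{pos} = S_{neg})} over all
#' \eqn{n_{pos} \times n_{neg}} ear pairs (lower score indicates the
#' dehiscent, positive class).
#'
#' @inheritParams confusion_at_cutoff
#' @return numeric AUC in \eqn{[0, 1]}, with attributes `concordant`,
#'   `ties` and `pairs` giving the exact pair counts behind the rank
#'   form.
#' @export
auc_ordinal <- function(dist_pos, dist_neg) {
  stopifnot(inherits(dist_pos, "score_dist"), inherits(dist_neg, "score_dist"))
  if (dist_pos$n == 0L || dist_neg$n == 0L) {
    fcd_stop("AUC undefined: a group is empty")
  }
  f <- as.numeric(dist_pos$counts)
  g <- as.numeric(dist_neg$counts)
  # Pairs where the dehiscent ear scores strictly lower, plus half-ties.
  g_above <- rev(cumsum(rev(g))) - g  # intact ears with score > s
  concordant <- sum(f * g_above)
  ties <- sum(f * g)
  pairs <- dist_pos$n * dist_neg$n
  auc_rank <- (concordant + ties / 2) / pairs

  pts <- roc_points(dist_pos, dist_neg)
  auc_trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                     utils::tail(pts$tpr, -1)) / 2)
  if (abs(auc_rank - auc_trap) > 1e-10) {
    fcd_stop("internal error: trapezoid and rank AUC disagree")
  }
  structure(auc_rank, concordant = concordant, ties = ties, pairs = pairs)
}

#' Optimal strict cutoff by Youden's index
#'
#' Maximizes Youden's index over the tabulated cutoffs; ties are broken
#' toward the cutoff with higher specificity, then the lower cutoff.
#'
#' @param rows data.frame from [metrics_table()].
#' @return single integer cutoff.
#' @export
optimal_cutoff <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    fcd_stop("'rows' must be a non-empty metrics table")
  }
  ord <- order(-rows$youden, -rows$specificity, rows$cutoff)
  as.integer(rows$cutoff[ord[1L]])
}

#' Predictive values and overall accuracy for a confusion table
#'
#' PPV, NPV, false-negative rate, false-positive rate and accuracy under
#' the canonical dehiscent-positive orientation, with the swapped
#' (intact-positive) rendering reported alongside. Metrics with a zero
#' denominator are returned as `NA` and listed in `undefined`.
#'
#' @param conf `"fcd_confusion"` object.
#' @param auc optional AUC value to carry in the summary.
#' @return object of class `"fcd_summary"`: list with `ppv`, `npv`,
#'   `fnr`, `fpr`, `accuracy`, `auc`, `swapped` (same metrics under
#'   intact-positive), `undefined` (character vector of NA metrics).
#' @export
diagnostic_summary <- function(conf, auc = NULL) {
  stopifnot(inherits(conf, "fcd_confusion"))
  one <- function(tp, fp, tn, fn) {
    m <- list(ppv = safe_ratio(tp, tp + fp), npv = safe_ratio(tn, tn + fn),
              fnr = safe_ratio(fn, fn + tp), fpr = safe_ratio(fp, fp + tn),
              accuracy = safe_ratio(tp + tn, tp + tn + fp + fn))
    m
  }
  main <- one(conf$tp, conf$fp, conf$tn, conf$fn)
  swapped <- one(conf$tn, conf$fn, conf$tp, conf$fp)
  res <- c(main, list(auc = if (is.null(auc)) NA_real_ else as.numeric(auc),
                      swapped = swapped,
                      undefined = names(main)[vapply(main, is.na, logical(1))],
                      cutoff = conf$cutoff))
  class(res) <- "fcd_summary"
  res
}

#' @export
print.fcd_summary <- function(x, ...) {
  cat(sprintf("Diagnostic summary at cutoff < %d (positive = dehiscent)\n",
              x$cutoff))
  for (m in c("ppv", "npv", "fnr", "fpr", "accuracy")) {
    cat(sprintf("  %-8s %s   [intact-positive: %s]\n", toupper(m),
                fmt_stat(x[[m]]), fmt_stat(x$swapped[[m]])))
  }
  if (!is.na(x$auc)) cat(sprintf("  AUC      %s\n", fmt_stat(x$auc)))
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
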