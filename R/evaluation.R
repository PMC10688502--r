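#' Confusion counts of a ranked prediction
#'
#' Predicted proteins are the positives; essential proteins inside the
#' network universe are the condition positives. Essentials outside the
#' universe are ignored (with a message reporting the count).
#'
#' @param prediction a `ranked_prediction` or character vector of predicted
#'   protein IDs.
#' @param essentials character vector of gold-standard essential proteins.
#' @param universe character vector of all network proteins.
#' @return An object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(prediction, essentials, universe) {
  pred <- prediction_ids(prediction)
  stopifnot(all(pred %in% universe))
  outside <- setdiff(essentials, universe)
  if (length(outside))
    message(sprintf("confusion: %d essential protein(s) outside the network ignored",
                    length(outside)))
  ess <- intersect(essentials, universe)
  if (!length(ess))
    warning("confusion: no essential protein in the universe; measures degenerate")
  tp <- length(intersect(pred, ess))
  fp <- length(pred) - tp
  fn <- length(ess) - tp
  tn <- length(universe) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

prediction_ids <- function(prediction) {
  if (inherits(prediction, "ranked_prediction")) prediction$protein
  else as.character(prediction)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Statistical measures from confusion counts
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, positive
#' and negative predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' F-measure (harmonic mean of SN and PPV) and accuracy
#' `ACC = (TP+TN)/total`. Any 0/0 ratio is defined as 0.
#'
#' @param counts a [confusion()] result.
#' @return Named list of class `sesn_measures` with `sn`, `sp`, `ppv`,
#'   `npv`, `f`, `acc`.
#' @export
measures <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(a, b) if (b == 0) 0 else a / b
  sn <- ratio(counts$tp, counts$tp + counts$fn)
  sp <- ratio(counts$tn, counts$tn + counts$fp)
  ppv <- ratio(counts$tp, counts$tp + counts$fp)
  npv <- ratio(counts$tn, counts$tn + counts$fn)
  f <- ratio(2 * sn * ppv, sn + ppv)
  acc <- ratio(counts$tp + counts$tn,
               counts$tp + counts$fp + counts$tn + counts$fn)
  structure(list(sn = sn, sp = sp, ppv = ppv, npv = npv, f = f, acc = acc),
            class = "sesn_measures")
}

#' @export
print.sesn_measures <- function(x, ...) {
  cat(sprintf("<measures> SN=%.4f SP=%.4f PPV=%.4f NPV=%.4f F=%.4f ACC=%.4f\n",
              x$sn, x$sp, x$ppv, x$npv, x$f, x$acc))
  invisible(x)
}

#' Jackknife curve of a ranked prediction
#'
#' Cumulative number of true essential proteins among the top-r ranked
#' predictions, for r = 1..n. The curve is non-decreasing with unit
#' increments and ends at the prediction's TP count.
#'
#' @inheritParams confusion
#' @return Integer vector of cumulative true-positive counts, one entry per
#'   rank.
#' @export
jackknife <- function(prediction, essentials) {
  pred <- prediction_ids(prediction)
  cumsum(as.integer(pred %in% essentials))
}

#' Write a jackknife curve as TSV
#'
#' @param curve a [jackknife()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jackknife <- function(curve, path) {
  utils::write.table(
    data.frame(rank = seq_along(curve), cumulative_tp = curve),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
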