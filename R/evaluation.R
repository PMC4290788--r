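# Evaluation against gold-standard subtype labels: one-vs-rest confusion
# counts per subtype, precision/recall/F1, and micro-averaging (counts are
# pooled across subtypes before computing the ratios).

# Accept either a classification data frame (pmid + '|'-joined labels) or a
# named list pmid -> character label vector.
as_label_map <- function(predicted) {
  if (is.data.frame(predicted)) return(labels_by_pmid(predicted))
  if (is.list(predicted)) return(predicted)
  stop("`predicted` must be a classification data frame or a named list of label vectors")
}

#' One-vs-rest confusion counts for a subtype
#'
#' The evaluation universe is the set of pmids in the gold standard;
#' documents absent from the predictions count as negative predictions, and
#' `TC`/`NON` predictions are negative for every subtype. Documents with
#' multiple labels are evaluated separately per label.
#'
#' @param predicted Classification data frame (columns `pmid`, `labels`) or
#'   named list mapping pmid to a character vector of labels.
#' @param gold A `gold_labels` object from [read_gold()], or a named list
#'   pmid -> subtype codes.
#' @param subtype Canonical subtype code.
#'
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(predicted, gold, subtype) {
  if (!subtype %in% subtype_codes()) stop("unknown subtype code: ", subtype)
  pred <- as_label_map(predicted)
  pmids <- names(gold)
  gold_pos <- vapply(pmids, function(p) subtype %in% gold[[p]], logical(1))
  pred_pos <- vapply(pmids, function(p) subtype %in% pred[[p]], logical(1))
  c(TP = sum(gold_pos & pred_pos),
    FP = sum(!gold_pos & pred_pos),
    FN = sum(gold_pos & !pred_pos),
    TN = sum(!gold_pos & !pred_pos))
}

#' Precision, recall and F1 from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); any 0/0 is defined as 0.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Named numeric vector `c(P, R, F1)`.
#' @export
#' @examples
#' prf(641, 14, 186)  # P 0.979, R 0.775, F1 0.865
prf <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F1 = f1)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN across subtypes before applying [prf()].
#'
#' @param per_subtype_counts Named list (or list of vectors) of per-subtype
#'   counts, each with components `TP`, `FP`, `FN` (a `TN` component is
#'   allowed and ignored for the ratios).
#' @return Named numeric vector `c(P, R, F1)`.
#' @export
micro_average <- function(per_subtype_counts) {
  if (!length(per_subtype_counts)) stop("need at least one subtype's counts")
  tp <- sum(vapply(per_subtype_counts, function(x) x[["TP"]], 0))
  fp <- sum(vapply(per_subtype_counts, function(x) x[["FP"]], 0))
  fn <- sum(vapply(per_subtype_counts, function(x) x[["FN"]], 0))
  prf(tp, fp, fn)
}

#' Evaluate predicted subtype labels against a gold standard
#'
#' @inheritParams confusion_counts
#' @param dtc_as_ftc Optional character vector of pmids whose gold label sets
#'   should additionally be treated as containing FTC. This reproduces
#'   re-crediting, as true positives, FTC predictions on differentiated
#'   thyroid cancer articles that the gold standard annotated only as PTC.
#'
#' @return Object of class `evaluation_report`: a data frame with one row per
#'   subtype plus a `Micro` row, columns `subtype`, `TP`, `TN`, `FN`, `FP`,
#'   `P`, `R`, `F1`.
#' @export
evaluate <- function(predicted, gold, dtc_as_ftc = NULL) {
  gold <- unclass(gold)
  if (!is.null(dtc_as_ftc)) {
    for (p in intersect(dtc_as_ftc, names(gold))) {
      gold[[p]] <- sort(unique(c(gold[[p]], "FTC")))
    }
  }
  rows <- list()
  counts <- list()
  for (j in subtype_codes()) {
    cc <- confusion_counts(predicted, gold, j)
    counts[[j]] <- cc
    m <- prf(cc[["TP"]], cc[["FP"]], cc[["FN"]])
    rows[[j]] <- data.frame(subtype = j, TP = cc[["TP"]], TN = cc[["TN"]],
                            FN = cc[["FN"]], FP = cc[["FP"]],
                            P = m[["P"]], R = m[["R"]], F1 = m[["F1"]],
                            stringsAsFactors = FALSE)
  }
  micro_counts <- c(TP = sum(vapply(counts, `[[`, 0, "TP")),
                    TN = sum(vapply(counts, `[[`, 0, "TN")),
                    FN = sum(vapply(counts, `[[`, 0, "FN")),
                    FP = sum(vapply(counts, `[[`, 0, "FP")))
  mm <- micro_average(counts)
  rows[["Micro"]] <- data.frame(subtype = "Micro", TP = micro_counts[["TP"]],
                                TN = micro_counts[["TN"]], FN = micro_counts[["FN"]],
                                FP = micro_counts[["FP"]], P = mm[["P"]],
                                R = mm[["R"]], F1 = mm[["F1"]],
                                stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("P", "R", "F1")) y[[col]] <- sprintf("%.3f", y[[col]])
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to TSV
#'
#' Metrics are rounded to 3 decimal places in the serialized report.
#'
#' @param report An `evaluation_report` from [evaluate()].
#' @param path Output TSV path.
#' @export
write_evaluation <- function(report, path) {
  y <- as.data.frame(report)
  for (col in c("P", "R", "F1")) y[[col]] <- sprintf("%.3f", y[[col]])
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
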