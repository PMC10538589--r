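#' Confusion counts and derived performance metrics
#'
#' Accuracy, precision, recall and F1 from the conventional formulas:
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R). A metric whose denominator is zero
#' (or, for accuracy, whose TN count is unavailable) is reported as `NA`, a
#' distinct "undefined" marker - never silently 0 or 1. Values are kept at
#' full precision; rounding happens only in the print method.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @param tn Non-negative integer count, or `NA` when true negatives are
#'   undefined (pair-level evaluation).
#'
#' @return An object of class `orade_metrics`.
#' @export
metrics_result <- function(tp, fp, fn, tn = NA_integer_) {
  counts <- c(tp = tp, fp = fp, fn = fn)
  stopifnot(all(!is.na(counts)), all(counts >= 0), is.na(tn) || tn >= 0)
  safe_div <- function(num, den) if (!is.na(den) && den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- if (is.na(tn)) NA_real_ else safe_div(tp + tn, tp + fp + fn + tn)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 tn = if (is.na(tn)) NA_integer_ else as.integer(tn),
                 accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1),
            class = "orade_metrics")
}

#' @export
print.orade_metrics <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(round(v, digits), nsmall = digits)
  cat("<orade_metrics>\n")
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%s\n", x$tp, x$fp, x$fn,
              if (is.na(x$tn)) "undefined" else x$tn))
  cat(sprintf("  accuracy=%s precision=%s recall=%s F1=%s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}

#' Score a corpus at note level against gold labels
#'
#' A note is predicted positive when it carries at least one unfiltered
#' candidate pair (set `include_filtered = TRUE` to count flagged pairs as
#' detections too). Gold notes absent from the predictions count as negative
#' predictions. Only notes present in `gold` are scored.
#'
#' @param pairs Candidate-pair data.frame (multi-note).
#' @param gold Gold-label data.frame with one row per note: `note_id`,
#'   `has_orade` (logical). The pair-level columns of [read_gold()] output
#'   are tolerated and ignored here.
#' @param include_filtered Count filtered pairs as positive predictions.
#'
#' @return An `orade_metrics` object.
#' @export
evaluate_note_level <- function(pairs, gold, include_filtered = FALSE) {
  gl <- unique(gold[c("note_id", "has_orade")])
  if (anyDuplicated(gl$note_id)) {
    stop("conflicting gold labels for note_id(s): ",
         paste(unique(gl$note_id[duplicated(gl$note_id)]), collapse = ", "),
         call. = FALSE)
  }
  use <- if (include_filtered) pairs else pairs[!pairs$filtered, , drop = FALSE]
  predicted <- unique(use$note_id)
  pos <- as.logical(gl$has_orade)
  pred <- gl$note_id %in% predicted
  metrics_result(tp = sum(pos & pred), fp = sum(!pos & pred),
                 fn = sum(pos & !pred), tn = sum(!pos & !pred))
}

#' Score extracted pairs against gold pairs
#'
#' Matching is on (note_id, generic drug, adverse-event preferred term) with
#' exact string equality after case folding. True negatives are undefined at
#' pair level, so accuracy is reported as `NA`.
#'
#' @param pairs Candidate-pair data.frame.
#' @param gold Gold data.frame carrying pair rows: `note_id`,
#'   `generic_drug`, `ae_pt` (rows with missing pair fields are ignored). An
#'   `out_of_window` column, when present and `TRUE`, marks planted pairs
#'   beyond the extraction window; these are excluded from the gold positive
#'   set by default.
#' @param include_filtered Count filtered pairs as predictions.
#' @param include_out_of_window Keep gold pairs flagged `out_of_window`.
#'
#' @return An `orade_metrics` object.
#' @export
evaluate_pair_level <- function(pairs, gold, include_filtered = FALSE,
                                include_out_of_window = FALSE) {
  gp <- gold[!is.na(gold$generic_drug) & nzchar(gold$generic_drug) &
               !is.na(gold$ae_pt) & nzchar(gold$ae_pt), , drop = FALSE]
  if (!include_out_of_window && "out_of_window" %in% names(gp)) {
    gp <- gp[!(gp$out_of_window %in% TRUE), , drop = FALSE]
  }
  use <- if (include_filtered) pairs else pairs[!pairs$filtered, , drop = FALSE]
  pkey <- unique(paste(use$note_id, tolower(use$generic_drug),
                       tolower(use$ae_pt), sep = "||"))
  gkey <- unique(paste(gp$note_id, tolower(gp$generic_drug),
                       tolower(gp$ae_pt), sep = "||"))
  metrics_result(tp = length(intersect(pkey, gkey)),
                 fp = length(setdiff(pkey, gkey)),
                 fn = length(setdiff(gkey, pkey)),
                 tn = NA_integer_)
}
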