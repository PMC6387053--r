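# Screening-performance evaluation: confusion counts and the five reported
# rates (sensitivity, specificity, accuracy, FAR, FRR).

#' Tally confusion counts
#'
#' Counts true/false positives/negatives over paired decision vectors, with
#' `"pathological"` as the positive class.
#'
#' @param predictions character vector of `"healthy"`/`"pathological"`.
#' @param truths character vector of the same length.
#' @return list of class `fs_confusion` with integer fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
tally_confusion <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths))
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  ok <- c("healthy", "pathological")
  if (!all(predictions %in% ok) || !all(truths %in% ok))
    stop("decisions must be 'healthy' or 'pathological'", call. = FALSE)
  pos_p <- predictions == "pathological"
  pos_t <- truths == "pathological"
  structure(list(tp = sum(pos_p & pos_t),
                 fp = sum(pos_p & !pos_t),
                 tn = sum(!pos_p & !pos_t),
                 fn = sum(!pos_p & pos_t)),
            class = "fs_confusion")
}

#' Summarize screening performance
#'
#' Computes, as percentages:
#' sensitivity `= 100 tp / (tp + fn)`, specificity `= 100 tn / (tn + fp)`,
#' accuracy `= 100 (tp + tn) / total`, and the false acceptance / rejection
#' rates over the total sample count, `FAR = 100 fp / total` and
#' `FRR = 100 fn / total` (so `FAR + FRR = 100 - accuracy`). A metric whose
#' denominator is zero is reported as `NA` (undefined).
#'
#' @param counts an `fs_confusion` object, or a list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return list of class `fs_metrics` with fields `sensitivity`,
#'   `specificity`, `accuracy`, `far`, `frr` (percent) and `counts`.
#' @examples
#' summarize_metrics(list(tp = 50, fn = 0, tn = 48, fp = 2))
#' @export
summarize_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot("counts must be non-negative" = all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0L)
    stop("all counts are zero: nothing was evaluated", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 accuracy = ratio(tp + tn, total),
                 far = ratio(fp, total),
                 frr = ratio(fn, total),
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "fs_metrics")
}

#' @export
print.fs_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("Screening performance",
      sprintf("(tp=%d fp=%d tn=%d fn=%d)\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  cat("  FAR:        ", fmt(x$far), "\n")
  cat("  FRR:        ", fmt(x$frr), "\n")
  invisible(x)
}

#' Evaluate a phantom (or clinical) cohort manifest
#'
#' Reads a manifest CSV with columns `path`, `label` and `laterality`, runs
#' the full screening pipeline on every row, and summarizes performance
#' against the truth labels. Unreadable rows are recorded as errors and
#' excluded from the tally.
#'
#' @param manifest path to the manifest CSV, or a data.frame with the three
#'   columns.
#' @param config a [pipeline_config()].
#' @param per_image_csv optional path; when given, a per-image results table
#'   (`path`, `truth`, `decision`, `lesion_pixel_count`, `error`) is written
#'   there.
#' @return an `fs_metrics` summary with the per-image table attached as
#'   attribute `"per_image"`. If any row errored, attribute `"n_errors"` is
#'   positive.
#' @export
evaluate_manifest <- function(manifest, config = pipeline_config(),
                              per_image_csv = NULL) {
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else base <- "."
  need <- c("path", "label", "laterality")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(manifest)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- manifest$path[i]
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    res <- tryCatch(
      screen_retina(p, manifest$laterality[i], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(path = manifest$path[i],
                              truth = manifest$label[i],
                              decision = NA_character_,
                              lesion_pixel_count = NA_integer_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(path = manifest$path[i],
                              truth = manifest$label[i],
                              decision = res$decision,
                              lesion_pixel_count = res$lesion_pixel_count,
                              error = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  per_image <- do.call(rbind, rows)
  if (!is.null(per_image_csv))
    utils::write.csv(per_image, per_image_csv, row.names = FALSE)
  ok <- is.na(per_image$error)
  if (!any(ok))
    stop("no manifest row could be evaluated", call. = FALSE)
  out <- summarize_metrics(tally_confusion(per_image$decision[ok],
                                           per_image$truth[ok]))
  attr(out, "per_image") <- per_image
  attr(out, "n_errors") <- sum(!ok)
  out
}
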