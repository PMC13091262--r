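#' Name-matching configuration
#'
#' Controls how extracted region names are normalized before exact
#' comparison with the ground truth. The default is case-sensitive exact
#' matching after whitespace trimming; a case-insensitive option exists for
#' annotators whose output casing is not reliable.
#'
#' @param case_sensitive Compare names case-sensitively. Default TRUE.
#' @param trim_whitespace Trim leading/trailing whitespace before comparing.
#'   Default TRUE.
#' @return An object of class \code{matcher_config}.
#' @export
matcher_config <- function(case_sensitive = TRUE, trim_whitespace = TRUE) {
  structure(list(case_sensitive = isTRUE(case_sensitive),
                 trim_whitespace = isTRUE(trim_whitespace)),
            class = "matcher_config")
}

normalize_names <- function(x, matcher) {
  if (matcher$trim_whitespace) x <- trimws(x)
  if (!matcher$case_sensitive) x <- tolower(x)
  x
}

#' Deduplicate extracted names within one image
#'
#' Converts the extracted name list to a set (after normalization) and
#' additionally reports which normalized names occurred more than once —
#' duplicated names are excluded from boundary scoring.
#'
#' @param records Extracted-record data frame (or character vector of names).
#' @param matcher A \code{matcher_config}.
#' @return List with \code{names} (unique normalized names) and
#'   \code{duplicated} (the subset seen more than once).
#' @export
dedupe_names <- function(records, matcher = matcher_config()) {
  nm <- if (is.data.frame(records)) records$sbre else records
  nm <- normalize_names(nm, matcher)
  tab <- table(nm)
  list(names = names(tab), duplicated = names(tab)[tab > 1])
}

pair_results_truths <- function(results, truths) {
  ids <- vapply(results, function(r) r$dataset_id, character(1))
  unknown <- setdiff(ids, names(truths))
  if (length(unknown))
    stop(sprintf("no ground truth for dataset(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  ids
}

#' Pooled precision/recall/F1 for region-name extraction
#'
#' Per image, the extracted names are deduplicated to a set and intersected
#' with the truth-name set; correct/extracted/truth counts are pooled
#' (micro-averaged) over all images before dividing. Blank results contribute
#' zero extracted names but their truth regions still count toward recall's
#' denominator. Precision is \code{NA} when nothing was extracted at all;
#' F1 is 0 when precision + recall is 0.
#'
#' @param results List of \code{annotation_result}.
#' @param truths Named list (by dataset_id) of ground-truth region data
#'   frames.
#' @param matcher A \code{matcher_config}.
#' @return List with \code{precision}, \code{recall}, \code{f1} and the
#'   pooled counts \code{n_correct}, \code{n_extracted}, \code{n_truth}.
#' @export
score_sbre_corpus <- function(results, truths, matcher = matcher_config()) {
  ids <- pair_results_truths(results, truths)
  n_correct <- n_extracted <- n_truth <- 0L
  for (i in seq_along(results)) {
    pred <- dedupe_names(results[[i]]$records, matcher)$names
    true <- unique(normalize_names(truths[[ids[i]]]$sbre, matcher))
    n_correct <- n_correct + length(intersect(pred, true))
    n_extracted <- n_extracted + length(pred)
    n_truth <- n_truth + length(true)
  }
  precision <- if (n_extracted > 0) n_correct / n_extracted else NA_real_
  recall <- if (n_truth > 0) n_correct / n_truth else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else if (!is.na(precision) && !is.na(recall)) 0 else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       n_correct = n_correct, n_extracted = n_extracted, n_truth = n_truth)
}

#' Signed boundary errors for uniquely name-matched records
#'
#' For each image, every predicted record whose normalized name matches
#' exactly one truth name and is not itself duplicated among the predictions
#' is paired with that truth region; signed errors (predicted minus truth)
#' are collected per endpoint. Records with unmatched or duplicated names are
#' excluded and counted. No validity filter is applied to predicted ranges
#' (inverted or out-of-range boundaries still produce errors).
#'
#' @inheritParams score_sbre_corpus
#' @return List of class \code{boundary_errors} with integer vectors
#'   \code{start_errors}, \code{end_errors} and the exclusion count
#'   \code{n_excluded}.
#' @export
boundary_errors <- function(results, truths, matcher = matcher_config()) {
  ids <- pair_results_truths(results, truths)
  start_errors <- integer(0)
  end_errors <- integer(0)
  n_excluded <- 0L
  for (i in seq_along(results)) {
    recs <- results[[i]]$records
    if (nrow(recs) == 0) next
    truth <- truths[[ids[i]]]
    pred_norm <- normalize_names(recs$sbre, matcher)
    true_norm <- normalize_names(truth$sbre, matcher)
    dup <- dedupe_names(recs, matcher)$duplicated
    for (k in seq_len(nrow(recs))) {
      hit <- which(true_norm == pred_norm[k])
      if (length(hit) == 1 && !pred_norm[k] %in% dup) {
        start_errors <- c(start_errors, recs$start[k] - truth$start[hit])
        end_errors <- c(end_errors, recs$end[k] - truth$end[hit])
      } else {
        n_excluded <- n_excluded + 1L
      }
    }
  }
  structure(list(start_errors = start_errors, end_errors = end_errors,
                 n_excluded = n_excluded),
            class = "boundary_errors")
}

#' Mean absolute boundary error per endpoint
#'
#' @param errors A \code{boundary_errors} object.
#' @return List with \code{mae_start} and \code{mae_end} (residues);
#'   \code{NA} when no pairs were matched.
#' @export
boundary_mae <- function(errors) {
  stopifnot(inherits(errors, "boundary_errors"))
  m <- function(v) if (length(v)) mean(abs(v)) else NA_real_
  list(mae_start = m(errors$start_errors), mae_end = m(errors$end_errors))
}

#' Histogram of signed boundary errors
#'
#' Bins the pooled signed errors (start and end together) into
#' integer-aligned bins of width \code{bin_width}; bin \code{[e, e +
#' bin_width)} by left edge. Counts conserve the number of error entries.
#'
#' @param errors A \code{boundary_errors} object.
#' @param bin_width Bin width in residues (integer, >= 1). Default 1.
#' @return List with \code{edges} (left edges plus final right edge) and
#'   \code{counts} (one per bin).
#' @export
error_histogram <- function(errors, bin_width = 1L) {
  stopifnot(inherits(errors, "boundary_errors"), bin_width >= 1)
  v <- c(errors$start_errors, errors$end_errors)
  if (!length(v))
    return(list(edges = numeric(0), counts = integer(0)))
  bin_width <- as.integer(bin_width)
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- (floor(max(v) / bin_width) + 1L) * bin_width
  edges <- seq.int(lo, hi, by = bin_width)
  idx <- findInterval(v, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  list(edges = edges, counts = counts)
}

#' Assemble a full evaluation report
#'
#' Combines name-set scoring, boundary errors, per-endpoint MAE and the
#' signed-error histogram into one serializable report. Deterministic given
#' its inputs.
#'
#' @inheritParams score_sbre_corpus
#' @param bin_width Histogram bin width in residues. Default 1.
#' @return An object of class \code{evaluation_report}.
#' @export
build_report <- function(results, truths, matcher = matcher_config(),
                         bin_width = 1L) {
  scores <- score_sbre_corpus(results, truths, matcher)
  errors <- boundary_errors(results, truths, matcher)
  mae <- boundary_mae(errors)
  structure(list(precision = scores$precision, recall = scores$recall,
                 f1 = scores$f1,
                 mae_start = mae$mae_start, mae_end = mae$mae_end,
                 n_images = length(results),
                 n_truth_regions = scores$n_truth,
                 n_extracted_names = scores$n_extracted,
                 n_correct_names = scores$n_correct,
                 errors = errors,
                 histogram = error_histogram(errors, bin_width)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(paste0("evaluation_report: %d images, %d truth regions\n",
                     "  precision %s  recall %s  F1 %s\n",
                     "  MAE(start) %s  MAE(end) %s  (%d matched pairs, %d excluded)\n"),
              x$n_images, x$n_truth_regions,
              fmt(x$precision), fmt(x$recall), fmt(x$f1),
              fmt(x$mae_start), fmt(x$mae_end),
              length(x$errors$start_errors), x$errors$n_excluded))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An \code{evaluation_report}.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- unclass(report)
  x$errors <- unclass(x$errors)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a serialized evaluation report
#'
#' @param path JSON path written by \code{\link{write_report}}.
#' @return An \code{evaluation_report}.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("precision", "recall", "f1", "mae_start", "mae_end"))
    x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
  x$errors <- structure(list(start_errors = as.integer(x$errors$start_errors),
                             end_errors = as.integer(x$errors$end_errors),
                             n_excluded = as.integer(x$errors$n_excluded)),
                        class = "boundary_errors")
  x$histogram <- list(edges = as.numeric(x$histogram$edges),
                      counts = as.integer(x$histogram$counts))
  structure(x, class = "evaluation_report")
}
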