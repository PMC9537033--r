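as_mask <- function(m, name = "mask") {
  if (is.numeric(m)) m <- m > 0.5
  if (!is.logical(m)) stop(name, " must be logical or numeric", call. = FALSE)
  m
}

#' Overlap (Jaccard) score between two masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the union is
#' empty; the score is defined as 1 with a warning.
#'
#' @param pred predicted binary mask (logical or 0/1 numeric)
#' @param truth ground-truth binary mask of the same shape
#' @return scalar in `[0, 1]`
#' @export
overlap_score <- function(pred, truth) {
  pred <- as_mask(pred, "pred"); truth <- as_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("mask shapes differ", call. = FALSE)
  un <- sum(pred | truth)
  if (un == 0L) {
    warning("both masks empty: overlap defined as 1")
    return(1)
  }
  sum(pred & truth) / un
}

#' Pixel-count precision and recall
#'
#' `P = |pred intersect truth| / |pred|`, `R = |pred intersect truth| /
#' |truth|`. An empty prediction has precision 0; an empty truth is an
#' error.
#'
#' @inheritParams overlap_score
#' @return named numeric vector `c(precision, recall)`
#' @export
precision_recall <- function(pred, truth) {
  pred <- as_mask(pred, "pred"); truth <- as_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("mask shapes differ", call. = FALSE)
  if (!any(truth)) stop("ground truth is empty", call. = FALSE)
  tp <- sum(pred & truth)
  c(precision = if (any(pred)) tp / sum(pred) else 0,
    recall = tp / sum(truth))
}

#' Beta-weighted F-measure
#'
#' `F_beta = (1 + beta) P R / (beta P + R)`; `beta = 0.3` weights
#' precision above recall. Returns 0 with a warning when the denominator
#' vanishes.
#'
#' @param precision,recall values in `[0, 1]` (vectorized)
#' @param beta trade-off weight (default 0.3)
#' @return F-measure value(s)
#' @export
f_measure <- function(precision, recall, beta = 0.3) {
  den <- beta * precision + recall
  out <- ifelse(den > 0, (1 + beta) * precision * recall / den, 0)
  if (any(den <= 0)) warning("beta * P + R = 0: F-measure defined as 0")
  out
}

#' Multi-rater consensus ground truth
#'
#' A pixel belongs to the consensus when at least `fraction` of the raters
#' marked it (the 50% criterion with four raters keeps pixels marked by at
#' least two).
#'
#' @param masks list of same-shape binary rater masks
#' @param fraction consensus fraction in `(0, 1]` (default 0.5)
#' @return logical consensus mask
#' @export
consensus_ground_truth <- function(masks, fraction = 0.5) {
  if (length(masks) < 1L) stop("at least one rater mask required", call. = FALSE)
  masks <- lapply(masks, as_mask)
  d1 <- dim(masks[[1L]])
  if (!all(vapply(masks, function(m) identical(dim(m), d1), logical(1L))))
    stop("mask shapes differ", call. = FALSE)
  votes <- Reduce(`+`, masks)
  votes / length(masks) >= fraction
}

#' Mean and sample standard deviation of per-case metric values
#'
#' The spread uses the sample (n - 1) standard deviation. A single value
#' has undefined spread; 0 is returned with a warning.
#'
#' @param values non-empty numeric vector
#' @return named numeric vector `c(mean, sd)`
#' @export
aggregate_metrics <- function(values) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  if (length(values) == 1L) {
    warning("single value: standard deviation undefined, returning 0")
    return(c(mean = as.numeric(values), sd = 0))
  }
  c(mean = mean(values), sd = stats::sd(values))
}

#' All evaluation metrics for one prediction
#'
#' @inheritParams overlap_score
#' @param beta F-measure weight (default 0.3)
#' @param case_id optional identifier carried into the result
#' @return a one-row tibble: `case_id`, `overlap`, `precision`, `recall`,
#'   `f_measure`
#' @export
evaluate_masks <- function(pred, truth, beta = 0.3, case_id = NA_character_) {
  pr <- precision_recall(pred, truth)
  tibble::tibble(case_id = case_id,
                 overlap = overlap_score(pred, truth),
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 f_measure = unname(f_measure(pr["precision"], pr["recall"], beta)))
}

#' Evaluate a batch of predictions
#'
#' One row per case plus a `mean` and a `sd` footer row, mirroring the
#' usual per-case result tables.
#'
#' @param preds list of predicted masks
#' @param truths list of ground-truth masks (same length)
#' @param beta F-measure weight
#' @param case_ids optional character identifiers
#' @return a tibble with `length(preds) + 2` rows
#' @export
evaluate_batch <- function(preds, truths, beta = 0.3, case_ids = NULL) {
  stopifnot(length(preds) == length(truths))
  case_ids <- case_ids %||% sprintf("case_%02d", seq_along(preds))
  rows <- do.call(rbind, Map(function(p, t, id) evaluate_masks(p, t, beta, id),
                             preds, truths, case_ids))
  num <- c("overlap", "precision", "recall", "f_measure")
  footer <- tibble::tibble(
    case_id = c("mean", "sd"),
    overlap = c(mean(rows$overlap), stats::sd(rows$overlap)),
    precision = c(mean(rows$precision), stats::sd(rows$precision)),
    recall = c(mean(rows$recall), stats::sd(rows$recall)),
    f_measure = c(mean(rows$f_measure), stats::sd(rows$f_measure)))
  rbind(rows, footer)
}
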