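new_score_set <- function(df, score_kind) {
  keep <- c("compound_id", "bucket", "truth", "cytotoxic", "score",
            "cytotox_assigned", "substituted_from_1x")
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "score_kind") <- score_kind
  class(df) <- c("score_set", "data.frame")
  df
}

score_kind <- function(scores) attr(scores, "score_kind")

#' Test-system-wise cytotoxic replacement score
#'
#' Cytotoxic conditions yield no expression data; for classification they
#' are assigned the highest SPS count observed anywhere in the test system
#' (across both concentration buckets) plus five, so they always sit above
#' any data-driven threshold.
#'
#' @param counts condition table with a `count` column (`NA` where
#'   cytotoxic).
#' @return scalar replacement score.
#' @export
cytotoxic_replacement_score <- function(counts) {
  observed <- counts$count[!counts$cytotoxic]
  if (!length(observed) || all(is.na(observed))) {
    stop("no observed SPS counts; cytotoxic replacement score undefined")
  }
  max(observed, na.rm = TRUE) + 5
}

#' Assign classifier scores to conditions
#'
#' Three cytotoxicity modes:
#' \describe{
#'   \item{combined}{non-cytotoxic conditions keep their SPS count;
#'     cytotoxic ones receive the test-system-wise replacement score
#'     (highest observed count plus five, or `cytotox_score` if supplied).}
#'   \item{cytotox_only}{score 1 if cytotoxic, 0 otherwise; expression data
#'     are ignored.}
#'   \item{gene_only}{non-cytotoxic conditions keep their count; cytotoxic
#'     conditions carry `NA` ("no data"). Downstream, [classify_scores()]
#'     counts them as test-negative and [roc_auc()] excludes them.}
#' }
#'
#' @param counts condition table with a `count` column (`NA` exactly where
#'   cytotoxic).
#' @param mode scoring mode.
#' @param cytotox_score optional pre-computed replacement score (needed
#'   when `counts` covers only part of the test system, or when all
#'   conditions are cytotoxic).
#' @return a `score_set` data.frame with attribute `score_kind`.
#' @export
assign_scores <- function(counts,
                          mode = c("combined", "cytotox_only", "gene_only"),
                          cytotox_score = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(counts)
  bad <- !df$cytotoxic & is.na(df$count)
  if (mode != "cytotox_only" && any(bad)) {
    stop("non-cytotoxic conditions without an SPS count: ",
         paste(df$compound_id[bad], collapse = ", "))
  }
  df$cytotox_assigned <- FALSE
  if (mode == "combined") {
    df$score <- as.numeric(df$count)
    if (any(df$cytotoxic)) {
      if (is.null(cytotox_score)) cytotox_score <- cytotoxic_replacement_score(df)
      df$score[df$cytotoxic] <- cytotox_score
      df$cytotox_assigned <- df$cytotoxic
    }
    kind <- "sps"
  } else if (mode == "cytotox_only") {
    df$score <- as.numeric(df$cytotoxic)
    df$cytotox_assigned <- df$cytotoxic
    kind <- "indicator"
  } else {
    df$score <- as.numeric(df$count)
    df$score[df$cytotoxic] <- NA_real_
    df$cytotox_assigned <- df$cytotoxic
    kind <- "sps"
  }
  new_score_set(df, kind)
}

#' Carry 1x scores into the 20x bucket for untestable compounds
#'
#' Compounds whose solubility limit was exceeded at the 20x bucket have no
#' native 20x result; their 1x scores stand in, flagged
#' `substituted_from_1x`.
#'
#' @param scores_1x,scores_20x score sets of the two buckets.
#' @param unavailable compound ids lacking a native 20x result; each must
#'   be present in `scores_1x`.
#' @return the 20x-bucket score set including the substituted rows.
#' @export
substitute_20x <- function(scores_1x, scores_20x, unavailable) {
  if (!length(unavailable)) return(scores_20x)
  missing_1x <- setdiff(unavailable, scores_1x$compound_id)
  if (length(missing_1x)) {
    stop("unavailable compounds missing at 1x: ",
         paste(missing_1x, collapse = ", "))
  }
  sub <- as.data.frame(scores_1x)[scores_1x$compound_id %in% unavailable, ,
                                  drop = FALSE]
  sub$bucket <- "20x"
  sub$substituted_from_1x <- TRUE
  out <- rbind(
    as.data.frame(scores_20x)[!scores_20x$compound_id %in% unavailable, ,
                              drop = FALSE],
    sub)
  new_score_set(out[order(match(out$compound_id, c(scores_20x$compound_id,
                                                   unavailable))), ,
                    drop = FALSE],
                score_kind(scores_20x))
}

#' Classify scores against a threshold
#'
#' A condition is test-positive iff its score strictly exceeds the
#' threshold. `NA` scores (gene-only cytotoxic conditions) are
#' test-negative.
#'
#' @param scores a `score_set`.
#' @param threshold classification threshold.
#' @return the score set with logical `predicted` and an `outcome` column
#'   (TP/TN/FP/FN).
#' @export
classify_scores <- function(scores, threshold) {
  df <- as.data.frame(scores)
  df$predicted <- !is.na(df$score) & df$score > threshold
  df$outcome <- ifelse(df$truth == "teratogen",
                       ifelse(df$predicted, "TP", "FN"),
                       ifelse(df$predicted, "FP", "TN"))
  df
}

#' Confusion counts and summary metrics
#'
#' @param predicted logical vector (test-positive).
#' @param truth character vector, `"teratogen"` / `"non_teratogen"`.
#' @return list with `TP`, `TN`, `FP`, `FN`, `accuracy`, `sensitivity`,
#'   `specificity` (the latter two `NA` when their class is empty).
#' @export
confusion_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == "teratogen"
  TP <- sum(predicted & pos); FN <- sum(!predicted & pos)
  FP <- sum(predicted & !pos); TN <- sum(!predicted & !pos)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = (TP + TN) / length(predicted),
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

#' Area under the empirical ROC curve
#'
#' Computed by pair counting over all (teratogen, non-teratogen) pairs with
#' ties scored 0.5, which equals the trapezoidal area under the empirical
#' ROC curve. `NA` scores (gene-only cytotoxic conditions) are excluded
#' from the ranking.
#'
#' @param scores a `score_set` (or numeric vector).
#' @param truth truth labels; defaults to the score set's own.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, truth = NULL) {
  if (inherits(scores, "score_set") || is.data.frame(scores)) {
    if (is.null(truth)) truth <- scores$truth
    scores <- scores$score
  }
  keep <- !is.na(scores)
  scores <- scores[keep]; truth <- truth[keep]
  pos <- truth == "teratogen"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: one class is empty")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Exhaustive threshold search with lexicographic tie-breaking
#'
#' Evaluates every distinct classification the strict `>` rule can produce:
#' candidate thresholds are the sorted unique observed scores plus one
#' value below the minimum (all-positive). The optimum maximizes accuracy,
#' then sensitivity, then specificity. Because classification is strict,
#' every threshold in the half-open interval between consecutive observed
#' scores is equivalent; the full interval is reported with its lower bound
#' as the canonical representative (round numbers quoted elsewhere, e.g.
#' 1000, are interior points of such intervals).
#'
#' @param scores a `score_set`.
#' @return a `classification_report`: list with `threshold`,
#'   `optimal_threshold_interval`, `predictions`, confusion counts,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
search_threshold <- function(scores) {
  s <- scores$score
  u <- sort(unique(s[!is.na(s)]))
  if (length(u) < 2) stop("need >= 2 distinct scores to search a threshold")
  cand <- c(-Inf, u)
  upper <- c(u, Inf)
  best <- NULL
  for (i in seq_along(cand)) {
    cm <- confusion_metrics(classify_scores(scores, cand[i])$predicted,
                            scores$truth)
    key <- c(cm$accuracy,
             ifelse(is.na(cm$sensitivity), -1, cm$sensitivity),
             ifelse(is.na(cm$specificity), -1, cm$specificity))
    if (is.null(best) || lex_greater(key, best$key)) {
      best <- list(key = key, i = i, cm = cm)
    }
  }
  threshold <- cand[best$i]
  report_at_threshold(scores, threshold,
                      interval = c(threshold, upper[best$i]))
}

lex_greater <- function(a, b) {
  for (j in seq_along(a)) {
    if (a[j] > b[j]) return(TRUE)
    if (a[j] < b[j]) return(FALSE)
  }
  FALSE
}

#' Classification report at a fixed threshold
#'
#' @param scores a `score_set`.
#' @param threshold classification threshold (strict `>`).
#' @param interval optional equivalence interval to record.
#' @return a `classification_report`.
#' @export
report_at_threshold <- function(scores, threshold, interval = NULL) {
  predictions <- classify_scores(scores, threshold)
  cm <- confusion_metrics(predictions$predicted, predictions$truth)
  auc <- tryCatch(roc_auc(scores), error = function(e) NA_real_)
  structure(c(list(threshold = threshold,
                   optimal_threshold_interval = interval,
                   predictions = predictions, auc = auc,
                   score_kind = score_kind(scores)),
              cm),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report: threshold %s | acc %.3f sens %.3f spec %.3f auc %.3f\n",
    format(x$threshold), x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  TP %d TN %d FP %d FN %d (n = %d)\n", x$TP, x$TN, x$FP, x$FN,
              x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Confusion metrics from published outcome labels
#'
#' Converts a vector of TP/TN/FP/FN labels (as printed in per-condition
#' classification tables) back into predictions and truths, and summarizes
#' them. `NA` labels (conditions absent from a column) are dropped.
#'
#' @param labels character vector of `"TP"`, `"TN"`, `"FP"`, `"FN"`, `NA`.
#' @return as [confusion_metrics()].
#' @export
confusion_from_labels <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!all(labels %in% c("TP", "TN", "FP", "FN"))) {
    stop("labels must be TP/TN/FP/FN")
  }
  predicted <- labels %in% c("TP", "FP")
  truth <- ifelse(labels %in% c("TP", "FN"), "teratogen", "non_teratogen")
  confusion_metrics(predicted, truth)
}
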