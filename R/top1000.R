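#' Select the k probe sets with highest variance
#'
#' Sample variance across the provided samples; ties broken
#' deterministically by probe-set id order.
#'
#' @param mat probe sets x samples matrix.
#' @param k number of probe sets to keep.
#' @return character vector of k probe-set ids, ordered by decreasing
#'   variance.
#' @export
select_top_variance <- function(mat, k) {
  if (k > nrow(mat)) {
    stop("k = ", k, " exceeds the ", nrow(mat), " available probe sets")
  }
  m <- rowMeans(mat)
  v <- rowSums((mat - m)^2) / (ncol(mat) - 1)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord[seq_len(k)]]
}

# fold assignment for the inner CV: all replicates of one training
# compound share a fold; folds are stratified by class so small n does
# not produce single-class folds
inner_foldid <- function(compound, truth_of_compound, nfolds) {
  compounds <- names(truth_of_compound)
  fold_of <- integer(length(compounds))
  names(fold_of) <- compounds
  for (cls in unique(truth_of_compound)) {
    members <- sample(compounds[truth_of_compound == cls])
    fold_of[members] <- rep_len(seq_len(nfolds), length(members))
  }
  unname(fold_of[compound])
}

#' Leave-one-compound-out penalized logistic prediction
#'
#' For each compound in turn, all of its samples (both concentration
#' buckets) are removed; the `k` probe sets with highest variance across
#' the remaining samples are selected; an L1-regularized logistic
#' regression is fit on those samples (labels: the compound truth of each
#' training sample's condition), with the penalty chosen to minimize the
#' mean 10-fold cross-validated binomial deviance ("lambda.min"); the
#' left-out samples are scored and per-replicate probabilities averaged per
#' condition. Cytotoxic conditions are assigned probability 1 exactly.
#' Inner CV folds keep all replicates of a training compound together and
#' are stratified by class. Deterministic given `seed`; the left-out
#' compound's data never enters feature selection, fitting, or fold
#' assignment.
#'
#' @param nd a `normalized_differences` (all non-control samples).
#' @param conditions a [condition_table()] covering every condition,
#'   including cytotoxic ones (which have no samples).
#' @param k number of probe sets selected per fold.
#' @param nfolds inner cross-validation folds.
#' @param seed integer seed.
#' @param standardize passed to [glmnet::cv.glmnet()].
#' @return list with `scores` (a probability `score_set`) and `folds`
#'   (per left-out compound: `selected`, `lambda`, `beta`,
#'   `replicate_probs`).
#' @export
loo_predict <- function(nd, conditions, k = 1000, nfolds = 10, seed = 1,
                        standardize = TRUE) {
  samples <- nd$samples
  cond <- as.data.frame(conditions)
  cond_key <- paste(cond$compound_id, cond$bucket)
  # samples carry the tested concentration label, which may differ from
  # the nominal bucket (10x / 1.67x substitutes live in the 20x bucket)
  label_key <- paste(cond$compound_id, cond$concentration_label)
  cond_idx <- match(paste(samples$compound_id, samples$concentration_label),
                    label_key)
  if (anyNA(cond_idx)) {
    stop("samples without a condition record: ",
         paste(unique(samples$sample_id[is.na(cond_idx)]), collapse = ", "))
  }
  sample_key <- cond_key[cond_idx]
  truth_of <- stats::setNames(cond$truth, cond_key)

  compounds <- unique(cond$compound_id)
  folds <- list()
  prob_of <- stats::setNames(rep(NA_real_, length(cond_key)), cond_key)

  for (ci in seq_along(compounds)) {
    cid <- compounds[ci]
    rows <- cond$compound_id == cid
    test_keys <- cond_key[rows & !cond$cytotoxic]
    prob_of[cond_key[rows & cond$cytotoxic]] <- 1
    if (!length(test_keys)) next
    test_idx <- which(samples$compound_id == cid)
    if (!length(test_idx)) {
      stop("no samples for non-cytotoxic compound ", cid)
    }
    train_idx <- which(samples$compound_id != cid)
    y <- as.integer(truth_of[sample_key[train_idx]] == "teratogen")
    if (length(unique(y)) < 2) {
      stop("fold for compound ", cid, " has single-class training data")
    }
    n_per_class <- table(tapply(y, samples$compound_id[train_idx], max))
    if (min(n_per_class) < 2) {
      stop("fold for compound ", cid, " has a class with fewer than 2 ",
           "training compounds; inner cross-validation is undefined")
    }
    # per-fold stream: seeded independently of all other folds, and never
    # touched by the left-out compound's values
    set.seed(compound_stream_seed(seed, ci))
    selected <- select_top_variance(nd$diffs[, train_idx, drop = FALSE], k)

    train_compound <- samples$compound_id[train_idx]
    truth_cmp <- vapply(split(y, train_compound), function(z) z[1], 0L)
    truth_cmp <- stats::setNames(ifelse(truth_cmp == 1, "teratogen",
                                        "non_teratogen"), names(truth_cmp))
    foldid <- inner_foldid(train_compound, truth_cmp, nfolds)

    fit <- glmnet::cv.glmnet(
      x = t(nd$diffs[selected, train_idx, drop = FALSE]), y = y,
      family = "binomial", alpha = 1, foldid = foldid,
      standardize = standardize)
    p <- as.numeric(stats::predict(
      fit, newx = t(nd$diffs[selected, test_idx, drop = FALSE]),
      s = "lambda.min", type = "response"))
    names(p) <- samples$sample_id[test_idx]
    test_cond <- sample_key[test_idx]
    for (key in test_keys) {
      prob_of[key] <- mean(p[test_cond == key])
    }
    folds[[cid]] <- list(
      selected = selected, lambda = fit$lambda.min,
      beta = as.numeric(stats::coef(fit, s = "lambda.min")),
      replicate_probs = p)
  }

  scores <- cond
  scores$score <- unname(prob_of[cond_key])
  scores$cytotox_assigned <- cond$cytotoxic
  list(scores = new_score_set(scores, "probability"), folds = folds)
}

#' Classify probability scores
#'
#' Delegates to the shared threshold machinery: searched threshold when
#' `threshold` is `NULL`, otherwise a fixed operating point.
#'
#' @param scores a probability `score_set`.
#' @param threshold optional fixed threshold.
#' @return a `classification_report`.
#' @export
classify_probabilities <- function(scores, threshold = NULL) {
  if (score_kind(scores) != "probability") {
    stop("scores are not probabilities")
  }
  if (is.null(threshold)) search_threshold(scores)
  else report_at_threshold(scores, threshold)
}
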