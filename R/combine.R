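#' Combine two test systems' score sets condition-wise
#'
#' Element-wise `min`, `max`, or arithmetic `mean` of the two systems'
#' scores for the same conditions. Cytotoxic conditions enter with their
#' assigned numeric scores (replacement count or probability 1); the
#' `cytotox_assigned` and `substituted_from_1x` flags propagate as "any".
#' Truth labels must agree between the systems.
#'
#' @param a,b score sets with identical condition keys and score kinds.
#' @param method `"min"`, `"max"` or `"mean"`.
#' @return the combined `score_set`.
#' @export
combine_scores <- function(a, b, method = c("mean", "min", "max")) {
  method <- match.arg(method)
  if (!identical(score_kind(a), score_kind(b))) {
    stop("cannot combine score kinds ", score_kind(a), " and ", score_kind(b))
  }
  key_a <- paste(a$compound_id, a$bucket)
  key_b <- paste(b$compound_id, b$bucket)
  only_a <- setdiff(key_a, key_b); only_b <- setdiff(key_b, key_a)
  if (length(only_a) || length(only_b)) {
    stop("condition keys differ; a-only: [",
         paste(only_a, collapse = ", "), "] b-only: [",
         paste(only_b, collapse = ", "), "]")
  }
  bb <- as.data.frame(b)[match(key_a, key_b), , drop = FALSE]
  if (!all(a$truth == bb$truth)) {
    stop("truth labels disagree for: ",
         paste(key_a[a$truth != bb$truth], collapse = ", "))
  }
  out <- as.data.frame(a)
  out$score <- switch(method,
                      min = pmin(a$score, bb$score),
                      max = pmax(a$score, bb$score),
                      mean = (a$score + bb$score) / 2)
  out$cytotoxic <- a$cytotoxic | bb$cytotoxic
  out$cytotox_assigned <- a$cytotox_assigned | bb$cytotox_assigned
  out$substituted_from_1x <- a$substituted_from_1x | bb$substituted_from_1x
  new_score_set(out, score_kind(a))
}

#' Drop conditions cytotoxic in either system (gene-only variant)
#'
#' In the gene-only reading of the `mean` and `max` combinations, every
#' condition that was cytotoxic in at least one test system is removed
#' from both score sets before combining.
#'
#' @param a,b score sets with identical condition keys.
#' @return list with filtered `a` and `b`.
#' @export
gene_only_filter <- function(a, b) {
  key_a <- paste(a$compound_id, a$bucket)
  key_b <- paste(b$compound_id, b$bucket)
  if (!setequal(key_a, key_b)) stop("condition keys differ between systems")
  bb <- as.data.frame(b)[match(key_a, key_b), , drop = FALSE]
  drop <- a$cytotoxic | bb$cytotoxic
  list(a = new_score_set(as.data.frame(a)[!drop, , drop = FALSE], score_kind(a)),
       b = new_score_set(bb[!drop, , drop = FALSE], score_kind(b)))
}
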