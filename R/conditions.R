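#' @keywords internal
"_PACKAGE"

CONCENTRATION_LABELS <- c("1x", "20x", "10x", "1.67x")
BUCKETS <- c("1x", "20x")
TRUTH_LEVELS <- c("teratogen", "non_teratogen")

#' Construct a validated condition table
#'
#' A condition is one compound at one nominal concentration bucket in one
#' test system. The nominal bucket (`1x` or `20x`) governs which
#' classification threshold applies; the actual tested concentration may
#' deviate (the `20x` bucket admits `10x` and `1.67x` substitutes where
#' solubility forced a lower multiple of the maximal plasma concentration
#' C_max). A compound may carry different truth labels at different buckets
#' (retinol: non-teratogenic at 1x, teratogenic at 20x), so conditions are
#' stored as independent rows, never as one mutable compound record.
#'
#' @param df data.frame with columns `compound_id`, `bucket`,
#'   `concentration_label`, `truth`, `cytotoxic` and optionally
#'   `substituted_from_1x` (default `FALSE`).
#' @return The validated data.frame with class `"condition_table"`.
#' @export
condition_table <- function(df) {
  required <- c("compound_id", "bucket", "concentration_label", "truth", "cytotoxic")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("condition table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"substituted_from_1x" %in% names(df)) df$substituted_from_1x <- FALSE
  if (!all(df$bucket %in% BUCKETS)) {
    stop("bucket must be one of: ", paste(BUCKETS, collapse = ", "))
  }
  if (!all(df$concentration_label %in% CONCENTRATION_LABELS)) {
    stop("concentration_label must be one of: ",
         paste(CONCENTRATION_LABELS, collapse = ", "))
  }
  if (!all(df$truth %in% TRUTH_LEVELS)) {
    stop("truth must be one of: ", paste(TRUTH_LEVELS, collapse = ", "))
  }
  if (any(df$substituted_from_1x & df$bucket != "20x")) {
    stop("substituted_from_1x is only meaningful for 20x-bucket conditions")
  }
  key <- paste(df$compound_id, df$bucket)
  if (anyDuplicated(key)) {
    stop("duplicated condition keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  class(df) <- c("condition_table", "data.frame")
  df
}

ref_path <- function(file) {
  system.file("extdata", "reference", file, package = "teratoclass", mustWork = TRUE)
}

#' Load the packaged reference screen
#'
#' Returns the shipped per-condition reference data of the two-assay
#' hiPSC developmental-toxicity screen: cytotoxicity status and counts of
#' significantly deregulated probe sets (up/down) for every UKN1 condition,
#' the published per-condition classification labels (TP/TN/FP/FN) for both
#' procedures and the assay combination, the published operating thresholds,
#' and the test-system-wise cytotoxic replacement scores.
#'
#' Four compounds (LFL, PHE, TER, VIS) exceeded solubility at the 20x
#' bucket, so the table carries no native 20x rows for them; use
#' [substitute_20x()] (or [reference_scores()], which applies it) to carry
#' their 1x results into 20x-bucket classification. Retinol appears twice
#' with different truth, once per bucket.
#'
#' @return list with elements `conditions` (a [condition_table()] including
#'   a `count` column, `NA` for cytotoxic conditions), `labels`,
#'   `operating_points`, `cytotoxic_scores` (named numeric vector),
#'   and `unavailable_20x` (compound ids requiring 1x substitution).
#' @export
load_reference_fixtures <- function() {
  cond <- utils::read.delim(ref_path("ukn1_conditions.tsv"),
                            colClasses = c(cytotoxic = "logical"))
  cond$count <- cond$up + cond$down
  cond$substituted_from_1x <- FALSE
  cond <- condition_table(cond)

  labels <- utils::read.delim(ref_path("classification_labels.tsv"))
  op <- utils::read.delim(ref_path("operating_points.tsv"))
  cyt <- utils::read.delim(ref_path("cytotoxic_scores.tsv"))
  cyt_scores <- stats::setNames(cyt$score, cyt$system)

  list(
    conditions = cond,
    labels = labels,
    operating_points = op,
    cytotoxic_scores = cyt_scores,
    unavailable_20x = c("LFL", "PHE", "TER", "VIS")
  )
}

#' Reference UKN1 score set for one bucket and scoring mode
#'
#' Builds a [score_set] from the packaged reference counts: assigns scores
#' in the requested cytotoxicity mode and, for the 20x bucket, substitutes
#' the 1x scores of the four compounds untestable at 20x.
#'
#' @param bucket `"1x"` or `"20x"`.
#' @param mode scoring mode passed to [assign_scores()].
#' @param fixtures optional pre-loaded result of [load_reference_fixtures()].
#' @return a score set (see [assign_scores()]).
#' @export
reference_scores <- function(bucket = c("20x", "1x"),
                             mode = c("combined", "cytotox_only", "gene_only"),
                             fixtures = load_reference_fixtures()) {
  bucket <- match.arg(bucket)
  mode <- match.arg(mode)
  cond <- fixtures$conditions
  # cytotoxic replacement is defined test-system-wise over ALL observed
  # counts (both buckets), so compute it before subsetting
  cyt_score <- unname(fixtures$cytotoxic_scores["UKN1"])
  score_for <- function(b) {
    assign_scores(cond[cond$bucket == b, , drop = FALSE],
                  mode = mode, cytotox_score = cyt_score)
  }
  if (bucket == "1x") return(score_for("1x"))
  substitute_20x(score_for("1x"), score_for("20x"),
                 unavailable = fixtures$unavailable_20x)
}
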