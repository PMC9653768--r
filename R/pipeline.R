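#' Classify the packaged reference screen
#'
#' Runs the SPS-procedure on the shipped reference counts at a given bucket
#' and cytotoxicity mode, either at the published operating threshold
#' (default) or with a fresh threshold search.
#'
#' @param bucket `"1x"` or `"20x"`.
#' @param mode scoring mode, see [assign_scores()].
#' @param threshold `"published"` (look up the shipped operating point),
#'   `"search"`, or a number. Cytotox-only mode uses the indicator's only
#'   meaningful operating point (positive iff cytotoxic); gene-only mode,
#'   which has no published threshold, falls back to the search.
#' @param fixtures optional pre-loaded [load_reference_fixtures()].
#' @return a `classification_report`.
#' @export
run_reference_classification <- function(bucket = c("20x", "1x"),
                                         mode = c("combined", "cytotox_only",
                                                  "gene_only"),
                                         threshold = "published",
                                         fixtures = load_reference_fixtures()) {
  bucket <- match.arg(bucket)
  mode <- match.arg(mode)
  scores <- reference_scores(bucket, mode, fixtures)
  if (identical(threshold, "published")) {
    if (mode == "combined") {
      op <- fixtures$operating_points
      hit <- op$system == "UKN1" & op$procedure == "sps" & op$bucket == bucket
      threshold <- op$threshold[hit]
    } else if (mode == "cytotox_only") {
      # the 0/1 indicator has exactly one meaningful operating point:
      # test-positive iff cytotoxic
      threshold <- 0
    } else {
      threshold <- "search"
    }
  }
  if (identical(threshold, "search")) search_threshold(scores)
  else report_at_threshold(scores, threshold)
}

#' Summary table of the reference classification
#'
#' One row per cytotoxicity mode and bucket, with AUC, accuracy,
#' sensitivity and specificity, at the published operating points for the
#' combined mode and searched thresholds otherwise.
#'
#' @param fixtures optional pre-loaded [load_reference_fixtures()].
#' @return data.frame.
#' @export
reference_summary <- function(fixtures = load_reference_fixtures()) {
  grid <- expand.grid(mode = c("cytotox_only", "gene_only", "combined"),
                      bucket = c("1x", "20x"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- run_reference_classification(grid$bucket[i], grid$mode[i],
                                        fixtures = fixtures)
    data.frame(mode = grid$mode[i], bucket = grid$bucket[i],
               threshold = rep$threshold, auc = rep$auc,
               accuracy = rep$accuracy, sensitivity = rep$sensitivity,
               specificity = rep$specificity)
  })
  do.call(rbind, rows)
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Run the full synthetic pipeline
#'
#' Simulates a study, writes its inputs, runs differential expression, the
#' SPS-procedure (searched thresholds per bucket), and the
#' leave-one-compound-out penalized-logistic procedure, and writes all
#' stage outputs plus a JSON summary under `out_dir`. One global seed fans
#' out to fixed per-stage seeds, so identical config and seed give
#' identical outputs.
#'
#' @param config a [simulation_config()] (e.g.
#'   [default_simulation_config()]).
#' @param out_dir output directory, created if needed.
#' @param seed global seed; overrides the config seed.
#' @param k,nfolds parameters of the penalized-logistic procedure.
#' @return (invisibly) list with `summary` data.frame, the per-bucket
#'   `classification_report`s of both procedures, and the stage objects.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed, k = 1000,
                         nfolds = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("pipeline start, seed %d\n", seed), file = log_path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    cat(sprintf("%-12s %6.1fs\n", name, proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }

  config$seed <- derive_seed(seed, 0)
  sim <- stage("simulate", generate_study(config))
  write_expression_study(sim$study, file.path(out_dir, "matrix.tsv"),
                         file.path(out_dir, "samples.tsv"))
  utils::write.table(sim$manifest, file.path(out_dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$conditions),
                     file.path(out_dir, "conditions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nd <- stage("normalize", normalize_to_controls(sim$study))
  de <- stage("diffexp", diffexp_all(nd, sim$conditions))
  utils::write.table(as.data.frame(de$counts),
                     file.path(out_dir, "sps_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sps_reports <- list(); top_reports <- list()
  loo <- stage("top1000", loo_predict(nd, sim$conditions, k = k,
                                      nfolds = nfolds,
                                      seed = derive_seed(seed, 1000)))
  for (b in unique(de$counts$bucket)) {
    counts_b <- de$counts[de$counts$bucket == b, , drop = FALSE]
    scores_b <- assign_scores(condition_table(counts_b), mode = "combined",
                              cytotox_score = if (any(counts_b$cytotoxic))
                                cytotoxic_replacement_score(de$counts) else NULL)
    sps_reports[[b]] <- stage(paste0("sps_", b), search_threshold(scores_b))
    top_b <- new_score_set(
      as.data.frame(loo$scores)[loo$scores$bucket == b, , drop = FALSE],
      "probability")
    top_reports[[b]] <- stage(paste0("top_", b), search_threshold(top_b))
  }

  summary <- do.call(rbind, c(
    lapply(names(sps_reports), function(b) report_row("sps", b, sps_reports[[b]])),
    lapply(names(top_reports), function(b) report_row("top1000", b, top_reports[[b]]))))
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, summary = summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, sps = sps_reports, top1000 = top_reports,
                 sim = sim, diffexp = de, loo = loo))
}

report_row <- function(procedure, bucket, rep) {
  data.frame(procedure = procedure, bucket = bucket,
             threshold = rep$threshold, auc = rep$auc,
             accuracy = rep$accuracy, sensitivity = rep$sensitivity,
             specificity = rep$specificity,
             TP = rep$TP, TN = rep$TN, FP = rep$FP, FN = rep$FN)
}
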