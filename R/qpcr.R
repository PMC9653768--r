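#' The seven-gene qPCR confirmation panel
#'
#' Genes selected for being deregulated by the largest numbers of
#' teratogens in the neuroepithelial differentiation assay, tagged by the
#' direction of their characteristic response.
#'
#' @return list with `up` and `down` gene symbol vectors.
#' @export
qpcr_panel_genes <- function() {
  list(up = c("CTHRC1", "SEMA3C", "SLIT2"),
       down = c("LMAN1", "PNCK", "RBM24", "ZNF385B"))
}

#' Fold-change and significance from replicate delta-delta-CT values
#'
#' The fold-change is `2^(-mean(ddct))`, reported as a signed linear
#' fold-change (values below 1 are expressed as `-1/x` so the |FC| > 2 cut
#' applies symmetrically). Significance is a two-sided one-sample t-test of
#' the replicate ddct values against 0. Zero-variance replicate sets yield
#' an undefined p-value, reported as `NA` with a warning (treated as
#' not significant downstream).
#'
#' @param ddct numeric vector of replicate delta-delta-CT values (>= 2).
#' @return list with `fold_change` (signed), `fold_change_linear`,
#'   `mean_ddct`, `p_value`, `n`.
#' @export
ddct_fold_change <- function(ddct) {
  if (length(ddct) < 2) stop("need >= 2 replicates for the t-test")
  m <- mean(ddct)
  fc_lin <- 2^(-m)
  p <- if (stats::sd(ddct) == 0) {
    warning("zero variance across replicates; p-value undefined")
    NA_real_
  } else {
    stats::t.test(ddct, mu = 0)$p.value
  }
  list(fold_change = if (fc_lin >= 1) fc_lin else -1 / fc_lin,
       fold_change_linear = fc_lin, mean_ddct = m, p_value = p,
       n = length(ddct))
}

#' Imputed panel records for a cytotoxic condition
#'
#' Cytotoxic conditions have no qPCR measurements; they are filled with
#' fixed values that always pass both significance cuts: mean ddct 2 for
#' the up-tagged genes and -1.6 for the down-tagged genes, each with
#' p = 0.01 (|2^2| = 4 > 2 and 2^1.6 = 3.03 > 2). The values are the
#' published conventions, stored literally; note that on the 2^(-ddct)
#' scale the up-tagged imputation lands below 1 — the imputation encodes
#' "unambiguously deregulated", not a direction, and only the |FC| and p
#' cuts feed classification.
#'
#' @param genes panel gene list as [qpcr_panel_genes()].
#' @return data.frame (`gene`, `mean_ddct`, `p_value`, `fold_change`,
#'   `imputed`).
#' @export
impute_cytotoxic <- function(genes = qpcr_panel_genes()) {
  df <- data.frame(
    gene = c(genes$up, genes$down),
    mean_ddct = c(rep(2, length(genes$up)), rep(-1.6, length(genes$down))),
    p_value = 0.01)
  fc_lin <- 2^(-df$mean_ddct)
  df$fold_change <- ifelse(fc_lin >= 1, fc_lin, -1 / fc_lin)
  df$imputed <- TRUE
  df
}

#' Summarize a replicate-level qPCR panel per condition and gene
#'
#' Applies [ddct_fold_change()] per condition x gene and fills cytotoxic
#' conditions via [impute_cytotoxic()].
#'
#' @param panel long data.frame (`compound_id`, `bucket`, `gene`,
#'   `replicate`, `ddct`).
#' @param conditions a [condition_table()].
#' @param genes panel gene list.
#' @return data.frame (`compound_id`, `bucket`, `truth`, `gene`,
#'   `mean_ddct`, `fold_change`, `p_value`, `imputed`).
#' @export
summarize_qpcr <- function(panel, conditions, genes = qpcr_panel_genes()) {
  cond <- as.data.frame(conditions)
  out <- list()
  for (i in seq_len(nrow(cond))) {
    if (cond$cytotoxic[i]) {
      rec <- impute_cytotoxic(genes)
    } else {
      sel <- panel$compound_id == cond$compound_id[i] &
        panel$bucket == cond$bucket[i]
      if (!any(sel)) {
        stop("no qPCR replicates for condition ", cond$compound_id[i],
             " / ", cond$bucket[i])
      }
      rec <- do.call(rbind, lapply(split(panel[sel, ], panel$gene[sel]),
        function(g) {
          r <- ddct_fold_change(g$ddct)
          data.frame(gene = g$gene[1], mean_ddct = r$mean_ddct,
                     p_value = r$p_value, fold_change = r$fold_change,
                     imputed = FALSE)
        }))
    }
    rec$compound_id <- cond$compound_id[i]
    rec$bucket <- cond$bucket[i]
    rec$truth <- cond$truth[i]
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("compound_id", "bucket", "truth", "gene", "mean_ddct",
          "fold_change", "p_value", "imputed")]
}

#' SPS-like classification of the qPCR panel
#'
#' A gene counts as significantly deregulated when its absolute signed
#' fold-change strictly exceeds `fc_cut` and its p-value is strictly below
#' `alpha` (undefined p-values never count). A condition is test-positive
#' when at least one panel gene is significant; imputed cytotoxic records
#' always are.
#'
#' @param panel_summary output of [summarize_qpcr()].
#' @param alpha,fc_cut significance cuts.
#' @return a `score_set` whose score is the number of significant genes
#'   (positive iff score > 0), plus per-condition columns in
#'   `attr(, "details")`.
#' @export
classify_sps_like <- function(panel_summary, alpha = 0.05, fc_cut = 2) {
  sig <- !is.na(panel_summary$p_value) & panel_summary$p_value < alpha &
    abs(panel_summary$fold_change) > fc_cut
  key <- paste(panel_summary$compound_id, panel_summary$bucket)
  n_sig <- tapply(sig, key, sum)
  first <- !duplicated(key)
  df <- data.frame(
    compound_id = panel_summary$compound_id[first],
    bucket = panel_summary$bucket[first],
    truth = panel_summary$truth[first],
    cytotoxic = tapply(panel_summary$imputed, key, any)[key[first]],
    score = as.numeric(n_sig[key[first]]),
    cytotox_assigned = tapply(panel_summary$imputed, key, any)[key[first]],
    substituted_from_1x = FALSE)
  new_score_set(df, "sps")
}

#' Top-1000-like classification of the qPCR panel
#'
#' Reuses the leave-one-compound-out penalized-logistic machinery with the
#' replicate delta-delta-CT values of the seven panel genes as features
#' (all genes enter; the variance pre-selection is the identity at
#' `k = number of genes`). Cytotoxic conditions receive probability 1.
#'
#' @param panel long replicate-level panel as in [summarize_qpcr()].
#' @param conditions a [condition_table()].
#' @param nfolds,seed,standardize as [loo_predict()].
#' @return as [loo_predict()].
#' @export
classify_top1000_like <- function(panel, conditions, nfolds = 10, seed = 1,
                                  standardize = TRUE) {
  genes <- sort(unique(panel$gene))
  sample_id <- paste(panel$compound_id, panel$bucket, panel$replicate,
                     sep = "_")
  mat <- matrix(NA_real_, length(genes), length(unique(sample_id)),
                dimnames = list(genes, unique(sample_id)))
  mat[cbind(match(panel$gene, genes), match(sample_id, colnames(mat)))] <-
    panel$ddct
  if (anyNA(mat)) stop("incomplete panel: every replicate needs all genes")
  first <- !duplicated(sample_id)
  samples <- data.frame(sample_id = sample_id[first],
                        compound_id = panel$compound_id[first],
                        concentration_label = panel$bucket[first],
                        replicate = panel$replicate[first])
  nd <- structure(list(diffs = mat, samples = samples),
                  class = "normalized_differences")
  loo_predict(nd, conditions, k = length(genes), nfolds = nfolds,
              seed = seed, standardize = standardize)
}
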