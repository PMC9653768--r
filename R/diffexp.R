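#' Normalize an expression study to its controls
#'
#' For each non-control sample the mean of its matched control samples is
#' subtracted probe-set-wise; samples without matched controls fall back to
#' the batch-wise mean of the control samples in their batch. Because batch
#' effects are shared with the controls that are subtracted, this
#' differencing removes them. The result keeps one column per treated
#' replicate.
#'
#' @param study an `expression_study`.
#' @return a `normalized_differences`: list with `diffs` (probe sets x
#'   treated samples) and `samples` (metadata of the treated samples).
#' @export
normalize_to_controls <- function(study) {
  mat <- study$matrix
  samples <- study$samples
  control_ids <- samples$sample_id[samples$is_control]
  treated <- samples[!samples$is_control, , drop = FALSE]
  diffs <- matrix(NA_real_, nrow(mat), nrow(treated),
                  dimnames = list(rownames(mat), treated$sample_id))
  for (i in seq_len(nrow(treated))) {
    matched <- parse_id_list(treated$matched_controls[i])
    if (!length(matched)) {
      matched <- intersect(
        control_ids, samples$sample_id[samples$batch == treated$batch[i]])
      if (!length(matched)) {
        stop("sample ", treated$sample_id[i],
             " cannot be resolved to any control")
      }
    }
    ctrl_mean <- rowMeans(mat[, matched, drop = FALSE])
    diffs[, i] <- mat[, treated$sample_id[i]] - ctrl_mean
  }
  structure(list(diffs = diffs, samples = treated),
            class = "normalized_differences")
}

#' Extract one condition's replicate differences
#'
#' @param nd a `normalized_differences`.
#' @param compound_id,bucket condition key; the bucket is matched against
#'   the sample `concentration_label`.
#' @return probe sets x replicates matrix.
#' @export
condition_diffs <- function(nd, compound_id, bucket) {
  keep <- nd$samples$compound_id == compound_id &
    nd$samples$concentration_label == bucket
  if (!any(keep)) stop("no samples for condition ", compound_id, " / ", bucket)
  nd$diffs[, keep, drop = FALSE]
}

trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  repeat {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Fit the scaled-F prior of the empirical-Bayes variance model
#'
#' Sample variances are modelled as `s_g^2 ~ s0^2 F(d_g, d0)`; the prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by
#' moment matching on `log s_g^2` via the digamma/trigamma equations.
#' Zero variances are excluded from estimation. When the observed spread
#' of log-variances does not exceed its sampling expectation, `d0` is
#' infinite (complete shrinkage).
#'
#' @param s2 vector of sample variances.
#' @param df residual degrees of freedom (scalar or vector).
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) stop("all variances are zero; prior unidentifiable")
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated one-sample t-test
#'
#' Tests, per probe set, whether the mean of the control-normalized
#' replicate differences is zero. The per-probe-set variance is shrunk
#' toward a prior estimated from all probe sets:
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` with `d_g = n - 1`;
#' the statistic `m_g / (s_tilde sqrt(1/n))` is referred to a t
#' distribution with `d0 + d_g` degrees of freedom. At `d0 = 0` this is the
#' ordinary one-sample t-test; at `d0 = Inf` all probe sets share `s0^2`.
#'
#' @param diffs probe sets x replicates matrix for one condition (>= 2
#'   replicates).
#' @param prior optional list `(d0, s0_sq)` overriding the estimated prior
#'   (use `list(d0 = 0)` for the unmoderated limit).
#' @return a `diffexp_table` data.frame with columns `probe_set`,
#'   `log2_fc`, `fc` (signed linear fold-change), `p_raw`, `p_adj`, and an
#'   `ebayes` attribute carrying the prior used.
#' @export
moderated_t_test <- function(diffs, prior = NULL) {
  n <- ncol(diffs)
  if (n < 2) stop("need >= 2 replicates for the one-sample test")
  m <- rowMeans(diffs)
  dg <- n - 1
  s2 <- rowSums((diffs - m)^2) / dg
  if (is.null(prior)) {
    prior <- fit_variance_prior(s2, dg)
  } else {
    if (is.null(prior$d0)) stop("prior must contain d0")
    if (prior$d0 > 0 && is.null(prior$s0_sq)) {
      prior$s0_sq <- fit_variance_prior(s2, dg)$s0_sq
    }
  }
  d0 <- prior$d0
  s0_sq <- if (is.null(prior$s0_sq)) NA_real_ else prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) {
    rep_len(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  if (any(s_tilde_sq == 0)) {
    if (all(s2 == 0)) stop("all variances are zero; prior unidentifiable")
    # zero posterior variance only with d0 = 0 and zero sample variance
    s_tilde_sq[s_tilde_sq == 0] <- NA_real_
  }
  t_stat <- m / sqrt(s_tilde_sq / n)
  df_total <- d0 + dg
  p_raw <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  p_raw[m == 0] <- 1
  t_stat[m == 0] <- 0
  out <- data.frame(probe_set = rownames(diffs), log2_fc = m,
                    fc = ifelse(m >= 0, 2^m, -(2^(-m))),
                    t = t_stat, p_raw = p_raw,
                    p_adj = bh_adjust(ifelse(is.na(p_raw), 1, p_raw)),
                    row.names = NULL)
  attr(out, "ebayes") <- list(d0 = d0, s0_sq = s0_sq)
  class(out) <- c("diffexp_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adj_(i) = min_{j >= i} min(1, p_(j) m / j)` in ascending sort order,
#' mapped back to the input order.
#'
#' @param p vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  desc <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  adj[desc] <- pmin(1, cummin(m / (m:1) * p[desc]))
  adj
}

#' Select significant probe sets (SPS)
#'
#' A probe set is significant when its FDR-adjusted p-value is strictly
#' below `alpha` and its absolute linear fold-change is strictly above
#' `fc_cut`. Both inequalities are strict; boundary values are excluded.
#'
#' @param table a `diffexp_table`.
#' @param alpha FDR cut (default 0.05).
#' @param fc_cut linear fold-change cut (default 2, i.e. |log2FC| > 1).
#' @return list with `up`, `down` (probe-set id vectors) and `n` (total).
#' @export
select_sps <- function(table, alpha = 0.05, fc_cut = 2) {
  sig <- !is.na(table$p_adj) & table$p_adj < alpha & abs(table$fc) > fc_cut
  up <- table$probe_set[sig & table$log2_fc > 0]
  down <- table$probe_set[sig & table$log2_fc < 0]
  list(up = up, down = down, n = length(up) + length(down))
}

#' Differential expression for every condition of a study
#'
#' Runs [moderated_t_test()] and [select_sps()] per non-cytotoxic
#' condition and tabulates SPS counts.
#'
#' @param nd a `normalized_differences`.
#' @param conditions a [condition_table()].
#' @param alpha,fc_cut selection cuts, see [select_sps()].
#' @return list with `counts` (the condition table plus `up`, `down`,
#'   `count`, `NA` for cytotoxic conditions) and `tables` / `sps`
#'   (per-condition results keyed `"compound bucket"`).
#' @export
diffexp_all <- function(nd, conditions, alpha = 0.05, fc_cut = 2) {
  counts <- as.data.frame(conditions)
  counts$up <- NA_integer_; counts$down <- NA_integer_
  tables <- list(); sps <- list()
  for (i in seq_len(nrow(counts))) {
    if (counts$cytotoxic[i]) next
    key <- paste(counts$compound_id[i], counts$bucket[i])
    tab <- moderated_t_test(
      condition_diffs(nd, counts$compound_id[i], counts$bucket[i]))
    sel <- select_sps(tab, alpha = alpha, fc_cut = fc_cut)
    tables[[key]] <- tab
    sps[[key]] <- sel
    counts$up[i] <- length(sel$up)
    counts$down[i] <- length(sel$down)
  }
  counts$count <- counts$up + counts$down
  list(counts = condition_table(counts), tables = tables, sps = sps)
}
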