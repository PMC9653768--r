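#' Principal components of condition means
#'
#' Replicates of each condition are averaged probe-set-wise; the principal
#' components of the centered condition-mean matrix are computed by
#' singular value decomposition. Optionally restricts to the `top_k` probe
#' sets with highest variance across condition means first.
#'
#' @param nd a `normalized_differences`.
#' @param top_k optional number of top-variance probe sets (e.g. 100).
#' @return list with `proportions` (explained-variance proportions, summing
#'   to 1), `coordinates` (conditions x PCs), `sdev`.
#' @export
condition_mean_pca <- function(nd, top_k = NULL) {
  key <- paste(nd$samples$compound_id, nd$samples$concentration_label,
               sep = "_")
  groups <- unique(key)
  if (length(groups) < 2) stop("need >= 2 conditions for a PCA")
  means <- vapply(groups,
                  function(g) rowMeans(nd$diffs[, key == g, drop = FALSE]),
                  numeric(nrow(nd$diffs)))
  if (!is.null(top_k)) {
    keep <- select_top_variance(means, top_k)
    means <- means[keep, , drop = FALSE]
  }
  x <- t(means)
  x <- sweep(x, 2, colMeans(x))
  if (sum(x^2) == 0) stop("total variance is zero; PCA undefined")
  sv <- svd(x)
  ev <- sv$d^2
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  dimnames(coords) <- list(groups, paste0("PC", seq_along(sv$d)))
  list(proportions = ev / sum(ev), coordinates = coords,
       sdev = sv$d / sqrt(max(1, nrow(x) - 1)))
}

#' Partition teratogen-deregulated probe sets across two systems
#'
#' Takes per-compound SPS sets for each system, keeps only probe sets
#' deregulated by at least one teratogen in that system (probe sets
#' exclusively deregulated by non-teratogens are discarded), and splits the
#' union into the three disjoint sets: deregulated in both systems, or
#' exclusively in one.
#'
#' @param sps_a,sps_b named lists, compound id -> character vector of SPS.
#' @param truth named character vector of compound truths.
#' @return list with `overlap`, `a_only`, `b_only`.
#' @export
venn_partition <- function(sps_a, sps_b, truth) {
  teratogen_union <- function(sps) {
    ter <- names(sps)[truth[names(sps)] == "teratogen"]
    unique(unlist(sps[ter], use.names = FALSE))
  }
  ua <- teratogen_union(sps_a)
  ub <- teratogen_union(sps_b)
  list(overlap = intersect(ua, ub),
       a_only = setdiff(ua, ub),
       b_only = setdiff(ub, ua))
}

#' Two-level ranking of top genes
#'
#' Each entry of `sps_tables` is one (compound, system) unit: a data.frame
#' of that unit's significant probe sets with their `log2_fc`. For the
#' single-system analysis pass one entry per compound; for the overlap
#' analysis pass the entries of both systems together, so per-system
#' compound counts are summed. Ranking: first by the number of entries
#' deregulating the probe set, then by the mean log2 fold-change over those
#' entries (absolute by default; signed available for the single-system
#' reading), descending, with probe-set id as the final tie-break. Probe
#' sets of one gene are collapsed to the highest-ranked one. Optionally
#' keeps only display-grade probe-set suffixes (`_at`, `_a_at`, `_s_at`).
#'
#' @param sps_tables list of data.frames with `probe_set`, `log2_fc`.
#' @param gene_map named character vector, probe set -> gene symbol.
#' @param restrict optional probe-set universe (e.g. a Venn partition set).
#' @param abs_fc use absolute log2 fold-changes for the second key.
#' @param filter_suffixes drop probe sets with non-display suffixes
#'   (`_x_at` and other lettered variants).
#' @return data.frame (`probe_set`, `gene`, `n_compounds`,
#'   `mean_log2fc`, `mapped`), ordered by rank, one row per gene.
#' @export
rank_top_genes <- function(sps_tables, gene_map, restrict = NULL,
                           abs_fc = TRUE, filter_suffixes = FALSE) {
  all_rows <- do.call(rbind, lapply(sps_tables, function(t)
    t[, c("probe_set", "log2_fc"), drop = FALSE]))
  if (!is.null(restrict)) {
    all_rows <- all_rows[all_rows$probe_set %in% restrict, , drop = FALSE]
  }
  if (!nrow(all_rows)) {
    return(data.frame(probe_set = character(), gene = character(),
                      n_compounds = integer(), mean_log2fc = numeric(),
                      mapped = logical()))
  }
  fc <- if (abs_fc) abs(all_rows$log2_fc) else all_rows$log2_fc
  n <- tapply(fc, all_rows$probe_set, length)
  m <- tapply(fc, all_rows$probe_set, mean)
  out <- data.frame(probe_set = names(n), n_compounds = as.integer(n),
                    mean_log2fc = as.numeric(m), row.names = NULL)
  if (filter_suffixes) {
    ok <- grepl("_at$", out$probe_set) &
      (grepl("_(a|s)_at$", out$probe_set) |
         !grepl("_[a-z]_at$", out$probe_set))
    out <- out[ok, , drop = FALSE]
  }
  out$mapped <- out$probe_set %in% names(gene_map)
  out$gene <- ifelse(out$mapped, unname(gene_map[out$probe_set]),
                     out$probe_set)
  out <- out[order(-out$n_compounds, -out$mean_log2fc, out$probe_set), ,
             drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("probe_set", "gene", "n_compounds", "mean_log2fc", "mapped")]
}

#' Fisher overrepresentation of a probe-set selection
#'
#' One-sided hypergeometric tail per term on the 2x2 table (in-selection x
#' in-term) over the given universe, with Benjamini-Hochberg adjustment
#' across terms. Terms with no universe members are skipped with a warning.
#'
#' @param sps selected probe sets (subset of `universe`).
#' @param universe all tested probe sets.
#' @param term_map named list, term id -> probe-set vector.
#' @return data.frame (`term`, `n_term`, `n_overlap`, `p`, `p_adj`).
#' @export
fisher_overrepresentation <- function(sps, universe, term_map) {
  bad <- setdiff(sps, universe)
  if (length(bad)) {
    stop("selection outside the universe: ", paste(bad, collapse = ", "))
  }
  members <- lapply(term_map, intersect, universe)
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning("terms with no universe members skipped: ",
            paste(names(term_map)[empty], collapse = ", "))
    members <- members[!empty]
  }
  N <- length(universe); n <- length(sps)
  p <- vapply(members, function(mem) {
    K <- length(mem)
    x <- length(intersect(sps, mem))
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  }, 0)
  data.frame(term = names(members),
             n_term = lengths(members),
             n_overlap = vapply(members, function(mem)
               length(intersect(sps, mem)), 0L),
             p = unname(p), p_adj = bh_adjust(unname(p)),
             row.names = NULL)
}

# topological order of terms, children before parents; dag: data.frame
# (child, parent), acyclic
topo_child_first <- function(terms, dag) {
  if (is.null(dag) || !nrow(dag)) return(terms)
  children_of <- split(dag$child, dag$parent)
  remaining <- terms
  done <- character(0)
  order <- character(0)
  while (length(remaining)) {
    ready <- vapply(remaining, function(t) {
      ch <- intersect(children_of[[t]], terms)
      all(ch %in% done)
    }, TRUE)
    if (!any(ready)) stop("term hierarchy contains a cycle")
    order <- c(order, remaining[ready])
    done <- c(done, remaining[ready])
    remaining <- remaining[!ready]
  }
  order
}

ancestors_map <- function(terms, dag) {
  parents_of <- split(dag$parent, dag$child)
  anc <- list()
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    direct <- intersect(parents_of[[t]], terms)
    res <- direct
    for (p in direct) res <- union(res, get_anc(p))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  anc
}

#' Overrepresentation with bottom-up elimination ('elim')
#'
#' Annotations are first propagated upward through the term hierarchy
#' (probe sets annotated to a child count for all ancestors). Terms are
#' then tested most-specific-first: whenever a term's Fisher p-value falls
#' strictly below `elim_cut`, its annotated probe sets are removed from all
#' of its ancestors before those are tested, so general terms are not
#' called significant on the strength of signal already explained by a
#' specific descendant. With `elim_cut = 0` nothing is ever eliminated and
#' the result equals plain [fisher_overrepresentation()] on the propagated
#' annotations. Significance is called at BH-adjusted p < `alpha`.
#'
#' @param sps,universe,term_map as [fisher_overrepresentation()].
#' @param dag data.frame (`child`, `parent`) term edges; `NULL` for a flat
#'   term set.
#' @param elim_cut elimination threshold on the raw p-value (default 0.01).
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame (`term`, `n_annotated`, `n_after_elim`, `n_overlap`,
#'   `p`, `p_adj`, `significant`).
#' @export
elim_overrepresentation <- function(sps, universe, term_map, dag = NULL,
                                    elim_cut = 0.01, alpha = 0.05) {
  bad <- setdiff(sps, universe)
  if (length(bad)) {
    stop("selection outside the universe: ", paste(bad, collapse = ", "))
  }
  terms <- names(term_map)
  order <- topo_child_first(terms, dag)
  ann <- lapply(term_map, intersect, universe)
  # propagate annotations upward, child-first so chains accumulate
  if (!is.null(dag) && nrow(dag)) {
    for (t in order) {
      for (p in intersect(dag$parent[dag$child == t], terms)) {
        ann[[p]] <- union(ann[[p]], ann[[t]])
      }
    }
    anc <- ancestors_map(terms, dag)
  } else {
    anc <- stats::setNames(vector("list", length(terms)), terms)
  }
  n_annotated <- lengths(ann)[order]
  N <- length(universe); n_sel <- length(sps)
  p <- numeric(length(order)); names(p) <- order
  n_after <- integer(length(order)); names(n_after) <- order
  n_overlap <- integer(length(order)); names(n_overlap) <- order
  for (t in order) {
    mem <- ann[[t]]
    K <- length(mem)
    x <- length(intersect(sps, mem))
    n_after[t] <- K; n_overlap[t] <- x
    p[t] <- if (K == 0) 1 else
      stats::phyper(x - 1, K, N - K, n_sel, lower.tail = FALSE)
    if (p[t] < elim_cut && length(anc[[t]])) {
      for (a in anc[[t]]) ann[[a]] <- setdiff(ann[[a]], mem)
    }
  }
  adj <- bh_adjust(unname(p))
  data.frame(term = order, n_annotated = unname(n_annotated),
             n_after_elim = unname(n_after), n_overlap = unname(n_overlap),
             p = unname(p), p_adj = adj, significant = adj < alpha,
             row.names = NULL)
}
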