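test_that("condition-mean PCA normalizes variance and flags degenerate input", {
  sim <- generate_study(separable_config(seed = 23, n_probe_sets = 120,
                                         n_dereg = 40))
  nd <- normalize_to_controls(sim$study)
  pca <- condition_mean_pca(nd)
  expect_equal(sum(pca$proportions), 1)
  expect_equal(nrow(pca$coordinates), 16)  # 8 compounds x 2 buckets
  top <- condition_mean_pca(nd, top_k = 20)
  expect_equal(sum(top$proportions), 1)

  one <- nd
  keep <- nd$samples$compound_id == "T01" & nd$samples$concentration_label == "1x"
  one$diffs <- nd$diffs[, keep, drop = FALSE]
  one$samples <- nd$samples[keep, , drop = FALSE]
  expect_error(condition_mean_pca(one), ">= 2 conditions")

  flat <- nd
  flat$diffs[] <- 3
  expect_error(condition_mean_pca(flat), "variance is zero")
})

test_that("a dominant planted axis captures most PCA variance", {
  # one strong shared axis: all teratogens deregulate the same probe sets
  n <- 200
  probes <- sprintf("p%03d", 1:n)
  conds <- c(sprintf("T%02d_1x", 1:6), sprintf("N%02d_1x", 1:4))
  diffs <- matrix(rnorm(n * 30, sd = 0.05), n, 30)
  axis <- c(rep(3, 40), rep(0, n - 40))
  strength <- rep(c(rep(1, 6), rep(0, 4)), each = 3)
  diffs <- diffs + outer(axis, strength)
  samples <- data.frame(
    sample_id = paste0("s", 1:30),
    compound_id = rep(sub("_1x", "", conds), each = 3),
    concentration_label = "1x", replicate = rep(1:3, 10))
  rownames(diffs) <- probes; colnames(diffs) <- samples$sample_id
  nd <- structure(list(diffs = diffs, samples = samples),
                  class = "normalized_differences")
  pca <- condition_mean_pca(nd)
  expect_gt(pca$proportions[1], 0.9)
})

test_that("Venn partition keeps only teratogen-deregulated probe sets", {
  truth <- c(T1 = "teratogen", T2 = "teratogen", N1 = "non_teratogen")
  sps_a <- list(T1 = c("p1", "p2"), N1 = "p9")
  sps_b <- list(T2 = c("p2", "p3"), N1 = "p9")
  v <- venn_partition(sps_a, sps_b, truth)
  expect_equal(v$overlap, "p2")
  expect_equal(v$a_only, "p1")
  expect_equal(v$b_only, "p3")
  expect_false("p9" %in% unlist(v))
  # disjointness and union
  expect_length(intersect(v$overlap, c(v$a_only, v$b_only)), 0)
  same <- venn_partition(sps_a["T1"], sps_a["T1"], truth)
  expect_length(same$a_only, 0)
  expect_length(same$b_only, 0)
})

test_that("top-gene ranking is lexicographic with gene collapse", {
  tab <- function(ps, fc) data.frame(probe_set = ps, log2_fc = fc)
  # p1 hit by 5 entries with small FC, p2 by 4 with large FC
  tables <- c(
    replicate(5, tab(c("p1_at"), 0.5), simplify = FALSE),
    replicate(4, tab(c("p2_at"), 5), simplify = FALSE))
  gene_map <- c(p1_at = "G1", p2_at = "G2")
  r <- rank_top_genes(tables, gene_map)
  expect_equal(r$gene, c("G1", "G2"))
  expect_equal(r$n_compounds, c(5L, 4L))

  # overlap context: 3 + 4 entries across two systems sum to 7
  tables2 <- c(replicate(3, tab("p1_at", 1), simplify = FALSE),
               replicate(4, tab("p1_at", -1), simplify = FALSE))
  r2 <- rank_top_genes(tables2, gene_map)
  expect_equal(r2$n_compounds, 7L)
  expect_equal(r2$mean_log2fc, 1)  # absolute by default
  expect_equal(rank_top_genes(tables2, gene_map, abs_fc = FALSE)$mean_log2fc,
               (3 - 4) / 7)

  # two probe sets of one gene: the higher-ranked one wins
  tables3 <- list(tab(c("p3_at", "p4_at", "p5_at"), c(2, 1, 3)),
                  tab(c("p3_at", "p5_at"), c(2, 3)))
  map3 <- c(p3_at = "G3", p4_at = "G3", p5_at = "G5")
  r3 <- rank_top_genes(tables3, map3)
  expect_equal(r3$probe_set[r3$gene == "G3"], "p3_at")

  # unmapped probe sets are retained and flagged
  r4 <- rank_top_genes(list(tab("px_at", 1)), gene_map)
  expect_equal(r4$gene, "px_at")
  expect_false(r4$mapped)

  # display filter keeps _at / _a_at / _s_at, drops _x_at
  tables5 <- list(tab(c("1_at", "2_a_at", "3_s_at", "4_x_at"), 1))
  r5 <- rank_top_genes(tables5, character(0), filter_suffixes = TRUE)
  expect_setequal(r5$probe_set, c("1_at", "2_a_at", "3_s_at"))
})

test_that("Fisher overrepresentation matches closed forms and enumeration", {
  universe <- sprintf("p%02d", 1:20)
  term_map <- list(all = universe, five = universe[1:5], none = character(0))
  expect_warning(res <- fisher_overrepresentation(universe[1:5], universe,
                                                  term_map),
                 "none")
  expect_equal(res$p[res$term == "all"], 1)
  expect_equal(res$p[res$term == "five"], 1 / choose(20, 5))

  empty <- fisher_overrepresentation(character(0), universe,
                                     list(t = universe[1:4]))
  expect_equal(empty$p, 1)

  expect_error(fisher_overrepresentation("zz", universe, term_map), "zz")

  # enumeration oracle on random small tables
  set.seed(88)
  for (i in 1:15) {
    N <- sample(8:25, 1)
    uni <- sprintf("u%02d", 1:N)
    term <- sample(uni, sample(1:N, 1))
    sel <- sample(uni, sample(1:N, 1))
    p <- suppressWarnings(
      fisher_overrepresentation(sel, uni, list(t = term))$p)
    x <- length(intersect(sel, term))
    expect_equal(p, hyper_tail_oracle(x, length(term), N, length(sel)))
  }
})

test_that("elim reduces to plain Fisher without hierarchy or elimination", {
  universe <- sprintf("p%02d", 1:20)
  term_map <- list(a = universe[1:6], b = universe[5:12], c = universe[10:20])
  sel <- universe[c(1:4, 11, 15)]
  plain <- fisher_overrepresentation(sel, universe, term_map)

  flat <- elim_overrepresentation(sel, universe, term_map, dag = NULL)
  expect_equal(flat$p[match(plain$term, flat$term)], plain$p)

  dag <- data.frame(child = c("a", "b"), parent = c("b", "c"))
  nocut <- elim_overrepresentation(sel, universe, term_map, dag, elim_cut = 0)
  # with propagation, parents accumulate child annotations before testing:
  # b absorbs a (p1..p12), c then absorbs the propagated b (everything)
  prop_map <- list(a = universe[1:6], b = universe[1:12], c = universe)
  prop <- fisher_overrepresentation(sel, universe, prop_map)
  expect_equal(nocut$p[match(prop$term, nocut$term)], prop$p)
})

test_that("a significant child is eliminated from its ancestors", {
  universe <- sprintf("p%02d", 1:10)
  term_map <- list(child = universe[1:4], parent = universe[1:6],
                   other = universe[7:10])
  dag <- data.frame(child = "child", parent = "parent")
  sel <- universe[1:4]  # all selection sits in the child
  res <- elim_overrepresentation(sel, universe, term_map, dag,
                                 elim_cut = 0.05)
  p_child <- res$p[res$term == "child"]
  p_parent <- res$p[res$term == "parent"]
  expect_lt(p_child, 0.05)
  expect_gte(p_parent, p_child)
  # the parent was tested on the emptied annotation set
  expect_equal(res$n_after_elim[res$term == "parent"], 2L)
  expect_equal(res$n_overlap[res$term == "parent"], 0L)

  # child above the cut leaves the parent untouched
  res2 <- elim_overrepresentation(sel, universe, term_map, dag,
                                  elim_cut = 1e-6)
  plain <- fisher_overrepresentation(sel, universe,
                                     list(parent = universe[1:6]))
  expect_equal(res2$p[res2$term == "parent"], plain$p)

  cyclic <- data.frame(child = c("child", "parent"),
                       parent = c("parent", "child"))
  expect_error(elim_overrepresentation(sel, universe, term_map, cyclic),
               "cycle")
})
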