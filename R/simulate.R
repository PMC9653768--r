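#' Simulation configuration for synthetic studies
#'
#' Describes a synthetic transcriptomics study with the statistical
#' structure the analysis pipeline assumes: a per-probe-set baseline,
#' additive probe-set-specific batch effects shared by every sample of a
#' batch (including its controls, so control differencing cancels them
#' exactly), compound-specific planted deregulation, and replicate-level
#' Gaussian noise. Cytotoxic conditions contribute no expression columns at
#' all, mirroring the operational definition of cytotoxicity in the assay
#' (no adherent cells / insufficient RNA), not an extreme signature.
#'
#' @param compounds data.frame with one row per condition: `compound_id`,
#'   `truth`, `bucket`, `n_deregulated`, `cytotoxic`, and optionally
#'   `n_replicates` (default 3).
#' @param n_probe_sets number of probe sets.
#' @param responsive_fraction fraction of probe sets forming the shared
#'   toxicant-responsive pool. Every compound plants its deregulation on a
#'   random subset of this pool, and each pool probe set has one fixed
#'   response direction, so teratogens share a common directional
#'   signature — the structure the cross-compound classifier exploits.
#'   Must be large enough that the pool covers the largest
#'   `n_deregulated`.
#' @param effect_size_range range of |log2 fold-change| of planted probe
#'   sets; the lower bound must be >= 1 so planted effects exceed the
#'   |FC| > 2 selection cut in expectation.
#' @param noise_sd replicate-level Gaussian standard deviation.
#' @param batch_sd standard deviation of batch effects.
#' @param n_batches number of batches; each receives its own control
#'   replicate set.
#' @param n_control_replicates control samples per batch.
#' @param seed integer seed; identical configs produce identical studies.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(compounds,
                              n_probe_sets = 5000,
                              responsive_fraction = 0.5,
                              effect_size_range = c(1.2, 3.0),
                              noise_sd = 0.25,
                              batch_sd = 0.5,
                              n_batches = 4,
                              n_control_replicates = 3,
                              seed = 1) {
  if (!"n_replicates" %in% names(compounds)) compounds$n_replicates <- 3L
  required <- c("compound_id", "truth", "bucket", "n_deregulated", "cytotoxic")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols)) {
    stop("compounds lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(compounds$n_deregulated > n_probe_sets)) {
    stop("n_deregulated exceeds n_probe_sets for: ",
         paste(compounds$compound_id[compounds$n_deregulated > n_probe_sets],
               collapse = ", "))
  }
  pool_size <- ceiling(responsive_fraction * n_probe_sets)
  if (any(compounds$n_deregulated > pool_size)) {
    stop("n_deregulated exceeds the responsive pool (",
         pool_size, " probe sets) for: ",
         paste(compounds$compound_id[compounds$n_deregulated > pool_size],
               collapse = ", "))
  }
  if (effect_size_range[1] < 1) {
    stop("effect_size_range lower bound must be >= 1 (|FC| > 2 cut)")
  }
  structure(list(compounds = compounds, n_probe_sets = n_probe_sets,
                 responsive_fraction = responsive_fraction,
                 effect_size_range = effect_size_range, noise_sd = noise_sd,
                 batch_sd = batch_sd, n_batches = n_batches,
                 n_control_replicates = n_control_replicates,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default synthetic study: 12 teratogens, 8 non-teratogens
#'
#' The default stated world for end-to-end checks: 12 teratogenic compounds
#' planting between 200 and 2000 deregulated probe sets per condition
#' (teratogens in the reference screen deregulate hundreds to thousands)
#' and 8 non-teratogens planting none, each at both concentration buckets
#' with three replicates, 5000 probe sets, no cytotoxic conditions.
#'
#' @param seed integer seed (also drives the per-compound deregulation draws).
#' @return a [simulation_config()].
#' @export
default_simulation_config <- function(seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("T%02d", 1:12), sprintf("N%02d", 1:8))
  truth <- rep(c("teratogen", "non_teratogen"), c(12, 8))
  grid <- expand.grid(compound_id = ids, bucket = c("1x", "20x"),
                      stringsAsFactors = FALSE)
  grid$truth <- truth[match(grid$compound_id, ids)]
  grid$n_deregulated <- ifelse(grid$truth == "teratogen",
                               sample(200:2000, nrow(grid), replace = TRUE), 0L)
  grid$cytotoxic <- FALSE
  simulation_config(grid, seed = seed)
}

compound_stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * k) %% .Machine$integer.max)
}

#' Generate a synthetic expression study
#'
#' Samples of non-cytotoxic conditions are
#' `baseline + batch effect + planted effect + noise`; controls are
#' `baseline + batch effect + noise`. Random streams are split per
#' compound, so adding a compound to the configuration leaves all other
#' compounds' data unchanged. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `study` (an `expression_study`), `manifest` (the
#'   ground truth: one row per planted probe set with its signed log2
#'   fold-change), and `conditions` (a [condition_table()]).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cmp <- config$compounds
  n <- config$n_probe_sets
  probe_sets <- sprintf("PS%05d_at", seq_len(n))

  set.seed(config$seed)
  baseline <- stats::rnorm(n, mean = 7, sd = 1.5)
  batch_eff <- matrix(stats::rnorm(n * config$n_batches, sd = config$batch_sd),
                      nrow = n)
  # shared toxicant-responsive pool with one fixed direction per probe set,
  # drawn from the global stream so compound streams stay independent
  pool <- sample.int(n, ceiling(config$responsive_fraction * n))
  pool_sign <- sample(c(-1, 1), length(pool), replace = TRUE)

  tested <- cmp[!cmp$cytotoxic, , drop = FALSE]
  tested$batch <- ((seq_len(nrow(tested)) - 1L) %% config$n_batches) + 1L

  # controls, one replicate set per batch, from the global stream
  cols <- list(); meta <- list()
  for (b in seq_len(config$n_batches)) {
    for (r in seq_len(config$n_control_replicates)) {
      id <- sprintf("CTL_B%d_%d", b, r)
      cols[[id]] <- baseline + batch_eff[, b] + stats::rnorm(n, sd = config$noise_sd)
      meta[[id]] <- data.frame(sample_id = id, compound_id = "CTL",
                               concentration_label = "1x", replicate = r,
                               batch = paste0("B", b), is_control = TRUE,
                               matched_controls = "")
    }
  }
  control_ids_by_batch <- split(
    names(meta), vapply(meta, function(m) m$batch, ""))

  manifest <- list()
  compound_ids <- unique(cmp$compound_id)
  for (k in seq_along(compound_ids)) {
    set.seed(compound_stream_seed(config$seed, k))
    rows <- which(tested$compound_id == compound_ids[k])
    for (i in rows) {
      nd <- tested$n_deregulated[i]
      effect <- numeric(n)
      if (nd > 0) {
        take <- sample.int(length(pool), nd)
        planted <- pool[take]
        sign <- pool_sign[take]
        size <- stats::runif(nd, config$effect_size_range[1],
                             config$effect_size_range[2])
        effect[planted] <- sign * size
        manifest[[length(manifest) + 1L]] <- data.frame(
          compound_id = tested$compound_id[i], bucket = tested$bucket[i],
          probe_set = probe_sets[planted], planted_log2fc = sign * size)
      }
      b <- tested$batch[i]
      batch_name <- paste0("B", b)
      batch_controls <- control_ids_by_batch[[batch_name]]
      for (r in seq_len(tested$n_replicates[i])) {
        id <- sprintf("%s_%s_%d", tested$compound_id[i], tested$bucket[i], r)
        cols[[id]] <- baseline + batch_eff[, b] + effect +
          stats::rnorm(n, sd = config$noise_sd)
        # replicate-paired matching: each treated replicate differs against
        # its own control, so within-condition differences stay independent
        # (sharing one control mean across replicates would correlate them
        # and make the one-sample test anti-conservative)
        meta[[id]] <- data.frame(
          sample_id = id, compound_id = tested$compound_id[i],
          concentration_label = tested$bucket[i], replicate = r,
          batch = batch_name, is_control = FALSE,
          matched_controls = batch_controls[(r - 1) %% length(batch_controls) + 1])
      }
    }
  }

  mat <- do.call(cbind, cols)
  rownames(mat) <- probe_sets
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL

  conditions <- condition_table(data.frame(
    compound_id = cmp$compound_id, bucket = cmp$bucket,
    concentration_label = cmp$bucket, truth = cmp$truth,
    cytotoxic = cmp$cytotoxic, substituted_from_1x = FALSE))

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(compound_id = character(), bucket = character(),
               probe_set = character(), planted_log2fc = numeric())

  list(study = validate_expression_study(new_expression_study(mat, samples)),
       manifest = manifest, conditions = conditions)
}

#' Generate synthetic qPCR delta-delta-CT replicates
#'
#' Adds Gaussian replicate noise around planted per-condition, per-gene
#' delta-delta-CT means. Planted means are recoverable by averaging as the
#' replicate count grows.
#'
#' @param planted data.frame with columns `compound_id`, `bucket`, `gene`,
#'   `ddct` (the planted mean).
#' @param n_replicates replicates per condition x gene; at least 2 (the
#'   one-sample t-test is undefined below that).
#' @param noise_sd replicate-level Gaussian standard deviation.
#' @param seed integer seed.
#' @return long data.frame (`compound_id`, `bucket`, `gene`, `replicate`,
#'   `ddct`).
#' @export
generate_qpcr <- function(planted, n_replicates = 3, noise_sd = 0.3, seed = 1) {
  if (n_replicates < 2) stop("need >= 2 replicates per condition")
  set.seed(seed)
  out <- planted[rep(seq_len(nrow(planted)), each = n_replicates), , drop = FALSE]
  out$replicate <- rep(seq_len(n_replicates), nrow(planted))
  out$ddct <- out$ddct + stats::rnorm(nrow(out), sd = noise_sd)
  rownames(out) <- NULL
  out[, c("compound_id", "bucket", "gene", "replicate", "ddct")]
}
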