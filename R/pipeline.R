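#' Pipeline configuration
#'
#' Exactly one of `sim` (synthetic mode) or `paths` (real-data mode: named
#' list with `gene_counts`, `tx_counts`, `samples`, `feature_map`) must be
#' provided.
#'
#' @param sim a [sim_config()] for synthetic mode, or `NULL`.
#' @param paths named list of input file paths for real-data mode, or `NULL`.
#' @param covariate_names covariates residualized out of both count levels.
#' @param min_count,min_frac,prior_count preprocessing parameters.
#' @param sd_mult PCA outlier threshold in standard deviations.
#' @param mi an [mi_params()].
#' @param hub_k hub degree threshold.
#' @param min_fold master-hub minimum fold.
#' @param q_thresh differential-expression FDR threshold.
#' @param validate a [perturb_config()], or `NULL` to skip the validation
#'   stage.
#' @param seed global seed recorded in every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            covariate_names = c("batch", "sex", "age", "bmi",
                                                paste0("cellpc", 1:5)),
                            min_count = 10, min_frac = 0.95, prior_count = 0.5,
                            sd_mult = 2, mi = mi_params(), hub_k = 10,
                            min_fold = 2, q_thresh = 0.05,
                            validate = perturb_config(), seed = 1L) {
  if (is.null(sim) == is.null(paths))
    stop("provide exactly one of 'sim' (synthetic mode) or 'paths'")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(paths)) {
    need <- c("gene_counts", "tx_counts", "samples", "feature_map")
    if (!all(need %in% names(paths)))
      stop("'paths' needs entries: ", paste(need, collapse = ", "))
    for (p in unlist(paths[need]))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(sim = sim, paths = paths, covariate_names = covariate_names,
                 min_count = min_count, min_frac = min_frac,
                 prior_count = prior_count, sd_mult = sd_mult, mi = mi,
                 hub_k = hub_k, min_fold = min_fold, q_thresh = q_thresh,
                 validate = validate, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every field of [pipeline_config()] can be set from a YAML file; missing
#' fields fall back to the defaults. `sim` and `mi`/`validate` sub-sections
#' map to [sim_config()], [mi_params()] and [perturb_config()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "mi", "validate"))]
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$mi)) args$mi <- do.call(mi_params, y$mi)
  if (!is.null(y$validate)) args$validate <- do.call(perturb_config, y$validate)
  do.call(pipeline_config, args)
}

config_digest <- function(config) {
  sprintf("%d", hash_strings(paste(deparse(unclass(config)), collapse = "")))
}

write_with_header <- function(df, path, digest, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config_digest=%s seed=%d", digest, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full two-group network comparison pipeline
#'
#' Executes, in order: simulate (or read) counts; preprocess gene and
#' transcript levels (filter, logCPM, residualize, drop-negative); moderated
#' differential expression at both levels plus isoform-specific DE; isoform
#' ratios; PCA outlier removal; per-group MI network inference; per-edge-type
#' median thresholding on the affected network; differential network analysis
#' (hubs, common hubs, unique-edge partition, master hubs in both directions,
#' modality subnetworks, hub modality composition); and, optionally, the
#' surrogate-graph embedding validation. All intermediates are written under
#' `outdir` with the config digest and seed in a header comment; identical
#' `(config, seed)` runs give identical outputs.
#'
#' Isoform-ratio features with (near-)zero variance across the retained
#' samples are dropped before network inference, with a message, since MI is
#' undefined for constant features.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return A `summary_report` list: per-network node/edge counts by type
#'   before and after thresholding, hub and common-hub counts, edge-partition
#'   percentages, master-hub counts by modality, modality-split percentages,
#'   and the validation accuracy.
#' @export
run_pipeline <- function(config, outdir = tempfile("isorewire_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (config %s): %s", name, digest,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- stage("input", {
    if (!is.null(config$sim)) {
      truth <- build_ground_truth(config$sim, seed = seed)
      sim <- simulate_counts(truth, config$sim, seed = seed + 1L)
      sim$truth <- truth
      sim
    } else {
      list(gene_counts = read_count_matrix(config$paths$gene_counts, "gene"),
           tx_counts = read_count_matrix(config$paths$tx_counts, "transcript"),
           samples = read_sample_table(config$paths$samples),
           feature_map = read_feature_map(config$paths$feature_map),
           truth = NULL)
    }
  })
  samples <- validate_sample_table(inputs$samples, inputs$gene_counts)

  corrected <- stage("preprocess", {
    gene <- preprocess_counts(inputs$gene_counts, samples,
                              config$covariate_names, config$min_count,
                              config$min_frac, config$prior_count)
    tx <- preprocess_counts(inputs$tx_counts, samples,
                            config$covariate_names, config$min_count,
                            config$min_frac, config$prior_count)
    list(gene = gene, tx = tx)
  })

  de <- stage("diffexpr", {
    gene_de <- moderated_de(corrected$gene, samples, q_thresh = config$q_thresh)
    tx_de <- moderated_de(corrected$tx, samples, q_thresh = config$q_thresh)
    iso <- isoform_specific_de(gene_de, tx_de, inputs$feature_map,
                               q_thresh = config$q_thresh)
    list(gene = gene_de, tx = tx_de, iso = iso)
  })

  ir <- stage("isoform_ratios",
              compute_isoform_ratios(corrected$tx, corrected$gene,
                                     inputs$feature_map))
  outliers <- stage("outliers",
                    detect_outlier_samples(corrected$gene, ir,
                                           sd_mult = config$sd_mult))
  kept_samples <- setdiff(colnames(corrected$gene), outliers)
  grp <- structure(samples$group, names = samples$sample_id)[kept_samples]

  nets <- stage("netinfer", {
    # constant IR features (e.g. single-isoform genes) carry no information
    v <- apply(unclass(ir)[, kept_samples, drop = FALSE], 1, stats::var)
    if (any(v < 1e-12))
      message("dropping ", sum(v < 1e-12),
              " zero-variance isoform-ratio feature(s) before inference")
    ir_use <- ir[v >= 1e-12, , drop = FALSE]
    net_a <- infer_network(corrected$gene, ir_use,
                           kept_samples[grp == "affected"], config$mi,
                           group_label = "affected")
    net_b <- infer_network(corrected$gene, ir_use,
                           kept_samples[grp == "unaffected"], config$mi,
                           group_label = "unaffected")
    thr <- threshold_pair(net_a, net_b)
    list(a_raw = net_a, b_raw = net_b,
         a_thr = thr$net_a_thr, b_thr = thr$net_b_thr,
         thresholds = thr$thresholds)
  })

  diff <- stage("diffnet", {
    hubs_a <- identify_hubs(nets$a_thr, config$hub_k)
    hubs_b <- identify_hubs(nets$b_thr, config$hub_k)
    ch <- common_hubs(hubs_a, hubs_b)
    part <- if (length(ch))
      partition_common_hub_edges(nets$a_thr, nets$b_thr, nets$a_raw,
                                 nets$b_raw, ch) else NULL
    mh_a <- master_hubs(nets$a_thr, nets$b_raw, config$hub_k, config$min_fold)
    mh_b <- master_hubs(nets$b_thr, nets$a_raw, config$hub_k, config$min_fold)
    msub <- modality_subnetworks(nets$a_thr, nets$b_thr, inputs$feature_map)
    comp_a <- hub_modality_composition(nets$a_thr)
    comp_b <- hub_modality_composition(nets$b_thr)
    list(hubs_a = hubs_a, hubs_b = hubs_b, common_hubs = ch, partition = part,
         master_a = mh_a, master_b = mh_b, modality = msub,
         composition_a = comp_a, composition_b = comp_b)
  })

  validation <- if (!is.null(config$validate)) stage("validate", {
    separation_score(nets$a_thr, nets$b_thr, config$validate,
                     seed = seed + 2L)
  }) else NULL

  stage("write", {
    w <- function(df, name) write_with_header(df, file.path(outdir, name),
                                              digest, seed)
    write_matrix_tsv(corrected$gene, file.path(outdir, "gene_corrected.tsv"))
    write_matrix_tsv(corrected$tx, file.path(outdir, "tx_corrected.tsv"))
    write_matrix_tsv(ir, file.path(outdir, "isoform_ratios.tsv"),
                     id_col = "transcript_id")
    writeLines(c(sprintf("# config_digest=%s seed=%d", digest, seed), outliers),
               file.path(outdir, "outlier_samples.txt"))
    w(de$gene, "de_genes.tsv")
    w(de$tx, "de_transcripts.tsv")
    w(diff$hubs_a, "hubs_affected.tsv")
    w(diff$hubs_b, "hubs_unaffected.tsv")
    w(diff$master_a, "master_hubs_affected.tsv")
    w(diff$master_b, "master_hubs_unaffected.tsv")
    if (!is.null(diff$partition)) w(diff$partition$summary, "edge_partition.tsv")
    w(diff$modality$summary, "modality_split.tsv")
    for (nm in c("a_raw", "b_raw", "a_thr", "b_thr"))
      export_network(nets[[nm]], file.path(outdir, paste0("network_", nm, ".tsv")),
                     format = "tsv")
    jsonlite::write_json(
      c(list(config_digest = digest, seed = seed),
        as.list(nets$thresholds),
        if (!is.null(validation)) list(validation_accuracy = validation$accuracy)),
      file.path(outdir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  })

  net_summary <- function(net) {
    tab <- table(factor(net$edges$edge_type,
                        levels = c("TE-TE", "TE-IR", "IR-IR")))
    c(nodes = nrow(net$nodes), edges = nrow(net$edges), as.list(tab))
  }
  report <- list(
    seed = seed,
    config_digest = digest,
    outdir = outdir,
    n_samples_used = length(kept_samples),
    n_outliers = length(outliers),
    de = list(n_genes = sum(de$gene$significant),
              n_transcripts = sum(de$tx$significant),
              n_isoform_specific = length(de$iso$transcripts),
              partition = de$iso$partition),
    networks = list(affected_raw = net_summary(nets$a_raw),
                    unaffected_raw = net_summary(nets$b_raw),
                    affected_thr = net_summary(nets$a_thr),
                    unaffected_thr = net_summary(nets$b_thr),
                    thresholds = nets$thresholds),
    hubs = list(n_affected = sum(diff$hubs_a$is_hub),
                n_unaffected = sum(diff$hubs_b$is_hub),
                n_common = length(diff$common_hubs)),
    edge_partition = if (!is.null(diff$partition)) diff$partition$summary,
    master_hubs = list(
      affected = table(factor(diff$master_a$modality, levels = c("TE", "IR"))),
      unaffected = table(factor(diff$master_b$modality, levels = c("TE", "IR")))),
    modality_split = diff$modality$summary,
    validation_accuracy = if (!is.null(validation)) validation$accuracy,
    truth = inputs$truth,
    details = list(networks = nets, diffnet = diff, de = de,
                   validation = validation, ir = ir,
                   corrected = corrected, samples = samples,
                   feature_map = inputs$feature_map)
  )
  class(report) <- "summary_report"
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("isorewire pipeline summary (seed ", x$seed, ")\n", sep = "")
  cat("  samples used: ", x$n_samples_used, " (", x$n_outliers,
      " outliers removed)\n", sep = "")
  cat("  DE: ", x$de$n_genes, " genes, ", x$de$n_transcripts,
      " transcripts, ", x$de$n_isoform_specific, " isoform-specific\n", sep = "")
  for (nm in names(x$networks)[1:4]) {
    s <- x$networks[[nm]]
    cat(sprintf("  %s: %d nodes, %d edges (TE-TE %s, TE-IR %s, IR-IR %s)\n",
                nm, s$nodes, s$edges, s$`TE-TE`, s$`TE-IR`, s$`IR-IR`))
  }
  cat("  hubs: ", x$hubs$n_affected, " affected, ", x$hubs$n_unaffected,
      " unaffected, ", x$hubs$n_common, " common\n", sep = "")
  cat("  master hubs: affected ", sum(x$master_hubs$affected),
      ", unaffected ", sum(x$master_hubs$unaffected), "\n", sep = "")
  if (!is.null(x$validation_accuracy))
    cat("  validation accuracy: ", round(x$validation_accuracy, 3), "\n", sep = "")
  invisible(x)
}
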