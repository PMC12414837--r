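#' Simulation configuration for the two-group count generator
#'
#' Defines the generative conditions for a synthetic two-group RNA-seq study:
#' negative-binomial gene counts driven by latent module factors with hub
#' genes, Dirichlet-multinomial transcript splits with optional usage
#' coupling, group-specific rewiring of module edges, planted master hubs,
#' isoform-usage switches with unchanged gene totals, planted differentially
#' expressed genes, and nuisance covariates (batch, sex, age, BMI, five
#' cell-type PCs).
#'
#' Genes are partitioned into `n_modules` equally sized modules; within a
#' module the first `hubs_per_module` genes act as hubs and the remaining
#' spokes each attach to one hub. A spoke's expression loads on the module
#' factor only in the groups where its hub edge is present, so the planted
#' adjacency is what drives group-specific co-expression.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range `c(min, max)` of isoforms per gene.
#' @param n_modules number of co-expression modules.
#' @param hubs_per_module hub genes per module.
#' @param n_affected,n_unaffected group sample sizes (each >= 2).
#' @param rewire_fraction proportion of non-planted module edges that are
#'   group-specific (half assigned to each group).
#' @param n_planted_master_hubs number of hub genes planted as master hubs of
#'   the affected group.
#' @param master_hub_fold minimum ratio (>= 1) of a planted hub's partner count
#'   in the affected group over the unaffected group.
#' @param n_switch_genes number of genes given a group-specific isoform-usage
#'   switch (gene totals unchanged).
#' @param switch_effect shift applied to the first isoform's usage logit in the
#'   affected group for switch genes.
#' @param n_de_genes number of genes with a true gene-level log2 fold change.
#' @param de_lfc absolute true log2 fold change of planted DE genes
#'   (alternating sign).
#' @param nb_dispersion negative-binomial size parameter (larger = less
#'   overdispersion).
#' @param libsize_range integer range of per-sample library sizes.
#' @param covariate_effects named log-scale effect sizes for
#'   `batch`, `sex`, `age`, `bmi` and `cellpc` (shared by the five cell PCs).
#' @param hub_loading,spoke_loading,planted_spoke_loading latent-factor
#'   loadings of hub genes, ordinary spokes, and spokes of planted master
#'   hubs. Planted-hub edges are given a higher loading so that they carry
#'   more mutual information than ordinary module edges.
#' @param noise_sd standard deviation of the per-gene latent noise for
#'   spokes.
#' @param hub_noise_sd latent noise of hub genes. Kept small so a hub is a
#'   near-noiseless readout of its module factor: spoke-spoke correlation is
#'   then roughly the square of hub-spoke correlation, which lets
#'   triangle-based pruning recover the planted star topology.
#' @param usage_coupling loading of the first isoform's usage logit on the
#'   module splicing factor (creates IR-IR and TE-IR co-expression).
#' @param usage_factor_cor correlation between a module's expression factor
#'   and its splicing factor; controls how much TE-IR co-expression links
#'   the two modalities.
#' @param usage_concentration Dirichlet concentration of per-sample isoform
#'   usage around its expected value.
#' @param seed default seed used by [build_ground_truth()] and
#'   [simulate_counts()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       isoforms_per_gene = c(2L, 3L),
                       n_modules = 9,
                       hubs_per_module = 1,
                       n_affected = 150,
                       n_unaffected = 75,
                       rewire_fraction = 0.5,
                       n_planted_master_hubs = 5,
                       master_hub_fold = 2.5,
                       n_switch_genes = 20,
                       switch_effect = 1.5,
                       n_de_genes = 20,
                       de_lfc = 1,
                       nb_dispersion = 30,
                       libsize_range = c(800000L, 1200000L),
                       covariate_effects = c(batch = 0.1, sex = 0.05, age = 0.02,
                                             bmi = 0.02, cellpc = 0.05),
                       hub_loading = 1,
                       spoke_loading = 0.45,
                       planted_spoke_loading = 0.85,
                       noise_sd = 0.6,
                       hub_noise_sd = 0.15,
                       usage_coupling = 1,
                       usage_factor_cor = 0.35,
                       usage_concentration = 30,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_modules = as.integer(n_modules),
              hubs_per_module = as.integer(hubs_per_module),
              n_affected = as.integer(n_affected),
              n_unaffected = as.integer(n_unaffected),
              rewire_fraction = rewire_fraction,
              n_planted_master_hubs = as.integer(n_planted_master_hubs),
              master_hub_fold = master_hub_fold,
              n_switch_genes = as.integer(n_switch_genes),
              switch_effect = switch_effect,
              n_de_genes = as.integer(n_de_genes),
              de_lfc = de_lfc,
              nb_dispersion = nb_dispersion,
              libsize_range = as.integer(libsize_range),
              covariate_effects = covariate_effects,
              hub_loading = hub_loading,
              spoke_loading = spoke_loading,
              planted_spoke_loading = planted_spoke_loading,
              noise_sd = noise_sd,
              hub_noise_sd = hub_noise_sd,
              usage_coupling = usage_coupling,
              usage_factor_cor = usage_factor_cor,
              usage_concentration = usage_concentration,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_modules > 0, hubs_per_module > 0,
              length(isoforms_per_gene) == 2,
              isoforms_per_gene[1] >= 1,
              isoforms_per_gene[2] >= isoforms_per_gene[1])
    if (n_affected < 2 || n_unaffected < 2)
      stop("both groups need at least 2 samples")
    if (rewire_fraction < 0 || rewire_fraction > 1)
      stop("rewire_fraction must be in [0, 1]")
    if (master_hub_fold < 1) stop("master_hub_fold must be >= 1")
    if (any(libsize_range <= 0) || libsize_range[2] < libsize_range[1])
      stop("invalid libsize_range")
    if (any(libsize_range != round(libsize_range)))
      stop("library sizes must be integers")
    if (!all(c("batch", "sex", "age", "bmi", "cellpc") %in% names(covariate_effects)))
      stop("covariate_effects needs entries batch, sex, age, bmi, cellpc")
    if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' Build the generative ground truth for a simulated study
#'
#' Lays out modules, hub-spoke edges, the shared/group-specific edge split,
#' planted master hubs, isoform counts, switch genes, and true DE genes.
#' Deterministic for a fixed `(config, seed)` pair.
#'
#' For a planted master hub all module edges are present in the affected
#' group; only `floor(degree / master_hub_fold)` of them are kept in the
#' unaffected group, so the recorded planted fold is always
#' `>= master_hub_fold`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list of class `ground_truth` with elements `module_membership`,
#'   `edges` (hub, spoke, module, status in shared/A_only/B_only),
#'   `planted_master_hubs`, `switch_genes`, `de_features`, `isoforms`, and the
#'   three unordered gene-pair sets `adjacency_shared`, `adjacency_A`
#'   (affected-specific) and `adjacency_B` (unaffected-specific).
#' @export
build_ground_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- config$n_genes
  M <- config$n_modules
  hpm <- config$hubs_per_module
  if (config$n_planted_master_hubs > M * hpm)
    stop("n_planted_master_hubs exceeds the number of hub genes (",
         M * hpm, ")")
  gene_ids <- sprintf("g%04d", seq_len(G))
  block <- ceiling(G / M)
  module <- rep(seq_len(M), each = block)[seq_len(G)]
  role <- rep("spoke", G)
  hub_of <- rep(NA_character_, G)
  hubs <- character(0)
  for (m in seq_len(M)) {
    idx <- which(module == m)
    if (length(idx) <= hpm)
      stop("module ", m, " has no spokes; reduce n_modules or hubs_per_module")
    mh <- idx[seq_len(hpm)]
    role[mh] <- "hub"
    hubs <- c(hubs, gene_ids[mh])
    spokes <- idx[-seq_len(hpm)]
    hub_of[spokes] <- gene_ids[mh][rep_len(seq_len(hpm), length(spokes))]
  }
  membership <- data.frame(gene_id = gene_ids, module = module, role = role,
                           hub = hub_of, stringsAsFactors = FALSE)

  edges <- data.frame(hub = hub_of[role == "spoke"],
                      spoke = gene_ids[role == "spoke"],
                      module = module[role == "spoke"],
                      stringsAsFactors = FALSE)

  planted <- if (config$n_planted_master_hubs > 0)
    sample(hubs, config$n_planted_master_hubs) else character(0)

  edges$status <- NA_character_
  edges$planted <- edges$hub %in% planted

  planted_tab <- NULL
  for (h in planted) {
    i <- which(edges$hub == h)
    d <- length(i)
    keep_b <- max(1L, floor(d / config$master_hub_fold))
    i <- sample(i)  # which spokes stay connected in the unaffected group
    edges$status[i[seq_len(keep_b)]] <- "shared"
    if (d > keep_b) edges$status[i[(keep_b + 1):d]] <- "A_only"
    planted_tab <- rbind(planted_tab,
                         data.frame(gene_id = h, degree_A = d, degree_B = keep_b,
                                    planted_fold = d / keep_b,
                                    stringsAsFactors = FALSE))
  }

  free <- which(is.na(edges$status))
  free <- sample(free)
  n_shared <- round((1 - config$rewire_fraction) * length(free))
  edges$status[free[seq_len(n_shared)]] <- "shared"
  if (length(free) > n_shared) {
    rest <- free[(n_shared + 1):length(free)]
    edges$status[rest] <- rep_len(c("A_only", "B_only"), length(rest))
  }

  n_iso <- sample(seq(config$isoforms_per_gene[1], config$isoforms_per_gene[2]),
                  G, replace = TRUE)
  isoforms <- data.frame(gene_id = gene_ids, n_isoforms = n_iso,
                         stringsAsFactors = FALSE)

  multi <- gene_ids[n_iso >= 2]
  if (config$n_switch_genes > length(multi))
    stop("not enough multi-isoform genes for n_switch_genes")
  switch_genes <- if (config$n_switch_genes > 0)
    sample(multi, config$n_switch_genes) else character(0)
  switch_tab <- data.frame(gene_id = switch_genes,
                           delta = rep(config$switch_effect,
                                       length(switch_genes)),
                           stringsAsFactors = FALSE)

  de_pool <- setdiff(gene_ids, switch_genes)
  if (config$n_de_genes > length(de_pool)) stop("not enough genes for n_de_genes")
  de_genes <- if (config$n_de_genes > 0) sample(de_pool, config$n_de_genes) else character(0)
  de_tab <- data.frame(feature_id = de_genes,
                       lfc = config$de_lfc * rep_len(c(1, -1), length(de_genes)),
                       stringsAsFactors = FALSE)

  pair_set <- function(rows) {
    if (!length(rows)) return(data.frame(gene_a = character(0), gene_b = character(0)))
    data.frame(gene_a = pmin(edges$hub[rows], edges$spoke[rows]),
               gene_b = pmax(edges$hub[rows], edges$spoke[rows]),
               stringsAsFactors = FALSE)
  }
  truth <- list(module_membership = membership,
                edges = edges,
                planted_master_hubs = planted_tab %||%
                  data.frame(gene_id = character(0), degree_A = integer(0),
                             degree_B = integer(0), planted_fold = numeric(0)),
                switch_genes = switch_tab,
                de_features = de_tab,
                isoforms = isoforms,
                adjacency_shared = pair_set(which(edges$status == "shared")),
                adjacency_A = pair_set(which(edges$status == "A_only")),
                adjacency_B = pair_set(which(edges$status == "B_only")),
                config = config)
  class(truth) <- "ground_truth"
  truth
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full per-group adjacency (shared plus group-specific edges)
#'
#' @param truth a [build_ground_truth()] result.
#' @param group `"affected"` or `"unaffected"`.
#' @return data.frame of unordered gene pairs.
#' @export
truth_adjacency <- function(truth, group = c("affected", "unaffected")) {
  group <- match.arg(group)
  extra <- if (group == "affected") truth$adjacency_A else truth$adjacency_B
  rbind(truth$adjacency_shared, extra)
}

#' Simulate gene and transcript counts from a ground truth
#'
#' Gene counts are negative binomial with a log mean combining a gene
#' baseline, module-factor signal (present only for edges in the group's
#' adjacency), covariate effects, and the planted DE fold changes. Transcript
#' counts are a Dirichlet-multinomial split of each gene's count, so per gene
#' and sample the transcript counts sum exactly to the gene count; usage
#' logits couple to a module splicing factor and are shifted by the switch
#' effect in the affected group for switch genes.
#'
#' @param truth a `ground_truth` object.
#' @param config the matching [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `gene_counts` and `tx_counts` ([count_matrix()]),
#'   `samples` (sample table with group and covariates), and `feature_map`
#'   (transcript_id, gene_id).
#' @export
simulate_counts <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (nrow(truth$module_membership) == 0) stop("empty ground truth")
  if (nrow(truth$module_membership) != config$n_genes)
    stop("truth and config disagree on the number of genes")
  set.seed(seed)
  G <- config$n_genes
  nA <- config$n_affected
  nU <- config$n_unaffected
  S <- nA + nU
  gene_ids <- truth$module_membership$gene_id
  module <- truth$module_membership$module
  role <- truth$module_membership$role

  sample_ids <- sprintf("s%04d", seq_len(S))
  group <- rep(c("affected", "unaffected"), c(nA, nU))
  batch <- sample(rep_len(c("run1", "run2"), S))
  sex <- sample(rep_len(c("female", "male"), S))
  age <- round(rnorm(S, 35, 10), 1)
  bmi <- round(rnorm(S, 25, 4), 1)
  cellpc <- matrix(rnorm(S * 5), S, 5,
                   dimnames = list(NULL, paste0("cellpc", 1:5)))
  samples <- data.frame(sample_id = sample_ids, group = group, batch = batch,
                        sex = sex, age = age, bmi = bmi, cellpc,
                        stringsAsFactors = FALSE)

  # covariate signal on the natural-log scale: global per-covariate effect
  # size times per-gene standard-normal weights
  Xc <- cbind(batch = as.numeric(batch == "run2"),
              sex = as.numeric(sex == "male"),
              age = as.numeric(scale(age)),
              bmi = as.numeric(scale(bmi)),
              cellpc)
  eff <- config$covariate_effects
  col_scale <- c(eff[["batch"]], eff[["sex"]], eff[["age"]], eff[["bmi"]],
                 rep(eff[["cellpc"]], 5))
  W <- matrix(rnorm(G * ncol(Xc)), G, ncol(Xc)) *
    matrix(col_scale, G, ncol(Xc), byrow = TRUE)
  cov_signal <- W %*% t(Xc)                       # G x S

  # latent module factors: expression factor Z and a correlated splicing
  # factor Sp (cor 0.5) that drives isoform usage
  M <- config$n_modules
  Z <- matrix(rnorm(S * M), S, M)
  fc <- config$usage_factor_cor
  Sp <- fc * Z + sqrt(1 - fc^2) * matrix(rnorm(S * M), S, M)

  # per-gene loading in each group: hubs always load; a spoke loads only if
  # its hub edge is present in that group's adjacency
  loading_for <- function(which_group) {
    lo <- numeric(G)
    lo[role == "hub"] <- config$hub_loading
    present <- truth$edges$status == "shared" |
      truth$edges$status == (if (which_group == "affected") "A_only" else "B_only")
    sp <- truth$edges$spoke[present]
    base <- ifelse(truth$edges$planted[present],
                   config$planted_spoke_loading, config$spoke_loading)
    lo[match(sp, gene_ids)] <- base
    lo
  }
  loadA <- loading_for("affected")
  loadB <- loading_for("unaffected")
  Lmat <- cbind(matrix(loadA, G, nA), matrix(loadB, G, nU))  # G x S
  Zg <- t(Z[, module, drop = FALSE])                         # G x S
  gene_noise <- ifelse(role == "hub", config$hub_noise_sd, config$noise_sd)
  # variance-preserving rewiring: where an edge is absent in one group the
  # factor variance is replaced by idiosyncratic noise of the same size, so
  # the marginal distribution of every gene is identical across groups and
  # rewiring changes co-expression only, never differential expression
  lam_max <- pmax(loadA, loadB)
  noise_sd_mat <- sqrt(gene_noise^2 + lam_max^2 - Lmat^2)
  latent <- Lmat * Zg + noise_sd_mat * matrix(rnorm(G * S), G, S)

  base <- rnorm(G, 0, 1)
  de_term <- matrix(0, G, S)
  if (nrow(truth$de_features)) {
    i <- match(truth$de_features$feature_id, gene_ids)
    de_term[i, group == "affected"] <- truth$de_features$lfc * log(2)
  }
  log_mu <- base + latent + cov_signal + de_term
  rel <- exp(log_mu)
  libsize <- sample(seq(config$libsize_range[1], config$libsize_range[2]), S,
                    replace = TRUE)
  mu <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(mu, 2, libsize, "*")
  counts <- matrix(rnbinom(G * S, mu = mu, size = config$nb_dispersion), G, S,
                   dimnames = list(gene_ids, sample_ids))

  # transcript split: Dirichlet-multinomial around usage logits
  n_iso <- truth$isoforms$n_isoforms[match(gene_ids, truth$isoforms$gene_id)]
  tx_ids <- unlist(lapply(seq_len(G), function(g)
    paste0(gene_ids[g], "-t", seq_len(n_iso[g]))))
  feature_map <- data.frame(transcript_id = tx_ids,
                            gene_id = rep(gene_ids, n_iso),
                            stringsAsFactors = FALSE)
  tx_counts <- matrix(0L, length(tx_ids), S,
                      dimnames = list(tx_ids, sample_ids))
  delta <- structure(truth$switch_genes$delta,
                     names = truth$switch_genes$gene_id)
  affected_col <- group == "affected"
  row0 <- 0L
  for (g in seq_len(G)) {
    K <- n_iso[g]
    rows <- row0 + seq_len(K)
    row0 <- row0 + K
    N <- counts[g, ]
    if (K == 1) { tx_counts[rows, ] <- N; next }
    alpha <- rnorm(K, 0, 1)
    logits <- matrix(alpha, K, S)
    logits[1, ] <- logits[1, ] + config$usage_coupling * Sp[, module[g]]
    if (gene_ids[g] %in% names(delta))
      logits[1, affected_col] <- logits[1, affected_col] + delta[[gene_ids[g]]]
    el <- exp(logits)
    pbar <- sweep(el, 2, colSums(el), "/")
    gam <- matrix(rgamma(K * S, shape = config$usage_concentration * pbar),
                  K, S)
    csum <- colSums(gam)
    csum[csum == 0] <- 1
    p <- sweep(gam, 2, csum, "/")
    # sequential binomial thinning = multinomial draw, vectorized over samples
    rem_n <- N
    rem_p <- rep(1, S)
    for (k in seq_len(K - 1)) {
      pk <- pmin(1, pmax(0, ifelse(rem_p > 0, p[k, ] / rem_p, 0)))
      ck <- rbinom(S, rem_n, pk)
      tx_counts[rows[k], ] <- ck
      rem_n <- rem_n - ck
      rem_p <- rem_p - p[k, ]
    }
    tx_counts[rows[K], ] <- rem_n
  }

  list(gene_counts = count_matrix(counts, "gene"),
       tx_counts = count_matrix(tx_counts, "transcript"),
       samples = samples,
       feature_map = feature_map)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes gene and transcript counts (TSV, features x samples), the sample
#' table, the transcript-to-gene map, and the ground truth (JSON).
#'
#' @param sim a [simulate_counts()] result.
#' @param truth the matching ground truth (optional).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gene = file.path(dir, "gene_counts.tsv"),
             tx = file.path(dir, "transcript_counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             map = file.path(dir, "feature_map.tsv"))
  write_matrix_tsv(sim$gene_counts, paths[["gene"]], id_col = "feature_id")
  write_matrix_tsv(sim$tx_counts, paths[["tx"]], id_col = "feature_id")
  utils::write.table(sim$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$feature_map, paths[["map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.json"))
    tr <- truth[setdiff(names(truth), "config")]
    jsonlite::write_json(tr, paths[["truth"]], dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
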