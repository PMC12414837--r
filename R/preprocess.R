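#' Filter features by minimum count prevalence
#'
#' Retains features with a count of at least `min_count` in at least
#' `ceil(min_frac * n_samples)` samples (boundary inclusive); everything else,
#' including all-zero features, is removed. Feature order is preserved.
#'
#' @param counts a [count_matrix()].
#' @param min_count minimum count (default 10).
#' @param min_frac minimum fraction of samples (default 0.95), in (0, 1].
#' @return The filtered `count_matrix`.
#' @export
filter_features <- function(counts, min_count = 10, min_frac = 0.95) {
  stopifnot(inherits(counts, "count_matrix"), nrow(counts) > 0, ncol(counts) > 0)
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  need <- ceiling(min_frac * ncol(counts))
  keep <- rowSums(unclass(counts) >= min_count) >= need
  counts[keep, , drop = FALSE]
}

#' log2 counts-per-million transform
#'
#' Computes `log2((count + prior_count) / (library_size + 1) * 1e6)` with the
#' library size taken as the sample's total count. Monotone in the count
#' within a sample.
#'
#' @param counts a [count_matrix()].
#' @param prior_count pseudo-count added to every entry (default 0.5).
#' @return An [expression_matrix()] at stage `"raw-logcpm"`.
#' @export
logcpm <- function(counts, prior_count = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(unclass(counts))
  if (any(lib <= 0)) stop("library sizes must be positive")
  vals <- log2(sweep(unclass(counts) + prior_count, 2, lib + 1, "/") * 1e6)
  expression_matrix(vals, level = attr(counts, "level"), stage = "raw-logcpm")
}

#' Residualize expression against nuisance covariates
#'
#' Fits, per feature, an ordinary-least-squares model on an intercept plus the
#' named covariates (categorical covariates are one-hot encoded with the
#' reference level dropped) and subtracts the fitted covariate contribution
#' while keeping the intercept, so values stay on the logCPM scale. The group
#' label must not be among the covariates, leaving group-associated signal
#' untouched.
#'
#' @param expr an [expression_matrix()].
#' @param samples sample table with one row per column of `expr`.
#' @param covariate_names character vector of column names of `samples` to
#'   remove; may be empty (identity).
#' @return A corrected [expression_matrix()] (stage `"corrected"` may contain
#'   negative values; see [drop_negative_features()]).
#' @export
residualize <- function(expr, samples, covariate_names) {
  stopifnot(inherits(expr, "expression_matrix"))
  validate_sample_table(samples, expr)
  if ("group" %in% covariate_names)
    stop("'group' must not be residualized out")
  vals <- unclass(expr)
  if (length(covariate_names) == 0)
    return(expression_matrix(vals, attr(expr, "level"), "corrected"))
  missing_cov <- setdiff(covariate_names, names(samples))
  if (length(missing_cov))
    stop("covariates not in sample table: ", paste(missing_cov, collapse = ", "))
  samples <- samples[match(colnames(vals), samples$sample_id), , drop = FALSE]
  covdf <- samples[, covariate_names, drop = FALSE]
  covdf[] <- lapply(covdf, function(x) if (is.character(x)) factor(x) else x)
  X <- stats::model.matrix(~ ., data = covdf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- t(qr.coef(qrX, t(vals)))          # features x columns(X)
  fitted_cov <- beta[, -1, drop = FALSE] %*% t(X[, -1, drop = FALSE])
  expression_matrix(vals - fitted_cov, attr(expr, "level"), "corrected")
}

#' Drop features with any negative corrected value
#'
#' After covariate subtraction some low-expressed features can go negative;
#' these are removed entirely (a feature with a single negative entry is
#' dropped).
#'
#' @param expr a corrected [expression_matrix()].
#' @return The pruned matrix.
#' @export
drop_negative_features <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (attr(expr, "stage") != "corrected")
    stop("drop_negative_features expects a corrected matrix")
  keep <- rowSums(unclass(expr) < 0) == 0
  expr[keep, , drop = FALSE]
}

#' Compute isoform ratios
#'
#' The isoform ratio of transcript t in sample s is the corrected
#' logCPM-transformed transcript value divided by the corresponding gene
#' value. A 0/0 entry (both transcript and gene exactly zero) is imputed with
#' the mean ratio of that transcript over all samples where it is defined; a
#' transcript undefined in every sample is dropped with a warning. A zero
#' denominator with a non-zero numerator is an error.
#'
#' Transcripts whose genes are absent from the gene matrix (filtered at an
#' earlier step) are removed up front.
#'
#' @param tx corrected transcript-level [expression_matrix()].
#' @param genes corrected gene-level [expression_matrix()].
#' @param map transcript-to-gene [validate_feature_map()] table.
#' @return An [ir_matrix()] with no non-finite values.
#' @export
compute_isoform_ratios <- function(tx, genes, map) {
  stopifnot(inherits(tx, "expression_matrix"), inherits(genes, "expression_matrix"))
  if (attr(tx, "stage") != "corrected" || attr(genes, "stage") != "corrected")
    stop("both matrices must be corrected before computing isoform ratios")
  validate_feature_map(map)
  unmapped <- setdiff(rownames(tx), map$transcript_id)
  if (length(unmapped))
    stop("transcripts without a gene mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  gene_of <- structure(map$gene_id, names = map$transcript_id)[rownames(tx)]
  keep <- gene_of %in% rownames(genes)
  txv <- unclass(tx)[keep, , drop = FALSE]
  gene_of <- gene_of[keep]
  if (!all(colnames(txv) == colnames(genes)))
    stop("transcript and gene matrices must share identical sample columns")
  gv <- unclass(genes)[gene_of, , drop = FALSE]
  bad <- gv == 0 & txv != 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("zero gene value with non-zero transcript value at (%s, %s)",
                 rownames(txv)[w[1]], colnames(txv)[w[2]]))
  }
  ir <- txv / gv
  ir[txv == 0 & gv == 0] <- NA_real_
  defined <- rowSums(!is.na(ir))
  if (any(defined == 0)) {
    warning("dropping ", sum(defined == 0),
            " transcript(s) with no defined isoform ratio in any sample")
    ir <- ir[defined > 0, , drop = FALSE]
    gene_of <- gene_of[defined > 0]
  }
  if (anyNA(ir)) {
    mn <- rowMeans(ir, na.rm = TRUE)
    idx <- which(is.na(ir), arr.ind = TRUE)
    ir[idx] <- mn[idx[, 1]]
  }
  ir_matrix(ir, gene_of)
}

#' Detect outlier samples on the first two principal components
#'
#' Runs PCA (samples as observations, features centered) separately on the
#' gene expression matrix and the isoform-ratio matrix, flags a sample whose
#' score deviates from the mean by more than `sd_mult` standard deviations on
#' PC1 or PC2 of either matrix, and returns the union.
#'
#' @param gene_expr corrected gene-level [expression_matrix()].
#' @param ir an [ir_matrix()] (optional; pass `NULL` to use genes only).
#' @param sd_mult positive deviation multiplier (default 2).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(gene_expr, ir = NULL, sd_mult = 2) {
  if (sd_mult <= 0) stop("sd_mult must be positive")
  flag_one <- function(mat) {
    m <- t(unclass(mat))
    if (nrow(m) < 3) stop("need at least 3 samples for outlier detection")
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = 2)
    sc <- pc$x
    out <- rep(FALSE, nrow(sc))
    for (j in seq_len(min(2, ncol(sc)))) {
      s <- stats::sd(sc[, j])
      if (s > 0) out <- out | abs(sc[, j] - mean(sc[, j])) > sd_mult * s
    }
    rownames(m)[out]
  }
  res <- flag_one(gene_expr)
  if (!is.null(ir)) res <- union(res, flag_one(ir))
  sort(res)
}

#' Standard preprocessing pipeline for one count level
#'
#' Applies the fixed order filter -> logCPM -> residualize -> drop-negative
#' and returns the corrected matrix.
#'
#' @param counts a [count_matrix()].
#' @param samples sample table.
#' @param covariate_names covariates to residualize out.
#' @param min_count,min_frac,prior_count see the individual steps.
#' @return corrected [expression_matrix()].
#' @export
preprocess_counts <- function(counts, samples, covariate_names,
                              min_count = 10, min_frac = 0.95,
                              prior_count = 0.5) {
  x <- filter_features(counts, min_count = min_count, min_frac = min_frac)
  x <- logcpm(x, prior_count = prior_count)
  x <- residualize(x, samples, covariate_names)
  drop_negative_features(x)
}
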