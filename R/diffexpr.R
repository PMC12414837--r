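#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up: sort the p-values, compute `p * n / rank`, enforce
#' monotonicity from the largest rank down, cap at 1, and map the adjusted
#' values back to the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
  q
}

# Newton solve of trigamma(x) = y, vectorized (Smyth-style moment matching
# needs the inverse on the log-variance scale).
trigamma_inverse <- function(y) {
  out <- y
  pos <- is.finite(y) & y > 0
  out[!pos] <- NA_real_
  x <- 0.5 + 1 / y[pos]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[pos]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x, na.rm = TRUE) < 1e-8) break
  }
  out[pos] <- x
  out
}

#' Moderated two-group differential expression
#'
#' Per feature, ordinary least squares of expression on an intercept plus
#' group (so the log fold change is exactly the affected-minus-unaffected
#' difference of group means), with residual variances shrunk toward a prior
#' by empirical Bayes. Hyperparameters come from method-of-moments matching on
#' the log residual variances; with `trend = TRUE` the prior variance is a
#' smooth (lowess) function of mean expression. The moderated t-statistic uses
#' the posterior variance and residual-plus-prior degrees of freedom.
#'
#' @param expr an [expression_matrix()] (typically corrected logCPM).
#' @param samples sample table with a `group` column covering both groups
#'   (each with at least 2 samples).
#' @param trend fit an intensity trend on the prior variance (default `TRUE`).
#' @param q_thresh FDR threshold for the `significant` flag (default 0.05).
#' @param prior_df override the estimated prior degrees of freedom; `0` gives
#'   the ordinary two-sample t-statistic, `NULL` (default) estimates it.
#' @return data.frame with `feature_id`, `logFC`, `ave_expr`, `t_stat`,
#'   `p_value`, `q_value`, `significant`, `direction`.
#' @export
moderated_de <- function(expr, samples, trend = TRUE, q_thresh = 0.05,
                         prior_df = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  validate_sample_table(samples, expr)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  grp <- samples$group
  nA <- sum(grp == "affected")
  nU <- sum(grp == "unaffected")
  if (nA < 2 || nU < 2) stop("both groups need at least 2 samples")
  vals <- unclass(expr)
  a <- vals[, grp == "affected", drop = FALSE]
  u <- vals[, grp == "unaffected", drop = FALSE]
  logFC <- rowMeans(a) - rowMeans(u)
  ave <- rowMeans(vals)
  df <- nA + nU - 2
  rss <- rowSums((a - rowMeans(a))^2) + rowSums((u - rowMeans(u))^2)
  s2 <- rss / df
  v_contrast <- 1 / nA + 1 / nU

  G <- length(s2)
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  if (trend && G >= 10) {
    lo <- stats::lowess(ave, e, f = 0.5)
    e0 <- stats::approx(lo$x, lo$y, xout = ave, rule = 2, ties = mean)$y
  } else {
    e0 <- rep(mean(e), G)
  }
  resid <- e - e0
  if (is.null(prior_df)) {
    mom <- mean(resid^2 * G / max(G - 1, 1) - trigamma(df / 2))
    d0 <- if (is.na(mom) || mom <= 0) Inf else 2 * trigamma_inverse(mom)
  } else {
    d0 <- prior_df
  }
  if (d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    s0_sq <- exp(e0)
    s2_post <- s0_sq
    df_total <- Inf
  } else {
    s0_sq <- exp(e0 + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  t_stat <- logFC / sqrt(s2_post * v_contrast)
  t_stat[!is.finite(t_stat)] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df_total)
  q <- bh_adjust(p)
  data.frame(feature_id = rownames(vals),
             logFC = logFC,
             ave_expr = ave,
             t_stat = t_stat,
             p_value = p,
             q_value = q,
             significant = q <= q_thresh,
             direction = ifelse(logFC >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Isoform-specific differential expression
#'
#' Returns transcripts significant at `q_thresh` whose parent gene is not
#' significant at the gene level (or was filtered out of the gene analysis),
#' plus the directional gene-level/transcript-level overlap partition: for
#' each direction, which genes are significant only at the gene level, at
#' both levels (a transcript mapped to its gene), or only at the transcript
#' level.
#'
#' @param gene_de gene-level [moderated_de()] result.
#' @param tx_de transcript-level [moderated_de()] result.
#' @param map transcript-to-gene table.
#' @param q_thresh FDR threshold (default 0.05).
#' @return list with `transcripts` (isoform-specific DE transcript ids) and
#'   `partition` (data.frame: direction, gene_only, both, transcript_only
#'   gene counts).
#' @export
isoform_specific_de <- function(gene_de, tx_de, map, q_thresh = 0.05) {
  validate_feature_map(map)
  unmapped <- setdiff(tx_de$feature_id, map$transcript_id)
  if (length(unmapped))
    stop("transcripts without a gene mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  gene_of <- structure(map$gene_id, names = map$transcript_id)
  gene_q <- structure(gene_de$q_value, names = gene_de$feature_id)

  tx_sig <- tx_de$feature_id[tx_de$q_value <= q_thresh]
  parent <- gene_of[tx_sig]
  parent_q <- gene_q[parent]                 # NA when filtered out at gene level
  iso_specific <- tx_sig[is.na(parent_q) | parent_q > q_thresh]

  part <- lapply(c("up", "down"), function(d) {
    g_sig <- gene_de$feature_id[gene_de$significant & gene_de$direction == d]
    t_sig <- tx_de$feature_id[tx_de$significant & tx_de$direction == d]
    t_genes <- unique(gene_of[t_sig])
    data.frame(direction = d,
               gene_only = length(setdiff(g_sig, t_genes)),
               both = length(intersect(g_sig, t_genes)),
               transcript_only = length(setdiff(t_genes, g_sig)),
               stringsAsFactors = FALSE)
  })
  list(transcripts = unname(iso_specific),
       partition = do.call(rbind, part))
}

#' Write a differential-expression table to TSV
#'
#' @param de a [moderated_de()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
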