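#' Count matrix container
#'
#' A light wrapper around an integer feature x sample matrix that records
#' whether the features are gene-level or transcript-level. Row names are
#' feature identifiers, column names are sample identifiers.
#'
#' @param values non-negative integer matrix (features x samples) with unique
#'   row and column names.
#' @param level `"gene"` or `"transcript"`.
#' @return An object of class `count_matrix` (a matrix with a `level`
#'   attribute).
#' @export
count_matrix <- function(values, level = c("gene", "transcript")) {
  level <- match.arg(level)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (any(values < 0)) stop("count matrix contains negative entries")
  if (any(values != round(values))) stop("count matrix contains non-integer entries")
  structure(values, level = level, class = c("count_matrix", "matrix", "array"))
}

#' Expression matrix container
#'
#' Real-valued feature x sample matrix on the logCPM scale, tagged with the
#' feature level and processing stage.
#'
#' @param values numeric matrix with row/column names.
#' @param level `"gene"` or `"transcript"`.
#' @param stage `"raw-logcpm"` (after the logCPM transform) or `"corrected"`
#'   (after covariate residualization).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, level = c("gene", "transcript"),
                              stage = c("raw-logcpm", "corrected")) {
  level <- match.arg(level)
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature and sample names")
  if (any(!is.finite(values))) stop("expression matrix contains non-finite entries")
  structure(values, level = level, stage = stage,
            class = c("expression_matrix", "matrix", "array"))
}

#' Isoform-ratio matrix container
#'
#' Transcript x sample matrix of isoform ratios (corrected transcript logCPM
#' divided by the parent gene's corrected logCPM), together with the parent
#' gene of each transcript.
#'
#' @param values numeric transcripts x samples matrix, all entries finite.
#' @param gene_of named character vector mapping each transcript (names) to
#'   its parent gene.
#' @return An object of class `ir_matrix`.
#' @export
ir_matrix <- function(values, gene_of) {
  if (!is.matrix(values) || !is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) stop("isoform-ratio matrix needs transcript row names")
  if (any(!is.finite(values))) stop("isoform-ratio matrix contains non-finite entries")
  if (!all(rownames(values) %in% names(gene_of)))
    stop("every transcript must have a parent gene in 'gene_of'")
  structure(values, gene_of = gene_of[rownames(values)],
            class = c("ir_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s-level]: %d features x %d samples\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s-level, %s]: %d features x %d samples\n",
              attr(x, "level"), attr(x, "stage"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.ir_matrix <- function(x, ...) {
  cat(sprintf("ir_matrix: %d transcripts x %d samples (%d parent genes)\n",
              nrow(x), ncol(x), length(unique(attr(x, "gene_of")))))
  invisible(x)
}

# Subsetting keeps class + attributes in step with the surviving rows and
# columns whenever the result is still a matrix (base drop semantics apply).
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, level = attr(x, "level"),
                     class = c("count_matrix", "matrix", "array"))
  out
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, level = attr(x, "level"), stage = attr(x, "stage"),
                     class = c("expression_matrix", "matrix", "array"))
  out
}

#' @export
`[.ir_matrix` <- function(x, i, j, ..., drop = TRUE) {
  gene_of <- attr(x, "gene_of")
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, gene_of = gene_of[rownames(out)],
                     class = c("ir_matrix", "matrix", "array"))
  out
}

#' Validate a sample metadata table against a count or expression matrix
#'
#' @param samples data.frame with at least `sample_id` and `group` columns;
#'   `group` must be one of `"affected"`/`"unaffected"` per sample.
#' @param mat matrix whose column names must all appear in `samples$sample_id`.
#' @return `samples`, invisibly, after validation.
#' @export
validate_sample_table <- function(samples, mat = NULL) {
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample table needs 'sample_id' and 'group' columns")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  if (any(is.na(samples$group))) stop("missing group labels")
  if (!all(samples$group %in% c("affected", "unaffected")))
    stop("group must be 'affected' or 'unaffected'")
  if (!is.null(mat) && !all(colnames(mat) %in% samples$sample_id))
    stop("samples missing from the metadata table: ",
         paste(setdiff(colnames(mat), samples$sample_id), collapse = ", "))
  invisible(samples)
}

#' Validate a transcript-to-gene feature map
#'
#' @param map data.frame with `transcript_id` and `gene_id` columns; each
#'   transcript maps to exactly one gene.
#' @return `map`, invisibly.
#' @export
validate_feature_map <- function(map) {
  if (!all(c("transcript_id", "gene_id") %in% names(map)))
    stop("feature map needs 'transcript_id' and 'gene_id' columns")
  if (anyDuplicated(map$transcript_id))
    stop("feature map assigns some transcript to more than one gene")
  invisible(map)
}
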