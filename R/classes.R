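#' Construct an expression matrix
#'
#' Thin container for a gene x sample numeric matrix of raw counts or
#' covariate-adjusted residuals, with explicit axis names.  Counts must be
#' non-negative; gene identifiers may be duplicated on construction (they are
#' resolved by [collapse_duplicates()]).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_names character vector of row identifiers.
#' @param sample_names character vector of column identifiers (unique).
#' @param kind `"counts"` or `"residuals"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_names = rownames(values),
                              sample_names = colnames(values),
                              kind = c("counts", "residuals")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(gene_names) || is.null(sample_names))
    stopf("expression_matrix needs gene and sample names")
  if (length(gene_names) != nrow(values) || length(sample_names) != ncol(values))
    stopf("axis lengths (%d genes, %d samples) do not match matrix shape %dx%d",
          length(gene_names), length(sample_names), nrow(values), ncol(values))
  if (anyDuplicated(sample_names))
    stopf("duplicated sample names: %s",
          paste(unique(sample_names[duplicated(sample_names)]), collapse = ", "))
  if (!is.numeric(values)) stopf("expression values must be numeric")
  if (kind == "counts" && any(values < 0))
    stopf("negative entries are not allowed in a counts matrix")
  dimnames(values) <- list(gene_names, sample_names)
  structure(list(values = values, gene_names = as.character(gene_names),
                 sample_names = as.character(sample_names), kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a covariate table
#'
#' Sample-level metadata aligned with an expression matrix.  `diagnosis` must
#' be a two-level factor (the case/control contrast); all remaining columns
#' are nuisance covariates, either numeric or categorical.
#'
#' @param df data.frame with a `sample` column, a `diagnosis` column and any
#'   number of additional covariate columns.
#' @return an object of class `covariate_table` (a data.frame).
#' @export
covariate_table <- function(df) {
  if (!is.data.frame(df)) stopf("covariate table must be a data.frame")
  if (!all(c("sample", "diagnosis") %in% names(df)))
    stopf("covariate table needs 'sample' and 'diagnosis' columns")
  if (anyDuplicated(df$sample)) stopf("duplicated sample identifiers")
  if (anyNA(df)) stopf("missing values in covariate table")
  df$sample <- as.character(df$sample)
  df$diagnosis <- factor(df$diagnosis)
  if (nlevels(droplevels(df$diagnosis)) != 2L)
    stopf("diagnosis must have exactly 2 observed levels, got %d",
          nlevels(droplevels(df$diagnosis)))
  df$diagnosis <- droplevels(df$diagnosis)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Construct a binary TF-gene motif prior network
#'
#' @param weights TF x gene matrix; any positive entry marks a motif hit and
#'   is stored as 1.
#' @param tf_names,gene_names axis identifiers.
#' @return an object of class `prior_network`.
#' @export
prior_network <- function(weights, tf_names = rownames(weights),
                          gene_names = colnames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(tf_names) || is.null(gene_names)) stopf("prior needs axis names")
  if (length(tf_names) != nrow(weights) || length(gene_names) != ncol(weights))
    stopf("prior axis lengths do not match matrix shape")
  if (any(weights < 0)) stopf("motif prior weights must be non-negative")
  weights <- (weights > 0) + 0
  dimnames(weights) <- list(tf_names, gene_names)
  structure(list(tf_names = as.character(tf_names),
                 gene_names = as.character(gene_names), weights = weights),
            class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf("prior_network: %d TFs x %d genes, %d motif edges\n",
              length(x$tf_names), length(x$gene_names), sum(x$weights)))
  invisible(x)
}

#' Construct a TF-TF protein-interaction matrix
#'
#' @param scores symmetric TF x TF matrix in `[0, 1]` (or binary after
#'   thresholding).
#' @param tf_names axis identifiers.
#' @param threshold_applied optional score threshold already applied.
#' @return an object of class `ppi_matrix`.
#' @export
ppi_matrix <- function(scores, tf_names = rownames(scores),
                       threshold_applied = NULL) {
  scores <- as.matrix(scores)
  if (is.null(tf_names)) stopf("PPI matrix needs TF names")
  if (nrow(scores) != ncol(scores)) stopf("PPI matrix must be square")
  if (length(tf_names) != nrow(scores)) stopf("PPI axis length mismatch")
  if (any(scores < 0 | scores > 1)) stopf("PPI scores must lie in [0, 1]")
  if (max(abs(scores - t(scores))) > 1e-12) stopf("PPI matrix must be symmetric")
  dimnames(scores) <- list(tf_names, tf_names)
  structure(list(tf_names = as.character(tf_names), scores = scores,
                 threshold_applied = threshold_applied),
            class = "ppi_matrix")
}

#' @export
print.ppi_matrix <- function(x, ...) {
  cat(sprintf("ppi_matrix: %d TFs%s\n", length(x$tf_names),
              if (!is.null(x$threshold_applied))
                sprintf(" (binarised at %g)", x$threshold_applied) else ""))
  invisible(x)
}

#' Construct a TF-gene regulatory network
#'
#' The result of PANDA message passing: a dense TF x gene matrix of edge
#' scores (z-score scale), plus convergence bookkeeping.
#'
#' @param weights TF x gene numeric matrix of edge scores.
#' @param tf_names,gene_names axis identifiers.
#' @param n_iterations number of message-passing iterations performed.
#' @param converged logical convergence flag.
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(weights, tf_names = rownames(weights),
                               gene_names = colnames(weights),
                               n_iterations = NA_integer_, converged = NA) {
  weights <- as.matrix(weights)
  if (is.null(tf_names) || is.null(gene_names)) stopf("network needs axis names")
  if (length(tf_names) != nrow(weights) || length(gene_names) != ncol(weights))
    stopf("network axis lengths do not match matrix shape")
  if (!all(is.finite(weights))) stopf("network weights must be finite")
  dimnames(weights) <- list(tf_names, gene_names)
  structure(list(tf_names = as.character(tf_names),
                 gene_names = as.character(gene_names), weights = weights,
                 n_iterations = as.integer(n_iterations), converged = converged),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d TFs x %d genes", length(x$tf_names),
              length(x$gene_names)))
  if (!is.na(x$n_iterations))
    cat(sprintf(" (%d iterations, %s)", x$n_iterations,
                if (isTRUE(x$converged)) "converged" else "not converged"))
  cat("\n")
  invisible(x)
}

#' Construct a signed TF signature
#'
#' A disease or drug perturbation summarised as an ordered list of TFs with
#' increased targeting (`positive`) and one with decreased targeting
#' (`negative`).  The two lists must be disjoint and each at most `k` long.
#'
#' @param name signature label.
#' @param positive,negative character vectors of TF identifiers.
#' @param k signature half-size bound (defaults to the longer list).
#' @return an object of class `signature`.
#' @export
new_signature <- function(name, positive, negative,
                          k = max(length(positive), length(negative))) {
  positive <- as.character(positive); negative <- as.character(negative)
  both <- intersect(positive, negative)
  if (length(both))
    stopf("TF(s) in both signature halves: %s", paste(both, collapse = ", "))
  if (anyDuplicated(positive) || anyDuplicated(negative))
    stopf("duplicated TF within a signature half")
  if (length(positive) > k || length(negative) > k)
    stopf("signature halves exceed k = %d", k)
  structure(list(name = as.character(name), positive = positive,
                 negative = negative, k = as.integer(k)),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d up / %d down TFs (k = %d)\n", x$name,
              length(x$positive), length(x$negative), x$k))
  invisible(x)
}

#' Construct a drug-signature database
#'
#' @param drugs named list of [new_signature()] objects.
#' @param vocabulary optional TF vocabulary; extended to cover all members.
#' @param metadata optional named list of free-form per-drug metadata.
#' @return an object of class `drug_signature_db`.
#' @export
drug_signature_db <- function(drugs, vocabulary = NULL, metadata = NULL) {
  if (!length(drugs)) stopf("drug database is empty")
  if (is.null(names(drugs)) || anyDuplicated(names(drugs)) || any(names(drugs) == ""))
    stopf("drugs must have unique non-empty names")
  for (d in drugs)
    if (!inherits(d, "signature")) stopf("every drug entry must be a signature")
  members <- unique(unlist(lapply(drugs, function(d) c(d$positive, d$negative))))
  vocabulary <- sort(unique(c(vocabulary, members)))
  structure(list(drugs = drugs, vocabulary = vocabulary,
                 metadata = metadata %||% list()),
            class = "drug_signature_db")
}

#' @export
print.drug_signature_db <- function(x, ...) {
  cat(sprintf("drug_signature_db: %d drugs over %d TFs\n",
              length(x$drugs), length(x$vocabulary)))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param descriptions optional character vector, one per set.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets)) stopf("gene-set collection is empty")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("gene sets must have unique names")
  if (any(!lengths(sets))) stopf("empty gene set: %s",
                                 paste(names(sets)[!lengths(sets)], collapse = ", "))
  descriptions <- descriptions %||% rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = lapply(sets, as.character), descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
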