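# Count filtering, duplicate-gene collapsing, covariate residualisation and
# the Pearson co-expression input for network inference.

#' Filter lowly expressed genes by counts per million
#'
#' CPM(g, s) = counts(g, s) / library_size(s) * 1e6, with library size the
#' raw column sum.  A gene is kept iff its CPM exceeds `cpm_threshold`
#' (strictly) in at least `ceiling(sample_fraction * n_samples)` samples.
#' Raw counts, not CPM, are returned for the kept genes: no between-sample
#' normalisation is applied anywhere in this pipeline, since normalisation
#' has been reported to hurt co-expression network construction.
#'
#' @param expr an [expression_matrix()] of counts.
#' @param cpm_threshold CPM cutoff, default 0.5.
#' @param sample_fraction fraction of samples required above the cutoff,
#'   default 0.3.
#' @return a filtered [expression_matrix()] of raw counts.
#' @export
cpm_filter <- function(expr, cpm_threshold = 0.5, sample_fraction = 0.3) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$kind != "counts") stopf("cpm_filter expects a counts matrix")
  lib <- colSums(expr$values)
  if (any(lib == 0))
    stopf("all-zero sample column(s): %s (CPM undefined)",
          paste(expr$sample_names[lib == 0], collapse = ", "))
  cpm <- sweep(expr$values, 2, lib, `/`) * 1e6
  need <- ceiling(sample_fraction * ncol(expr$values))
  keep <- rowSums(cpm > cpm_threshold) >= need
  expression_matrix(expr$values[keep, , drop = FALSE],
                    expr$gene_names[keep], expr$sample_names, kind = "counts")
}

#' Average duplicated gene rows and drop all-zero genes
#'
#' Rows sharing a gene identifier are replaced by their element-wise mean at
#' the position of first occurrence; rows that are entirely zero are removed.
#'
#' @param expr an [expression_matrix()].
#' @return an [expression_matrix()] with unique gene identifiers.
#' @export
collapse_duplicates <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- expr$gene_names
  if (anyDuplicated(genes)) {
    first <- !duplicated(genes)
    vals <- rowsum(expr$values, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    vals <- vals[match(genes[first], unique(genes)), , drop = FALSE]
    genes <- genes[first]
  } else {
    vals <- expr$values
  }
  nonzero <- rowSums(vals != 0) > 0
  expression_matrix(vals[nonzero, , drop = FALSE], genes[nonzero],
                    expr$sample_names, kind = expr$kind)
}

# Build the per-covariate design blocks (dummy-coded, no intercept column)
# used by both variance_partition and residualize.
covariate_blocks <- function(covariates, columns) {
  blocks <- list()
  for (cn in columns) {
    v <- covariates[[cn]]
    if (is.numeric(v)) {
      blocks[[cn]] <- matrix(v, ncol = 1, dimnames = list(NULL, cn))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) stopf("covariate '%s' is constant", cn)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cn, levels(f)[-1])
      blocks[[cn]] <- mm
    }
  }
  blocks
}

check_full_rank <- function(X, labels) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("collinear covariate design; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  q
}

#' Partition per-gene expression variance across covariates
#'
#' For every gene a fixed-effects linear model on all covariates is fitted
#' and the coefficient-of-determination is attributed to individual
#' covariates by averaging the sequential R-squared gain over all covariate
#' orderings (Shapley decomposition; identical to sequential R-squared for
#' orthogonal designs).  Fractions are non-negative up to numerical noise and
#' sum to 1 with the residual fraction.
#'
#' @param expr an [expression_matrix()].
#' @param covariates a [covariate_table()] aligned with `expr`.
#' @return a data.frame (class `variance_partition`), one row per gene, with
#'   one fraction column per covariate plus `residual`.
#' @export
variance_partition <- function(expr, covariates) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(covariates, "covariate_table"))
  covariates <- align_covariates(covariates, expr)
  covnames <- setdiff(names(covariates), "sample")
  blocks <- covariate_blocks(covariates, covnames)
  n <- ncol(expr$values)
  X_full <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  check_full_rank(X_full, colnames(X_full))

  Y <- expr$values
  tss <- rowSums((Y - rowMeans(Y))^2)
  k <- length(covnames)
  # R^2 for every covariate subset, computed jointly for all genes
  subset_r2 <- new.env(parent = emptyenv())
  r2_of <- function(members) {
    key <- paste0("s:", paste(sort(members), collapse = "|"))
    if (exists(key, envir = subset_r2, inherits = FALSE))
      return(get(key, envir = subset_r2, inherits = FALSE))
    X <- cbind(1, do.call(cbind, c(list(matrix(nrow = n, ncol = 0)),
                                   blocks[members])))
    Q <- qr.Q(qr(X))
    fitted <- (Y %*% Q) %*% t(Q)
    rss <- rowSums((Y - fitted)^2)
    r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
    assign(key, r2, envir = subset_r2)
    r2
  }
  frac <- matrix(0, nrow(Y), k, dimnames = list(expr$gene_names, covnames))
  subsets <- lapply(0:(2^k - 1), function(m) covnames[bitwAnd(m, 2^(0:(k - 1))) > 0])
  weights <- factorial(0:(k - 1)) * factorial(k - 1 - (0:(k - 1))) / factorial(k)
  for (cn in covnames) {
    for (S in subsets) {
      if (cn %in% S) next
      gain <- r2_of(c(S, cn)) - r2_of(S)
      frac[, cn] <- frac[, cn] + weights[length(S) + 1] * gain
    }
  }
  res <- data.frame(gene = expr$gene_names, frac,
                    residual = 1 - r2_of(covnames),
                    check.names = FALSE, row.names = NULL)
  class(res) <- c("variance_partition", "data.frame")
  res
}

align_covariates <- function(covariates, expr) {
  m <- match(expr$sample_names, covariates$sample)
  if (anyNA(m))
    stopf("sample(s) missing from covariate table: %s",
          paste(expr$sample_names[is.na(m)], collapse = ", "))
  out <- covariates[m, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove nuisance covariate effects, keeping the diagnosis contrast
#'
#' Per gene, fits `y = intercept + beta_keep * keep + sum(beta_nuis * nuis)`
#' by ordinary least squares and returns
#' `intercept + beta_keep * keep + (y - fitted)`: nuisance effects are
#' regressed out while the fitted effect of the kept variable (by default
#' `diagnosis`) and the intercept are added back.  This is a fixed-effects
#' approximation of mixed-model residualisation; for balanced designs the
#' two coincide in expectation.
#'
#' @param expr an [expression_matrix()].
#' @param covariates a [covariate_table()] aligned with `expr`.
#' @param keep name of the covariate column to retain, default `"diagnosis"`.
#' @return an [expression_matrix()] of kind `"residuals"`.
#' @export
residualize <- function(expr, covariates, keep = "diagnosis") {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(covariates, "covariate_table"))
  covariates <- align_covariates(covariates, expr)
  covnames <- setdiff(names(covariates), "sample")
  if (!keep %in% covnames) stopf("keep column '%s' not in covariate table", keep)
  blocks <- covariate_blocks(covariates, covnames)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  q <- check_full_rank(X, colnames(X))
  keep_cols <- c("(Intercept)", colnames(blocks[[keep]]))
  B <- t(qr.coef(q, t(expr$values)))        # genes x coefficients
  fitted <- B %*% t(X)
  addback <- B[, keep_cols, drop = FALSE] %*% t(X[, keep_cols, drop = FALSE])
  out <- addback + (expr$values - fitted)
  expression_matrix(out, expr$gene_names, expr$sample_names, kind = "residuals")
}

#' Gene-gene Pearson co-expression
#'
#' Computes the gene x gene Pearson correlation matrix across samples.
#' Zero-variance genes get correlation 0 off the diagonal and 1 on it, so
#' downstream message passing always receives finite input.
#'
#' @param expr an [expression_matrix()] (typically residuals).
#' @return symmetric correlation matrix with unit diagonal, gene names on
#'   both axes.
#' @export
pearson_coexpression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 3) stopf("need >= 3 samples for co-expression")
  C <- suppressWarnings(stats::cor(t(expr$values)))
  if (anyNA(C)) {
    C[is.na(C)] <- 0
    diag(C) <- 1
  }
  dimnames(C) <- list(expr$gene_names, expr$gene_names)
  C
}
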