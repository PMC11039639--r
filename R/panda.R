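# Legacy PANDA message passing: merges a binary motif prior, a TF-TF protein
# interaction network and gene-gene co-expression into a dense TF x gene
# matrix of edge scores by iteratively "passing messages" (responsibility and
# availability, both Tanimoto similarities) until the network stops moving.

#' Message-passing parameters
#'
#' @param alpha learning rate in `[0, 1]`; default 0.1.  `alpha = 0` is the
#'   degenerate identity limit: no message is mixed in and the returned
#'   network equals the T-normalised motif prior.
#' @param tolerance convergence threshold on the mean absolute disagreement
#'   between the network and the incoming message; default 0.001.
#' @param max_iter iteration cap, default 200.
#' @return an object of class `panda_params`.
#' @export
panda_params <- function(alpha = 0.1, tolerance = 0.001, max_iter = 200) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (tolerance <= 0) stopf("tolerance must be > 0")
  if (max_iter < 1) stopf("max_iter must be >= 1")
  structure(list(alpha = alpha, tolerance = tolerance,
                 max_iter = as.integer(max_iter), mode = "legacy"),
            class = "panda_params")
}

#' Align motif, PPI and expression onto shared axes
#'
#' Implements the strict intersection semantics (remove-missing): TFs are
#' restricted to those present in both the motif prior and the PPI, genes to
#' those present in both the motif prior and the expression matrix.  All
#' outputs share identical sorted axes; co-expression is computed on the
#' gene intersection.
#'
#' @param motif a [prior_network()].
#' @param ppi a [ppi_matrix()].
#' @param expr an [expression_matrix()] (residuals or counts).
#' @return list with `motif` (TF x gene matrix), `ppi` (TF x TF matrix),
#'   `coexpr` (gene x gene Pearson matrix), `tf_names`, `gene_names`.
#' @export
prepare_inputs <- function(motif, ppi, expr) {
  stopifnot(inherits(motif, "prior_network"), inherits(ppi, "ppi_matrix"),
            inherits(expr, "expression_matrix"))
  tfs <- sort(intersect(motif$tf_names, ppi$tf_names))
  genes <- sort(intersect(motif$gene_names, expr$gene_names))
  if (!length(tfs)) stopf("empty TF intersection between motif and PPI")
  if (!length(genes)) stopf("empty gene intersection between motif and expression")
  sub_expr <- expression_matrix(
    expr$values[match(genes, expr$gene_names), , drop = FALSE],
    genes, expr$sample_names, kind = expr$kind)
  list(motif = motif$weights[tfs, genes, drop = FALSE],
       ppi = ppi$scores[tfs, tfs, drop = FALSE],
       coexpr = pearson_coexpression(sub_expr),
       tf_names = tfs, gene_names = genes)
}

#' Row-and-column z-score normalisation (T-normalisation)
#'
#' `Z(i, j) = (Zrow(i, j) + Zcol(i, j)) / sqrt(2)` where `Zrow` / `Zcol`
#' z-score within rows / columns using the population standard deviation.
#' A row or column with zero spread contributes 0 instead of NaN, so
#' constant priors cannot poison the run.
#'
#' @param M numeric matrix.
#' @return matrix of the same shape.
#' @export
t_normalize <- function(M) {
  if (!length(M)) stopf("cannot normalise an empty matrix")
  if (!all(is.finite(M))) stopf("non-finite entries in matrix to normalise")
  n_r <- nrow(M); n_c <- ncol(M)
  rmu <- rowMeans(M)
  rsd <- sqrt(pmax(rowMeans(M * M) - rmu^2, 0))
  cmu <- colMeans(M)
  csd <- sqrt(pmax(colMeans(M * M) - cmu^2, 0))
  Zr <- (M - rmu) / ifelse(rsd > 0, rsd, Inf)
  Zc <- (M - matrix(cmu, n_r, n_c, byrow = TRUE)) /
    matrix(ifelse(csd > 0, csd, Inf), n_r, n_c, byrow = TRUE)
  (Zr + Zc) / sqrt(2)
}

#' Tanimoto similarity kernel
#'
#' `T(i, j) = (X Y)(i, j) / sqrt(||X(i, .)||^2 + ||Y(., j)||^2 - |(X Y)(i, j)|)`
#' with the denominator floored at 1e-10 to guard all-zero rows.
#'
#' @param X numeric `a x k` matrix.
#' @param Y numeric `k x b` matrix.
#' @return `a x b` similarity matrix.
#' @export
tanimoto <- function(X, Y) {
  if (ncol(X) != nrow(Y))
    stopf("tanimoto dimension mismatch: %dx%d vs %dx%d",
          nrow(X), ncol(X), nrow(Y), ncol(Y))
  A <- X %*% Y
  den <- sqrt(pmax(outer(rowSums(X * X), colSums(Y * Y), `+`) - abs(A), 0))
  A / pmax(den, 1e-10)
}

#' Infer a regulatory network by legacy PANDA message passing
#'
#' Inputs must come from [prepare_inputs()] (aligned sorted axes).  The
#' motif prior `W`, PPI `P` and co-expression `C` are each T-normalised,
#' then iterated:
#' \itemize{
#'   \item responsibility `R = tanimoto(P, W)`; availability
#'     `A = tanimoto(W, C)`;
#'   \item `hamming = mean(|W - (R + A)/2|)`, the pre-mixing disagreement
#'     used by the reference legacy implementations;
#'   \item `W <- (1 - alpha) W + alpha (R + A)/2`;
#'   \item while not converged, `P` and `C` are updated towards the network
#'     self-similarity `tanimoto(W, t(W))` / `tanimoto(t(W), W)`, with the
#'     legacy diagonal refill: the diagonal is replaced by the off-diagonal
#'     population standard deviation of its row times the matrix dimension
#'     times `exp(2 * alpha * step)`.
#' }
#' Iteration stops when `hamming < tolerance` or `max_iter` is reached.
#'
#' @param motif TF x gene binary prior matrix (aligned).
#' @param ppi TF x TF symmetric matrix (aligned).
#' @param coexpr gene x gene symmetric correlation matrix (aligned).
#' @param params a [panda_params()] object.
#' @return a [regulatory_network()] of edge scores with `n_iterations`,
#'   `converged` and, as attribute `"hamming"`, the final disagreement.
#' @export
panda <- function(motif, ppi, coexpr, params = panda_params()) {
  stopifnot(inherits(params, "panda_params"))
  if (is.list(motif) && !is.null(motif$motif))
    stopf("pass prepare_inputs() components individually: panda(pi$motif, pi$ppi, pi$coexpr)")
  motif <- as.matrix(motif); ppi <- as.matrix(ppi); coexpr <- as.matrix(coexpr)
  n_tfs <- nrow(motif); n_genes <- ncol(motif)
  if (nrow(ppi) != n_tfs || ncol(ppi) != n_tfs)
    stopf("PPI shape %dx%d does not match %d TFs", nrow(ppi), ncol(ppi), n_tfs)
  if (nrow(coexpr) != n_genes || ncol(coexpr) != n_genes)
    stopf("co-expression shape does not match %d genes", n_genes)
  if (max(abs(ppi - t(ppi))) > 1e-8) stopf("PPI must be symmetric")
  if (max(abs(coexpr - t(coexpr))) > 1e-8) stopf("co-expression must be symmetric")
  tf_names <- rownames(motif) %||% sprintf("TF%d", seq_len(n_tfs))
  gene_names <- colnames(motif) %||% sprintf("G%d", seq_len(n_genes))

  W <- t_normalize(motif)
  P <- t_normalize(ppi)
  C <- t_normalize(coexpr)
  alpha <- params$alpha
  hamming <- Inf
  step <- 0L
  while (hamming > params$tolerance && step < params$max_iter) {
    R <- tanimoto(P, W)
    A <- tanimoto(W, C)
    RA <- 0.5 * (R + A)
    hamming <- mean(abs(W - RA))
    if (!is.finite(hamming))
      stopf("non-finite network update at iteration %d", step + 1L)
    W <- (1 - alpha) * W + alpha * RA
    if (hamming > params$tolerance) {
      Pu <- legacy_diagonal(tanimoto(W, t(W)), n_tfs, alpha, step)
      P <- (1 - alpha) * P + alpha * Pu
      Cu <- legacy_diagonal(tanimoto(t(W), W), n_genes, alpha, step)
      C <- (1 - alpha) * C + alpha * Cu
      if (!all(is.finite(P)) || !all(is.finite(C)))
        stopf("non-finite prior update at iteration %d", step + 1L)
    }
    step <- step + 1L
  }
  converged <- hamming < params$tolerance
  if (!converged)
    warnf("PANDA did not converge in %d iterations (hamming %.3g > %.3g)",
          step, hamming, params$tolerance)
  net <- regulatory_network(W, tf_names, gene_names,
                            n_iterations = step, converged = converged)
  attr(net, "hamming") <- hamming
  net
}

# Legacy diagonal refill for the square self-similarity updates: replace the
# diagonal by (population sd of the off-diagonal entries of each row) * n *
# exp(2 * alpha * step).
legacy_diagonal <- function(M, num, alpha, step) {
  if (num == 1) { M[1, 1] <- 0; return(M) }
  diag(M) <- NA
  mu <- rowMeans(M, na.rm = TRUE)
  sd_off <- sqrt(pmax(rowMeans(M * M, na.rm = TRUE) - mu^2, 0))
  diag(M) <- sd_off * num * exp(2 * alpha * step)
  M
}

#' Run legacy PANDA end-to-end from package containers
#'
#' Convenience wrapper: [prepare_inputs()] then [panda()].
#'
#' @inheritParams prepare_inputs
#' @param params a [panda_params()] object.
#' @return a [regulatory_network()].
#' @export
panda_network <- function(motif, ppi, expr, params = panda_params()) {
  pi <- prepare_inputs(motif, ppi, expr)
  panda(pi$motif, pi$ppi, pi$coexpr, params)
}
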