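# Case-minus-control differential network, node targeting scores, per-TF
# significance testing and the signed top-TF signature.

#' Differential regulatory network
#'
#' Aligns the two networks on the sorted intersection of their TF and gene
#' axes and subtracts control edge weights from case edge weights.  Positive
#' entries mean increased targeting in the case condition, negative entries
#' decreased targeting.  Gene targeting is the weighted in-degree difference
#' (column sum of delta), TF targeting the weighted out-degree difference
#' (row sum).
#'
#' @param net_case,net_control [regulatory_network()] objects.
#' @return an object of class `differential_network` with fields `tf_names`,
#'   `gene_names`, `delta`, `gene_targeting`, `tf_targeting`.
#' @export
differential_network <- function(net_case, net_control) {
  stopifnot(inherits(net_case, "regulatory_network"),
            inherits(net_control, "regulatory_network"))
  tfs <- sort(intersect(net_case$tf_names, net_control$tf_names))
  genes <- sort(intersect(net_case$gene_names, net_control$gene_names))
  if (!length(tfs) || !length(genes))
    stopf("empty TF or gene intersection between the two networks")
  delta <- net_case$weights[tfs, genes, drop = FALSE] -
    net_control$weights[tfs, genes, drop = FALSE]
  structure(list(tf_names = tfs, gene_names = genes, delta = delta,
                 gene_targeting = colSums(delta),
                 tf_targeting = rowSums(delta)),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("differential_network: %d TFs x %d genes; TF targeting range [%.3g, %.3g]\n",
              length(x$tf_names), length(x$gene_names),
              min(x$tf_targeting), max(x$tf_targeting)))
  invisible(x)
}

#' Per-TF differential targeting tests
#'
#' For each TF the paired samples are its case and control edge weights
#' across the shared target genes.  A two-sided Wilcoxon signed-rank test is
#' applied to the paired differences (exact for n <= 25 non-zero differences
#' without ties, normal approximation with continuity correction otherwise;
#' zero differences are dropped, Wilcoxon's original rule).  A Shapiro-Wilk
#' normality p-value on the differences is reported as a diagnostic, and
#' Benjamini-Hochberg q-values are computed across all TFs.
#'
#' @param net_case,net_control [regulatory_network()] objects.
#' @param alpha_fdr FDR level used for the `significant` flag, default 0.05.
#' @return a data.frame (class `tf_test_result`), one row per TF: `tf`,
#'   `targeting_diff`, `statistic`, `p_value`, `shapiro_p`, `q_value`,
#'   `direction`, `significant`, `all_zero`.
#' @export
tf_significance <- function(net_case, net_control, alpha_fdr = 0.05) {
  stopifnot(inherits(net_case, "regulatory_network"),
            inherits(net_control, "regulatory_network"))
  tfs <- sort(intersect(net_case$tf_names, net_control$tf_names))
  genes <- sort(intersect(net_case$gene_names, net_control$gene_names))
  if (length(genes) < 6)
    stopf("need >= 6 shared genes for a meaningful signed-rank test, got %d",
          length(genes))
  case <- net_case$weights[tfs, genes, drop = FALSE]
  ctl <- net_control$weights[tfs, genes, drop = FALSE]
  out <- data.frame(tf = tfs, targeting_diff = rowSums(case - ctl),
                    statistic = NA_real_, p_value = NA_real_,
                    shapiro_p = NA_real_, all_zero = FALSE)
  for (i in seq_along(tfs)) {
    d <- case[i, ] - ctl[i, ]
    dnz <- d[d != 0]
    if (!length(dnz)) {
      out$p_value[i] <- 1
      out$all_zero[i] <- TRUE
      next
    }
    exact <- length(dnz) <= 25 && !anyDuplicated(abs(dnz))
    wt <- suppressWarnings(stats::wilcox.test(dnz, mu = 0, exact = exact,
                                              correct = TRUE))
    out$statistic[i] <- unname(wt$statistic)
    out$p_value[i] <- wt$p.value
    ds <- if (length(d) > 5000) d[seq(1, length(d), length.out = 5000)] else d
    out$shapiro_p[i] <- tryCatch(stats::shapiro.test(ds)$p.value,
                                 error = function(e) NA_real_)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$targeting_diff >= 0, "increased", "decreased")
  out$significant <- out$q_value < alpha_fdr
  class(out) <- c("tf_test_result", "data.frame")
  out
}

#' Extract the signed top-k TF signature of a differential network
#'
#' The positive half holds up to `k` TFs with the largest strictly positive
#' differential targeting scores (descending); the negative half up to `k`
#' TFs with the most negative scores (ascending).  Zero-targeting TFs are
#' excluded; ties are broken by lexicographic TF name.
#'
#' @param diffnet a [differential_network()].
#' @param k signature half-size, default 100.
#' @param name signature label, default `"disease"`.
#' @return a [new_signature()] object.
#' @export
top_signature <- function(diffnet, k = 100, name = "disease") {
  stopifnot(inherits(diffnet, "differential_network"))
  s <- diffnet$tf_targeting
  tfs <- diffnet$tf_names
  if (all(s == 0)) stopf("no TF with nonzero differential targeting")
  pos_idx <- which(s > 0)
  pos_idx <- pos_idx[order(-s[pos_idx], tfs[pos_idx])]
  neg_idx <- which(s < 0)
  neg_idx <- neg_idx[order(s[neg_idx], tfs[neg_idx])]
  new_signature(name,
                tfs[utils::head(pos_idx, k)],
                tfs[utils::head(neg_idx, k)], k = k)
}
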