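# Rank-based gene set enrichment (weighted running-sum statistic) of
# differential gene targeting scores, with a gene-label permutation null.

#' Build a ranked list from named scores
#'
#' @param scores named numeric vector (e.g. differential gene targeting).
#' @return named numeric vector sorted by decreasing score (ties broken by
#'   gene name for determinism), class `ranked_list`.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stopf("scores must be uniquely named by gene")
  if (anyNA(scores)) stopf("scores must be non-missing")
  ord <- order(-scores, names(scores))
  structure(scores[ord], class = "ranked_list")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom; each set member ("hit") increments
#' the running sum by `|score|^p / sum(|score of hits|^p)` and each
#' non-member decrements it by `1 / (N - N_hits)`.  The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (signed);
#' the leading edge contains the members at or before the extremum for a
#' positive score, and at or after it for a negative one.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of member genes.
#' @param weight_exponent exponent `p` on the scores, default 1.
#' @return list with `es`, `running_sum`, `leading_edge`; `NULL` (with a
#'   warning) if the set has no member in the list.
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- names(ranked) %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) {
    warnf("gene set has no member in the ranked list; skipped")
    return(NULL)
  }
  N <- length(ranked)
  if (n_hit == N) stopf("gene set covers the whole ranked list")
  w <- abs(unclass(ranked))^weight_exponent
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / n_hit, N)
  steps <- ifelse(hit, inc, -1 / (N - n_hit))
  running <- cumsum(steps)
  at <- which.max(abs(running))
  es <- running[[at]]
  le <- if (es >= 0) names(ranked)[hit & seq_len(N) <= at]
        else names(ranked)[hit & seq_len(N) >= at]
  list(es = unname(es), running_sum = unname(running), leading_edge = le)
}

#' Gene set enrichment with a gene-label permutation null
#'
#' Sets are filtered to those with between `min_size` and `max_size` members
#' present in the ranked list.  For each retained set, `n_perm` null
#' enrichment scores are drawn by randomly re-assigning the set labels over
#' the list (scores stay fixed); the normalised enrichment score divides the
#' observed score by the mean magnitude of same-sign null scores, and the
#' two-sided empirical p-value uses the add-one rule
#' `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`.  Permutation streams
#' are seeded per set name, so results do not depend on evaluation order and
#' identical sets get identical results.  BH q-values are computed across
#' all retained sets with a defined NES.
#'
#' @param ranked a [ranked_list()].
#' @param sets a [gene_set_collection()].
#' @param n_perm permutations per set, default 1000 (a warning is issued
#'   below 100).
#' @param min_size,max_size in-list set size bounds, defaults 10 and 500.
#' @param weight_exponent exponent on the scores, default 1.
#' @param seed integer seed expanded into per-set substreams.
#' @return a data.frame (class `enrichment_result`) sorted by p-value:
#'   `set`, `size`, `es`, `nes`, `p_value`, `q_value`, `leading_edge`
#'   (list column).
#' @export
gsea <- function(ranked, sets, n_perm = 1000, min_size = 10, max_size = 500,
                 weight_exponent = 1, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(sets, "gene_set_collection"))
  if (n_perm < 100) warnf("n_perm = %d < 100: permutation p-values are unstable", n_perm)
  genes <- names(ranked)
  in_list <- lapply(sets$sets, intersect, x = genes)
  sizes <- lengths(in_list)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stopf("no gene set within size bounds [%d, %d]", min_size, max_size)
  nm <- names(sets$sets)[keep]

  rows <- lapply(nm, function(set_name) {
    members <- in_list[[set_name]]
    obs <- gsea_es(ranked, members, weight_exponent)
    set.seed(stage_seed(seed, paste0("gsea:", set_name)))
    null_es <- replicate(n_perm, {
      fake <- sample(genes, length(members))
      gsea_es(ranked, fake, weight_exponent)$es
    })
    same_sign <- null_es[sign(null_es) == sign(obs$es) & null_es != 0]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
    data.frame(set = set_name, size = length(members), es = obs$es, nes = nes,
               p_value = p, leading_edge = I(list(obs$leading_edge)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  ok <- !is.na(res$nes)
  res$q_value[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res <- res[order(res$p_value, res$set), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
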