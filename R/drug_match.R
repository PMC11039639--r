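# Signature-reversion drug matching: cosine similarity between signed TF
# signatures, size-matched empirical null, BH q-values.

#' Signed vector representation of a signature
#'
#' +1 at positive members, -1 at negative members, 0 elsewhere over the
#' given vocabulary (extended on the fly to cover all members).
#'
#' @param sig a [new_signature()] object.
#' @param vocabulary character vector of TF identifiers.
#' @return named numeric vector over the (possibly extended) vocabulary.
#' @export
signature_vector <- function(sig, vocabulary = character(0)) {
  stopifnot(inherits(sig, "signature"))
  if (length(intersect(sig$positive, sig$negative)))
    stopf("signature halves overlap")
  vocab <- union(vocabulary, c(sig$positive, sig$negative))
  v <- stats::setNames(numeric(length(vocab)), vocab)
  v[sig$positive] <- 1
  v[sig$negative] <- -1
  v
}

#' Cosine similarity between two signed signatures
#'
#' Computed over the union vocabulary; algebraically equal to
#' `(|P∩P'| + |N∩N'| - |P∩N'| - |N∩P'|) / sqrt((|P|+|N|) (|P'|+|N'|))`.
#' A drug identical to the disease signature scores +1; a perfect reverser
#' (sign-flipped signature) scores -1 — more negative means more reversing.
#'
#' @param disease,drug [new_signature()] objects (both non-empty).
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_score <- function(disease, drug) {
  stopifnot(inherits(disease, "signature"), inherits(drug, "signature"))
  if (!length(c(disease$positive, disease$negative)))
    stopf("disease signature is empty")
  if (!length(c(drug$positive, drug$negative)))
    stopf("drug signature is empty")
  vocab <- unique(c(disease$positive, disease$negative,
                    drug$positive, drug$negative))
  a <- signature_vector(disease, vocab)[vocab]
  b <- signature_vector(drug, vocab)[vocab]
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Rank a drug database by signature reversal
#'
#' Scores every drug signature against the disease signature by cosine
#' similarity and sorts ascending (most reversing first).  Significance is
#' empirical: for each (positive size, negative size) class occurring in the
#' database, `n_null` random signatures of those sizes are drawn from the
#' vocabulary and scored; the one-sided reversal p-value is
#' `(1 + #{null <= observed}) / (n_null + 1)` (small cosine = strong
#' reversal), BH-adjusted across drugs.  Null draws are cached per size
#' class and seeded by the class, so the ranking is invariant to database
#' iteration order.
#'
#' @param disease a [new_signature()] object.
#' @param db a [drug_signature_db()].
#' @param n_null null draws per size class, default 10000.
#' @param seed integer seed.
#' @return a data.frame (class `drug_match`) sorted by cosine: `drug`,
#'   `cosine`, overlap counts (`pp`, `pn`, `np`, `nn`), `p_value`, `q_value`.
#' @export
match_drugs <- function(disease, db, n_null = 10000, seed = 1L) {
  stopifnot(inherits(disease, "signature"), inherits(db, "drug_signature_db"))
  vocab <- union(db$vocabulary, c(disease$positive, disease$negative))
  sizes <- vapply(db$drugs, function(d)
    c(length(d$positive), length(d$negative)), numeric(2))
  if (any(colSums(sizes) > length(vocab)))
    stopf("vocabulary (%d TFs) smaller than a drug signature", length(vocab))

  null_cache <- new.env(parent = emptyenv())
  null_for <- function(np, nn) {
    key <- sprintf("c:%d:%d", np, nn)
    if (exists(key, envir = null_cache, inherits = FALSE))
      return(get(key, envir = null_cache, inherits = FALSE))
    set.seed(stage_seed(seed, paste0("drugnull:", key)))
    draws <- vapply(seq_len(n_null), function(i) {
      picked <- sample(vocab, np + nn)
      rnd <- new_signature("null", utils::head(picked, np),
                           utils::tail(picked, nn), k = max(np, nn, 1L))
      cosine_score(disease, rnd)
    }, numeric(1))
    assign(key, draws, envir = null_cache)
    draws
  }

  res <- do.call(rbind, lapply(names(db$drugs), function(nm) {
    d <- db$drugs[[nm]]
    cs <- cosine_score(disease, d)
    nulls <- null_for(length(d$positive), length(d$negative))
    data.frame(drug = nm, cosine = cs,
               pp = length(intersect(disease$positive, d$positive)),
               pn = length(intersect(disease$positive, d$negative)),
               np = length(intersect(disease$negative, d$positive)),
               nn = length(intersect(disease$negative, d$negative)),
               p_value = (1 + sum(nulls <= cs)) / (length(nulls) + 1),
               stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$cosine, res$drug), ]
  rownames(res) <- NULL
  class(res) <- c("drug_match", "data.frame")
  res
}
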