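# Shared fixture builders and independent oracles used across the suite.

# Random aligned PANDA instance (binary motif, symmetric binary PPI with unit
# diagonal, Pearson co-expression from random expression).
random_panda_instance <- function(seed, n_tfs, n_genes, n_samples = 40) {
  set.seed(seed)
  tf <- sprintf("TF%02d", seq_len(n_tfs))
  gn <- sprintf("G%03d", seq_len(n_genes))
  motif <- matrix(rbinom(n_tfs * n_genes, 1, 0.2), n_tfs, n_genes,
                  dimnames = list(tf, gn))
  ppi <- matrix(rbinom(n_tfs * n_tfs, 1, 0.3), n_tfs, n_tfs)
  ppi <- pmax(ppi, t(ppi)); diag(ppi) <- 1
  dimnames(ppi) <- list(tf, tf)
  C <- stats::cor(matrix(rnorm(n_genes * n_samples), n_samples, n_genes))
  dimnames(C) <- list(gn, gn)
  list(motif = motif, ppi = ppi, coexpr = C)
}

write_dense_tsv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M)))
    writeLines(paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])),
                     collapse = "\t"), con)
}

# Runs the independent numpy transcription of legacy PANDA shipped with the
# package and returns its edge-weight matrix.
numpy_panda_oracle <- function(inst, alpha = 0.1, tolerance = 0.001,
                               max_iter = 200) {
  wd <- tempfile("panda_oracle_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  write_dense_tsv(inst$motif, file.path(wd, "motif.tsv"))
  write_dense_tsv(inst$ppi, file.path(wd, "ppi.tsv"))
  write_dense_tsv(inst$coexpr, file.path(wd, "coexpr.tsv"))
  script <- system.file("oracle", "panda_legacy_numpy.py", package = "pandiff")
  status <- system2("python", c(script, file.path(wd, "motif.tsv"),
                                file.path(wd, "ppi.tsv"),
                                file.path(wd, "coexpr.tsv"),
                                file.path(wd, "out.tsv"),
                                format(alpha, digits = 17),
                                format(tolerance, digits = 17), max_iter),
                    stdout = TRUE, stderr = TRUE)
  out_file <- file.path(wd, "out.tsv")
  if (!file.exists(out_file))
    stop("numpy oracle failed: ", paste(status, collapse = "\n"))
  as.matrix(utils::read.delim(out_file, row.names = 1, check.names = FALSE))
}

# Brute-force running-sum GSEA oracle: literal walk down the ranked list.
brute_force_es <- function(scores_sorted, gene_set, p = 1) {
  N <- length(scores_sorted)
  hits <- names(scores_sorted) %in% gene_set
  n_hit <- sum(hits)
  denom <- sum(abs(scores_sorted[hits])^p)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hits[i]) {
      cur + (if (denom > 0) abs(scores_sorted[i])^p / denom else 1 / n_hit)
    } else {
      cur - 1 / (N - n_hit)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (no ties, no zeros assumed).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  centre <- n * (n + 1) / 4
  mean(abs(vs - centre) >= abs(v_obs - centre))
}

# Closed-form cosine from set overlaps, for the dual-route identity check.
cosine_from_sets <- function(dis, drug) {
  num <- length(intersect(dis$positive, drug$positive)) +
    length(intersect(dis$negative, drug$negative)) -
    length(intersect(dis$positive, drug$negative)) -
    length(intersect(dis$negative, drug$positive))
  num / sqrt((length(dis$positive) + length(dis$negative)) *
               (length(drug$positive) + length(drug$negative)))
}

tiny_network <- function(weights, tfs = rownames(weights),
                         genes = colnames(weights)) {
  regulatory_network(weights, tfs, genes)
}
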