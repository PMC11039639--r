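# Readers and writers for every file format the pipeline touches.
# All tables are tab-delimited UTF-8 with '.' decimal; gz paths are handled
# transparently by R's connection layer.

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("%s file is empty: %s", what, path)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers.  Duplicate gene identifiers are retained (with a warning) for
#' later resolution by [collapse_duplicates()].  Any non-numeric or missing
#' cell is a located format error.
#'
#' @param path TSV file, optionally gzipped.
#' @param kind `"counts"` (default) or `"residuals"`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, kind = c("counts", "residuals")) {
  kind <- match.arg(kind)
  rows <- read_tsv_strict(path, "expression")
  header <- rows[[1]]
  if (length(header) < 2) stopf("expression header must list at least one sample")
  # header may or may not carry a leading cell for the gene-id column
  body <- rows[-1]
  if (!length(body)) stopf("expression file has no gene rows")
  ncell <- lengths(body)
  samples <- if (length(header) == ncell[1]) header[-1] else header
  if (any(ncell != length(samples) + 1L))
    stopf("ragged expression file: row %d has %d cells, expected %d",
          which(ncell != length(samples) + 1L)[1] + 1L,
          ncell[which(ncell != length(samples) + 1L)[1]], length(samples) + 1L)
  genes <- vapply(body, `[`, "", 1L)
  vals <- matrix(NA_real_, length(body), length(samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v))
    if (length(bad))
      stopf("non-numeric or missing value at gene '%s', sample '%s'",
            genes[i], samples[bad[1]])
    vals[i, ] <- v
  }
  if (anyDuplicated(genes))
    warnf("duplicated gene identifier(s): %s (kept; use collapse_duplicates)",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dimnames(vals) <- NULL
  structure(list(values = `dimnames<-`(vals, list(genes, samples)),
                 gene_names = genes, sample_names = samples, kind = kind),
            class = "expression_matrix")
}

#' Write an expression matrix to TSV
#' @param expr an [expression_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", expr$sample_names), collapse = "\t"), con)
  body <- apply(expr$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(expr$gene_names, body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample covariate table from TSV
#'
#' First column `sample`, a `diagnosis` column with exactly two observed
#' levels, and any further covariate columns (numeric columns are parsed as
#' numeric, others kept categorical).
#'
#' @param path TSV file.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  covariate_table(df)
}

#' Write a covariate table to TSV
#' @param cov a [covariate_table()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_covariates <- function(cov, path) {
  utils::write.table(as.data.frame(cov), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TF-gene motif prior from a 3-column edge list
#'
#' Columns `tf`, `gene`, `weight`.  The dense TF x gene matrix is built over
#' the union of listed names; absent pairs are 0 and any positive weight is
#' binarised to 1.  Duplicate pairs with conflicting weights are an error.
#'
#' @param path TSV file with a header row.
#' @return a [prior_network()].
#' @export
read_prior_edges <- function(path) {
  rows <- read_tsv_strict(path, "motif prior")
  body <- rows[-1]
  if (!length(body)) stopf("no edges in motif prior file: %s", path)
  if (any(lengths(body) != 3)) stopf("motif prior rows must have 3 columns")
  tf <- vapply(body, `[`, "", 1L)
  gene <- vapply(body, `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
  if (anyNA(w)) stopf("non-numeric motif weight at row %d", which(is.na(w))[1] + 1L)
  key <- paste(tf, gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    grp <- w[key == dup]
    if (length(unique(grp)) > 1)
      stopf("conflicting duplicate motif edge: %s", gsub("\r", " -> ", dup))
    keep <- !duplicated(key)
    tf <- tf[keep]; gene <- gene[keep]; w <- w[keep]
  }
  tfs <- sort(unique(tf)); genes <- sort(unique(gene))
  M <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  M[cbind(match(tf, tfs), match(gene, genes))] <- as.numeric(w > 0)
  prior_network(M)
}

#' Write a motif prior as a 3-column edge list (nonzero edges only)
#' @param prior a [prior_network()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_prior_edges <- function(prior, path) {
  stopifnot(inherits(prior, "prior_network"))
  idx <- which(prior$weights != 0, arr.ind = TRUE)
  df <- data.frame(tf = prior$tf_names[idx[, 1]],
                   gene = prior$gene_names[idx[, 2]],
                   weight = prior$weights[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style TF-TF interaction table and binarise it
#'
#' Columns `tf_a`, `tf_b`, `combined_score` with scores in `[0, 1]` (the
#' STRING 0-1000 scale divided by 1000 upstream).  The binary rule is
#' inclusive: 1 iff score >= `threshold`.  The matrix is symmetrised and its
#' diagonal set to 1.
#'
#' @param path TSV file with header.
#' @param threshold confidence cutoff, default 0.7 (high confidence).
#' @return a [ppi_matrix()] with `threshold_applied` recorded.
#' @export
read_ppi_table <- function(path, threshold = 0.7) {
  rows <- read_tsv_strict(path, "PPI")
  body <- rows[-1]
  if (!length(body)) stopf("no interactions in PPI file: %s", path)
  if (any(lengths(body) != 3)) stopf("PPI rows must have 3 columns")
  a <- vapply(body, `[`, "", 1L)
  b <- vapply(body, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
  if (anyNA(s)) stopf("non-numeric PPI score at row %d", which(is.na(s))[1] + 1L)
  if (any(s < 0 | s > 1))
    stopf("PPI score outside [0, 1] at row %d (value %g)",
          which(s < 0 | s > 1)[1] + 1L, s[which(s < 0 | s > 1)[1]])
  tfs <- sort(unique(c(a, b)))
  M <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  bin <- as.numeric(s >= threshold)
  M[cbind(match(a, tfs), match(b, tfs))] <- bin
  M <- pmax(M, t(M))   # symmetrise: an edge listed one way counts both ways
  diag(M) <- 1
  ppi_matrix(M, threshold_applied = threshold)
}

#' Write a PPI matrix as a 3-column score table (upper triangle + diagonal)
#' @param ppi a [ppi_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ppi_table <- function(ppi, path) {
  stopifnot(inherits(ppi, "ppi_matrix"))
  idx <- which(upper.tri(ppi$scores, diag = TRUE) & ppi$scores != 0, arr.ind = TRUE)
  df <- data.frame(tf_a = ppi$tf_names[idx[, 1]], tf_b = ppi$tf_names[idx[, 2]],
                   combined_score = ppi$scores[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member genes.  Duplicate members within a set
#' are de-duplicated with a warning; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  rows <- read_tsv_strict(path, "GMT")
  short <- which(lengths(rows) < 3)
  if (length(short))
    stopf("GMT line %d has %d fields; need name, description and >= 1 member",
          short[1], lengths(rows)[short[1]])
  nm <- vapply(rows, `[`, "", 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(rows, `[`, "", 2L)
  sets <- lapply(rows, function(r) {
    members <- r[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members))
      warnf("duplicated member(s) in set '%s' de-duplicated", r[1])
    unique(members)
  })
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param gsc a [gene_set_collection()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a dense regulatory network as long-format TSV
#'
#' Full-precision `tf`, `gene`, `weight` rows covering every TF x gene pair
#' (dense contract).  `read_network(write_network(x))` reproduces the weights
#' to better than 1e-12.
#'
#' @param net a [regulatory_network()].
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns a
#'   [regulatory_network()].
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  df <- data.frame(
    tf = rep(net$tf_names, times = length(net$gene_names)),
    gene = rep(net$gene_names, each = length(net$tf_names)),
    weight = sprintf("%.17g", as.vector(net$weights)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  rows <- read_tsv_strict(path, "network")
  body <- rows[-1]
  if (!length(body)) stopf("no edges in network file: %s", path)
  if (any(lengths(body) != 3)) stopf("network rows must have 3 columns")
  tf <- vapply(body, `[`, "", 1L)
  gene <- vapply(body, `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
  if (anyNA(w)) stopf("non-numeric network weight at row %d", which(is.na(w))[1] + 1L)
  tfs <- sort(unique(tf)); genes <- sort(unique(gene))
  if (length(tf) != length(tfs) * length(genes))
    stopf("network file is not dense: %d rows for %d TFs x %d genes",
          length(tf), length(tfs), length(genes))
  key <- paste(tf, gene, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate (tf, gene) pair in network file")
  M <- matrix(NA_real_, length(tfs), length(genes), dimnames = list(tfs, genes))
  M[cbind(match(tf, tfs), match(gene, genes))] <- w
  regulatory_network(M)
}

#' Read / write a drug-signature database as JSON
#'
#' JSON object mapping drug name to `{"up": [...], "down": [...]}` TF lists
#' (`up` = the drug's positive half, `down` = negative).
#'
#' @param path JSON file.
#' @return `read_drug_db` returns a [drug_signature_db()].
#' @export
read_drug_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(obj)) stopf("drug database is empty: %s", path)
  drugs <- lapply(names(obj), function(nm) {
    entry <- obj[[nm]]
    up <- as.character(entry$up %||% character(0))
    down <- as.character(entry$down %||% character(0))
    new_signature(nm, up, down, k = max(length(up), length(down), 1L))
  })
  names(drugs) <- names(obj)
  drug_signature_db(drugs)
}

#' @rdname read_drug_db
#' @param db a [drug_signature_db()].
#' @export
write_drug_db <- function(db, path) {
  stopifnot(inherits(db, "drug_signature_db"))
  obj <- lapply(db$drugs, function(d) list(up = d$positive, down = d$negative))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Write a drug-signature database as long-format TSV
#'
#' Columns `drug`, `tf`, `direction` (`up`/`down`); one row per signature
#' member.
#'
#' @param db a [drug_signature_db()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_drug_db_tsv <- function(db, path) {
  stopifnot(inherits(db, "drug_signature_db"))
  rows <- do.call(rbind, lapply(db$drugs, function(d) {
    rbind(
      if (length(d$positive))
        data.frame(drug = d$name, tf = d$positive, direction = "up"),
      if (length(d$negative))
        data.frame(drug = d$name, tf = d$negative, direction = "down"))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
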