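# End-to-end orchestration: preprocess -> per-group PANDA -> differential
# statistics -> enrichment -> drug matching, with a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter and input path.  File inputs may also be
#' passed as in-memory objects to [run_pipeline()]; the GMT and drug
#' database are optional (their stages are reported as skipped).
#'
#' @param counts,covariates,motif,ppi input file paths (TSV).
#' @param gmt optional gene-set GMT path.
#' @param drug_db optional drug-signature JSON path.
#' @param output_dir directory for artifacts; `NULL` disables writing.
#' @param cpm_threshold,sample_fraction CPM filter parameters (0.5, 0.3).
#' @param ppi_threshold STRING-style confidence cutoff, default 0.7.
#' @param keep covariate retained by residualisation, default `"diagnosis"`.
#' @param alpha,tolerance,max_iter message-passing parameters.
#' @param k signature half-size, default 100.
#' @param n_perm GSEA permutations, default 1000.
#' @param min_size,max_size GSEA set-size bounds.
#' @param n_null drug-match null draws, default 10000.
#' @param case_level diagnosis level treated as the case condition; `NULL`
#'   (default) takes the second factor level.
#' @param seed global integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, covariates = NULL, motif = NULL,
                            ppi = NULL, gmt = NULL, drug_db = NULL,
                            output_dir = NULL, cpm_threshold = 0.5,
                            sample_fraction = 0.3, ppi_threshold = 0.7,
                            keep = "diagnosis", alpha = 0.1,
                            tolerance = 0.001, max_iter = 200, k = 100,
                            n_perm = 1000, min_size = 10, max_size = 500,
                            n_null = 10000, case_level = NULL, seed = 1L) {
  for (p in c(counts, covariates, motif, ppi, gmt, drug_db))
    if (is.character(p) && !file.exists(p)) stopf("input file not found: %s", p)
  if (cpm_threshold < 0 || sample_fraction <= 0 || sample_fraction > 1)
    stopf("invalid CPM filter parameters")
  if (ppi_threshold < 0 || ppi_threshold > 1) stopf("ppi_threshold must be in [0, 1]")
  structure(list(counts = counts, covariates = covariates, motif = motif,
                 ppi = ppi, gmt = gmt, drug_db = drug_db,
                 output_dir = output_dir, cpm_threshold = cpm_threshold,
                 sample_fraction = sample_fraction,
                 ppi_threshold = ppi_threshold, keep = keep,
                 alpha = alpha, tolerance = tolerance,
                 max_iter = as.integer(max_iter), k = as.integer(k),
                 n_perm = as.integer(n_perm), min_size = as.integer(min_size),
                 max_size = as.integer(max_size), n_null = as.integer(n_null),
                 case_level = case_level, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("counts", "covariates", "motif", "ppi", "gmt", "drug_db",
                "output_dir"))
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  do.call(pipeline_config, cfg)
}

#' Run the full differential-network drug-repurposing pipeline
#'
#' Stages: read inputs, collapse duplicate genes and drop all-zero rows,
#' CPM-filter, residualise nuisance covariates (keeping diagnosis), align
#' motif/PPI/expression on a shared TF and gene intersection, run legacy
#' PANDA per diagnosis group (shared axes, group-specific co-expression),
#' form the differential network and per-TF targeting tests, extract the
#' signed top-k TF signature, then (optionally) rank-based enrichment of
#' gene targeting scores against a gene-set collection and cosine-reversal
#' matching against a drug database.  Artifacts and a JSON manifest with
#' parameters, seeds and md5 checksums are written to `output_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @param inputs optional named list of in-memory inputs (`expr`,
#'   `covariates`, `motif`, `ppi`, `gmt`, `drug_db`) overriding file paths.
#' @return list with `net_case`, `net_control`, `diffnet`, `tf_tests`,
#'   `signature`, `enrichment` (or `NULL`), `drug_ranking` (or `NULL`),
#'   `skipped`, `manifest`.
#' @export
run_pipeline <- function(config, inputs = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "read_inputs"
  result <- tryCatch({
    expr <- inputs$expr %||% read_expression_matrix(config$counts)
    covariates <- inputs$covariates %||% read_covariates(config$covariates)
    motif <- inputs$motif %||% read_prior_edges(config$motif)
    ppi <- inputs$ppi %||% read_ppi_table(config$ppi, config$ppi_threshold)
    gmt <- inputs$gmt %||% (if (!is.null(config$gmt)) read_gmt(config$gmt))
    drug_db <- inputs$drug_db %||%
      (if (!is.null(config$drug_db)) read_drug_db(config$drug_db))

    stage <- "preprocess"
    expr <- collapse_duplicates(expr)
    expr <- cpm_filter(expr, config$cpm_threshold, config$sample_fraction)
    resid <- residualize(expr, covariates, keep = config$keep)

    stage <- "panda"
    covariates <- align_covariates(covariates, resid)
    case_level <- config$case_level %||% levels(covariates$diagnosis)[2]
    if (!case_level %in% levels(covariates$diagnosis))
      stopf("case_level '%s' is not a diagnosis level", case_level)
    groups <- c(setdiff(levels(covariates$diagnosis), case_level), case_level)
    params <- panda_params(config$alpha, config$tolerance, config$max_iter)
    # shared TF/gene axes from the pooled expression; group-specific
    # co-expression computed on the shared gene intersection
    pooled <- prepare_inputs(motif, ppi, resid)
    nets <- lapply(groups, function(g) {
      sel <- covariates$diagnosis == g
      sub <- expression_matrix(resid$values[pooled$gene_names, sel, drop = FALSE],
                               pooled$gene_names, resid$sample_names[sel],
                               kind = "residuals")
      panda(pooled$motif, pooled$ppi, pearson_coexpression(sub), params)
    })
    names(nets) <- groups
    net_control <- nets[[1]]; net_case <- nets[[2]]

    stage <- "differential"
    diffnet <- differential_network(net_case, net_control)
    tf_tests <- tf_significance(net_case, net_control)
    sig <- top_signature(diffnet, k = config$k)

    skipped <- character(0)
    stage <- "gsea"
    enr <- NULL
    if (!is.null(gmt)) {
      ranked <- ranked_list(diffnet$gene_targeting)
      enr <- gsea(ranked, gmt, n_perm = config$n_perm,
                  min_size = config$min_size, max_size = config$max_size,
                  seed = config$seed)
    } else skipped <- c(skipped, "gsea")

    stage <- "repurpose"
    drugs <- NULL
    if (!is.null(drug_db)) {
      drugs <- match_drugs(sig, drug_db, n_null = config$n_null,
                           seed = config$seed)
    } else skipped <- c(skipped, "repurpose")

    list(net_case = net_case, net_control = net_control, diffnet = diffnet,
         tf_tests = tf_tests, signature = sig, enrichment = enr,
         drug_ranking = drugs, skipped = skipped)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  result$manifest <- write_pipeline_artifacts(result, config)
  result
}

write_pipeline_artifacts <- function(result, config) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("pandiff")),
    seed = config$seed,
    parameters = config[c("cpm_threshold", "sample_fraction", "ppi_threshold",
                          "keep", "alpha", "tolerance", "max_iter", "k",
                          "n_perm", "min_size", "max_size", "n_null")],
    stages_skipped = as.list(result$skipped),
    panda = list(
      case_iterations = result$net_case$n_iterations,
      case_converged = isTRUE(result$net_case$converged),
      control_iterations = result$net_control$n_iterations,
      control_converged = isTRUE(result$net_control$converged)))
  if (is.null(config$output_dir)) return(manifest)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  write_network(result$net_case, out("network_case.tsv"))
  write_network(result$net_control, out("network_control.tsv"))
  diff_as_net <- regulatory_network(result$diffnet$delta,
                                    result$diffnet$tf_names,
                                    result$diffnet$gene_names)
  write_network(diff_as_net, out("network_differential.tsv"))
  utils::write.table(
    data.frame(tf = result$tf_tests$tf,
               score = result$tf_tests$targeting_diff,
               p = result$tf_tests$p_value, q = result$tf_tests$q_value,
               direction = result$tf_tests$direction),
    out("tf_targeting.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(positive = result$signature$positive,
                            negative = result$signature$negative),
                       out("signature.json"))
  if (!is.null(result$enrichment)) {
    enr <- result$enrichment
    enr$leading_edge <- vapply(enr$leading_edge, paste, "", collapse = ",")
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(result$drug_ranking))
    utils::write.table(result$drug_ranking, out("drug_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
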