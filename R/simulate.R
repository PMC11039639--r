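#' Simulation parameters for the synthetic regulatory testbed
#'
#' Bundles every knob of the synthetic-data generator.  The defaults define a
#' desk-scale testbed: 30 TFs regulating 200 genes, two diagnosis groups of
#' 50 samples each, 3 TFs with amplified regulation and 3 with attenuated
#' regulation in the case group (2-fold on the regulatory weights), motif and
#' PPI priors corrupted at a 5% flip rate, and a drug database of 100
#' signatures of which 5 are planted reversers of the case perturbation.
#'
#' @param n_tfs,n_genes,n_samples_per_group dimensions of the testbed.
#' @param n_perturbed_up,n_perturbed_down number of TFs whose regulatory
#'   strengths are amplified / attenuated in the case group.
#' @param effect_multiplier fold change (> 1) applied to perturbed TF rows.
#' @param nb_dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2).
#' @param library_size_range two positive numbers; per-sample sequencing
#'   depths are drawn uniformly from this range.
#' @param covariate_effect_sd standard deviation of per-gene nuisance
#'   covariate effects on the log scale (0 disables them).
#' @param prior_false_positive_rate,prior_false_negative_rate flip rates used
#'   to corrupt the motif prior (and, off-diagonal, the PPI).
#' @param n_drugs,n_reversers drug-database composition.
#' @param drug_signature_noise fraction of a planted reverser's signature
#'   entries replaced by random TFs.
#' @param seed global integer seed; expanded into per-stage substreams.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_tfs = 30, n_genes = 200,
                              n_samples_per_group = 50,
                              n_perturbed_up = 3, n_perturbed_down = 3,
                              effect_multiplier = 2, nb_dispersion = 0.15,
                              library_size_range = c(1e6, 2e6),
                              covariate_effect_sd = 0.1,
                              prior_false_positive_rate = 0.05,
                              prior_false_negative_rate = 0.05,
                              n_drugs = 100, n_reversers = 5,
                              drug_signature_noise = 0.2, seed = 1L) {
  if (n_tfs < 1 || n_genes < 1 || n_samples_per_group < 1)
    stopf("dimensions must be positive integers")
  if (n_perturbed_up < 0 || n_perturbed_down < 0)
    stopf("perturbed TF counts must be non-negative")
  if (n_perturbed_up + n_perturbed_down > n_tfs)
    stopf("n_perturbed_up + n_perturbed_down exceeds n_tfs")
  if (effect_multiplier <= 1) stopf("effect_multiplier must be > 1")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stopf("library_size_range must be an increasing pair of positive numbers")
  if (covariate_effect_sd < 0) stopf("covariate_effect_sd must be >= 0")
  for (r in c(prior_false_positive_rate, prior_false_negative_rate,
              drug_signature_noise))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  if (n_reversers > n_drugs) stopf("n_reversers exceeds n_drugs")
  structure(list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_perturbed_up = as.integer(n_perturbed_up),
                 n_perturbed_down = as.integer(n_perturbed_down),
                 effect_multiplier = effect_multiplier,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 covariate_effect_sd = covariate_effect_sd,
                 prior_false_positive_rate = prior_false_positive_rate,
                 prior_false_negative_rate = prior_false_negative_rate,
                 n_drugs = as.integer(n_drugs),
                 n_reversers = as.integer(n_reversers),
                 drug_signature_noise = drug_signature_noise,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate the ground-truth regulatory structure
#'
#' Draws a sparse TF x gene matrix of true regulatory strengths: each gene is
#' regulated by 1-3 randomly chosen TFs with signed uniform weights
#' (magnitude in `[0.25, 0.75]`).  The case-group matrix equals the control
#' matrix except that the rows of `perturbed_tfs_up` are multiplied by
#' `effect_multiplier` and the rows of `perturbed_tfs_down` divided by it.
#'
#' @param params a [simulation_params()] object.
#' @return an object of class `ground_truth` with fields `tf_names`,
#'   `gene_names`, `B_control`, `B_case`, `perturbed_tfs_up`,
#'   `perturbed_tfs_down`, `seed`.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(stage_seed(params$seed, "truth"))
  tf_names <- sprintf("TF%02d", seq_len(params$n_tfs))
  gene_names <- sprintf("G%03d", seq_len(params$n_genes))
  B <- matrix(0, params$n_tfs, params$n_genes,
              dimnames = list(tf_names, gene_names))
  for (g in seq_len(params$n_genes)) {
    n_reg <- sample(1:3, 1)
    regs <- sample.int(params$n_tfs, min(n_reg, params$n_tfs))
    B[regs, g] <- runif(length(regs), 0.25, 0.75)
  }
  n_pert <- params$n_perturbed_up + params$n_perturbed_down
  pert <- if (n_pert > 0) sample(tf_names, n_pert) else character(0)
  up <- if (params$n_perturbed_up > 0) pert[seq_len(params$n_perturbed_up)] else character(0)
  down <- setdiff(pert, up)
  B_case <- B
  if (length(up)) B_case[up, ] <- B_case[up, , drop = FALSE] * params$effect_multiplier
  if (length(down)) B_case[down, ] <- B_case[down, , drop = FALSE] / params$effect_multiplier
  structure(list(tf_names = tf_names, gene_names = gene_names,
                 B_control = B, B_case = B_case,
                 perturbed_tfs_up = up, perturbed_tfs_down = down,
                 seed = params$seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d TFs x %d genes (%d up-, %d down-perturbed)\n",
              length(x$tf_names), length(x$gene_names),
              length(x$perturbed_tfs_up), length(x$perturbed_tfs_down)))
  invisible(x)
}

#' Simulate two-group RNA-seq counts from a ground truth
#'
#' Latent TF activities are standard normal per sample; the log mean of each
#' target gene is a baseline plus the group-specific regulatory combination
#' `t(B) %*% activity` plus per-gene nuisance covariate effects.  Each TF's
#' own transcript is included among the gene rows with its latent activity as
#' its log-scale signal, so TF-target co-expression is informative.  Expected
#' counts are rescaled to a sampled library size and counts drawn from a
#' negative binomial.
#'
#' @param truth a [simulate_truth()] result.
#' @param params the matching [simulation_params()] object.
#' @return list with `expr` (an [expression_matrix()] of counts whose rows
#'   are the TF transcripts followed by the target genes) and `covariates`
#'   (a [covariate_table()] with diagnosis, an age-like numeric covariate and
#'   a batch-like categorical covariate).
#' @export
simulate_counts <- function(truth, params) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "simulation_params"))
  if (!identical(truth$tf_names, sprintf("TF%02d", seq_len(params$n_tfs))) ||
      !identical(truth$gene_names, sprintf("G%03d", seq_len(params$n_genes))))
    stopf("truth axes do not match simulation params")
  set.seed(stage_seed(params$seed, "counts"))
  n <- 2L * params$n_samples_per_group
  sample_names <- sprintf("S%03d", seq_len(n))
  diagnosis <- factor(rep(c("control", "case"), each = params$n_samples_per_group),
                      levels = c("control", "case"))
  age <- rnorm(n, 50, 10)
  batch <- factor(sample(c("b1", "b2", "b3"), n, replace = TRUE))
  age_std <- (age - 50) / 10

  n_rows <- params$n_tfs + params$n_genes
  row_names <- c(truth$tf_names, truth$gene_names)
  baseline <- rnorm(n_rows, 4, 0.7)
  beta_age <- rnorm(n_rows, 0, params$covariate_effect_sd)
  beta_batch <- matrix(rnorm(n_rows * 3, 0, params$covariate_effect_sd),
                       n_rows, 3, dimnames = list(NULL, levels(batch)))
  activity <- matrix(rnorm(params$n_tfs * n), params$n_tfs, n)

  logmu <- matrix(baseline, n_rows, n) +
    outer(beta_age, age_std) + beta_batch[, as.integer(batch)]
  logmu[seq_len(params$n_tfs), ] <- logmu[seq_len(params$n_tfs), ] + activity
  idx_gene <- params$n_tfs + seq_len(params$n_genes)
  is_case <- diagnosis == "case"
  logmu[idx_gene, !is_case] <- logmu[idx_gene, !is_case] +
    crossprod(truth$B_control, activity[, !is_case, drop = FALSE])
  logmu[idx_gene, is_case] <- logmu[idx_gene, is_case] +
    crossprod(truth$B_case, activity[, is_case, drop = FALSE])

  mu <- exp(logmu)
  libs <- runif(n, params$library_size_range[1], params$library_size_range[2])
  mu <- sweep(mu, 2, libs / colSums(mu), `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
                   n_rows, n, dimnames = list(row_names, sample_names))
  list(expr = expression_matrix(counts, kind = "counts"),
       covariates = covariate_table(data.frame(
         sample = sample_names, diagnosis = diagnosis,
         age = age, batch = batch, stringsAsFactors = FALSE)))
}

#' Simulate noisy motif and PPI priors from a ground truth
#'
#' The motif prior is the binarised support of the true control network with
#' independent flips: each true edge is dropped at
#' `prior_false_negative_rate` and each non-edge added at
#' `prior_false_positive_rate`.  The PPI is 1 where two TFs share at least
#' one true target gene, with symmetric off-diagonal flips at the same rates
#' and a unit diagonal.
#'
#' @param truth a [simulate_truth()] result.
#' @param params the matching [simulation_params()] object.
#' @return list with `motif` (a [prior_network()]) and `ppi`
#'   (a [ppi_matrix()]).
#' @export
simulate_priors <- function(truth, params) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "simulation_params"))
  set.seed(stage_seed(params$seed, "priors"))
  support <- (truth$B_control != 0) + 0
  flip <- matrix(runif(length(support)), nrow(support))
  motif <- support
  motif[support == 1 & flip < params$prior_false_negative_rate] <- 0
  motif[support == 0 & flip < params$prior_false_positive_rate] <- 1

  share <- (support %*% t(support) > 0) + 0
  nt <- params$n_tfs
  if (nt > 1) {
    up_tri <- upper.tri(share)
    u <- runif(sum(up_tri))
    vals <- share[up_tri]
    vals[vals == 1 & u < params$prior_false_negative_rate] <- 0
    vals[vals == 0 & u < params$prior_false_positive_rate] <- 1
    share[up_tri] <- vals
    share[lower.tri(share)] <- t(share)[lower.tri(share)]
  }
  diag(share) <- 1
  list(motif = prior_network(motif, truth$tf_names, truth$gene_names),
       ppi = ppi_matrix(share, truth$tf_names))
}

#' Simulate a drug-signature database with planted reversers
#'
#' Planted reversers carry the sign-flipped disease perturbation (positive
#' list from the down-perturbed TFs, negative list from the up-perturbed
#' TFs), with a `drug_signature_noise` fraction of entries replaced by random
#' TFs.  Decoy drugs get random disjoint TF lists of the same sizes.  Drug
#' names are neutral (`drug001`, ...) and reverser positions are randomised.
#'
#' @param truth a [simulate_truth()] result.
#' @param params the matching [simulation_params()] object.
#' @return list with `db` (a [drug_signature_db()]) and `planted_reversers`
#'   (character vector of drug names).
#' @export
simulate_drug_db <- function(truth, params) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "simulation_params"))
  up <- truth$perturbed_tfs_up; down <- truth$perturbed_tfs_down
  if (params$n_reversers > 0 && !length(up) && !length(down))
    stopf("cannot plant reversers: no perturbed TFs in ground truth")
  set.seed(stage_seed(params$seed, "drugs"))
  drug_names <- sprintf("drug%03d", seq_len(params$n_drugs))
  rev_idx <- if (params$n_reversers > 0)
    sample.int(params$n_drugs, params$n_reversers) else integer(0)
  pos_size <- max(length(down), 1L); neg_size <- max(length(up), 1L)

  corrupt <- function(tfs) {
    # replace a noise fraction of entries by random TFs outside this half
    n_rep <- sum(runif(length(tfs)) < params$drug_signature_noise)
    pool <- setdiff(truth$tf_names, tfs)
    n_rep <- min(n_rep, length(pool))
    if (n_rep == 0) return(tfs)
    repl_at <- sample(seq_along(tfs), n_rep)
    tfs[repl_at] <- sample(pool, n_rep)
    tfs
  }
  drugs <- vector("list", params$n_drugs)
  names(drugs) <- drug_names
  for (i in seq_len(params$n_drugs)) {
    if (i %in% rev_idx) {
      pos <- corrupt(down)
      neg <- corrupt(up)
      # corruption may collide across halves; keep the halves disjoint
      pos <- unique(pos); neg <- setdiff(unique(neg), pos)
    } else {
      both <- sample(truth$tf_names, min(pos_size + neg_size, params$n_tfs))
      pos <- both[seq_len(min(pos_size, length(both)))]
      neg <- setdiff(both, pos)
    }
    drugs[[i]] <- new_signature(drug_names[i], pos, neg,
                                k = max(length(pos), length(neg), 1L))
  }
  list(db = drug_signature_db(drugs, vocabulary = truth$tf_names),
       planted_reversers = drug_names[sort(rev_idx)])
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_truth()], [simulate_counts()],
#' [simulate_priors()] and [simulate_drug_db()] under one parameter set.
#'
#' @param params a [simulation_params()] object.
#' @return list with `truth`, `expr`, `covariates`, `motif`, `ppi`, `drug_db`
#'   and `planted_reversers`.
#' @export
simulate_dataset <- function(params) {
  truth <- simulate_truth(params)
  cnt <- simulate_counts(truth, params)
  pri <- simulate_priors(truth, params)
  db <- simulate_drug_db(truth, params)
  list(truth = truth, expr = cnt$expr, covariates = cnt$covariates,
       motif = pri$motif, ppi = pri$ppi, drug_db = db$db,
       planted_reversers = db$planted_reversers)
}

#' The planted disease signature of a ground truth
#'
#' The signed TF signature the case perturbation should produce: increased
#' targeting for the amplified TFs, decreased for the attenuated ones.
#'
#' @param truth a [simulate_truth()] result.
#' @return a [new_signature()] object named `"planted"`.
#' @export
planted_signature <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  new_signature("planted", truth$perturbed_tfs_up, truth$perturbed_tfs_down,
                k = max(length(truth$perturbed_tfs_up),
                        length(truth$perturbed_tfs_down), 1L))
}

#' Write a simulated dataset to disk in the pipeline's file formats
#'
#' Emits the same formats the real pipeline reads: counts TSV, covariates
#' TSV, 3-column motif prior TSV, PPI score TSV, drug database JSON and an
#' equivalent long-format TSV.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             motif = file.path(dir, "motif.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             drug_db_json = file.path(dir, "drug_db.json"),
             drug_db_tsv = file.path(dir, "drug_db.tsv"),
             truth = file.path(dir, "truth_edges.tsv"))
  write_expression_matrix(sim$expr, paths["counts"])
  write_covariates(sim$covariates, paths["covariates"])
  write_prior_edges(sim$motif, paths["motif"])
  write_ppi_table(sim$ppi, paths["ppi"])
  write_drug_db(sim$drug_db, paths["drug_db_json"])
  write_drug_db_tsv(sim$drug_db, paths["drug_db_tsv"])
  truth_net <- regulatory_network(sim$truth$B_case - sim$truth$B_control,
                                  sim$truth$tf_names, sim$truth$gene_names)
  write_network(truth_net, paths["truth"])
  invisible(paths)
}
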