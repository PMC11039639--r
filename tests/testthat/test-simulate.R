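test_that("ground truth obeys the perturbation contract", {
  p <- simulation_params(seed = 7)
  truth <- simulate_truth(p)
  expect_length(intersect(truth$perturbed_tfs_up, truth$perturbed_tfs_down), 0)
  # unperturbed rows identical, perturbed rows scaled exactly
  unpert <- setdiff(truth$tf_names,
                    c(truth$perturbed_tfs_up, truth$perturbed_tfs_down))
  expect_identical(truth$B_case[unpert, ], truth$B_control[unpert, ])
  for (t in truth$perturbed_tfs_up)
    expect_equal(truth$B_case[t, ], truth$B_control[t, ] * p$effect_multiplier)
  for (t in truth$perturbed_tfs_down)
    expect_equal(truth$B_case[t, ], truth$B_control[t, ] / p$effect_multiplier)

  # no perturbation => identical matrices
  p0 <- simulation_params(seed = 7, n_perturbed_up = 0, n_perturbed_down = 0)
  t0 <- simulate_truth(p0)
  expect_identical(t0$B_case, t0$B_control)
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  p <- simulation_params(seed = 11, n_drugs = 20, n_reversers = 2)
  a <- simulate_dataset(p)
  b <- simulate_dataset(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$motif$weights, b$motif$weights)
  expect_identical(a$ppi$scores, b$ppi$scores)
  expect_identical(lapply(a$drug_db$drugs, unclass),
                   lapply(b$drug_db$drugs, unclass))
  expect_identical(a$planted_reversers, b$planted_reversers)
  # a different seed changes the draw
  c <- simulate_dataset(simulation_params(seed = 12, n_drugs = 20,
                                          n_reversers = 2))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(simulation_params(effect_multiplier = 1), "effect_multiplier")
  expect_error(simulation_params(n_tfs = 0), "positive")
  expect_error(simulation_params(n_perturbed_up = 20, n_perturbed_down = 20,
                                 n_tfs = 30), "exceeds")
  expect_error(simulation_params(n_reversers = 5, n_drugs = 3), "exceeds")
  p0 <- simulation_params(n_perturbed_up = 0, n_perturbed_down = 0,
                          n_reversers = 2)
  expect_error(simulate_drug_db(simulate_truth(p0), p0), "no perturbed TFs")
})

test_that("counts carry the planted co-expression signal and covariate effects", {
  p <- simulation_params(seed = 3, n_samples_per_group = 50)
  truth <- simulate_truth(p)
  cnt <- simulate_counts(truth, p)
  expect_s3_class(cnt$expr, "expression_matrix")
  expect_equal(dim(cnt$expr$values),
               c(p$n_tfs + p$n_genes, 2 * p$n_samples_per_group))
  # TF transcripts are among the gene rows
  expect_true(all(truth$tf_names %in% cnt$expr$gene_names))

  # planted direction: over several seeds, the mean within-group correlation
  # between an up-perturbed TF's transcript and its targets is higher in the
  # case group, and lower for a down-perturbed TF
  diffs_up <- diffs_down <- numeric(0)
  for (s in 1:10) {
    ps <- simulation_params(seed = s, n_samples_per_group = 50)
    tr <- simulate_truth(ps)
    cc <- simulate_counts(tr, ps)
    lg <- log1p(cc$expr$values)
    case <- cc$covariates$diagnosis == "case"
    corr_with_targets <- function(tf, sel) {
      tg <- names(which(tr$B_control[tf, ] != 0))
      mean(stats::cor(lg[tf, sel], t(lg[tg, sel, drop = FALSE])))
    }
    up <- tr$perturbed_tfs_up[1]; down <- tr$perturbed_tfs_down[1]
    diffs_up <- c(diffs_up, corr_with_targets(up, case) -
                    corr_with_targets(up, !case))
    diffs_down <- c(diffs_down, corr_with_targets(down, case) -
                      corr_with_targets(down, !case))
  }
  expect_gt(mean(diffs_up), 0)
  expect_lt(mean(diffs_down), 0)

  # zero covariate effect: regression of log counts on the nuisance
  # covariates explains essentially nothing beyond noise
  p0 <- simulation_params(seed = 5, covariate_effect_sd = 0,
                          n_samples_per_group = 100)
  t0 <- simulate_truth(p0)
  c0 <- simulate_counts(t0, p0)
  lg <- log1p(c0$expr$values)
  age <- c0$covariates$age
  slopes <- apply(lg, 1, function(y) coef(lm(y ~ age))[2])
  expect_lt(abs(mean(slopes)), 0.005)
})

test_that("null ground truth yields independent-looking genes", {
  p <- simulation_params(seed = 9, n_samples_per_group = 100,
                         n_perturbed_up = 0, n_perturbed_down = 0)
  truth <- simulate_truth(p)
  truth$B_control[] <- 0
  truth$B_case[] <- 0
  cnt <- simulate_counts(truth, p)
  # depth-normalise first: the sampled library sizes couple raw counts of
  # all genes, which is not a regulatory dependence
  cpm <- sweep(cnt$expr$values, 2, colSums(cnt$expr$values), `/`) * 1e6
  lg <- log1p(cpm[truth$gene_names[1:50], ])
  C <- stats::cor(t(lg))
  offdiag <- C[upper.tri(C)]
  expect_lt(mean(abs(offdiag)), 0.1)
})

test_that("priors reproduce the true support at zero noise and flip at rate one", {
  p0 <- simulation_params(seed = 13, prior_false_positive_rate = 0,
                          prior_false_negative_rate = 0)
  truth <- simulate_truth(p0)
  pri <- simulate_priors(truth, p0)
  expect_identical(pri$motif$weights, (truth$B_control != 0) + 0)

  p1 <- simulation_params(seed = 13, prior_false_positive_rate = 0,
                          prior_false_negative_rate = 1)
  pri1 <- simulate_priors(simulate_truth(p1), p1)
  expect_true(all(pri1$motif$weights[truth$B_control != 0] == 0))

  # PPI invariants hold for arbitrary seeds
  for (s in c(1, 2, 3)) {
    ps <- simulation_params(seed = s)
    pp <- simulate_priors(simulate_truth(ps), ps)$ppi
    expect_identical(pp$scores, t(pp$scores))
    expect_true(all(diag(pp$scores) == 1))
  }
})

test_that("drug database plants exact reversers at zero noise", {
  p <- simulation_params(seed = 21, drug_signature_noise = 0)
  truth <- simulate_truth(p)
  db <- simulate_drug_db(truth, p)
  expect_length(db$planted_reversers, p$n_reversers)
  dis <- planted_signature(truth)
  for (nm in db$planted_reversers) {
    d <- db$db$drugs[[nm]]
    expect_setequal(d$positive, truth$perturbed_tfs_down)
    expect_setequal(d$negative, truth$perturbed_tfs_up)
    expect_equal(cosine_score(dis, d), -1)
  }
  # no reversers requested -> none planted
  p0 <- simulation_params(seed = 21, n_reversers = 0)
  expect_length(simulate_drug_db(simulate_truth(p0), p0)$planted_reversers, 0)
})
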