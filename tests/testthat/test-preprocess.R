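make_expr <- function(M, kind = "counts") {
  if (is.null(rownames(M))) rownames(M) <- sprintf("G%d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- sprintf("S%d", seq_len(ncol(M)))
  expression_matrix(M, kind = kind)
}

test_that("cpm_filter applies the strict threshold and ceiling rule", {
  # 2 samples with library size 1e6: counts of 10 -> CPM 10 > 0.5 everywhere
  M <- rbind(G1 = c(10, 10), G2 = c(0, 0), Gfill = c(1e6 - 10, 1e6 - 10))
  colnames(M) <- c("S1", "S2")
  kept <- cpm_filter(make_expr(M))
  expect_true("G1" %in% kept$gene_names)       # CPM 10 in 2/2 samples
  expect_false("G2" %in% kept$gene_names)      # all-zero row always removed
  expect_equal(kept$values["G1", ], c(S1 = 10, S2 = 10))  # raw counts returned

  # ceiling rule: 10 samples at fraction 0.3 need ceil(3) = 3 samples
  set.seed(1)
  M10 <- matrix(1000, 3, 10, dimnames = list(paste0("G", 1:3), paste0("S", 1:10)))
  M10[2, ] <- c(rep(1000, 3), rep(0, 7))   # exactly 3 passing samples
  M10[3, ] <- c(rep(1000, 2), rep(0, 8))   # only 2 passing samples
  kept10 <- cpm_filter(make_expr(M10), cpm_threshold = 0.5, sample_fraction = 0.3)
  expect_true(all(c("G1", "G2") %in% kept10$gene_names))
  expect_false("G3" %in% kept10$gene_names)

  # invariant to gene and sample order
  perm <- cpm_filter(make_expr(M10[c(3, 1, 2), c(5, 1:4, 6:10)]))
  expect_setequal(perm$gene_names, kept10$gene_names)

  Mz <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("G1", "G2"), c("S1", "S2")))
  expect_error(cpm_filter(make_expr(Mz)), "all-zero sample")
})

test_that("collapse_duplicates averages duplicates and drops zero rows", {
  M <- rbind(c(1, 3), c(3, 5), c(0, 0), c(7, 7))
  expr <- expression_matrix(M, c("G1", "G1", "Gz", "G2"), c("S1", "S2"))
  out <- collapse_duplicates(expr)
  expect_equal(out$gene_names, c("G1", "G2"))
  expect_equal(unname(out$values["G1", ]), c(2, 4))
  # identity when nothing to do
  clean <- make_expr(matrix(1:4, 2, 2))
  expect_equal(collapse_duplicates(clean)$values, clean$values)
})

test_that("variance partition attributes variance correctly", {
  set.seed(8)
  n <- 200
  cov <- covariate_table(data.frame(
    sample = sprintf("S%03d", 1:n),
    diagnosis = rep(c("control", "case"), each = n / 2),
    age = rnorm(n), batch = rep(c("b1", "b2"), times = n / 2)))
  age <- cov$age
  Y <- rbind(exact = age,                       # gene equal to a covariate
             noise = rnorm(n))
  colnames(Y) <- cov$sample
  vp <- variance_partition(make_expr(Y, kind = "residuals"), cov)
  # Shapley attribution shares chance sample correlation with the other
  # covariates, so the exact-covariate gene attributes ~all (not exactly all)
  # of its variance to age, with zero residual
  expect_gt(vp[vp$gene == "exact", "age"], 0.99)
  expect_equal(vp[vp$gene == "exact", "residual"], 0, tolerance = 1e-10)
  expect_gt(vp[vp$gene == "noise", "residual"], 0.9)
  # fractions sum to one for every gene
  sums <- rowSums(vp[, setdiff(names(vp), "gene")])
  expect_equal(sums, rep(1, nrow(vp)), tolerance = 1e-8)

  # pure-noise residual fraction converges to 1 across seeds
  res_fracs <- vapply(1:10, function(s) {
    set.seed(500 + s)
    Yn <- matrix(rnorm(n), 1, n, dimnames = list("g", cov$sample))
    vpn <- variance_partition(make_expr(Yn, kind = "residuals"), cov)
    vpn$residual
  }, numeric(1))
  expect_gt(mean(res_fracs), 0.95)

  # collinear design is rejected with the aliased column named
  cov_bad <- covariate_table(data.frame(
    sample = cov$sample, diagnosis = cov$diagnosis,
    age = age, age2 = 2 * age))
  expect_error(variance_partition(make_expr(Y, kind = "residuals"), cov_bad),
               "collinear.*age")
})

test_that("residualize removes nuisance effects and keeps the diagnosis contrast", {
  set.seed(5)
  n <- 80
  cov <- covariate_table(data.frame(
    sample = sprintf("S%03d", 1:n),
    diagnosis = factor(rep(c("control", "case"), each = n / 2),
                       levels = c("control", "case")),
    batch = sample(c("b1", "b2"), n, replace = TRUE)))
  batch_ind <- as.numeric(cov$batch == "b2")
  dx <- cov$diagnosis
  y <- 2 * batch_ind + rnorm(n, sd = 0.1)
  Y <- matrix(y, 1, n, dimnames = list("g", cov$sample))
  out <- residualize(make_expr(Y, kind = "residuals"), cov)
  # the batch effect is removed: its partial slope given diagnosis is zero
  slope <- coef(lm(out$values["g", ] ~ dx + batch_ind))[["batch_ind"]]
  expect_lt(abs(slope), 1e-10)

  # fitted diagnosis contrast preserved exactly
  fit <- lm(y ~ dx + batch_ind)
  case_eff <- coef(fit)[["dxcase"]]
  grp_diff <- mean(out$values["g", dx == "case"]) -
    mean(out$values["g", dx == "control"])
  expect_equal(grp_diff, case_eff, tolerance = 1e-10)

  # idempotence
  twice <- residualize(out, cov)
  expect_equal(twice$values, out$values, tolerance = 1e-10)

  # nothing to remove -> identity
  cov_min <- covariate_table(data.frame(sample = cov$sample,
                                        diagnosis = cov$diagnosis))
  only_diag <- residualize(make_expr(Y, kind = "residuals"), cov_min)
  expect_equal(only_diag$values, Y, tolerance = 1e-10)
})

test_that("pearson co-expression matches hand values and handles degeneracy", {
  M <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 4), g3 = c(3, 2, 1), flat = c(5, 5, 5))
  colnames(M) <- paste0("S", 1:3)
  C <- pearson_coexpression(make_expr(M, kind = "residuals"))
  expect_equal(diag(C), c(g1 = 1, g2 = 1, g3 = 1, flat = 1))
  expect_equal(C["g1", "g3"], -1)                    # exact anti-correlation
  expect_equal(C["g1", "g2"], 0.981980506, tolerance = 1e-8)
  expect_equal(C["flat", "g1"], 0)                   # zero-variance fill-in
  expect_identical(C, t(C))

  # PSD up to tolerance when no degenerate genes are present
  set.seed(2)
  R <- matrix(rnorm(50 * 8), 8, 50,
              dimnames = list(paste0("g", 1:8), paste0("S", 1:50)))
  ev <- eigen(pearson_coexpression(make_expr(R, kind = "residuals")),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)

  expect_error(pearson_coexpression(make_expr(M[, 1:2], kind = "residuals")),
               "3 samples")
})
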