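test_that("differential network subtraction and targeting sums are exact", {
  W_case <- matrix(c(1, 2), 1, 2, dimnames = list("T1", c("G1", "G2")))
  W_ctl <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("T1", c("G1", "G2")))
  d <- differential_network(tiny_network(W_case), tiny_network(W_ctl))
  expect_equal(unname(d$delta), matrix(c(0.5, 1.5), 1, 2))
  expect_equal(unname(d$tf_targeting), 2.0)
  expect_equal(unname(d$gene_targeting), c(0.5, 1.5))

  # identical networks -> all zero
  d0 <- differential_network(tiny_network(W_case), tiny_network(W_case))
  expect_true(all(d0$delta == 0))

  # swapping case and control negates delta exactly
  dsw <- differential_network(tiny_network(W_ctl), tiny_network(W_case))
  expect_equal(dsw$delta, -d$delta)

  # grand-sum conservation on random differential networks
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(40), 5, 8,
                dimnames = list(paste0("T", 1:5), paste0("G", 1:8)))
    B <- matrix(rnorm(40), 5, 8, dimnames = dimnames(A))
    dd <- differential_network(tiny_network(A), tiny_network(B))
    expect_equal(sum(dd$gene_targeting), sum(dd$tf_targeting))
    expect_equal(dd$gene_targeting, colSums(dd$delta))
    expect_equal(dd$tf_targeting, rowSums(dd$delta))
  }
})

test_that("alignment keeps only the intersection of axes", {
  A <- matrix(1, 3, 4, dimnames = list(paste0("T", 1:3), paste0("G", 1:4)))
  B <- matrix(2, 2, 3, dimnames = list(c("T2", "T3"), c("G2", "G3", "G9")))
  d <- differential_network(tiny_network(A), tiny_network(B))
  expect_equal(d$tf_names, c("T2", "T3"))
  expect_equal(d$gene_names, c("G2", "G3"))
  C <- matrix(1, 2, 2, dimnames = list(c("X1", "X2"), c("G1", "G2")))
  expect_error(differential_network(tiny_network(A), tiny_network(C)),
               "empty")
})

test_that("signed-rank testing matches exact enumeration", {
  # 6 uniformly signed differences: two-sided exact p = 2/2^6
  genes <- paste0("G", 1:6)
  ctl <- matrix(0, 1, 6, dimnames = list("T1", genes))
  case <- matrix(seq(0.1, 0.6, by = 0.1), 1, 6, dimnames = list("T1", genes))
  res <- tf_significance(tiny_network(case), tiny_network(ctl))
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$p_value, enumerate_signed_rank_p(case[1, ] - ctl[1, ]))
  expect_equal(res$direction, "increased")

  # exact path agrees with enumeration for random instances, n <= 10
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:10, 1)
    d <- round(rnorm(n), 6)
    d <- d + (d == 0) * 0.1
    while (anyDuplicated(abs(d))) d <- rnorm(n)
    case_r <- matrix(d, 1, n, dimnames = list("T1", paste0("G", 1:n)))
    ctl_r <- matrix(0, 1, n, dimnames = list("T1", paste0("G", 1:n)))
    got <- tf_significance(tiny_network(case_r), tiny_network(ctl_r))$p_value
    expect_equal(got, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }

  # perfectly symmetric differences sit at the null centre
  d <- c(1, -1, 2, -2, 3, -3)
  case_s <- matrix(d, 1, 6, dimnames = list("T1", paste0("G", 1:6)))
  ctl_s <- matrix(0, 1, 6, dimnames = list("T1", paste0("G", 1:6)))
  expect_equal(tf_significance(tiny_network(case_s),
                               tiny_network(ctl_s))$p_value, 1)

  # all-zero differences are flagged with p = 1
  z <- matrix(1, 2, 6, dimnames = list(c("T1", "T2"), paste0("G", 1:6)))
  z2 <- z; z2["T2", ] <- z2["T2", ] + seq(0.1, 0.6, by = 0.1)
  rz <- tf_significance(tiny_network(z2), tiny_network(z))
  expect_true(rz$all_zero[rz$tf == "T1"])
  expect_equal(rz$p_value[rz$tf == "T1"], 1)

  expect_error(tf_significance(tiny_network(z[, 1:5]), tiny_network(z[, 1:5])),
               "6 shared genes")
})

test_that("BH adjustment follows the step-up rule", {
  # classic hand example: p = (0.01, 0.02, 0.03, 0.04), m = 4 -> all q = 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # q-values within a result are a monotone transform with q >= p
  set.seed(2)
  case <- matrix(rnorm(80), 8, 10,
                 dimnames = list(paste0("T", 1:8), paste0("G", 1:10)))
  ctl <- matrix(rnorm(80), 8, 10, dimnames = dimnames(case))
  res <- tf_significance(tiny_network(case), tiny_network(ctl))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  ord <- order(res$p_value)
  expect_true(all(diff(cummin(rev(res$q_value[ord]))) <= 1e-12))
})

test_that("top_signature ranks, signs and breaks ties deterministically", {
  delta <- matrix(c(2, -1, 0, 1, 1), 5, 1,
                  dimnames = list(c("TFa", "TFb", "TFc", "TFx", "TFw"), "G1"))
  d <- differential_network(tiny_network(delta),
                            tiny_network(0 * delta))
  sig <- top_signature(d, k = 2)
  expect_equal(sig$positive, c("TFa", "TFw"))  # tie TFw/TFx broken by name
  expect_equal(sig$negative, "TFb")            # zero-targeting TFc excluded
  # k larger than eligible TFs returns everything sign-eligible
  sig_all <- top_signature(d, k = 10)
  expect_setequal(sig_all$positive, c("TFa", "TFx", "TFw"))
  expect_equal(sig_all$positive[1], "TFa")
})
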