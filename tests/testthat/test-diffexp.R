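sim_matrix <- function(n_genes, group, batch = NULL, effect = 0, seed = 1) {
  set.seed(seed)
  n <- length(group)
  mat <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n))))
  mat[, group == "MES"] <- mat[, group == "MES"] + effect
  if (!is.null(batch)) {
    for (b in unique(batch)) {
      mat[, batch == b] <- mat[, batch == b] + rnorm(n_genes)
    }
  }
  mat
}

test_that("per-gene OLS matches a normal-equations solve", {
  set.seed(17)
  group <- rep(c("MES", "nonMES"), each = 6)
  batch <- rep(c("b1", "b2"), times = 6)
  mat <- sim_matrix(20, group, batch, effect = 0.5, seed = 17)
  design <- design_info(group, batch, ref = "nonMES")
  fits <- fit_gene_models(mat, design)
  for (g in c(1, 7, 20)) {
    beta <- oracle_ols(design$matrix, mat[g, ])
    expect_lt(abs(fits$effect[g] - beta["groupMES", 1]), 1e-8)
    res <- mat[g, ] - design$matrix %*% beta
    expect_lt(abs(fits$s2[g] - sum(res^2) / design$df_resid), 1e-8)
  }
})

test_that("single-batch effect is the difference of group means", {
  group <- rep(c("MES", "nonMES"), each = 5)
  mat <- sim_matrix(10, group, effect = 1, seed = 2)
  fits <- fit_gene_models(mat, design_info(group, ref = "nonMES"))
  diffs <- rowMeans(mat[, group == "MES"]) - rowMeans(mat[, group == "nonMES"])
  expect_equal(fits$effect, unname(diffs), tolerance = 1e-12)

  # equal group means -> effect exactly 0
  sym <- mat
  sym[, group == "MES"] <- sym[, group == "nonMES"]
  fits0 <- fit_gene_models(sym, design_info(group, ref = "nonMES"))
  expect_equal(fits0$effect, rep(0, 10), tolerance = 1e-14)
})

test_that("a confounded design errors with the aliased column named", {
  group <- rep(c("MES", "nonMES"), each = 4)
  batch <- group  # batch == group: aliased
  expect_error(design_info(group, batch), "aliased")
})

test_that("EB moderation hits its documented limits", {
  # identical variances: infinite prior df, complete pooling
  eb <- eb_moderate(rep(2.5, 50), df_resid = 10)
  expect_equal(eb$d0, Inf)
  expect_equal(eb$s2_post, rep(2.5, 50))

  # forced d0 = 0: no shrinkage
  s2 <- rchisq(50, 10) / 10
  eb0 <- eb_moderate(s2, 10, d0_override = 0)
  expect_equal(eb0$s2_post, s2)

  expect_error(eb_moderate(c(rep(1, 20), -1), 10), "positive")
  expect_error(eb_moderate(rep(1, 5), 10), "10 genes")
})

test_that("EB prior parameters are recovered from simulated variances", {
  set.seed(23)
  d0_true <- 4; s0sq_true <- 1; df <- 10
  s2 <- s0sq_true * rf(5000, df, d0_true)
  eb <- eb_moderate(s2, df)
  expect_gte(eb$d0, 2.5); expect_lte(eb$d0, 6)
  expect_gte(eb$s0sq, 0.8); expect_lte(eb$s0sq, 1.25)
})

test_that("moderated t reduces to the classical t-test at d0 = 0", {
  set.seed(29)
  group <- rep(c("MES", "nonMES"), each = 8)
  batch <- rep(c("b1", "b2"), times = 8)
  mat <- sim_matrix(15, group, batch, effect = 0.3, seed = 29)
  res <- diffexp(mat, group, batch, ref = "nonMES", d0_override = 0)
  for (g in seq_len(nrow(mat))) {
    fit <- lm(mat[g, ] ~ factor(group, levels = c("nonMES", "MES")) +
                factor(batch))
    p_classical <- summary(fit)$coefficients[2, 4]
    expect_lt(abs(res$p[g] - p_classical), 1e-8)
  }
})

test_that("moderated statistics agree with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(31)
  group <- rep(c("MES", "nonMES"), each = 10)
  # heteroscedastic genes so shrinkage is non-trivial
  mat <- sim_matrix(200, group, effect = 0.2, seed = 31) *
    sqrt(rf(200, 8, 4))
  res <- diffexp(mat, group, ref = "nonMES")
  X <- model.matrix(~factor(group, levels = c("nonMES", "MES")))
  lf <- limma::eBayes(limma::lmFit(mat, X))
  expect_equal(attr(res, "d0"), unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(attr(res, "s0sq"), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(res$t_mod, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("trivial moderated-test cases and BH agree with hand computation", {
  group <- rep(c("MES", "nonMES"), each = 5)
  mat <- sim_matrix(12, group, seed = 5)
  mat[1, group == "MES"] <- mat[1, group == "nonMES"]  # exact null gene
  res <- diffexp(mat, group, ref = "nonMES")
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_true(all(res$q >= res$p))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
})

test_that("batch indicators absorb additive batch effects exactly", {
  set.seed(37)
  group <- rep(c("MES", "nonMES"), 12)
  batch <- rep(c("b1", "b2", "b3"), each = 8)
  clean <- sim_matrix(30, group, effect = 0.4, seed = 37)
  shifted <- clean
  for (b in unique(batch)) {
    shifted[, batch == b] <- shifted[, batch == b] + rnorm(30, sd = 3)
  }
  f_clean <- fit_gene_models(clean, design_info(group, batch, ref = "nonMES"))
  f_shift <- fit_gene_models(shifted,
                             design_info(group, batch, ref = "nonMES"))
  expect_lt(max(abs(f_clean$effect - f_shift$effect)), 1e-8)
})

test_that("signature extraction honours thresholds and planted truth", {
  set.seed(41)
  group <- rep(c("MES", "nonMES"), each = 30)
  mat <- sim_matrix(400, group, seed = 41)
  up_genes <- rownames(mat)[1:50]
  mat[1:50, group == "MES"] <- mat[1:50, group == "MES"] + 2
  res <- diffexp(mat, group, ref = "nonMES")
  sig <- make_signature(res, q_threshold = 0.05, top_n = 100)
  expect_true(all(up_genes %in% sig$up))
  expect_equal(length(sig$top), 100)

  # all q = 1 -> empty lists with a warning
  res_null <- res
  res_null$q <- 1
  expect_warning(sig0 <- make_signature(res_null), "no genes")
  expect_length(sig0$up, 0)
  expect_length(sig0$down, 0)

  # top_n = gene count -> every gene, ordered by q
  sig_all <- make_signature(res, top_n = nrow(res))
  expect_setequal(sig_all$top, res$gene)
  expect_equal(sig_all$top[1:10],
               res$gene[order(res$q, -abs(res$t_mod), res$gene)][1:10])
})
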