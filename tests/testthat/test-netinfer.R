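test_that("copula MI is symmetric, monotone-invariant and matches closed form", {
  set.seed(3)
  x <- rnorm(40)
  y <- rnorm(40)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # strictly monotone transform preserves ranks, hence MI; y = x^3 is an
  # exact-dependence case that hits the clip bound
  expect_equal(mutual_information(x, x^3), mutual_information(x, x))
  expect_equal(mutual_information(x, x^3), -0.5 * log(1e-12),
               tolerance = 1e-5)
  # closed form at a fixed normal-score correlation
  expect_equal(regmra:::mi_from_r(0.8), -0.5 * log(0.36))
  expect_equal(regmra:::mi_from_r(0), 0)
  expect_error(mutual_information(rep(1, 40), y), "constant")
  expect_error(mutual_information(x[1:5], y[1:5]), ">= 8")
})

test_that("edge p-values: planted edge hits the pooled-null minimum", {
  set.seed(5)
  n <- 60
  mat <- matrix(rnorm(20 * n), 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  mat["g02", ] <- mat["g01", ] + rnorm(n, sd = 0.05)  # planted target of g01
  edges <- edge_pvalues(mat, "g01", n_perm = 100, seed = 9)
  pool <- attr(edges, "pool_size")
  expect_equal(pool, 100 * 19)
  planted <- edges[edges$target == "g02", ]
  expect_equal(planted$p, 1 / (pool + 1))
  expect_equal(planted$sign, 1L)

  expect_identical(edge_pvalues(mat, "g01", n_perm = 100, seed = 9), edges)
  expect_error(edge_pvalues(mat, "g01", n_perm = 50), "n_perm")
  expect_error(edge_pvalues(mat[, 1:5], "g01"), "8 samples")
})

test_that("edge filtering is a plain q threshold", {
  tab <- data.frame(regulator = "a", target = letters[2:6], mi = 1:5 / 10,
                    sign = 1L, p = c(0.001, 0.2, 0.01, 0.5, 0.04),
                    q = c(0.005, 0.4, 0.04, 0.8, 0.12))
  expect_equal(filter_edges(tab, 0.05)$target, c("b", "d"))
  expect_equal(nrow(filter_edges(tab, 1.0)), 5)
  tab$q <- 1
  expect_equal(nrow(filter_edges(tab, 0.05)), 0)
})

test_that("DPI removes the weakest edge of a full triangle", {
  tri <- data.frame(regulator = c("TF1", "TF2", "TF1"),
                    target = c("TF2", "t1", "t1"),
                    mi = c(0.5, 0.4, 0.3), sign = 1L, p = 0.001, q = 0.001)
  net <- dpi_prune(tri, tfs = c("TF1", "TF2"))
  expect_equal(nrow(net$edges), 2)
  expect_false(any(net$edges$regulator == "TF1" & net$edges$target == "t1"))

  # tolerance keeps the weak edge: 0.3 >= 0.7 * 0.4
  net_tol <- dpi_prune(tri, tfs = c("TF1", "TF2"), tolerance = 0.3)
  expect_equal(nrow(net_tol$edges), 3)

  # tied minimum: nothing removed
  tie <- tri; tie$mi <- c(0.5, 0.3, 0.3)
  expect_equal(nrow(dpi_prune(tie, c("TF1", "TF2"))$edges), 3)

  # protecting TF-TF edges redirects removal
  tf_weak <- tri; tf_weak$mi <- c(0.2, 0.4, 0.3)
  expect_false(any(dpi_prune(tf_weak, c("TF1", "TF2"))$edges$mi == 0.2))
  prot <- dpi_prune(tf_weak, c("TF1", "TF2"), protect_tf_tf = TRUE)
  expect_true(any(prot$edges$mi == 0.2))
})

test_that("DPI matches exhaustive triangle enumeration on random graphs", {
  set.seed(19)
  for (i in 1:40) {
    tab <- random_edge_table(8, 15)
    if (is.null(tab)) next
    tfs <- sprintf("TF%02d", 1:8)
    got <- dpi_prune(tab, tfs)$edges
    got_keys <- unique(paste(pmin(got$regulator, got$target),
                             pmax(got$regulator, got$target)))
    expect_setequal(got_keys, oracle_dpi(tab, tfs))
  }
})

test_that("DPI output is a subset of its input and pruning is idempotent", {
  set.seed(23)
  tab <- random_edge_table(6, 12, p_edge = 0.6)
  tfs <- sprintf("TF%02d", 1:6)
  net1 <- dpi_prune(tab, tfs)
  expect_lte(nrow(net1$edges), nrow(tab))
  net2 <- dpi_prune(net1$edges, tfs)
  expect_equal(net2$edges, net1$edges)
})

test_that("planted regulons are recovered with correct signs", {
  recov <- numeric(3); signs <- numeric(3)
  for (s in 1:3) {
    sim <- gen_expression(n_genes = 400, n_samples = 120, n_batches = 1,
                          n_tfs = 10, n_mes_tfs = 10, regulon_size = 30,
                          effect = 1, noise_sd = 1, batch_shift = 0,
                          seed = 100 + s)
    hm <- harmonize(sim$datasets)
    net <- infer_network(hm$matrix, sim$truth$tfs, n_perm = 200,
                         seed = 200 + s)
    planted <- do.call(rbind, lapply(names(sim$truth$regulons), function(tf) {
      cbind(tf = tf, sim$truth$regulons[[tf]])
    }))
    key <- paste(net$edges$regulator, net$edges$target)
    hit <- match(paste(planted$tf, planted$target), key)
    recov[s] <- mean(!is.na(hit))
    signs[s] <- mean(net$edges$sign[hit[!is.na(hit)]] ==
                       planted$sign[!is.na(hit)])
  }
  expect_gte(mean(recov), 0.9)
  expect_gte(mean(signs), 0.95)
})

test_that("regulon GMT export splits signed targets", {
  tab <- data.frame(regulator = "TF1", target = c("t1", "t2", "t3"),
                    mi = c(0.5, 0.4, 0.3), sign = c(1L, -1L, 1L),
                    p = 0.001, q = 0.001)
  net <- dpi_prune(tab, "TF1")
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  regulons_to_gmt(net, path, signed = TRUE)
  sets <- read_gmt(path)
  expect_setequal(sets$TF1_pos, c("t1", "t3"))
  expect_equal(sets$TF1_neg, "t2")
})
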