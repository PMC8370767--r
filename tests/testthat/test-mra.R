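test_that("hypergeometric overlap p matches the closed form and direct sum", {
  universe <- sprintf("g%02d", 1:20)
  sig <- universe[1:5]
  regs <- list(TFa = universe[1:5],    # full overlap
               TFb = universe[6:10])   # zero overlap
  res <- hypergeom_mra(regs, sig, universe)
  expect_equal(res$p_hyper[res$tf == "TFa"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$overlap[res$tf == "TFb"], 0L)
  expect_equal(res$p_hyper[res$tf == "TFb"], 1)

  expect_error(hypergeom_mra(regs, character(0), universe), "signature")
  expect_error(hypergeom_mra(regs, sig, character(0)), "universe")
})

test_that("hypergeometric tails match enumeration on random regulons", {
  set.seed(43)
  universe <- sprintf("g%03d", 1:200)
  sig <- sample(universe, 40)
  regs <- lapply(setNames(1:100, sprintf("TF%03d", 1:100)), function(i) {
    sample(universe, sample(3:60, 1))
  })
  res <- hypergeom_mra(regs, sig, universe)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_hyper[i],
                 oracle_hyper_tail(res$overlap[i], 40, 200,
                                   res$regulon_size[i]),
                 tolerance = 1e-10)
  }
  expect_true(all(res$q_hyper >= res$p_hyper))
})

test_that("hypergeometric p is monotone decreasing in overlap", {
  p <- vapply(0:10, function(k) {
    phyper(k - 1, 20, 180, 10, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("GSEA running sum matches the hand examples", {
  stats_vec <- c(a = 3, b = 2, c = 1, d = -1)
  expect_equal(gsea_es(stats_vec, "a", weight = 1), 1)
  expect_equal(gsea_es(stats_vec, "d", weight = 1), -1)
  expect_error(gsea_es(stats_vec, c("a", "b", "c", "d")), "covers")
  expect_error(gsea_es(stats_vec, "zzz"), "overlap")
})

test_that("unweighted single-gene ES equals the KS deviation at each rank", {
  N <- 10
  stats_vec <- setNames(seq(N, 1), sprintf("g%02d", 1:N))
  for (r in 1:N) {
    es <- gsea_es(stats_vec, names(stats_vec)[r], weight = 0)
    # running sum: rises to 1 at r after dropping (r-1)/(N-1)
    up <- 1 - (r - 1) / (N - 1)
    down <- -(r - 1) / (N - 1)
    expected <- if (up >= -down) up else down
    expect_equal(es, expected, tolerance = 1e-12)
  }
})

test_that("one-tail regulon GSEA: planted top set, null behaviour, seeds", {
  set.seed(47)
  N <- 300
  stats_vec <- setNames(sort(rnorm(N), decreasing = TRUE),
                        sprintf("g%03d", 1:N))
  top_set <- names(stats_vec)[1:20]
  g <- regulon_gsea_1t(top_set, stats_vec, n_perm = 200, seed = 3)
  expect_gt(g$es, 0)
  expect_equal(g$p_gsea, 1 / 201)

  g2 <- regulon_gsea_1t(top_set, stats_vec, n_perm = 200, seed = 3)
  expect_identical(g, g2)

  expect_warning(tiny <- regulon_gsea_1t(names(stats_vec)[1:2], stats_vec),
                 "fewer than 3")
  expect_null(tiny)

  # random regulons rarely reach |NES| of 2
  nes <- vapply(1:200, function(i) {
    regulon_gsea_1t(sample(names(stats_vec), 15), stats_vec, n_perm = 100,
                    seed = i)$nes
  }, numeric(1))
  expect_gte(mean(abs(nes) < 2), 0.95)
})

test_that("master-regulator ranking applies the declared tie-breaks", {
  tab <- data.frame(tf = c("Z", "A", "M"), regulon_size = 10, overlap = 5,
                    universe_size = 100,
                    p_hyper = c(0.01, 0.01, 0.01),
                    q_hyper = c(0.03, 0.03, 0.03),
                    es = 1, nes = c(1.5, 1.2, 2.0), p_gsea = 0.01)
  rk <- rank_mrs(tab, alpha = 0.05)
  expect_equal(rk$ranked$tf, c("M", "Z", "A"))  # |nes| desc, then id
  expect_equal(rk$top, c("M", "Z", "A"))
  expect_length(rank_mrs(tab, alpha = 0)$top, 0)

  # without NES columns the fallback is q, p, then id
  tab2 <- tab[, 1:6]
  tab2$q_hyper <- c(0.5, 0.01, 0.2)
  expect_equal(rank_mrs(tab2)$ranked$tf, c("A", "M", "Z"))
})

test_that("planted master regulators surface through the full analysis", {
  sim <- gen_expression(n_genes = 800, n_samples = 120, n_batches = 2,
                        n_tfs = 40, n_mes_tfs = 4, regulon_size = 30,
                        effect = 1, seed = 301)
  hm <- harmonize(sim$datasets)
  de <- diffexp(hm$matrix,
                ifelse(sim$truth$subtype[hm$sample_ids] == "MES",
                       "MES", "nonMES"),
                hm$batch_labels, ref = "nonMES")
  net <- infer_network(hm$matrix, sim$truth$tfs, n_perm = 200, seed = 302)
  sig <- make_signature(de)
  mr <- run_mra(net, union(sig$up, sig$down), hm$gene_ids,
                ranked_stats = setNames(de$t_mod, de$gene),
                n_perm = 100, seed = 303)
  rk <- rank_mrs(mr, alpha = 0.01)
  expect_true(all(sim$truth$mes_tfs %in% rk$ranked$tf[1:8]))
  expect_true(all(sim$truth$mes_tfs %in% rk$top))
  # planted regulators carry large one-tail enrichment
  planted_nes <- rk$ranked$nes[rk$ranked$tf %in% sim$truth$mes_tfs]
  expect_true(all(abs(planted_nes) > 1 | is.na(planted_nes)))
})
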