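# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the slow, literal route (enumeration, direct
# summation, grid search) and share no code with the package internals.

# ssGSEA running sum computed step by step from the definition.
oracle_ssgsea <- function(profile, signature, w) {
  ord <- order(-profile, names(profile), method = "radix")
  ranked <- names(profile)[ord]
  N <- length(ranked)
  inset <- ranked %in% signature
  stat <- (N:1)^w
  win <- ifelse(inset, stat, 0)
  win <- win / sum(win)
  wout <- ifelse(inset, 0, 1 / sum(!inset))
  sum(cumsum(win) - cumsum(wout))
}

# Upper-tail hypergeometric P(X >= k) by direct summation of point masses.
oracle_hyper_tail <- function(k, n_sig, n_universe, n_draw) {
  xs <- k:min(n_sig, n_draw)
  sum(choose(n_sig, xs) * choose(n_universe - n_sig, n_draw - xs)) /
    choose(n_universe, n_draw)
}

# OLS coefficients by explicit normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Log-rank statistic from a per-event-time O/E/V table.
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Single-hit log-likelihood maximized by exhaustive grid search.
oracle_lda_grid <- function(data, f_grid = seq(1e-5, 1, by = 1e-5)) {
  ll <- vapply(f_grid, function(f) {
    p_pos <- 1 - exp(-f * data$dose)
    p_pos <- pmin(pmax(p_pos, 1e-300), 1 - 1e-16)
    sum(data$positive * log(p_pos) +
          (data$tested - data$positive) * log(1 - p_pos))
  }, numeric(1))
  list(f = f_grid[which.max(ll)], loglik = max(ll))
}

# DPI pruning by exhaustive triangle enumeration over all (TF, TF, target)
# triples, recomputed from scratch (marks against the input table, applied
# at the end). Returns surviving (regulator, target) keys, undirected.
oracle_dpi <- function(edges, tfs, tolerance = 0) {
  und <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- und(edges$regulator, edges$target)
  mi <- tapply(edges$mi, ek, max)
  nodes <- unique(c(edges$regulator, edges$target))
  targets <- nodes
  drop <- character(0)
  for (t1 in seq_along(tfs)) {
    for (t2 in seq_along(tfs)) {
      if (t2 <= t1) next
      for (tg in targets) {
        if (tg == tfs[t1] || tg == tfs[t2]) next
        k12 <- und(tfs[t1], tfs[t2])
        k1t <- und(tfs[t1], tg)
        k2t <- und(tfs[t2], tg)
        if (any(!(c(k12, k1t, k2t) %in% names(mi)))) next
        vals <- mi[c(k12, k1t, k2t)]
        w <- which.min(vals)
        if (sum(vals == vals[w]) > 1L) next
        if (vals[w] < (1 - tolerance) * min(vals[-w])) {
          drop <- c(drop, names(vals)[w])
        }
      }
    }
  }
  setdiff(unique(ek), drop)
}

# Random edge table over a small TF/target universe, with TF-TF edges
# included, for DPI oracle comparisons.
random_edge_table <- function(n_tfs = 8, n_targets = 15, p_edge = 0.4) {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  tgt <- sprintf("t%02d", seq_len(n_targets))
  rows <- list()
  for (a in tfs) {
    for (b in c(tfs[tfs > a], tgt)) {
      if (runif(1) < p_edge) {
        rows[[length(rows) + 1L]] <- data.frame(
          regulator = a, target = b, mi = round(runif(1, 0.01, 1), 3),
          sign = sample(c(-1L, 1L), 1), p = 0.001, q = 0.001,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
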