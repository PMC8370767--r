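# TF-target regulon network inference. Pairwise dependence is measured by a
# Gaussian-copula mutual information: both vectors are transformed to normal
# scores (rank -> standard normal quantiles, average ranks on ties), and
# MI = -0.5 * log(1 - r^2) for their Pearson correlation r. The estimator is
# symmetric, deterministic, nonnegative and invariant to strictly monotone
# transforms of either input. Edge significance comes from a pooled
# permutation null: each TF's vector is permuted across samples, MI is
# recomputed against every target, and all null values are pooled into one
# distribution shared by all edges, exactly as a pooled-null network run with
# 1000 permutations. Edges passing a BH threshold are then pruned by the data
# processing inequality: in any fully connected triangle of two TFs and a
# target, the weakest edge is removed as presumptively indirect.

#' Gaussian-copula mutual information between two vectors
#'
#' @param x,y Numeric vectors of equal length (>= 8), no missing values.
#' @param clip `r^2` is clipped at `1 - clip` so deterministic monotone
#'   relationships give a large finite value instead of Inf.
#' @return Nonnegative mutual-information estimate (nats).
#' @export
mutual_information <- function(x, y, clip = 1e-12) {
  stopifnot(length(x) == length(y), length(x) >= 8L, !anyNA(x), !anyNA(y))
  mi_from_r(stats::cor(normal_scores(x), normal_scores(y)), clip = clip)
}

# Histogram MI on a fixed equal-frequency grid; provided for comparison with
# the copula estimator, not used by the default pipeline.
mutual_information_binned <- function(x, y, n_bins = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 8L)
  bx <- cut(rank(x, ties.method = "first"), n_bins, labels = FALSE)
  by <- cut(rank(y, ties.method = "first"), n_bins, labels = FALSE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Mutual information and pooled-permutation p-values for all TF-target pairs
#'
#' Computes MI between every TF and every other gene in the matrix. The null
#' distribution is built by permuting the sample order of each TF's
#' normal-score vector `n_perm` times and recomputing MI against all of that
#' TF's targets; all null values are pooled into a single distribution, and
#' each edge's p-value is (1 + #\{null MI >= observed\}) / (pool size + 1).
#' q-values are BH over all tested edges; the edge sign is the sign of the
#' normal-score correlation.
#'
#' @param mat Genes-by-samples matrix (>= 8 samples).
#' @param tfs Character vector of regulator gene ids (subset of rownames).
#' @param n_perm Permutations per TF (>= 100).
#' @param seed Integer seed for the permutations.
#' @return `EdgeTable` data frame: regulator, target, mi, sign, p, q.
#' @export
edge_pvalues <- function(mat, tfs, n_perm = 1000, seed = 1) {
  if (ncol(mat) < 8L) stop("need at least 8 samples")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  tfs <- as.character(tfs)
  if (length(tfs) == 0L || !all(tfs %in% rownames(mat))) {
    stop("tfs must be a non-empty subset of the matrix genes")
  }
  genes <- rownames(mat)
  n <- ncol(mat)
  Z <- normal_score_rows(mat)               # rows unit-norm, mean 0
  tf_idx <- match(tfs, genes)

  # observed correlations: TF rows x all rows
  R <- tcrossprod(Z[tf_idx, , drop = FALSE], Z)
  reg <- rep(tfs, each = length(genes))
  tgt <- rep(genes, times = length(tfs))
  keep <- reg != tgt
  r_obs <- as.vector(t(R))[keep]
  edges <- data.frame(regulator = reg[keep], target = tgt[keep],
                      mi = mi_from_r(r_obs), sign = ifelse(r_obs >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)

  # pooled null: for each TF, n_perm permuted copies of its row against all
  # its targets; counts of null >= observed accumulated chunk-wise against
  # the sorted observed MI values to avoid materializing the full pool
  ord <- order(edges$mi)
  sorted_obs <- edges$mi[ord]
  count_sorted <- numeric(nrow(edges))
  pool_size <- 0
  with_seed(seed, {
    for (i in seq_along(tf_idx)) {
      z <- Z[tf_idx[i], ]
      P <- matrix(0, n_perm, n)
      for (p in seq_len(n_perm)) P[p, ] <- z[sample.int(n)]
      null_r <- tcrossprod(P, Z[-tf_idx[i], , drop = FALSE])
      null_mi <- sort(mi_from_r(as.vector(null_r)))
      pool_size <- pool_size + length(null_mi)
      # #{null >= obs} = pool - #{null < obs}
      count_sorted <- count_sorted + length(null_mi) -
        findInterval(sorted_obs, null_mi, left.open = TRUE)
    }
  })
  count_ge <- numeric(nrow(edges))
  count_ge[ord] <- count_sorted
  edges$p <- (1 + count_ge) / (pool_size + 1)
  edges$q <- stats::p.adjust(edges$p, method = "BH")
  attr(edges, "n_perm") <- n_perm
  attr(edges, "seed") <- seed
  attr(edges, "pool_size") <- pool_size
  class(edges) <- c("EdgeTable", "data.frame")
  edges
}

#' Keep edges passing the FDR threshold
#'
#' @param edges An `EdgeTable` with q-values.
#' @param alpha FDR threshold (default 0.05).
#' @return The filtered `EdgeTable`.
#' @export
filter_edges <- function(edges, alpha = 0.05) {
  out <- edges[edges$q < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Data-processing-inequality pruning and regulon assembly
#'
#' For every triangle consisting of two TFs and one target in which all three
#' edges are present, the edge with the smallest MI is marked for removal
#' when its MI is below (1 - tolerance) times the smaller of the other two;
#' exact ties are left alone. All marks are computed against the pre-pruning
#' table and applied simultaneously, so the result does not depend on
#' enumeration order. By default any of the three edges may be removed,
#' including the TF-TF edge; `protect_tf_tf = TRUE` restricts removal to
#' TF-target edges.
#'
#' @param edges A filtered `EdgeTable` (TF-TF pairs may appear in either or
#'   both directions; they are treated as one undirected edge).
#' @param tfs Character vector of regulator gene ids.
#' @param tolerance Relative tolerance in [0, 1); 0 reproduces strict DPI.
#' @param protect_tf_tf Never remove TF-TF edges if `TRUE` (default FALSE).
#' @return A `RegulonNetwork`: list with `edges` (surviving `EdgeTable`),
#'   `regulons` (TF -> data frame of target, mi, sign) and `params`.
#' @export
dpi_prune <- function(edges, tfs, tolerance = 0, protect_tf_tf = FALSE) {
  tfs <- as.character(tfs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ek <- key(edges$regulator, edges$target)
  # undirected lookup: first occurrence wins (duplicates have identical mi)
  first <- !duplicated(ek)
  mi_of <- stats::setNames(edges$mi[first], ek[first])
  drop_key <- character(0)

  # regulating TFs per target (targets include TFs themselves)
  by_target <- split(edges$regulator, edges$target)
  for (tg in names(by_target)) {
    regs <- sort(unique(by_target[[tg]]))
    if (tg %in% tfs) regs <- setdiff(regs, tg)
    if (length(regs) < 2L) next
    for (a in seq_len(length(regs) - 1L)) {
      for (b in (a + 1L):length(regs)) {
        tf1 <- regs[a]; tf2 <- regs[b]
        k12 <- key(tf1, tf2)
        mi12 <- mi_of[k12]
        if (is.na(mi12)) next      # TF-TF edge absent: no triangle
        k1t <- key(tf1, tg); k2t <- key(tf2, tg)
        tri_mi <- c(mi12, mi_of[k1t], mi_of[k2t])
        tri_key <- c(k12, k1t, k2t)
        w <- which.min(tri_mi)
        others_min <- min(tri_mi[-w])
        if (sum(tri_mi == tri_mi[w]) > 1L) next   # tied minimum: keep all
        if (tri_mi[w] < (1 - tolerance) * others_min) {
          if (protect_tf_tf && tri_key[w] == k12) next
          drop_key <- c(drop_key, tri_key[w])
        }
      }
    }
  }
  survivors <- edges[!(ek %in% drop_key), , drop = FALSE]
  rownames(survivors) <- NULL
  tf_target <- survivors[!(survivors$target %in% tfs), , drop = FALSE]
  regulons <- lapply(stats::setNames(tfs, tfs), function(tf) {
    r <- tf_target[tf_target$regulator == tf, c("target", "mi", "sign")]
    rownames(r) <- NULL
    r
  })
  structure(list(edges = survivors, regulons = regulons,
                 params = list(tolerance = tolerance,
                               protect_tf_tf = protect_tf_tf)),
            class = "RegulonNetwork")
}

#' @export
print.RegulonNetwork <- function(x, ...) {
  sizes <- vapply(x$regulons, nrow, integer(1))
  cat("RegulonNetwork: ", length(x$regulons), " TFs, ",
      nrow(x$edges), " surviving edges; regulon sizes ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Infer a regulon network from a harmonized matrix
#'
#' Runs [edge_pvalues()], [filter_edges()] and [dpi_prune()] in sequence.
#'
#' @inheritParams edge_pvalues
#' @inheritParams dpi_prune
#' @param alpha FDR threshold for edge retention.
#' @return A `RegulonNetwork`.
#' @export
infer_network <- function(mat, tfs, n_perm = 1000, alpha = 0.05,
                          tolerance = 0, protect_tf_tf = FALSE, seed = 1) {
  if (inherits(mat, "HarmonizedMatrix")) mat <- mat$matrix
  tfs <- intersect(as.character(tfs), rownames(mat))
  edges <- edge_pvalues(mat, tfs, n_perm = n_perm, seed = seed)
  net <- dpi_prune(filter_edges(edges, alpha = alpha), tfs,
                   tolerance = tolerance, protect_tf_tf = protect_tf_tf)
  net$params <- c(net$params,
                  list(n_perm = n_perm, alpha = alpha, seed = seed))
  net
}

#' Export regulons as GMT gene sets
#'
#' @param network A `RegulonNetwork`.
#' @param path Output GMT path.
#' @param signed If `TRUE`, each regulon is split into "_pos"/"_neg" sets by
#'   edge sign.
#' @export
regulons_to_gmt <- function(network, path, signed = FALSE) {
  regs <- network$regulons
  regs <- regs[vapply(regs, nrow, integer(1)) > 0L]
  sets <- if (signed) {
    out <- list()
    for (tf in names(regs)) {
      r <- regs[[tf]]
      if (any(r$sign > 0)) out[[paste0(tf, "_pos")]] <- r$target[r$sign > 0]
      if (any(r$sign < 0)) out[[paste0(tf, "_neg")]] <- r$target[r$sign < 0]
    }
    out
  } else {
    lapply(regs, function(r) r$target)
  }
  write_gmt(sets, path)
}
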