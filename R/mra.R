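# Master-regulator ranking. Each TF's regulon is tested for overlap with the
# phenotype's differential-expression signature by an upper-tail
# hypergeometric test (BH-corrected across TFs), and for positional
# enrichment in the moderated-t ranking by one-tail GSEA with a size-matched
# resampling null.

#' Hypergeometric regulon-signature overlap tests
#'
#' For each TF, the number of regulon genes falling in the signature is
#' referred to the hypergeometric distribution: population = universe genes,
#' successes = signature genes, draws = regulon size;
#' p = P(X >= overlap), upper tail. q-values are BH across TFs.
#'
#' @param network A `RegulonNetwork` (or a named list of character regulons).
#' @param signature_genes Character vector of phenotype signature genes
#'   (subset of `universe`).
#' @param universe Character vector of all genes the network and signature
#'   were derived from (typically the harmonized matrix's genes).
#' @return `MRResult` data frame: tf, regulon_size, overlap, universe_size,
#'   p_hyper, q_hyper.
#' @export
hypergeom_mra <- function(network, signature_genes, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(signature_genes) == 0L) stop("empty signature")
  if (!all(signature_genes %in% universe)) {
    stop("signature genes must be a subset of the universe")
  }
  regulons <- if (inherits(network, "RegulonNetwork")) {
    lapply(network$regulons, function(r) r$target)
  } else {
    network
  }
  regulons <- lapply(regulons, function(g) intersect(unique(g), universe))
  m <- length(signature_genes)
  N <- length(universe)
  out <- data.frame(
    tf = names(regulons),
    regulon_size = vapply(regulons, length, integer(1)),
    overlap = vapply(regulons, function(g) {
      sum(g %in% signature_genes)
    }, integer(1)),
    universe_size = N,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p_hyper <- stats::phyper(out$overlap - 1L, m, N - m, out$regulon_size,
                               lower.tail = FALSE)
  out$q_hyper <- stats::p.adjust(out$p_hyper, method = "BH")
  class(out) <- c("MRResult", "data.frame")
  out
}

#' Classical GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running sum over a ranking: in-set genes
#' advance the sum by |stat|^weight normalized over in-set genes, out-of-set
#' genes retreat it by 1/(N - n_set). The score is the signed maximum
#' deviation from zero (positive deviation wins an exact magnitude tie).
#'
#' @param ranked_stats Named numeric vector of ranking statistics; will be
#'   sorted decreasing (ties broken by gene id).
#' @param gene_set Character vector; must overlap the ranked genes and not
#'   cover them all.
#' @param weight Exponent on |stat| for in-set steps (default 1, classical
#'   weighted GSEA; 0 gives the unweighted KS statistic).
#' @return The enrichment score in [-1, 1].
#' @export
gsea_es <- function(ranked_stats, gene_set, weight = 1) {
  ord <- order(-ranked_stats, names(ranked_stats), method = "radix")
  stats_sorted <- ranked_stats[ord]
  hits <- names(stats_sorted) %in% gene_set
  if (!any(hits)) stop("gene set does not overlap the ranked genes")
  if (all(hits)) stop("gene set covers every ranked gene")
  gsea_es_hits(abs(stats_sorted), hits, weight)
}

# Running sum on a precomputed hit indicator; abs_stats aligned to the
# decreasing ranking.
gsea_es_hits <- function(abs_stats, hits, weight) {
  w <- abs_stats[hits]^weight
  sw <- sum(w)
  inc <- numeric(length(hits))
  inc[hits] <- if (sw > 0) w / sw else 1 / sum(hits)
  inc[!hits] <- -1 / sum(!hits)
  rs <- cumsum(inc)
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
}

#' One-tail GSEA of a regulon against a phenotype ranking
#'
#' The regulon is taken as an unsigned target set. The null distribution is
#' built from size-matched gene sets drawn uniformly from the ranked genes;
#' NES = ES / mean(|null ES|) and p = (1 + #\{|null ES| >= |ES|\}) /
#' (n_perm + 1).
#'
#' @param regulon Character vector of target genes.
#' @param ranked_stats Named numeric vector (e.g. moderated t statistics).
#' @param n_perm Number of null sets.
#' @param weight See [gsea_es()].
#' @param seed Integer seed.
#' @return List with `es`, `nes`, `p_gsea`, `size`; `NULL` (with a warning)
#'   when fewer than 3 regulon genes intersect the ranking.
#' @export
regulon_gsea_1t <- function(regulon, ranked_stats, n_perm = 1000, weight = 1,
                            seed = 1) {
  genes <- names(ranked_stats)
  set <- intersect(unique(regulon), genes)
  if (length(set) < 3L) {
    warning("regulon has fewer than 3 genes in the ranking; skipped")
    return(NULL)
  }
  ord <- order(-ranked_stats, genes, method = "radix")
  abs_sorted <- abs(ranked_stats[ord])
  hits <- names(ranked_stats)[ord] %in% set
  es <- gsea_es_hits(abs_sorted, hits, weight)
  k <- length(set)
  N <- length(genes)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(N)
      h[sample.int(N, k)] <- TRUE
      gsea_es_hits(abs_sorted, h, weight)
    }, numeric(1))
  })
  list(es = es, nes = es / mean(abs(null_es)),
       p_gsea = (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1),
       size = k)
}

#' Full master-regulator analysis over a network
#'
#' Combines [hypergeom_mra()] with per-TF one-tail GSEA against the supplied
#' ranking.
#'
#' @param network A `RegulonNetwork`.
#' @param signature_genes Signature gene vector (e.g.
#'   `make_signature()$up` union `$down`).
#' @param universe Gene universe.
#' @param ranked_stats Optional named statistic vector for the GSEA arm; when
#'   `NULL` only the hypergeometric columns are filled.
#' @param n_perm,weight,seed Passed to [regulon_gsea_1t()].
#' @param min_regulon TFs with smaller regulons (after intersection with the
#'   universe) get NA GSEA columns.
#' @return `MRResult` data frame with columns tf, regulon_size, overlap,
#'   universe_size, p_hyper, q_hyper, es, nes, p_gsea.
#' @export
run_mra <- function(network, signature_genes, universe, ranked_stats = NULL,
                    n_perm = 1000, weight = 1, seed = 1, min_regulon = 3L) {
  out <- hypergeom_mra(network, signature_genes, universe)
  out$es <- NA_real_; out$nes <- NA_real_; out$p_gsea <- NA_real_
  if (!is.null(ranked_stats)) {
    for (i in seq_len(nrow(out))) {
      reg <- network$regulons[[out$tf[i]]]$target
      if (length(intersect(reg, names(ranked_stats))) < min_regulon) next
      g <- suppressWarnings(
        regulon_gsea_1t(reg, ranked_stats, n_perm = n_perm, weight = weight,
                        seed = stage_seed(seed, out$tf[i]))
      )
      if (!is.null(g)) {
        out$es[i] <- g$es; out$nes[i] <- g$nes; out$p_gsea[i] <- g$p_gsea
      }
    }
  }
  out
}

#' Rank TFs by master-regulator significance
#'
#' Sorts by hypergeometric q ascending, ties broken by p, then |NES|
#' descending (missing NES treated as 0), then TF id; the top slice contains
#' the TFs with q below `alpha`.
#'
#' @param mr_table An `MRResult` data frame.
#' @param alpha Significance cut for the top slice (default 1e-4, i.e.
#'   BH-adjusted p < 0.0001).
#' @return List with `ranked` (the reordered table) and `top` (TF ids with
#'   q_hyper < alpha, in rank order).
#' @export
rank_mrs <- function(mr_table, alpha = 1e-4) {
  nes_mag <- abs(mr_table$nes %||% rep(NA_real_, nrow(mr_table)))
  nes_mag[is.na(nes_mag)] <- 0
  ord <- order(mr_table$q_hyper, mr_table$p_hyper, -nes_mag, mr_table$tf)
  ranked <- mr_table[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  list(ranked = ranked, top = ranked$tf[ranked$q_hyper < alpha])
}
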