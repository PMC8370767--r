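# Single-sample GSEA subtype scoring and resampling-based classification.
#
# A sample's genes are ranked by decreasing expression; the score for a gene
# set is the running-sum integral: at each ranked position the cumulative
# in-set weighted fraction minus the cumulative out-of-set fraction, summed
# over all positions. In-set weights are the descending rank statistic
# (N - position + 1) raised to `weight_exponent`, normalized to sum to 1, so
# the score depends only on ranks and is invariant to strictly monotone
# transforms of the profile.

# Core scorer on in-set positions. For positions p_1..p_k in a ranking of N
# genes with in-set weights w (sum 1):
#   sum_i P_in(i)  = sum_j w_j * (N - p_j + 1)
#   sum_i P_out(i) = (T - sum_j (N - p_j + 1)) / (N - k),  T = N(N+1)/2
# because an out-of-set gene at position q contributes (N - q + 1) unit steps.
score_from_positions <- function(pos, N, weight_exponent) {
  k <- length(pos)
  tail_len <- N - pos + 1          # number of positions at/after each hit
  w <- tail_len^weight_exponent
  w <- w / sum(w)
  sum_in <- sum(w * tail_len)
  sum_out <- (N * (N + 1) / 2 - sum(tail_len)) / (N - k)
  sum_in - sum_out
}

# Deterministic within-sample ranking: decreasing value, ties broken
# lexicographically by gene id.
profile_order <- function(profile) {
  order(-profile, names(profile), method = "radix")
}

#' Single-sample GSEA enrichment score
#'
#' @param profile Named numeric vector: one sample's expression, names = gene
#'   ids.
#' @param signature Character vector of gene ids (the gene set).
#' @param weight_exponent Nonnegative exponent applied to the descending rank
#'   statistic when weighting in-set steps; 0 gives unweighted steps. Default
#'   0.25, the canonical single-sample GSEA choice.
#' @return Enrichment score (dimensionless).
#' @export
ssgsea_score <- function(profile, signature, weight_exponent = 0.25) {
  stopifnot(length(profile) >= 2L, !is.null(names(profile)),
            weight_exponent >= 0)
  ord <- profile_order(profile)
  ranked_genes <- names(profile)[ord]
  pos <- which(ranked_genes %in% signature)
  if (length(pos) == 0L) stop("signature does not overlap the profile")
  if (length(pos) == length(profile)) {
    stop("signature covers every profile gene; enrichment undefined")
  }
  score_from_positions(pos, length(profile), weight_exponent)
}

#' Classify one sample against a set of subtype signatures
#'
#' Each signature is scored by [ssgsea_score()]; its empirical p-value is
#' computed against size-matched gene sets drawn uniformly without replacement
#' from the profile's genes: p = (1 + #\{null score >= observed\}) /
#' (n_perm + 1). The winning label is the signature with the smallest p,
#' ties broken by larger observed score, then by signature order.
#'
#' @param profile Named numeric vector for one sample.
#' @param signatures Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm Number of resampled gene sets per signature (>= 100).
#' @param weight_exponent See [ssgsea_score()].
#' @param seed Integer seed; the call is fully reproducible given it.
#' @return A `SubtypeCall`: list with `sample_id`, `scores`, `pvalues`,
#'   `label`.
#' @export
classify_sample <- function(profile, signatures, n_perm = 1000,
                            weight_exponent = 0.25, seed = 1,
                            sample_id = "sample") {
  stopifnot(length(signatures) >= 2L, n_perm >= 100L)
  N <- length(profile)
  ord <- profile_order(profile)
  ranked_genes <- names(profile)[ord]
  scores <- numeric(length(signatures))
  pvalues <- numeric(length(signatures))
  null_by_size <- list()   # shared across equal-size signatures, so two
                           # identical signatures get identical p-values
  for (s in seq_along(signatures)) {
    pos <- which(ranked_genes %in% signatures[[s]])
    if (length(pos) == 0L) stop("signature '", names(signatures)[s],
                                "' does not overlap the profile")
    if (length(pos) == N) stop("signature '", names(signatures)[s],
                               "' covers every profile gene")
    k <- length(pos)
    obs <- score_from_positions(pos, N, weight_exponent)
    size_key <- as.character(k)
    if (is.null(null_by_size[[size_key]])) {
      null_by_size[[size_key]] <- with_seed(stage_seed(seed, size_key), {
        vapply(seq_len(n_perm), function(i) {
          score_from_positions(sample.int(N, k), N, weight_exponent)
        }, numeric(1))
      })
    }
    scores[s] <- obs
    pvalues[s] <- (1 + sum(null_by_size[[size_key]] >= obs)) / (n_perm + 1)
  }
  names(scores) <- names(pvalues) <- names(signatures)
  win <- order(pvalues, -scores, seq_along(signatures))[1L]
  structure(list(sample_id = sample_id, scores = scores, pvalues = pvalues,
                 label = names(signatures)[win]),
            class = "SubtypeCall")
}

#' Classify every sample of a harmonized matrix
#'
#' @param hm A `HarmonizedMatrix` (or plain genes-by-samples matrix).
#' @param signatures Named list of gene sets.
#' @inheritParams classify_sample
#' @return Data frame with one row per sample: per-signature scores
#'   (`score.<name>`), p-values (`p.<name>`) and the winning `label`.
#' @export
classify_samples <- function(hm, signatures, n_perm = 1000,
                             weight_exponent = 0.25, seed = 1) {
  mat <- if (inherits(hm, "HarmonizedMatrix")) hm$matrix else hm
  calls <- lapply(seq_len(ncol(mat)), function(j) {
    classify_sample(stats::setNames(mat[, j], rownames(mat)), signatures,
                    n_perm = n_perm, weight_exponent = weight_exponent,
                    seed = stage_seed(seed, colnames(mat)[j]),
                    sample_id = colnames(mat)[j])
  })
  df <- data.frame(sample_id = vapply(calls, `[[`, character(1), "sample_id"),
                   stringsAsFactors = FALSE)
  for (nm in names(signatures)) {
    df[[paste0("score.", nm)]] <- vapply(calls, function(x) x$scores[[nm]],
                                         numeric(1))
    df[[paste0("p.", nm)]] <- vapply(calls, function(x) x$pvalues[[nm]],
                                     numeric(1))
  }
  df$label <- vapply(calls, `[[`, character(1), "label")
  df
}

#' Retain samples with concordant calls under two classification schemes
#'
#' A sample is retained when its label in scheme B belongs to the set of
#' labels that the mapping allows for its scheme-A label (e.g. mesenchymal
#' samples must also be called injury-response, proneural/classical must be
#' called developmental).
#'
#' @param calls_a,calls_b Data frames with columns `sample_id` and `label`
#'   (as returned by [classify_samples()]), over the same samples.
#' @param mapping Named list: scheme-A label -> character vector of concordant
#'   scheme-B labels.
#' @return List with `retained` (sample ids) and `concordance` (fraction).
#' @export
concordance_filter <- function(calls_a, calls_b, mapping) {
  stopifnot(setequal(calls_a$sample_id, calls_b$sample_id))
  b <- calls_b$label[match(calls_a$sample_id, calls_b$sample_id)]
  unmapped <- setdiff(unique(calls_a$label), names(mapping))
  if (length(unmapped)) {
    stop("no concordance mapping for label(s): ",
         paste(unmapped, collapse = ", "))
  }
  ok <- vapply(seq_along(b), function(i) {
    b[i] %in% mapping[[calls_a$label[i]]]
  }, logical(1))
  list(retained = calls_a$sample_id[ok], concordance = mean(ok))
}
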