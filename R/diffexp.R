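# Batch-aware two-group moderated differential expression. Per-gene ordinary
# least squares on intercept + group + batch indicators, then empirical-Bayes
# shrinkage of the residual variances toward a scaled inverse-chi-square
# (equivalently scaled-F) prior estimated by method of moments on log s2,
# giving a moderated t statistic with df_resid + d0 degrees of freedom.

#' Build and validate a two-group, multi-batch design
#'
#' @param group Character/factor per-sample labels with exactly two levels;
#'   the second level of the factor is the "high" group whose effect is
#'   reported (default levels: sorted, so e.g. MES vs nonMES reports
#'   nonMES - MES unless `ref` is given).
#' @param batch Character/factor per-sample batch ids.
#' @param ref Optional reference (baseline) group level.
#' @return List with the design `matrix`, `coef` (name of the group
#'   coefficient) and `df_resid`.
#' @export
design_info <- function(group, batch = NULL, ref = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (any(table(group) == 0L)) stop("both groups must be non-empty")
  if (!is.null(ref)) group <- stats::relevel(group, ref = ref)
  if (is.null(batch) || length(unique(batch)) == 1L) {
    X <- stats::model.matrix(~group)
  } else {
    batch <- as.factor(batch)
    X <- stats::model.matrix(~ group + batch)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  df_resid <- length(group) - ncol(X)
  if (df_resid < 2L) stop("fewer than 2 residual degrees of freedom")
  list(matrix = X, coef = paste0("group", levels(group)[2L]),
       df_resid = df_resid, group_levels = levels(group))
}

#' Per-gene least-squares fits
#'
#' @param mat Genes-by-samples matrix (e.g. `HarmonizedMatrix$matrix`).
#' @param design A [design_info()] result whose rows match the columns of
#'   `mat`.
#' @return Data frame with per-gene `effect` (group coefficient), `s2`
#'   (residual variance) and attributes `df_resid` and `v_coef` (the unscaled
#'   variance of the group coefficient from the design).
#' @export
fit_gene_models <- function(mat, design) {
  X <- design$matrix
  stopifnot(ncol(mat) == nrow(X))
  fit <- stats::lm.fit(X, t(mat))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  df_resid <- design$df_resid
  s2 <- rowSums(res^2) / df_resid
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  out <- data.frame(gene = rownames(mat),
                    effect = coefs[, design$coef],
                    s2 = s2, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_resid") <- df_resid
  attr(out, "v_coef") <- xtx_inv[design$coef, design$coef]
  out
}

# Newton solve of trigamma(y) = x for y > 0 (vectorized over x), used to
# invert the variance moment equation. Monotone decreasing, so the iteration
# from the large-x asymptote 1/x converges quadratically.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0sq` of a
#' scaled-F model s2 ~ s0sq * F(df_resid, d0) by matching the mean and
#' variance of log(s2):
#'   Var log s2 = trigamma(df/2) + trigamma(d0/2)
#'   E   log s2 = log s0sq + digamma(df/2) - log(df/2)
#'                - digamma(d0/2) + log(d0/2)
#' If the observed variance of log s2 does not exceed trigamma(df/2), the
#' excess dispersion is zero: d0 = Inf and the posterior collapses to the
#' pooled mean variance. Posterior (shrunken) variance is the precision-
#' weighted combination (d0*s0sq + df*s2) / (d0 + df).
#'
#' @param s2 Positive per-gene residual variances (>= 10 genes).
#' @param df_resid Residual degrees of freedom of the fits.
#' @param d0_override Optional forced prior df; `0` disables shrinkage
#'   (posterior = s2), `Inf` forces complete pooling.
#' @return List with `d0`, `s0sq` and `s2_post`.
#' @export
eb_moderate <- function(s2, df_resid, d0_override = NULL) {
  if (length(s2) < 10L) stop("need at least 10 genes to estimate the prior")
  if (any(s2 <= 0)) stop("all residual variances must be positive")
  z <- log(s2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (d0 == 0) {
      return(list(d0 = 0, s0sq = NA_real_, s2_post = s2))
    }
  } else {
    excess <- stats::var(z) - trigamma(df_resid / 2)
    d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  }
  if (is.infinite(d0)) {
    s0sq <- mean(s2)
    return(list(d0 = Inf, s0sq = s0sq, s2_post = rep(s0sq, length(s2))))
  }
  s0sq <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq,
       s2_post = (d0 * s0sq + df_resid * s2) / (d0 + df_resid))
}

#' Moderated t-tests with Benjamini-Hochberg correction
#'
#' @param fits Result of [fit_gene_models()].
#' @param eb Result of [eb_moderate()] on `fits$s2`.
#' @return `ModeratedResult` data frame: gene, effect, s2, t_mod, p, q, with
#'   attributes `d0`, `s0sq`, `df_total`.
#' @export
moderated_test <- function(fits, eb = eb_moderate(fits$s2,
                                                  attr(fits, "df_resid"))) {
  df_resid <- attr(fits, "df_resid")
  v_coef <- attr(fits, "v_coef")
  t_mod <- fits$effect / sqrt(eb$s2_post * v_coef)
  df_total <- df_resid + eb$d0
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  out <- data.frame(gene = fits$gene, effect = fits$effect, s2 = fits$s2,
                    s2_post = eb$s2_post, t_mod = t_mod, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- eb$d0
  attr(out, "s0sq") <- eb$s0sq
  attr(out, "df_total") <- df_total
  attr(out, "df_resid") <- df_resid
  out
}

#' Batch-aware moderated differential expression in one call
#'
#' @param mat Genes-by-samples matrix.
#' @param group,batch Per-sample labels (see [design_info()]).
#' @param ref Reference group level.
#' @param d0_override See [eb_moderate()].
#' @return A `ModeratedResult` data frame (see [moderated_test()]).
#' @export
diffexp <- function(mat, group, batch = NULL, ref = NULL,
                    d0_override = NULL) {
  design <- design_info(group, batch, ref = ref)
  fits <- fit_gene_models(mat, design)
  eb <- eb_moderate(fits$s2, design$df_resid, d0_override = d0_override)
  moderated_test(fits, eb)
}

#' Extract signature gene lists from differential-expression results
#'
#' @param results A `ModeratedResult` data frame.
#' @param q_threshold FDR threshold for signature membership (default 0.05).
#' @param top_n Number of genes for the display list, ranked by q with ties
#'   broken by |t_mod| then gene id (default 100).
#' @return List with `up`, `down` and `top` gene vectors.
#' @export
make_signature <- function(results, q_threshold = 0.05, top_n = 100) {
  up <- results$gene[results$q < q_threshold & results$effect > 0]
  down <- results$gene[results$q < q_threshold & results$effect < 0]
  if (length(up) + length(down) == 0L) {
    warning("no genes pass q < ", q_threshold)
  }
  ord <- order(results$q, -abs(results$t_mod), results$gene)
  list(up = up, down = down,
       top = results$gene[ord][seq_len(min(top_n, nrow(results)))])
}
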