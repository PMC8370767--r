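#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic operations in the package funnel through this so that results
# are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed deterministically spawns one seed per stage, so any
#' stage can be rerun in isolation and still reproduce its output. The stage
#' name is folded into the seed by summing its character codes with positional
#' weights, modulo a Mersenne-size prime, keeping the result a valid 32-bit
#' integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (i in seq_along(codes)) {
    h <- (h * 131 + codes[i]) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

# Rank-to-normal-scores transform: qnorm(rank / (n + 1)), average ranks on ties.
# Errors on constant input because ranks (and hence scores) are then undefined
# for dependence estimation.
normal_scores <- function(x) {
  if (length(unique(x)) < 2L) {
    stop("normal scores undefined for a constant vector")
  }
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# Row-wise normal scores of a gene-by-sample matrix, each row centred and
# scaled to unit Euclidean norm so that tcrossprod() of two such rows is their
# Pearson correlation.
normal_score_rows <- function(mat) {
  n <- ncol(mat)
  z <- t(apply(mat, 1L, function(x) {
    stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  }))
  z <- z - rowMeans(z)
  z / sqrt(rowSums(z^2))
}

# Gaussian-copula mutual information from a Pearson correlation on normal
# scores; r^2 clipped away from 1 to keep the estimate finite.
mi_from_r <- function(r, clip = 1e-12) {
  r2 <- pmin(r^2, 1 - clip)
  -0.5 * log1p(-r2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
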