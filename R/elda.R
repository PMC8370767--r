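# Limiting-dilution analysis under the single-hit Poisson model: a well
# plated with d cells is negative with probability exp(-f*d), where f is the
# frequency of sphere-forming cells. The maximum-likelihood fit is a binomial
# GLM for positive-well counts with a complementary-log-log link and offset
# log(dose), whose intercept is log(f); the 95% CI is a Wald interval on
# log f, reported on the "1 in N" scale (N = 1/f). Group differences are
# tested by the likelihood-ratio chi-square between the pooled and per-group
# fits.

validate_lda_data <- function(data) {
  stopifnot(all(c("dose", "tested", "positive") %in% names(data)))
  if (any(data$dose <= 0)) stop("doses must be positive")
  if (any(data$tested < 1L)) stop("tested well counts must be >= 1")
  if (any(data$positive < 0 | data$positive > data$tested)) {
    stop("positive wells must lie in [0, tested]")
  }
  invisible(data)
}

# Single-hit binomial log-likelihood at frequency f.
lda_loglik <- function(f, data) {
  p_pos <- -expm1(-f * data$dose)
  p_pos <- pmin(pmax(p_pos, 1e-300), 1 - 1e-16)
  sum(data$positive * log(p_pos) +
        (data$tested - data$positive) * log1p(-p_pos))
}

#' Fit the single-hit model to one group's well counts
#'
#' @param data Data frame with columns `dose`, `tested`, `positive` (a
#'   `group` column, if present, must hold a single value).
#' @param conf_level Confidence level for the Wald interval on log f.
#' @param profile If `TRUE` the CI is computed by profile likelihood
#'   (chi-square(1) cutoff) instead of the Wald interval.
#' @return An `LDAFit`: list with `frequency` (f), `N` (1/f, "1 in N"),
#'   `ci_low`, `ci_high` (on the N scale, ci_low <= N <= ci_high), `loglik`,
#'   `boundary` flag and `n_wells`.
#' @export
fit_single_hit <- function(data, conf_level = 0.95, profile = FALSE) {
  validate_lda_data(data)
  if ("group" %in% names(data) && length(unique(data$group)) > 1L) {
    stop("fit_single_hit expects a single group; use compare_groups")
  }
  agg <- stats::aggregate(cbind(tested, positive) ~ dose, data = data, sum)
  if (all(agg$positive == 0)) {
    return(structure(list(frequency = 0, N = Inf, ci_low = NA_real_,
                          ci_high = Inf, loglik = 0, boundary = TRUE,
                          n_wells = sum(agg$tested)),
                     class = "LDAFit"))
  }
  if (all(agg$positive == agg$tested)) {
    stop("all wells positive at every dose: frequency unbounded")
  }
  # saturated doses (all wells positive) are routine in dilution series and
  # push fitted probabilities to 1; the resulting glm warning is expected
  fit <- withCallingHandlers(
    stats::glm(cbind(positive, tested - positive) ~ 1,
               family = stats::binomial(link = "cloglog"),
               offset = log(dose), data = agg),
    warning = function(w) {
      if (grepl("fitted probabilities numerically", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  log_f <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (profile) {
    cut <- lda_loglik(exp(log_f), agg) -
      stats::qchisq(conf_level, df = 1) / 2
    lo <- stats::uniroot(function(lf) lda_loglik(exp(lf), agg) - cut,
                         c(log_f - 20, log_f))$root
    hi <- stats::uniroot(function(lf) lda_loglik(exp(lf), agg) - cut,
                         c(log_f, min(log_f + 20, 0)))$root
    ci_logf <- c(lo, hi)
  } else {
    ci_logf <- log_f + c(-1, 1) * zq * se
  }
  f <- exp(log_f)
  structure(list(frequency = f, N = 1 / f,
                 # larger N = rarer cells, so the upper N bound comes from
                 # the lower frequency bound
                 ci_low = exp(-ci_logf[2L]), ci_high = exp(-ci_logf[1L]),
                 loglik = lda_loglik(f, agg), boundary = FALSE,
                 n_wells = sum(agg$tested)),
            class = "LDAFit")
}

#' @export
print.LDAFit <- function(x, ...) {
  if (x$boundary) {
    cat("LDAFit: no positive wells; frequency 0 (1 in Inf), boundary\n")
  } else {
    cat(sprintf("LDAFit: 1 in %.1f (95%% CI %.1f-%.1f), %d wells\n",
                x$N, x$ci_low, x$ci_high, x$n_wells))
  }
  invisible(x)
}

#' Likelihood-ratio comparison of sphere-forming frequencies between groups
#'
#' Deviance difference between the pooled single-frequency fit and the
#' per-group fits, referred to chi-square with (groups - 1) degrees of
#' freedom.
#'
#' @param data Data frame with columns `dose`, `tested`, `positive`, `group`
#'   (>= 2 groups).
#' @return List with `chi_square`, `df`, `p` and `fits` (per-group
#'   `LDAFit`s).
#' @export
compare_groups <- function(data) {
  validate_lda_data(data)
  stopifnot("group" %in% names(data))
  groups <- unique(data$group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  fits <- lapply(stats::setNames(groups, groups), function(g) {
    d <- data[data$group == g, , drop = FALSE]
    tryCatch(fit_single_hit(d),
             error = function(e) stop("group '", g, "' is unfittable: ",
                                      conditionMessage(e)))
  })
  ll_sep <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  pooled <- fit_single_hit(data[, c("dose", "tested", "positive")])
  chi <- 2 * (ll_sep - pooled$loglik)
  chi <- max(chi, 0)
  df <- length(groups) - 1L
  list(chi_square = chi, df = df,
       p = stats::pchisq(chi, df = df, lower.tail = FALSE),
       fits = fits)
}
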