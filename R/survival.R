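# Expression-percentile survival stratification: the cohort is split into
# the top and bottom expression fractions for a marker gene (30%/30% by
# default), compared by Kaplan-Meier curves and the log-rank test. The
# product-limit and log-rank computations are delegated to the survival
# package; this module owns the stratification rule and the interfaces.

validate_survival_records <- function(records) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("event flags must be 0 or 1")
  invisible(records)
}

#' Stratify samples by a gene's expression percentiles
#'
#' Samples are sorted by decreasing expression (ties broken by sample id);
#' the first floor(high_fraction * n) are labeled "high", the last
#' floor(low_fraction * n) "low", and the middle "excluded". The floor
#' convention and the id tie-break make the split deterministic.
#'
#' @param expr Named numeric vector: marker expression per sample.
#' @param high_fraction,low_fraction Fractions assigned to the tails
#'   (defaults 0.30/0.30); must sum to at most 1.
#' @return Named character vector in \{"high", "low", "excluded"\}.
#' @export
stratify_by_expression <- function(expr, high_fraction = 0.30,
                                   low_fraction = 0.30) {
  if (high_fraction + low_fraction > 1) {
    stop("high_fraction + low_fraction must not exceed 1")
  }
  n <- length(expr)
  if (n < 4L) stop("need at least 4 samples")
  ids <- names(expr)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ord <- order(-expr, ids, method = "radix")
  nh <- floor(high_fraction * n)
  nl <- floor(low_fraction * n)
  grp <- rep("excluded", n)
  if (nh > 0L) grp[ord[seq_len(nh)]] <- "high"
  if (nl > 0L) grp[ord[seq(n - nl + 1L, n)]] <- "low"
  if (nh > 0L && nl > 0L && nh + nl < n) {
    cut_hi <- expr[ord[nh]]
    cut_lo <- expr[ord[n - nl + 1L]]
    if (cut_hi == expr[ord[nh + 1L]] || cut_lo == expr[ord[n - nl]]) {
      warning("tied expression values at a percentile cut; ",
              "split resolved by sample-id order")
    }
  }
  stats::setNames(grp, ids)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; at tied times events are processed before
#' censorings (the standard convention).
#'
#' @param records Data frame with columns `sample_id`, `time`, `event`.
#' @return A `KMCurve`: list with `time` (distinct event times, ascending),
#'   `surv` (survival probabilities), `n_risk`, `n_event` and `median`.
#' @export
km_estimate <- function(records) {
  validate_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median = med),
            class = "KMCurve")
}

#' Two-group log-rank test
#'
#' Classical (unweighted) log-rank: at each distinct event time the observed
#' minus hypergeometric-expected events in one group are accumulated;
#' statistic = (sum(O - E))^2 / sum(V), p from chi-square with 1 df. No
#' tied-time continuity correction is applied.
#'
#' @param records Data frame with columns `sample_id`, `time`, `event`,
#'   `group` (exactly two levels among non-excluded samples; "excluded"
#'   labels are dropped).
#' @return List with `chi_square`, `p`, `n` (per-group sizes) and
#'   `events` (per-group observed events).
#' @export
logrank_test <- function(records) {
  validate_survival_records(records)
  records <- records[records$group != "excluded", , drop = FALSE]
  grp <- factor(records$group)
  if (nlevels(grp) != 2L) stop("log-rank test needs exactly 2 groups")
  ev <- tapply(records$event, grp, sum)
  if (any(ev == 0)) {
    warning("group '", names(ev)[ev == 0][1L], "' has no events")
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp,
                               data = records, rho = 0)
  chi <- unname(sd_fit$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = as.vector(table(grp)), events = as.vector(ev))
}

#' Marker-stratified survival analysis in one call
#'
#' Stratifies by [stratify_by_expression()], fits per-group KM curves and
#' runs the log-rank test on high vs low.
#'
#' @param expr Named marker expression vector.
#' @param records Survival data frame (`sample_id`, `time`, `event`) covering
#'   the expression samples.
#' @inheritParams stratify_by_expression
#' @return List with `groups`, per-group `km` curves and `logrank`.
#' @export
survival_by_marker <- function(expr, records, high_fraction = 0.30,
                               low_fraction = 0.30) {
  common <- intersect(names(expr), records$sample_id)
  if (length(common) < 4L) stop("fewer than 4 samples with both expression ",
                                "and survival data")
  grp <- stratify_by_expression(expr[common], high_fraction, low_fraction)
  rec <- records[match(common, records$sample_id), , drop = FALSE]
  rec$group <- grp[rec$sample_id]
  km <- lapply(c(high = "high", low = "low"), function(g) {
    km_estimate(rec[rec$group == g, , drop = FALSE])
  })
  list(groups = grp, km = km,
       logrank = logrank_test(rec))
}
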