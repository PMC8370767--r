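# Ground-truth synthetic data for pipeline validation. The expression
# generator emulates a multi-batch stem-cell collection with two latent
# transcriptional states (MES vs non-MES), TF-driven co-expression modules
# (planted regulons) and per-batch affine distortions; companion generators
# produce survival cohorts tied to a marker gene and limiting-dilution well
# counts under the single-hit model. Every generator is a pure function of
# (config, seed).

#' Generate a multi-batch expression collection with planted structure
#'
#' Half the samples (balanced within each batch) are labeled MES. Genes are
#' laid out as: `n_tfs` TF genes (the first `n_mes_tfs` of which gain an
#' additive effect `a` in MES samples), disjoint regulons of `regulon_size`
#' targets for each of the first `n_reg_tfs` TFs (each target =
#' sign * TF value + Gaussian noise), and i.i.d. background genes. Each
#' batch then receives an independent per-gene affine distortion (additive
#' shift ~ N(0, batch_shift), multiplicative scale ~ LogNormal(0, 0.25)),
#' which per-batch gene standardization removes exactly.
#'
#' @param n_genes,n_samples Total genes and samples.
#' @param n_batches Number of batches (samples split as evenly as possible).
#' @param n_tfs Number of TF genes.
#' @param n_mes_tfs Number of TFs carrying the MES effect.
#' @param n_reg_tfs Number of TFs given planted regulons (default
#'   `n_mes_tfs`; must satisfy `n_tfs + n_reg_tfs * regulon_size <=
#'   n_genes`).
#' @param regulon_size Targets per planted regulon.
#' @param effect Additive MES effect `a` on MES-TF genes.
#' @param batch_shift SD of the per-gene additive batch shift.
#' @param noise_sd SD of the target-level noise (TF and background genes use
#'   unit noise).
#' @param heavy_tails If `TRUE`, noise is drawn from a t distribution with 3
#'   degrees of freedom (scaled to the requested SD) instead of Gaussian.
#' @param seed Integer seed.
#' @return List with `datasets` (list of [expression_dataset()]s, one per
#'   batch) and `truth` (a `GroundTruth` list: `subtype`, `batch`, `tfs`,
#'   `mes_tfs`, `regulons` (TF -> data frame target/sign), `effect`,
#'   `signatures` (MES/NM gene sets for subtype classification), `seed`).
#' @export
gen_expression <- function(n_genes = 2000, n_samples = 150, n_batches = 3,
                           n_tfs = 100, n_mes_tfs = 5, n_reg_tfs = n_mes_tfs,
                           regulon_size = 40, effect = 1.0, batch_shift = 1.0,
                           noise_sd = 1.0, heavy_tails = FALSE, seed = 1) {
  stopifnot(n_mes_tfs <= n_tfs, n_reg_tfs <= n_tfs)
  if (n_tfs + n_reg_tfs * regulon_size > n_genes) {
    stop("infeasible config: n_tfs + n_reg_tfs * regulon_size exceeds n_genes")
  }
  if (n_samples < 2L * n_batches) stop("need >= 2 samples per batch")
  genes <- sprintf("g%04d", seq_len(n_genes))
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  genes[seq_len(n_tfs)] <- tfs
  samples <- sprintf("s%03d", seq_len(n_samples))
  batch <- rep_len(sprintf("batch%d", seq_len(n_batches)), n_samples)
  # alternate MES within each batch so state and batch are unconfounded
  is_mes <- logical(n_samples)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    is_mes[idx] <- seq_along(idx) %% 2L == 1L
  }

  rnoise <- function(n, sd) {
    if (heavy_tails) sd * stats::rt(n, df = 3) / sqrt(3) else
      stats::rnorm(n, sd = sd)
  }

  with_seed(seed, {
    mat <- matrix(rnoise(n_genes * n_samples, 1), n_genes, n_samples,
                  dimnames = list(genes, samples))
    # MES effect on the first n_mes_tfs TF genes
    for (i in seq_len(n_mes_tfs)) {
      mat[i, is_mes] <- mat[i, is_mes] + effect
    }
    # planted regulons: disjoint target blocks after the TF block
    regulons <- list()
    next_row <- n_tfs
    for (i in seq_len(n_reg_tfs)) {
      rows <- next_row + seq_len(regulon_size)
      next_row <- next_row + regulon_size
      signs <- sample(c(-1L, 1L), regulon_size, replace = TRUE)
      mat[rows, ] <- signs * mat[rep(i, regulon_size), ] +
        matrix(rnoise(regulon_size * n_samples, noise_sd),
               regulon_size, n_samples)
      regulons[[tfs[i]]] <- data.frame(target = genes[rows], sign = signs,
                                       stringsAsFactors = FALSE)
    }
    # per-batch per-gene affine distortion
    datasets <- lapply(unique(batch), function(b) {
      cols <- batch == b
      shift <- stats::rnorm(n_genes, sd = batch_shift)
      scale <- exp(stats::rnorm(n_genes, sd = 0.25))
      expression_dataset(mat[, cols, drop = FALSE] * scale + shift,
                         batch_id = b, platform = "synthetic")
    })
    # subtype signatures: MES = positively driven planted genes; NM = a
    # size-matched draw from the background
    mes_sig <- unique(c(tfs[seq_len(n_mes_tfs)],
                        unlist(lapply(regulons[seq_len(min(n_mes_tfs,
                                                           length(regulons)))],
                                      function(r) r$target[r$sign > 0]))))
    background <- setdiff(genes, c(tfs, unlist(lapply(regulons,
                                                      function(r) r$target))))
    nm_sig <- sample(background, min(length(mes_sig), length(background)))
    truth <- list(subtype = stats::setNames(ifelse(is_mes, "MES", "NM"),
                                            samples),
                  batch = stats::setNames(batch, samples),
                  tfs = tfs, mes_tfs = tfs[seq_len(n_mes_tfs)],
                  regulons = regulons, effect = effect,
                  signatures = list(MES = mes_sig, NM = sort(nm_sig)),
                  seed = seed)
    list(datasets = datasets, truth = truth)
  })
}

#' Generate a survival cohort tied to a marker gene
#'
#' Marker values are standard normal; samples at or above the marker median
#' form the high group, whose event hazard is multiplied by `hazard_ratio`.
#' Event and censoring times are independent exponentials.
#'
#' @param n Cohort size.
#' @param hazard_ratio Hazard multiplier for marker-high samples (> 0).
#' @param censor_rate Hazard of the independent exponential censoring
#'   process (0 = no censoring; all events observed).
#' @param base_hazard Baseline event hazard (default 1/500 per day).
#' @param seed Integer seed.
#' @return List with `records` (data frame sample_id, time, event) and
#'   `marker` (named expression vector).
#' @export
gen_survival <- function(n = 200, hazard_ratio = 2, censor_rate = 0,
                         base_hazard = 1 / 500, seed = 1) {
  stopifnot(hazard_ratio > 0)
  with_seed(seed, {
    ids <- sprintf("p%04d", seq_len(n))
    marker <- stats::setNames(stats::rnorm(n), ids)
    high <- marker >= stats::median(marker)
    hz <- base_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = hz)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n, rate = censor_rate)
      records <- data.frame(sample_id = ids,
                            time = pmin(t_event, t_cens),
                            event = as.integer(t_event <= t_cens),
                            stringsAsFactors = FALSE)
    } else {
      records <- data.frame(sample_id = ids, time = t_event,
                            event = 1L, stringsAsFactors = FALSE)
    }
    list(records = records, marker = marker)
  })
}

#' Generate limiting-dilution well counts under the single-hit model
#'
#' @param doses Cells plated per well at each dilution.
#' @param wells_per_dose Wells plated at each dose (recycled).
#' @param true_N Named vector of per-group true frequencies on the "1 in N"
#'   scale; `Inf` (capped internally) yields all-negative wells.
#' @param seed Integer seed.
#' @return Data frame with columns dose, tested, positive, group.
#' @export
gen_lda <- function(doses = c(100, 50, 25, 10, 5, 1), wells_per_dose = 16,
                    true_N = c(ctrl = 3), seed = 1) {
  stopifnot(all(true_N > 0))
  wells <- rep_len(wells_per_dose, length(doses))
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(true_N), function(g) {
      f <- 1 / min(true_N[[g]], 1e12)
      data.frame(dose = doses, tested = wells,
                 positive = stats::rbinom(length(doses), wells,
                                          -expm1(-doses * f)),
                 group = g, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
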