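# Multi-platform harmonization: probe collapse, common-gene intersection and
# per-batch gene standardization, producing the single matrix on which the
# subtype, differential-expression and network stages operate.

#' Construct an expression dataset
#'
#' The raw unit of the pipeline: one platform/batch gene-by-sample (or
#' probe-by-sample) matrix with identifying metadata.
#'
#' @param matrix Numeric matrix, rows = probes or genes, columns = samples.
#'   Row and column names are required.
#' @param batch_id Character scalar identifying the batch/dataset.
#' @param platform Free-text platform description.
#' @param impute If `TRUE`, missing entries are replaced by the per-row median
#'   within the dataset; by default missing values are rejected.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(matrix, batch_id, platform = "unknown",
                               impute = FALSE) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  if (ncol(matrix) < 2L) {
    stop("a dataset needs at least 2 samples (batch '", batch_id, "')")
  }
  if (anyDuplicated(colnames(matrix))) {
    stop("duplicated sample ids within batch '", batch_id, "'")
  }
  if (anyNA(matrix)) {
    if (!impute) {
      stop("missing values in batch '", batch_id,
           "'; set impute = TRUE to use per-row median imputation")
    }
    for (i in which(rowSums(is.na(matrix)) > 0L)) {
      row <- matrix[i, ]
      row[is.na(row)] <- stats::median(row, na.rm = TRUE)
      matrix[i, ] <- row
    }
  }
  structure(
    list(matrix = matrix, row_ids = rownames(matrix),
         sample_ids = colnames(matrix), batch_id = as.character(batch_id),
         platform = as.character(platform)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset '", x$batch_id, "' (", x$platform, "): ",
      nrow(x$matrix), " rows x ", ncol(x$matrix), " samples\n", sep = "")
  invisible(x)
}

#' Collapse probe-level rows to gene level by the per-sample median
#'
#' Probes without a mapping are dropped; each gene's expression in a sample is
#' the median over that gene's probes (even probe counts use the mean of the
#' two middle values, the usual median convention).
#'
#' @param dataset An [expression_dataset()].
#' @param probe_map Data frame with columns `probe` and `gene`
#'   (see [read_probe_map()]).
#' @return An `ExpressionDataset` with one row per gene.
#' @export
collapse_probes <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (nrow(probe_map) == 0L) stop("empty probe map")
  if (anyDuplicated(probe_map$probe)) {
    stop("probe map assigns some probes to more than one gene")
  }
  keep <- dataset$row_ids %in% probe_map$probe
  if (!any(keep)) stop("no probes in the dataset are covered by the map")
  m <- dataset$matrix[keep, , drop = FALSE]
  genes <- probe_map$gene[match(rownames(m), probe_map$probe)]
  gene_levels <- sort(unique(genes))
  collapsed <- matrix(NA_real_, length(gene_levels), ncol(m),
                      dimnames = list(gene_levels, colnames(m)))
  idx <- split(seq_len(nrow(m)), factor(genes, levels = gene_levels))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    collapsed[g, ] <- if (length(rows) == 1L) {
      m[rows, ]
    } else {
      apply(m[rows, , drop = FALSE], 2L, stats::median)
    }
  }
  stopifnot(!anyDuplicated(rownames(collapsed)))
  expression_dataset(collapsed, dataset$batch_id, dataset$platform)
}

#' Intersect the gene sets of several datasets
#'
#' @param datasets List of gene-level `ExpressionDataset`s.
#' @return Sorted character vector of genes present in every dataset.
#' @export
intersect_genes <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least 2 datasets to intersect")
  sets <- lapply(datasets, function(d) d$row_ids)
  common <- sets[[1L]]
  for (i in 2:length(sets)) {
    common <- intersect(common, sets[[i]])
    if (length(common) == 0L) {
      stop("empty gene intersection between datasets 1..", i - 1L, " and ", i)
    }
  }
  sort(common)
}

#' Standardize datasets per gene within batch and assemble one matrix
#'
#' Each dataset is restricted to the common gene list, every gene row is
#' z-scored across that dataset's samples (mean 0, population SD 1, divisor
#' n), and the standardized blocks are concatenated column-wise. Genes with
#' zero variance in any dataset are removed from all datasets and reported,
#' since their standardized values are undefined and they would produce
#' degenerate dependence estimates downstream.
#'
#' @param datasets List of gene-level `ExpressionDataset`s.
#' @param genes Common gene list, typically from [intersect_genes()].
#' @return A `HarmonizedMatrix`: list with `matrix` (genes x all samples),
#'   `gene_ids`, `sample_ids`, `batch_labels` (one batch id per sample) and
#'   `removed_genes`.
#' @export
scale_and_assemble <- function(datasets, genes = NULL) {
  if (is.null(genes)) {
    genes <- if (length(datasets) == 1L) sort(datasets[[1L]]$row_ids)
             else intersect_genes(datasets)
  }
  all_samples <- unlist(lapply(datasets, function(d) d$sample_ids))
  if (anyDuplicated(all_samples)) {
    stop("sample ids are not unique across datasets")
  }
  for (d in datasets) {
    if (ncol(d$matrix) < 2L) stop("batch '", d$batch_id, "' has fewer than 2 ",
                                  "samples; SD undefined")
    if (!all(genes %in% d$row_ids)) {
      stop("batch '", d$batch_id, "' is missing some of the requested genes")
    }
  }
  blocks <- lapply(datasets, function(d) d$matrix[genes, , drop = FALSE])
  # population SD (divisor n); flag genes constant within any batch
  zero_var <- Reduce(`|`, lapply(blocks, function(b) {
    apply(b, 1L, stats::sd) == 0
  }))
  removed <- genes[zero_var]
  keep <- genes[!zero_var]
  if (length(keep) == 0L) stop("all common genes are constant in some batch")
  scaled <- lapply(blocks, function(b) {
    b <- b[keep, , drop = FALSE]
    n <- ncol(b)
    mu <- rowMeans(b)
    sdp <- sqrt(rowSums((b - mu)^2) / n)
    (b - mu) / sdp
  })
  out <- do.call(cbind, scaled)
  structure(
    list(matrix = out, gene_ids = keep, sample_ids = colnames(out),
         batch_labels = rep(vapply(datasets, function(d) d$batch_id,
                                   character(1)),
                            vapply(datasets, function(d) ncol(d$matrix),
                                   integer(1))),
         removed_genes = removed),
    class = "HarmonizedMatrix"
  )
}

#' @export
print.HarmonizedMatrix <- function(x, ...) {
  cat("HarmonizedMatrix: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples in ", length(unique(x$batch_labels)), " batches (",
      length(x$removed_genes), " zero-variance genes removed)\n", sep = "")
  invisible(x)
}

#' Split a harmonized matrix back into per-batch datasets
#'
#' Convenience inverse used to check idempotence of standardization and to
#' rerun stages on a subset of batches.
#'
#' @param hm A `HarmonizedMatrix`.
#' @return List of `ExpressionDataset`s, one per batch.
#' @export
split_batches <- function(hm, platform = "harmonized") {
  lapply(unique(hm$batch_labels), function(b) {
    expression_dataset(hm$matrix[, hm$batch_labels == b, drop = FALSE],
                       batch_id = b, platform = platform)
  })
}

#' Harmonize a collection of datasets end to end
#'
#' Optionally collapses probes, intersects genes and standardizes per batch.
#'
#' @param datasets List of `ExpressionDataset`s.
#' @param probe_maps Optional list (parallel to `datasets`, or a single data
#'   frame applied to all) of probe maps; datasets whose entry is `NULL` are
#'   assumed to be gene-level already.
#' @return A `HarmonizedMatrix`.
#' @export
harmonize <- function(datasets, probe_maps = NULL) {
  if (!is.null(probe_maps)) {
    if (is.data.frame(probe_maps)) probe_maps <- rep(list(probe_maps),
                                                     length(datasets))
    datasets <- lapply(seq_along(datasets), function(i) {
      if (is.null(probe_maps[[i]])) datasets[[i]]
      else collapse_probes(datasets[[i]], probe_maps[[i]])
    })
  }
  scale_and_assemble(datasets)
}
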