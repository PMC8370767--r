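# End-to-end orchestration: harmonize -> subtype -> diffexp -> netinfer ->
# mra, with optional survival and limiting-dilution stages. A single global
# seed deterministically derives per-stage seeds (stage-name hashing), so any
# stage can be rerun in isolation, and rerunning the whole pipeline with the
# same config and seed reproduces every output byte for byte.

#' Validate a pipeline configuration
#'
#' The configuration is a plain named list (or a YAML file with the same
#' structure): `seed`, `outdir`, an input block (`simulate` with
#' [gen_expression()] arguments, or `datasets` with per-file paths), optional
#' `tf_list`, `signatures`, `clinical`, `lda` paths, and a `params` block
#' (`weight_exponent`, `n_perm`, `alpha`, `dpi_tolerance`, `q_threshold`,
#' `top_n`, `high_fraction`, `low_fraction`, `mra_alpha`, `group_source`).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  p <- config$params %||% list()
  defaults <- list(weight_exponent = 0.25, n_perm = 1000, alpha = 0.05,
                   dpi_tolerance = 0, q_threshold = 0.05, top_n = 100,
                   high_fraction = 0.30, low_fraction = 0.30,
                   mra_alpha = 1e-4, group_source = "classify",
                   mra_gsea = TRUE)
  for (nm in names(defaults)) p[[nm]] <- p[[nm]] %||% defaults[[nm]]
  if (p$n_perm < 100) stop("params$n_perm must be >= 100")
  if (p$alpha <= 0 || p$alpha > 1) stop("params$alpha must be in (0, 1]")
  if (p$high_fraction + p$low_fraction > 1) {
    stop("params$high_fraction + params$low_fraction must not exceed 1")
  }
  if (!p$group_source %in% c("classify", "truth", "file")) {
    stop("params$group_source must be 'classify', 'truth' or 'file'")
  }
  config$params <- p
  if (is.null(config$simulate)) {
    if (is.null(config$datasets)) {
      stop("config needs either a 'simulate' block or 'datasets'")
    }
    for (d in config$datasets) {
      if (!file.exists(d$path)) stop("missing input file: ", d$path)
    }
    for (f in c("tf_list", "signatures", "clinical", "lda", "probe_map",
                "groups_file")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
        stop("missing input file: ", config[[f]])
      }
    }
  }
  config
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% stage_seed(config$seed, "simulate")
    sim <- do.call(gen_expression, sim_args)
    list(datasets = sim$datasets, truth = sim$truth,
         tfs = sim$truth$tfs, signatures = sim$truth$signatures)
  } else {
    datasets <- lapply(config$datasets, function(d) {
      expression_dataset(read_matrix_tsv(d$path), batch_id = d$batch_id,
                         platform = d$platform %||% "unknown")
    })
    if (!is.null(config$probe_map)) {
      pm <- read_probe_map(config$probe_map)
      datasets <- lapply(datasets, function(ds) {
        if (any(ds$row_ids %in% pm$probe)) collapse_probes(ds, pm) else ds
      })
    }
    list(datasets = datasets, truth = NULL,
         tfs = if (!is.null(config$tf_list)) {
           readLines(config$tf_list, warn = FALSE)
         },
         signatures = if (!is.null(config$signatures)) {
           read_gmt(config$signatures)
         })
  }
}

#' Run the master-regulator pipeline end to end
#'
#' Executes harmonize -> subtype -> diffexp -> netinfer -> mra (plus
#' survival and limiting-dilution stages when their inputs are present),
#' writes every stage's outputs under `outdir` and returns a run manifest.
#' On a stage failure the manifest is written with a FAILED marker naming the
#' stage, and partial outputs are retained.
#'
#' @param config Named list or YAML path (see [validate_config()]).
#' @return The run manifest (invisibly written to `outdir/manifest.json`):
#'   parameters, seed, input checksums, stage status and timings, and the
#'   key results (top master regulators, concordance, counts).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  manifest <- list(seed = config$seed, params = p, stages = list())
  if (!is.null(config$datasets)) {
    manifest$input_checksums <- lapply(config$datasets, function(d) {
      list(path = d$path, md5 = unname(tools::md5sum(d$path)))
    })
  }
  ok <- TRUE
  timed_stage <- function(name, fun) {
    if (!ok) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      ok <<- FALSE
      manifest$stages[[name]] <<- list(status = "FAILED",
                                       error = conditionMessage(res),
                                       seconds = elapsed)
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "completed",
                                       seconds = elapsed)
      res
    }
  }

  inputs <- timed_stage("load", function() load_pipeline_inputs(config))

  hm <- timed_stage("harmonize", function() {
    hm <- harmonize(inputs$datasets)
    write_matrix_tsv(hm$matrix, file.path(config$outdir, "harmonized.tsv"),
                     id_col = "gene")
    write_json_file(list(batch_labels = as.list(stats::setNames(
                           hm$batch_labels, hm$sample_ids)),
                         removed_genes = hm$removed_genes,
                         n_genes = length(hm$gene_ids),
                         n_samples = length(hm$sample_ids)),
                    file.path(config$outdir, "harmonized.json"))
    hm
  })

  calls <- timed_stage("subtype", function() {
    if (is.null(inputs$signatures)) return(NULL)
    calls <- classify_samples(hm, inputs$signatures, n_perm = p$n_perm,
                              weight_exponent = p$weight_exponent,
                              seed = stage_seed(config$seed, "subtype"))
    utils::write.table(calls, file.path(config$outdir, "subtype_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  de <- timed_stage("diffexp", function() {
    group <- switch(p$group_source,
      classify = {
        if (is.null(calls)) stop("no subtype calls to derive groups from")
        ifelse(calls$label[match(hm$sample_ids, calls$sample_id)] == "MES",
               "MES", "nonMES")
      },
      truth = {
        if (is.null(inputs$truth)) stop("group_source 'truth' needs simulate")
        ifelse(inputs$truth$subtype[hm$sample_ids] == "MES", "MES", "nonMES")
      },
      file = {
        g <- utils::read.delim(config$groups_file, stringsAsFactors = FALSE)
        ifelse(g[[2L]][match(hm$sample_ids, g[[1L]])] == "MES",
               "MES", "nonMES")
      })
    de <- diffexp(hm$matrix, group, hm$batch_labels, ref = "nonMES")
    utils::write.table(de[, c("gene", "effect", "t_mod", "p", "q")],
                       file.path(config$outdir, "diffexp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de
  })

  sig <- timed_stage("signature", function() {
    sig <- make_signature(de, q_threshold = p$q_threshold, top_n = p$top_n)
    write_gmt(list(up = sig$up, down = sig$down, top = sig$top),
              file.path(config$outdir, "signature.gmt"))
    sig
  })

  net <- timed_stage("netinfer", function() {
    tfs <- inputs$tfs %||% stop("no TF list available")
    net <- infer_network(hm$matrix, tfs, n_perm = p$n_perm, alpha = p$alpha,
                         tolerance = p$dpi_tolerance,
                         seed = stage_seed(config$seed, "netinfer"))
    utils::write.table(net$edges, file.path(config$outdir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    regulons_to_gmt(net, file.path(config$outdir, "regulons.gmt"))
    net
  })

  mr <- timed_stage("mra", function() {
    signature_genes <- union(sig$up, sig$down)
    stats_vec <- if (isTRUE(p$mra_gsea)) stats::setNames(de$t_mod, de$gene)
    mr <- run_mra(net, signature_genes, universe = hm$gene_ids,
                  ranked_stats = stats_vec, n_perm = p$n_perm,
                  seed = stage_seed(config$seed, "mra"))
    ranked <- rank_mrs(mr, alpha = p$mra_alpha)
    utils::write.table(ranked$ranked, file.path(config$outdir, "mra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(ranked$ranked$tf, file.path(config$outdir, "mra_ranked.txt"))
    ranked
  })

  if (!is.null(config$clinical) && ok) {
    timed_stage("survival", function() {
      clin <- read_clinical(config$clinical)
      marker <- config$marker_gene %||% mr$ranked$tf[1L]
      sv <- survival_by_marker(
        stats::setNames(hm$matrix[marker, ], hm$sample_ids), clin,
        high_fraction = p$high_fraction, low_fraction = p$low_fraction)
      write_json_file(list(marker = marker, logrank = sv$logrank),
                      file.path(config$outdir, "survival.json"))
      utils::write.table(
        data.frame(sample_id = names(sv$groups), group = sv$groups,
                   row.names = NULL),
        file.path(config$outdir, "survival_groups.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      km_df <- do.call(rbind, lapply(names(sv$km), function(g) {
        data.frame(group = g, time = sv$km[[g]]$time,
                   surv = sv$km[[g]]$surv, n_risk = sv$km[[g]]$n_risk)
      }))
      utils::write.table(km_df, file.path(config$outdir, "km_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sv
    })
  }

  if (!is.null(config$lda) && ok) {
    timed_stage("elda", function() {
      lda <- read_lda_table(config$lda)
      cmp <- compare_groups(lda)
      write_json_file(
        list(groups = lapply(cmp$fits, function(f) {
               list(frequency = f$frequency, N = f$N, ci_low = f$ci_low,
                    ci_high = f$ci_high, boundary = f$boundary)
             }),
             chi_square = cmp$chi_square, df = cmp$df, p = cmp$p),
        file.path(config$outdir, "elda.json"))
      cmp
    })
  }

  manifest$status <- if (ok) "completed" else "FAILED"
  write_json_file(manifest, file.path(config$outdir, "manifest.json"))
  if (!ok) {
    failed <- names(manifest$stages)[vapply(manifest$stages, function(s) {
      s$status == "FAILED"
    }, logical(1))]
    stop("pipeline failed at stage '", failed[1L], "': ",
         manifest$stages[[failed[1L]]]$error)
  }
  invisible(list(manifest = manifest, harmonized = hm, calls = calls,
                 diffexp = de, signature = sig, network = net, mra = mr,
                 truth = inputs$truth))
}
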