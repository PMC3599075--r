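# End-to-end orchestration: simulate (or load) -> QC -> normalize ->
# detect -> concordance -> GSEA -> clustering -> qPCR, with deterministic
# per-stage seeding and a manifest.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with the conventional defaults:
#' detection threshold 300 (linear sample-channel signal), normexp offset
#' 50, loess span 0.30, 10,000 random gene pairs, top 1,000 variable
#' genes, and a 46-cycle qPCR limit.
#'
#' @param sim a [sim_config()], or NULL when reading from files.
#' @param signal_path,meta_path input TSVs (used when `sim` is NULL).
#' @param gmt_path optional GMT file of gene sets for the GSEA stage.
#' @param qc_alpha Dixon significance level for all QC scans.
#' @param offset,span normalization parameters.
#' @param detection_threshold detection cutoff in signal units.
#' @param n_pairs random-pair count for the difference-of-M statistic.
#' @param n_top_genes variable-gene count for clustering.
#' @param gsea_n_perm,gsea_p GSEA permutation count and weight exponent.
#' @param run_qpcr simulate and analyze a qPCR validation plate (only
#'   when `sim` is given).
#' @param seed global seed; per-stage seeds are derived from it by a
#'   fixed offset so stages are individually reproducible.
#' @return a `RunConfig` list.
#' @export
run_config <- function(sim = NULL, signal_path = NULL, meta_path = NULL,
                       gmt_path = NULL, qc_alpha = 0.05,
                       offset = 50, span = 0.30,
                       detection_threshold = 300, n_pairs = 10000,
                       n_top_genes = 1000, gsea_n_perm = 1000, gsea_p = 1,
                       run_qpcr = !is.null(sim), seed = 1L) {
  if (is.null(sim) && (is.null(signal_path) || is.null(meta_path)))
    stop("run_config: provide either a SimConfig or signal/meta paths",
         call. = FALSE)
  structure(list(sim = sim, signal_path = signal_path, meta_path = meta_path,
                 gmt_path = gmt_path, qc_alpha = qc_alpha, offset = offset,
                 span = span, detection_threshold = detection_threshold,
                 n_pairs = n_pairs, n_top_genes = n_top_genes,
                 gsea_n_perm = gsea_n_perm, gsea_p = gsea_p,
                 run_qpcr = run_qpcr, seed = as.integer(seed)),
            class = "RunConfig")
}

# fixed fan-out of the global seed into per-stage seeds (kept < 2^31)
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, qc = 202L, pairs = 303L, gsea = 404L,
            qpcr = 505L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> array-distribution QC -> normalization ->
#' per-group detection -> pairwise concordance (smaller cell count scored
#' against the larger as gold standard) with M-ratio statistics -> GSEA
#' (when gene sets are given) -> top-variable-gene clustering -> qPCR
#' summaries (simulated runs), writing every report as TSV/JSON into
#' `out_dir` together with a manifest recording the seed and the
#' serialized configuration.  Stages whose inputs are absent are skipped;
#' a failing stage aborts with its name.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # config snapshot + hash (serialized verbatim into the run directory)
  cfg_path <- file.path(out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)
  if (!is.null(cfg_ser$sim$days)) cfg_ser$sim$days <- "custom-function"
  .write_json(cfg_ser, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  es <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- .stage_seed(config$seed, "simulate")
      simulate_experiment(sim)
    } else {
      read_experiment(config$signal_path, config$meta_path)
    }
  })

  qc_rep <- stage("qc", {
    rep <- flag_outlier_samples(array_distribution_metrics(es),
                                alpha = config$qc_alpha,
                                seed = .stage_seed(config$seed, "qc"))
    excl <- rep$exclusions
    bad <- excl$sample_id[excl$excluded]
    if (length(bad)) {
      i <- match(bad, es$samples$sample_id)
      es$samples$qc_excluded[i] <- TRUE
      es$samples$qc_reason[i] <- excl$reason[match(bad, excl$sample_id)]
    }
    utils::write.table(rep$metrics, file.path(out_dir, "qc_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(excl, file.path(out_dir, "qc_exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  ns <- stage("normalize", {
    ns <- run_preprocess(es, offset = config$offset, span = config$span)
    write_matrix_tsv(ns$af3, file.path(out_dir, "normalized_af3.tsv"))
    write_matrix_tsv(ns$M, file.path(out_dir, "m_ratio.tsv"))
    .write_json(ns$provenance, file.path(out_dir, "provenance.json"))
    ns
  })

  groups <- unique(ns$samples$group[!ns$samples$qc_excluded])
  detections <- stage("detect", {
    d <- lapply(groups, function(g)
      call_detection(ns, g, threshold = config$detection_threshold))
    names(d) <- groups
    counts <- data.frame(group = groups,
                         n_detected = vapply(d, function(x) sum(x$detected), 0L),
                         universe = vapply(d, function(x) length(x$detected), 0L))
    utils::write.table(counts, file.path(out_dir, "detection_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })

  concord <- stage("concord", {
    num <- suppressWarnings(as.numeric(groups))
    reports <- list()
    if (!anyNA(num) && length(groups) >= 2) {
      ord <- groups[order(num)]
      pairs <- utils::combn(ord, 2, simplify = FALSE)
      for (pr in pairs) {
        test <- detections[[pr[1]]]; gold <- detections[[pr[2]]]
        rep <- sensitivity_specificity(test, gold)
        prof <- m_ratio_profile(ns, detections[pr])
        if (nrow(prof) >= 3) {
          rep$pearson <- m_ratio_correlations(prof, "pearson")
          rep$spearman <- m_ratio_correlations(prof, "spearman")
          np <- min(config$n_pairs, choose(nrow(prof), 2))
          rp <- random_pair_difference_correlation(
            prof, n_pairs = np, seed = .stage_seed(config$seed, "pairs"))
          rep$pair_diff_pearson <- rp$coefficient
          rep$n_pairs <- np
        }
        reports[[paste(pr, collapse = "_vs_")]] <- rep
      }
    }
    if (length(reports)) {
      flat <- lapply(reports, function(r) {
        list(test_group = r$test_group, gold_group = r$gold_group,
             counts = as.list(r$counts), sensitivity = r$sensitivity,
             sensitivity_ci = as.list(r$sensitivity_ci),
             specificity = r$specificity,
             specificity_ci = as.list(r$specificity_ci),
             m_ratio_pearson = r$pearson, m_ratio_spearman = r$spearman,
             pair_diff_pearson = r$pair_diff_pearson, n_pairs = r$n_pairs)
      })
      .write_json(flat, file.path(out_dir, "concordance.json"))
    }
    reports
  })

  gsea_res <- NULL
  if (!is.null(config$gmt_path)) {
    gsea_res <- stage("gsea", {
      sets <- read_gmt(config$gmt_path)
      res <- lapply(groups, function(g)
        nes_and_fdr(build_ranked_list(ns, g), sets,
                    n_perm = config$gsea_n_perm, p = config$gsea_p,
                    seed = .stage_seed(config$seed, "gsea")))
      names(res) <- groups
      for (g in groups)
        utils::write.table(res[[g]],
                           file.path(out_dir, sprintf("gsea_%s.tsv", g)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  cluster <- NULL
  if (sum(!ns$samples$qc_excluded) >= 2) {
    cluster <- stage("cluster", {
      cl <- cluster_top_variable(ns, n_genes = config$n_top_genes)
      write_cluster_newick(cl, file.path(out_dir, "cluster_tree.nwk"))
      cl
    })
  }

  qpcr_res <- NULL
  if (isTRUE(config$run_qpcr) && !is.null(config$sim)) {
    qpcr_res <- stage("qpcr", {
      genes <- c("AR", "EPCAM", "KLK3", "TMPRSS2", "FKBP5", "ACPP",
                 "ACTB", "RPL13A", "YWHAZ", "GAPDH")
      plate <- simulate_qpcr(config$sim, genes,
                             seed = .stage_seed(config$seed, "qpcr"))
      calls <- summarize_plate(plate)
      utils::write.table(calls, file.path(out_dir, "qpcr_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts <- detection_count_table(calls, genes)
      utils::write.table(data.frame(gene = rownames(counts), counts,
                                    check.names = FALSE),
                         file.path(out_dir, "qpcr_detection_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(plate = plate, calls = calls, counts = counts,
           failed = flag_failed_samples(calls, alpha = config$qc_alpha))
    })
  }

  manifest <- list(package = "scarray",
                   version = as.character(utils::packageVersion("scarray")),
                   seed = config$seed, config_hash = cfg_hash,
                   stages = c("input", "qc", "normalize", "detect", "concord",
                              if (!is.null(gsea_res)) "gsea",
                              if (!is.null(cluster)) "cluster",
                              if (!is.null(qpcr_res)) "qpcr"))
  if (!is.null(es$truth)) {
    manifest$truth_recovery <- lapply(detections, function(d) {
      tr <- truth_sens_spec(d, es$truth)
      list(group = d$group, sensitivity = tr[["sensitivity"]],
           specificity = tr[["specificity"]])
    })
  }
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(experiment = es, qc = qc_rep, normalized = ns,
                 detections = detections, concordance = concord,
                 gsea = gsea_res, cluster = cluster, qpcr = qpcr_res,
                 manifest = manifest))
}

#' Detection sensitivity/specificity against simulation truth
#'
#' Scores a group's detection calls against the simulated ground truth:
#' a probe is truth-positive when it was truly expressed for that group
#' and captured in at least one of the group's arrays.
#'
#' @param detection `DetectionProfile`.
#' @param truth the `truth` element of a simulated ExperimentSet.
#' @return named vector `sensitivity`, `specificity`.
#' @export
truth_sens_spec <- function(detection, truth) {
  probes <- names(detection$detected)
  grp <- detection$group
  cols <- grep(sprintf("^c%s_", grp), colnames(truth$captured))
  pos <- truth$expressed[probes, grp] &
    rowSums(truth$captured[probes, cols, drop = FALSE]) > 0
  det <- detection$detected
  c(sensitivity = sum(det & pos) / max(sum(pos), 1),
    specificity = sum(!det & !pos) / max(sum(!pos), 1))
}
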