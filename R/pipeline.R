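# End-to-end orchestration: validated YAML/list configs, staged runs with
# a checksummed output manifest, fully deterministic under one seed.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "quantify", "topics", "diff"),
    simulate = list(n_region = 400L, n_type = 3L, n_cell_per_type = 60L,
                    depth_median = 3000, depth_sigma = 0.5,
                    frac_dynamic = 0.1, fold_spec = c(1, 2, 0.5),
                    n_plate = 1L, batch_sd = 0),
    quantify = list(min_cuts = 100, bin_cutoff = NULL, bin_width = 50000,
                    tss_halfwidth = 5000),
    topics = list(K = NULL, n_iter = 200L, n_avg = 50L),
    diff = list(mark = "H3K4me1", reference = NULL,
                q_thresholds = as.list(default_q_thresholds())),
    motifs = list(n_motif = 20L, n_active = 3L, z_threshold = 0.7),
    velocity = list(knn_k = 10L, delta = 0.01, spline_df = 6L)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Unknown keys are rejected by
#' name; omitted blocks and fields receive defaults (50 kb bins, 5 kb TSS
#' half-width, q thresholds 1e-50 for the active marks and H3K27me3 and
#' 1e-9 for H3K9me3, motif z threshold 0.7, k = 10 marker-imputation
#' neighbours, velocity look-ahead 0.01).
#'
#' @param cfg Path to a YAML config or a list.
#' @return Normalised `pipeline_config` list with every default filled.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop_config("config must be a list or a YAML path")
  defaults <- pipeline_defaults()
  top_known <- c(names(defaults), "output_dir")
  unknown <- setdiff(names(cfg), top_known)
  if (length(unknown)) {
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$output_dir)) stop_config("missing required key: output_dir")
  out <- defaults
  out$output_dir <- cfg$output_dir
  for (key in setdiff(names(cfg), "output_dir")) {
    if (is.list(defaults[[key]])) {
      bad <- setdiff(names(cfg[[key]]), names(defaults[[key]]))
      if (length(bad)) {
        stop_config("unknown key(s) in '%s': %s", key, paste(bad, collapse = ", "))
      }
      out[[key]] <- utils::modifyList(defaults[[key]], cfg[[key]])
    } else {
      out[[key]] <- cfg[[key]]
    }
  }
  bad_stage <- setdiff(out$stages, c("simulate", "quantify", "topics", "diff",
                                     "motifs"))
  if (length(bad_stage)) {
    stop_config("unknown stage(s): %s", paste(bad_stage, collapse = ", "))
  }
  out$seed <- as.integer(out$seed)
  structure(out, class = "pipeline_config")
}

log_line <- function(con, stage, msg, ...) {
  rec <- list(stage = stage, message = msg, ...)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the pipeline end to end from a configuration
#'
#' Executes the enabled stages in dependency order — synthetic data
#' generation, quantification/QC, topic modelling, differential testing
#' and (optionally) motif activity inference — writing every artifact
#' under `output_dir` in standard formats plus a JSON manifest with an
#' md5 checksum per file. Two runs from one config are bit-identical.
#'
#' @param cfg A config accepted by [validate_config()].
#' @return Invisibly, the manifest (data.frame file, md5).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$output_dir, "run.log.jsonl"), open = "wt")
  on.exit(close(logf))
  stages <- cfg$stages
  state <- list()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop_config("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_cfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      truth <- simulate_profiles(sim_cfg)
      cells <- simulate_cells(truth, sim_cfg)
      state$sim_cfg <<- sim_cfg; state$truth <<- truth; state$cells <<- cells
      write_counts(cells$counts, file.path(cfg$output_dir, "counts"))
      write_tsv(data.frame(cell = names(cells$cell_labels),
                           celltype = cells$cell_labels,
                           plate = cells$plate, depth = cells$depth),
                file.path(cfg$output_dir, "cell_metadata.tsv"))
      write_tsv(data.frame(region = colnames(truth$type_profiles),
                           dynamic = truth$dynamic_mask),
                file.path(cfg$output_dir, "truth_dynamic.tsv"))
      yaml::write_yaml(unclass(sim_cfg),
                       file.path(cfg$output_dir, "sim_config.yaml"))
      log_line(logf, "simulate", "done", n_cell = ncol(cells$counts),
               n_region = nrow(cells$counts), seed = cfg$seed)
    })
  }
  if ("quantify" %in% stages) {
    run_stage("quantify", function() {
      counts <- state$cells$counts %||%
        read_counts(file.path(cfg$output_dir, "counts"))
      filt <- filter_cells(counts, min_cuts = cfg$quantify$min_cuts)
      mask <- suppressWarnings(
        bins_above_background(filt$counts,
                              manual_cutoff = cfg$quantify$bin_cutoff))
      state$counts <<- filt$counts[mask, , drop = FALSE]
      write_tsv(filt$qc, file.path(cfg$output_dir, "qc_report.tsv"))
      write_counts(state$counts, file.path(cfg$output_dir, "counts_filtered"))
      log_line(logf, "quantify", "done", cells_kept = ncol(state$counts),
               bins_kept = nrow(state$counts))
    })
  }
  if ("topics" %in% stages) {
    run_stage("topics", function() {
      counts <- state$counts %||%
        read_counts(file.path(cfg$output_dir, "counts_filtered"))
      K <- cfg$topics$K %||% state$sim_cfg$n_type %||% 10L
      fit <- fit_topics(counts, K = K, n_iter = cfg$topics$n_iter,
                        n_avg = cfg$topics$n_avg,
                        seed = substream(cfg$seed, 10L))
      state$fit <<- fit
      state$clusters <<- cluster_cells(fit$theta, k = K,
                                       seed = substream(cfg$seed, 11L))
      write_tsv(data.frame(cell = rownames(fit$theta),
                           cluster = state$clusters, fit$theta),
                file.path(cfg$output_dir, "topics_theta.tsv"))
      write_tsv(data.frame(topic = rownames(fit$phi), fit$phi),
                file.path(cfg$output_dir, "topics_phi.tsv"))
      log_line(logf, "topics", "done", K = K)
    })
  }
  if ("diff" %in% stages) {
    run_stage("diff", function() {
      counts <- state$counts %||%
        read_counts(file.path(cfg$output_dir, "counts_filtered"))
      meta <- read_tsv(file.path(cfg$output_dir, "cell_metadata.tsv"))
      labels <- setNames(meta$celltype, meta$cell)[colnames(counts)]
      res <- diff_mark_test(counts, labels, reference = cfg$diff$reference)
      res <- call_dynamic(res, cfg$diff$mark,
                          q_thresholds = unlist(cfg$diff$q_thresholds))
      state$diff <<- res
      write_tsv(as.data.frame(res), file.path(cfg$output_dir, "diff_result.tsv"))
      log_line(logf, "diff", "done", dynamic = sum(res$dynamic))
    })
  }
  if ("motifs" %in% stages) {
    run_stage("motifs", function() {
      counts <- state$counts %||%
        read_counts(file.path(cfg$output_dir, "counts_filtered"))
      fit <- state$fit
      if (is.null(fit)) stop("motif stage needs the topics stage")
      signal <- impute_signal(fit)
      design <- simulate_motif_design(
        n_region = nrow(signal), n_motif = cfg$motifs$n_motif,
        n_cell = ncol(signal), n_active = cfg$motifs$n_active,
        seed = substream(cfg$seed, 12L))
      rownames(design$N) <- rownames(signal)
      afit <- fit_activities(signal, design$N,
                             seed = substream(cfg$seed, 13L))
      zs <- motif_zscores(afit, threshold = cfg$motifs$z_threshold)
      write_tsv(data.frame(motif = rownames(afit$A), afit$A),
                file.path(cfg$output_dir, "motif_activities.tsv"))
      write_tsv(data.frame(motif = names(zs$z), z = zs$z,
                           significant = names(zs$z) %in% zs$significant),
                file.path(cfg$output_dir, "motif_zscores.tsv"))
      log_line(logf, "motifs", "done", lambda = afit$lambda)
    })
  }

  close(logf); on.exit()
  files <- sort(setdiff(list.files(cfg$output_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$output_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
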