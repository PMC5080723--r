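#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: (optionally) simulate a synthetic
#' study, normalize the H3K27me3 samples, call per-gene marks, classify
#' H3K27me3 profiles, tabulate bivalency transitions and retention, and
#' integrate expression. Writes per-stage TSV/JSON outputs plus a run
#' manifest (config snapshot, seed, input checksums, stage outputs) so a
#' re-run with the same config reproduces identical files.
#'
#' @param config Either a named list or a path to a YAML file. Recognized
#'   keys: `out_dir` (required), `seed`, `stages` (subset of simulate,
#'   normalize, mark, classify, bivalency, expression), `sim` (list of
#'   [sim_config()] overrides), `params` (list of [pipeline_params()]
#'   overrides), and — when the simulate stage is disabled — input paths
#'   `genes_file`, `expression_file`, and `peak_files` (named list
#'   `<mark>_<timepoint>` -> path).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  all_stages <- c("simulate", "normalize", "mark", "classify", "bivalency",
                  "expression")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(pipeline_params, config$params %||% list())
  seed <- config$seed %||% 1L

  log_stage <- function(name) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
  }
  results <- list()
  manifest <- list(seed = seed, stages = stages,
                   params = unclass(params), outputs = list())

  ## ---- inputs: simulate or load ----
  if ("simulate" %in% stages) {
    log_stage("simulate")
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    study <- simulate_study(scfg, out_dir = file.path(out_dir, "fixture"))
    manifest$outputs$simulate <- file.path(out_dir, "fixture")
    manifest$sim_config <- scfg[setdiff(names(scfg), "")]
  } else {
    for (key in c("genes_file", "expression_file", "peak_files")) {
      if (is.null(config[[key]])) {
        stop("stage inputs missing: config key '", key,
             "' is required when the simulate stage is disabled")
      }
    }
    peaksets <- lapply(names(config$peak_files), function(nm) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      read_peaks(config$peak_files[[nm]], parts[1], parts[2])
    })
    names(peaksets) <- names(config$peak_files)
    study <- list(genes = read_gene_models(config$genes_file),
                  peaksets = peaksets,
                  expression = read_expression(config$expression_file),
                  truth = NULL)
    manifest$input_checksums <- as.list(tools::md5sum(unlist(
      c(config$genes_file, config$expression_file, config$peak_files)
    )))
  }
  results$study <- study
  genes <- study$genes
  k27_names <- grep("^H3K27me3_", names(study$peaksets), value = TRUE)
  k4_names <- grep("^H3K4me3_", names(study$peaksets), value = TRUE)

  ## ---- normalize ----
  norm <- NULL
  if ("normalize" %in% stages) {
    log_stage("normalize")
    norm <- normalize_h3k27me3(study$peaksets[k27_names], genes,
                               study$expression, params)
    utils::write.table(norm$invariant_regions$regions,
                       file.path(out_dir, "invariant_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    for (nm in names(norm$scaled_samples)) {
      write_peaks(norm$scaled_samples[[nm]],
                  file.path(out_dir, paste0(nm, ".scaled.bed")))
    }
    jsonlite::write_json(
      list(scale_factors = as.list(norm$scale_factors),
           background_cutoff = norm$background_cutoff,
           achieved_clean_fraction = norm$achieved_clean_fraction,
           n_high_genes = norm$n_high_genes),
      file.path(out_dir, "normalization.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$outputs$normalize <- "normalization.json"
    results$normalization <- norm
  }

  k27_samples <- if (!is.null(norm)) norm$scaled_samples else
    study$peaksets[k27_names]
  cutoff <- if (!is.null(norm)) norm$background_cutoff else 0

  ## ---- mark ----
  if ("mark" %in% stages) {
    log_stage("mark")
    calls <- list()
    for (nm in k4_names) {
      tp <- sub("^H3K4me3_", "", nm)
      calls[[nm]] <- call_gene_marks(genes, study$peaksets[[nm]],
                                     cutoff = 0, flank = params$flank_bp)
    }
    for (nm in names(k27_samples)) {
      tp <- sub("^H3K27me3_", "", nm)
      calls[[nm]] <- call_gene_marks(genes, k27_samples[[nm]],
                                     cutoff = cutoff,
                                     flank = params$flank_bp)
    }
    all_calls <- do.call(rbind, calls)
    utils::write.table(all_calls, file.path(out_dir, "gene_marks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$mark <- "gene_marks.tsv"
    results$mark_calls <- calls
  }

  ## ---- classify ----
  if ("classify" %in% stages) {
    log_stage("classify")
    stopifnot(!is.null(results$mark_calls))
    prof <- list()
    for (nm in names(k27_samples)) {
      marked <- results$mark_calls[[nm]]
      mg <- genes[genes$gene_id %in% marked$gene_id[marked$marked], ,
                  drop = FALSE]
      prof[[nm]] <- classify_profiles(mg, k27_samples[[nm]], cutoff, params)
    }
    all_prof <- do.call(rbind, prof)
    utils::write.table(all_prof, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$classify <- "profiles.tsv"
    results$profiles <- prof
  }

  ## ---- bivalency ----
  if ("bivalency" %in% stages) {
    log_stage("bivalency")
    stopifnot(!is.null(results$mark_calls))
    states <- lapply(TIMEPOINTS, function(tp) {
      mark_states(results$mark_calls[[paste0("H3K4me3_", tp)]],
                  results$mark_calls[[paste0("H3K27me3_", tp)]])
    })
    names(states) <- TIMEPOINTS
    state_df <- do.call(rbind, states)
    utils::write.table(state_df, file.path(out_dir, "mark_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trans <- list(
      t0_t8 = transitions(states$t0, states$t8),
      t8_t24 = transitions(states$t8, states$t24),
      t24_reox8 = transitions(states$t24, states$reox8)
    )
    ret <- retention(states)
    jsonlite::write_json(
      list(transitions = lapply(trans, function(tt)
             list(from = tt$from, to = tt$to,
                  counts = as.data.frame(as.table(tt$counts)),
                  summaries = as.list(tt$summaries))),
           retention_counts = as.list(ret$counts),
           retained_fraction_of_gained = ret$retained_fraction_of_gained),
      file.path(out_dir, "bivalency.json"), auto_unbox = TRUE, digits = NA)
    manifest$outputs$bivalency <- "bivalency.json"
    results$states <- states
    results$transitions <- trans
    results$retention <- ret
  }

  ## ---- expression ----
  if ("expression" %in% stages) {
    log_stage("expression")
    flags <- expressed_flags(study$expression, params)
    diff <- differential_calls(study$expression, params)
    utils::write.table(flags, file.path(out_dir, "expression_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff, file.path(out_dir, "differential_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$expression <- "differential_calls.tsv"
    results$expression_flags <- flags
    results$differential <- diff
  }

  manifest$version <- as.character(utils::packageVersion("hypomark"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
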