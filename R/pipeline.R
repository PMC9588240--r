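#' Pipeline configuration
#'
#' Bundles input (either file paths or a simulation config), the analysis
#' thresholds, the stage list to execute, and the output directory. All
#' thresholds default to the values used throughout the package: minimum
#' count 15, padj 0.05, equilibrium theta 100, onset 30 TPM, responder floor
#' 10 TPM, monotone fold 25 with end cap 20.
#'
#' @param input Either a [sim_config()] or a named list with elements
#'   `counts`, `tpm`, `sheet` (file paths) plus a `grid`.
#' @param out_dir Output directory.
#' @param stages Pipeline stages to run, in order.
#' @param min_count,alpha,theta,onset_tpm,responder_floor,monotone_fold,
#'   monotone_cap Analysis thresholds.
#' @param net Network parameters ([network_params()]).
#' @param network_lineages,network_stages Scope of the co-expression network
#'   input filter (mean TPM > 15 rule); defaults target the mesendoderm
#'   lineages at gastrula stages when present.
#' @param gene_sets Optional path to a GMT file of gene sets for enrichment
#'   traces.
#' @param seed Seed governing all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir,
                            stages = c("preprocess", "de", "trajectory",
                                       "dynamics", "patterns", "networks"),
                            min_count = 15, alpha = 0.05, theta = 100,
                            onset_tpm = 30, responder_floor = 10,
                            monotone_fold = 25, monotone_cap = 20,
                            net = network_params(),
                            network_lineages = NULL, network_stages = NULL,
                            gene_sets = NULL, seed = 1L) {
  stopifnot(min_count >= 0, alpha > 0, theta > 0, onset_tpm > 0,
            responder_floor > 0, monotone_fold > 1, monotone_cap > 0)
  known <- c("preprocess", "de", "trajectory", "dynamics", "patterns", "networks")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown pipeline stages: ", paste(bad, collapse = ", "))
  if (!inherits(input, "sim_config")) {
    need <- c("counts", "tpm", "sheet", "grid")
    miss <- setdiff(need, names(input))
    if (length(miss)) stop("input must be a sim_config or a list with: ",
                           paste(miss, collapse = ", "))
    for (p in unlist(input[c("counts", "tpm", "sheet")])) {
      if (!file.exists(p)) stop("input path not found: ", p)
    }
  }
  if (!is.null(gene_sets) && !file.exists(gene_sets)) {
    stop("gene set file not found: ", gene_sets)
  }
  structure(list(input = input, out_dir = out_dir, stages = stages,
                 min_count = min_count, alpha = alpha, theta = theta,
                 onset_tpm = onset_tpm, responder_floor = responder_floor,
                 monotone_fold = monotone_fold, monotone_cap = monotone_cap,
                 net = net, network_lineages = network_lineages,
                 network_stages = network_stages, gene_sets = gene_sets,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

dep_check <- function(stage, have, need) {
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop("stage '", stage, "' requires skipped stage(s): ",
         paste(miss, collapse = ", "))
  }
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (count filter, homeolog merge, replicate summary),
#' the differential-expression scan, trajectory geometry, temporal dynamics,
#' pattern modelling and network detection in order, writing each stage's
#' tables under the configured output directory and returning a manifest
#' report. Identical configuration and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (manifest, parameters, warnings, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  warns <- character(0)
  note <- function(f) manifest <<- c(manifest, f)
  emit <- function(df, name) {
    f <- file.path(config$out_dir, name)
    readr::write_tsv(tibble::as_tibble(df), f)
    note(f)
  }
  set.seed(config$seed)

  if (inherits(config$input, "sim_config")) {
    sim <- simulate_study(config$input)
    study <- sim$study
    emit(sim$truth, "truth.tsv")
  } else {
    study <- load_study(config$input$counts, config$input$tpm,
                        config$input$sheet, config$input$grid)
  }

  done <- character(0)
  summ <- NULL; scan <- NULL
  failure <- NULL
  try_stages <- function(expr) {
    tryCatch(expr, error = function(e) failure <<- conditionMessage(e))
  }
  try_stages(withCallingHandlers({
    if ("preprocess" %in% config$stages) {
      study <- filter_min_count(study, config$min_count)  # filter before merge
      study <- merge_homeologs(study)
      summ <- summarize_replicates(study)
      emit(tibble::as_tibble(study$counts, rownames = "gene_id"), "counts_filtered.tsv")
      emit(summ, "summary.tsv")
      done <- c(done, "preprocess")
    }
    if ("de" %in% config$stages) {
      dep_check("de", done, "preprocess")
      scan <- run_de_scan(study, alpha = config$alpha)
      emit(scan, "de_scan.tsv")
      done <- c(done, "de")
    }
    if ("trajectory" %in% config$stages) {
      dep_check("trajectory", done, "preprocess")
      pca <- run_pca(study)
      emit(tidy(pca), "pca_scores.tsv")
      emit(glance(pca), "pca_scree.tsv")
      dists <- trajectory_distances(pca, study$grid$stage[1],
                                    study$grid$stage[nrow(study$grid)])
      emit(dplyr::select(dists, -"distances"), "trajectory_distances.tsv")
      tests <- distance_tests(dists, pca)
      f <- file.path(config$out_dir, "distance_tests.json")
      jsonlite::write_json(list(wilcoxon = tests$wilcoxon, ks = tests$ks),
                           f, auto_unbox = TRUE, digits = NA)
      note(f)
      done <- c(done, "trajectory")
    }
    if ("dynamics" %in% config$stages) {
      dep_check("dynamics", done, "de")
      prof <- de_count_profile(scan, config$alpha)
      emit(prof, "dynamics_profile.tsv")
      eq <- detect_equilibrium(prof, config$theta)
      f <- file.path(config$out_dir, "equilibrium.json")
      jsonlite::write_json(eq, f, auto_unbox = TRUE, digits = NA)
      note(f)
      sig_up <- tibble::as_tibble(scan) |>
        dplyr::filter(.data$type == "temporal", !is.na(.data$padj),
                      .data$padj <= config$alpha)
      sets <- split(sig_up$gene_id, sig_up$lineage)
      sets <- lapply(sets, unique)
      if (length(sets) >= 2 && length(sets) <= 6) {
        part <- overlap_partition(sets)
        emit(dplyr::select(part$cells, -"genes"), "de_overlap_partition.tsv")
      }
      if (!is.null(config$gene_sets)) {
        gs <- read_gmt(config$gene_sets)
        traces <- purrr::imap_dfr(gs, function(members, nm) {
          dplyr::mutate(set_enrichment_trace(scan, members,
                                             alpha = config$alpha),
                        gene_set = nm)
        })
        emit(traces, "enrichment_traces.tsv")
      }
      done <- c(done, "dynamics")
    }
    if ("patterns" %in% config$stages) {
      dep_check("patterns", done, "preprocess")
      fit <- fit_trends(study)
      emit(fit, "trend_fits.tsv")
      cls <- classify_dynamics(fit, alpha = config$alpha)
      emit(cls, "dynamics_classes.tsv")
      mono <- monotonic_decrease_filter(summ, fold = config$monotone_fold,
                                        end_cap = config$monotone_cap)
      emit(tibble::tibble(gene_id = mono), "monotone_decreasing.tsv")
      emit(onset_stages(summ, config$onset_tpm), "onset_stages.tsv")
      done <- c(done, "patterns")
    }
    if ("networks" %in% config$stages) {
      dep_check("networks", done, "preprocess")
      lns <- config$network_lineages %||%
        intersect(c("endoderm", "ventral_mesoderm"), unique(study$sheet$lineage))
      sts <- config$network_stages %||%
        intersect(c("10", "10.5", "11"), study$grid$stage)
      if (!length(lns)) lns <- unique(study$sheet$lineage)
      if (!length(sts)) sts <- study$grid$stage
      genes <- filter_network_genes(summ, lns, sts)
      sid <- study$sheet$sample_id[study$sheet$lineage %in% lns]
      x <- log2(study$tpm[genes, sid, drop = FALSE] + 1)
      x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
      sft <- pick_soft_threshold(x, target_r2 = config$net$target_r2)
      tom <- tom_similarity(signed_adjacency(x, sft$power))
      mods <- detect_modules(tom, config$net, exprs = x)
      emit(mods, "modules.tsv")
      if (any(mods$module != "unassigned")) {
        me <- module_eigengenes(x, mods)
        emit(tibble::as_tibble(me, rownames = "sample_id"), "eigengenes.tsv")
        sh <- study$sheet[match(colnames(x), study$sheet$sample_id), ]
        traits <- data.frame(
          minutes = study$grid$minutes[match(sh$stage, study$grid$stage)])
        for (ln in lns) traits[[ln]] <- as.integer(sh$lineage == ln)
        emit(module_trait_correlation(me, traits), "module_traits.tsv")
      }
      f <- file.path(config$out_dir, "network_params.json")
      jsonlite::write_json(list(power = sft$power,
                                min_module_size = config$net$min_module_size,
                                merge_height = config$net$merge_height),
                           f, auto_unbox = TRUE, digits = NA)
      note(f)
      done <- c(done, "networks")
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }))

  report <- structure(list(
    manifest = manifest,
    parameters = config[setdiff(names(config), c("input", "net"))],
    network_params = unclass(config$net),
    seed = config$seed,
    version = as.character(utils::packageVersion("lineagetraj")),
    warnings = warns,
    error = failure
  ), class = "run_report")
  write_report(report, file.path(config$out_dir, "report.json"))
  if (!is.null(failure)) {
    stop("pipeline stage failed after writing a partial report: ", failure)
  }
  report
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run report back from JSON
#'
#' @param path Path written by [write_report()].
#' @return A `run_report` list.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, ", ", length(x$manifest), " outputs, ",
      length(x$warnings), " warnings\n", sep = "")
  invisible(x)
}
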