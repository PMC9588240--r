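#' Archetype specification for the synthetic time-course generator
#'
#' Each spec describes a block of genes sharing a designed temporal program.
#' Archetypes mirror the dynamics classes seen in stage-resolved lineage
#' time courses: maternal/pluripotency decay, lineage-restricted monotonic
#' activation, transient peaks at intermediate stages, programs shared across
#' lineages until a late divergence point, flat housekeeping-like genes, and
#' co-expression module members sharing a common temporal shape.
#'
#' @param archetype One of `"pluripotency_decay"`, `"lineage_monotonic_up"`,
#'   `"transient_peak"`, `"shared_then_diverge"`, `"flat"`, `"module_member"`.
#' @param n_genes Number of genes in the block.
#' @param baseline Baseline expression (TPM-scale units); scalar or length
#'   `n_genes`.
#' @param fold Designed fold change (> 0); meaning depends on the archetype
#'   (end/start ratio for decay is `1/fold`).
#' @param lineages Target lineages (character); `NULL` means all lineages.
#' @param peak_stage Stage label at which a transient peak attains its maximum.
#' @param rise_start,rise_end Stage labels bounding the rise window of a
#'   monotonic activation (defaults: full grid span). Setting them to two
#'   consecutive stages yields a step-like onset concentrated at one
#'   transition.
#' @param diverge_stage Stage label after which `shared_then_diverge` traces
#'   separate between target and non-target lineages.
#' @param module Module id (integer) for `module_member` genes.
#' @param shape_degree Orthogonal-polynomial degree (1-3) giving a module its
#'   temporal shape; distinct degrees are exactly orthogonal on the grid, so
#'   designed traces of different modules are uncorrelated.
#' @param amp Amplitude (log2 units) of the module shape.
#' @param sets Character vector of gene-set names the block belongs to
#'   (e.g. `"BMP_responsive"`).
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(archetype, n_genes, baseline = 30, fold = 1,
                           lineages = NULL, peak_stage = NULL,
                           rise_start = NULL, rise_end = NULL,
                           diverge_stage = NULL, module = NULL,
                           shape_degree = NULL, amp = 1.5,
                           sets = character()) {
  known <- c("pluripotency_decay", "lineage_monotonic_up", "transient_peak",
             "shared_then_diverge", "flat", "module_member")
  if (!archetype %in% known) {
    stop("unknown archetype: ", archetype)
  }
  stopifnot(n_genes >= 1, all(fold > 0), all(baseline > 0))
  structure(list(
    archetype = archetype, n_genes = as.integer(n_genes),
    baseline = baseline, fold = fold, lineages = lineages,
    peak_stage = peak_stage, rise_start = rise_start, rise_end = rise_end,
    diverge_stage = diverge_stage, module = module,
    shape_degree = shape_degree, amp = amp, sets = sets
  ), class = "archetype_spec")
}

stage_minutes <- function(grid, label) {
  i <- match(as.character(label), grid$stage)
  if (is.na(i)) stop("stage not on grid: ", label)
  grid$minutes[i]
}

module_shape <- function(grid, degree) {
  p <- stats::poly(grid$minutes, degree = max(degree, 1L))
  p[, degree]
}

#' Designed mean-expression trace for one archetype in one lineage
#'
#' Deterministic designed trace over the stage grid (expression units, before
#' any per-sample normalization or noise). Decay traces are strictly
#' non-increasing with end/start ratio `1/fold`; transient peaks attain their
#' maximum exactly at the designated stage; diverge archetypes are identical
#' across lineages up to and including the divergence stage and differ after.
#'
#' @param spec An [archetype_spec()] (scalar `baseline` used).
#' @param lineage Lineage name.
#' @param grid Stage grid.
#' @return Numeric vector, one value per grid stage.
#' @export
archetype_mean_curve <- function(spec, lineage, grid) {
  t <- grid$minutes
  T_end <- max(t)
  b <- spec$baseline[1]
  targeted <- is.null(spec$lineages) || lineage %in% spec$lineages
  curve <- switch(spec$archetype,
    pluripotency_decay = b * spec$fold^(-t / T_end),
    flat = rep(b, length(t)),
    lineage_monotonic_up = {
      if (!targeted) rep(b, length(t)) else {
        ts <- if (is.null(spec$rise_start)) t[1] else stage_minutes(grid, spec$rise_start)
        te <- if (is.null(spec$rise_end)) T_end else stage_minutes(grid, spec$rise_end)
        w <- pmin(pmax((t - ts) / (te - ts), 0), 1)
        b * spec$fold^w
      }
    },
    transient_peak = {
      if (!targeted) rep(b, length(t)) else {
        if (is.null(spec$peak_stage)) stop("transient_peak needs peak_stage")
        tp <- stage_minutes(grid, spec$peak_stage)
        i <- match(as.character(spec$peak_stage), grid$stage)
        gaps <- c(if (i > 1) t[i] - t[i - 1], if (i < length(t)) t[i + 1] - t[i])
        sigma <- mean(gaps) / 2   # bump width: half the local inter-stage gap
        w <- exp(-(t - tp)^2 / (2 * sigma^2))
        w[w < 0.05] <- 0  # compact support: stages beyond the bump stay flat
        b * spec$fold^w
      }
    },
    shared_then_diverge = {
      if (is.null(spec$diverge_stage)) stop("shared_then_diverge needs diverge_stage")
      td <- stage_minutes(grid, spec$diverge_stage)
      if (!targeted) rep(b, length(t)) else {
        w <- ifelse(t <= td, 0, (t - td) / (T_end - td))
        b * spec$fold^w
      }
    },
    module_member = {
      if (!targeted) rep(b, length(t)) else {
        if (is.null(spec$shape_degree)) stop("module_member needs shape_degree")
        s <- module_shape(grid, spec$shape_degree)
        b * 2^(spec$amp * s)
      }
    }
  )
  curve
}

#' Default archetype blocks for the four-lineage study design
#'
#' The default simulated study emulates a four-lineage (epidermis, neural,
#' endoderm, ventral mesoderm) six-stage three-replicate design: shared
#' pluripotency decay, lineage-restricted activation programs (the neural
#' program carries half the log-scale displacement of the others and
#' plateaus at stage 11, giving that lineage a designed minimal trajectory
#' and an early equilibrium), a BMP-responsive gene set switching on at the
#' 10 to 10.5 transition in ventral mesoderm, transient intermediate-stage
#' peaks, a late-divergence block, novel endoderm-restricted transient
#' regulators, three orthogonal co-expression modules confined to the
#' mesendoderm lineages, and flat filler genes on a deterministic log-normal
#' baseline spread.
#'
#' @param n_genes Total gene count (default 2000; the remainder after the
#'   designed blocks is flat filler).
#' @return Named list of [archetype_spec()]s.
#' @export
default_archetypes <- function(n_genes = 2000) {
  specs <- list(
    pluripotency_decay = archetype_spec("pluripotency_decay", 40,
                                        baseline = 100, fold = 50),
    epidermis_program = archetype_spec("lineage_monotonic_up", 120,
                                       baseline = 30, fold = 16,
                                       lineages = "epidermis"),
    endoderm_program = archetype_spec("lineage_monotonic_up", 120,
                                      baseline = 30, fold = 16,
                                      lineages = "endoderm",
                                      sets = "known_grn"),
    mesoderm_program = archetype_spec("lineage_monotonic_up", 120,
                                      baseline = 30, fold = 16,
                                      lineages = "ventral_mesoderm",
                                      sets = "known_grn"),
    neural_program = archetype_spec("lineage_monotonic_up", 120,
                                    baseline = 30, fold = 4,
                                    lineages = "neural",
                                    rise_start = "10", rise_end = "11"),
    bmp_response = archetype_spec("lineage_monotonic_up", 60,
                                  baseline = 10, fold = 12,
                                  lineages = "ventral_mesoderm",
                                  rise_start = "10", rise_end = "10.5",
                                  sets = c("BMP_responsive", "known_grn")),
    transient = archetype_spec("transient_peak", 80,
                               baseline = 20, fold = 5, peak_stage = "10",
                               lineages = c("epidermis", "neural")),
    grn_novel = archetype_spec("transient_peak", 20,
                               baseline = 40, fold = 6, peak_stage = "12",
                               lineages = "endoderm",
                               sets = "grn_novel"),
    late_diverge = archetype_spec("shared_then_diverge", 60,
                                  baseline = 30, fold = 8,
                                  diverge_stage = "12",
                                  lineages = c("epidermis", "endoderm",
                                               "ventral_mesoderm")),
    module1 = archetype_spec("module_member", 50, baseline = 60,
                             lineages = c("endoderm", "ventral_mesoderm"),
                             module = 1L, shape_degree = 1L, amp = 1.5,
                             sets = "known_grn"),
    module2 = archetype_spec("module_member", 50, baseline = 60,
                             lineages = c("endoderm", "ventral_mesoderm"),
                             module = 2L, shape_degree = 2L, amp = 1.5,
                             sets = "known_grn"),
    module3 = archetype_spec("module_member", 50, baseline = 60,
                             lineages = c("endoderm", "ventral_mesoderm"),
                             module = 3L, shape_degree = 3L, amp = 1.5,
                             sets = "known_grn")
  )
  n_used <- sum(vapply(specs, function(s) s$n_genes, 1L))
  n_flat <- n_genes - n_used
  if (n_flat < 0) stop("n_genes smaller than the designed blocks (", n_used, ")")
  if (n_flat > 0) {
    # deterministic log-normal spread of baselines, median 15 TPM
    specs$flat <- archetype_spec("flat", n_flat,
                                 baseline = stats::qlnorm(stats::ppoints(n_flat),
                                                          log(15), 1.1))
  }
  specs
}

#' Simulation configuration
#'
#' @param specs Named list of [archetype_spec()]s; default [default_archetypes()].
#' @param lineages Lineage names.
#' @param grid Stage grid; default [nf_stage_grid()].
#' @param replicates Biological replicates per (lineage, stage) cell.
#' @param dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param lib_factor_sd Log-normal sd of per-sample library-size factors.
#' @param count_scale Multiplier from expression units to expected counts.
#' @param tpm_total Fixed per-sample total of the full simulated
#'   transcriptome (panel plus background); `NULL` (default) uses the mean
#'   designed total so designed values keep their TPM scale at the
#'   scaled-down gene count.
#' @param panel_fraction Fraction of the transcriptome the simulated gene
#'   panel represents (default 2000/45661, the default panel size over a
#'   realistic expressed-transcriptome size). The remaining mass is a constant
#'   unsimulated background entering the TPM normalization, so that the
#'   compositional drift of the scaled-down panel matches what the same
#'   programs would induce in a full-size transcriptome. With
#'   `panel_fraction = 1` the panel TPM columns sum exactly to the constant.
#' @param homeolog_split If `TRUE`, each designed gene is emitted as `.L`/`.S`
#'   homeolog rows with a random per-gene allelic ratio (a fraction of genes
#'   keep a single homeolog), emulating an allotetraploid annotation.
#' @param noise_free If `TRUE`, counts equal rounded expected means and TPM
#'   equals the designed values (no sampling noise).
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(specs = default_archetypes(),
                       lineages = c("epidermis", "neural", "endoderm",
                                    "ventral_mesoderm"),
                       grid = nf_stage_grid(), replicates = 3,
                       dispersion = 0.05, lib_factor_sd = 0.1,
                       count_scale = 5, tpm_total = NULL,
                       panel_fraction = 2000 / 45661,
                       homeolog_split = TRUE, noise_free = FALSE,
                       seed = 1L) {
  stopifnot(dispersion >= 0, replicates >= 1, count_scale > 0,
            lib_factor_sd >= 0, length(lineages) >= 1,
            panel_fraction > 0, panel_fraction <= 1)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    stop("specs must be a named list")
  }
  for (s in specs) {
    stopifnot(inherits(s, "archetype_spec"))
    for (lab in c(s$peak_stage, s$rise_start, s$rise_end, s$diverge_stage)) {
      if (!is.null(lab) && !as.character(lab) %in% grid$stage) {
        stop("spec references stage not on grid: ", lab)
      }
    }
  }
  structure(list(specs = specs, lineages = lineages, grid = grid,
                 replicates = as.integer(replicates), dispersion = dispersion,
                 lib_factor_sd = lib_factor_sd, count_scale = count_scale,
                 tpm_total = tpm_total, panel_fraction = panel_fraction,
                 homeolog_split = homeolog_split,
                 noise_free = noise_free, seed = as.integer(seed)),
            class = "sim_config")
}

# designed per-gene unit matrix (genes x lineage-stage cells) and truth labels
build_designed <- function(config) {
  grid <- config$grid
  cells <- tidyr::expand_grid(lineage = config$lineages, stage = grid$stage)
  n_total <- sum(vapply(config$specs, function(s) s$n_genes, 1L))
  gene_id <- sprintf("g%04d", seq_len(n_total))
  U <- matrix(0, n_total, nrow(cells),
              dimnames = list(gene_id, paste(cells$lineage, cells$stage, sep = "@")))
  truth <- vector("list", length(config$specs))
  row0 <- 0L
  for (nm in names(config$specs)) {
    spec <- config$specs[[nm]]
    idx <- row0 + seq_len(spec$n_genes)
    base <- rep_len(spec$baseline, spec$n_genes)
    for (ln in config$lineages) {
      proto <- archetype_mean_curve(spec, ln, grid)   # at baseline[1]
      shape <- proto / spec$baseline[1]
      cols <- which(cells$lineage == ln)
      U[idx, cols] <- outer(base, shape)
    }
    truth[[nm]] <- tibble::tibble(
      gene_id = gene_id[idx], block = nm, archetype = spec$archetype,
      module = if (is.null(spec$module)) NA_character_ else paste0("M", spec$module),
      target_lineages = if (is.null(spec$lineages)) "all"
                        else paste(spec$lineages, collapse = ","),
      sets = paste(spec$sets, collapse = ",")
    )
    row0 <- row0 + spec$n_genes
  }
  list(U = U, cells = cells, truth = dplyr::bind_rows(truth))
}

designed_equilibria <- function(U, cells, grid, theta = 100, min_lfc = 0.5) {
  out <- lapply(unique(cells$lineage), function(ln) {
    cols <- match(paste(ln, grid$stage, sep = "@"),
                  paste(cells$lineage, cells$stage, sep = "@"))
    M <- U[, cols, drop = FALSE]
    lfc <- abs(log2((M[, -1, drop = FALSE] + 1e-9) /
                    (M[, -ncol(M), drop = FALSE] + 1e-9)))
    totals <- colSums(lfc >= min_lfc)
    n_t <- length(totals)
    eq <- "none"
    for (i in seq_len(n_t)) {
      if (all(totals[i:n_t] < theta)) { eq <- grid$stage[i]; break }
    }
    tibble::tibble(lineage = ln, equilibrium_stage = eq)
  })
  dplyr::bind_rows(out)
}

#' Simulate a stage-resolved multi-lineage expression study with ground truth
#'
#' Draws negative-binomial counts around the designed archetype means
#' (variance = mu + alpha * mu^2; Poisson when alpha = 0), applies per-sample
#' library-size factors, and derives TPM as depth-corrected counts rescaled so
#' every TPM column sums to a fixed constant. Optionally splits each gene into
#' `.L`/`.S` homeolog rows. The returned truth table records each gene's
#' archetype, module and set memberships; attributes carry the designed
#' per-stage TPM traces and the designed per-lineage equilibrium calls.
#'
#' @param config A [sim_config()].
#' @return List with elements `study` (an [expression_study()]) and `truth`
#'   (tibble, one row per designed gene, with attributes `designed`,
#'   `designed_equilibrium`, `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- config$grid
  des <- build_designed(config)
  U <- des$U
  cells <- des$cells

  sheet <- tidyr::expand_grid(lineage = config$lineages, stage = grid$stage,
                              replicate = seq_len(config$replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$lineage, "_s", .data$stage,
                                     "_r", .data$replicate)) |>
    dplyr::relocate("sample_id")
  n_samp <- nrow(sheet)
  cell_of_sample <- match(paste(sheet$lineage, sheet$stage, sep = "@"),
                          paste(cells$lineage, cells$stage, sep = "@"))

  lib <- if (config$noise_free || config$lib_factor_sd == 0) rep(1, n_samp)
         else stats::rlnorm(n_samp, 0, config$lib_factor_sd)

  # homeolog layout decided before count draws so the RNG stream is stable
  if (config$homeolog_split) {
    r <- stats::runif(nrow(U))
    form <- ifelse(r < 0.80, "LS", ifelse(r < 0.95, "L", "none"))
    prop_l <- stats::runif(nrow(U), 0.35, 0.65)
  } else {
    form <- rep("none", nrow(U))
    prop_l <- rep(1, nrow(U))
  }

  row_gene <- integer(0); row_id <- character(0); row_prop <- numeric(0)
  for (g in seq_len(nrow(U))) {
    if (form[g] == "LS") {
      row_gene <- c(row_gene, g, g)
      row_id <- c(row_id, paste0(rownames(U)[g], ".L"), paste0(rownames(U)[g], ".S"))
      row_prop <- c(row_prop, prop_l[g], 1 - prop_l[g])
    } else if (form[g] == "L") {
      row_gene <- c(row_gene, g)
      row_id <- c(row_id, paste0(rownames(U)[g], ".L"))
      row_prop <- c(row_prop, 1)
    } else {
      row_gene <- c(row_gene, g)
      row_id <- c(row_id, rownames(U)[g])
      row_prop <- c(row_prop, 1)
    }
  }

  mu_cells <- U[row_gene, , drop = FALSE] * row_prop      # rows x cells
  mu <- mu_cells[, cell_of_sample, drop = FALSE] * config$count_scale
  mu <- sweep(mu, 2, lib, `*`)
  dimnames(mu) <- list(row_id, sheet$sample_id)

  counts <- if (config$noise_free) {
    round(mu)
  } else if (config$dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), dimnames = dimnames(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow(mu), dimnames = dimnames(mu))
  }

  # TPM: depth-corrected counts normalized against the full transcriptome
  # (panel + constant unsimulated background mass)
  raw_tpm <- if (config$noise_free) {
    mu / config$count_scale
  } else {
    sweep(counts, 2, lib * config$count_scale, `/`)
  }
  panel_mean <- mean(colSums(mu_cells[, cell_of_sample]))
  bg <- panel_mean * (1 - config$panel_fraction) / config$panel_fraction
  const <- if (is.null(config$tpm_total)) panel_mean + bg else config$tpm_total
  tpm <- sweep(raw_tpm, 2, const / (colSums(raw_tpm) + bg), `*`)

  study <- expression_study(counts, tpm, sheet, grid)

  # designed TPM per (gene, lineage, stage): same normalization, noise-free
  cell_tot <- colSums(U)
  D <- sweep(U, 2, const / (cell_tot + bg), `*`)
  designed <- tibble::as_tibble(D, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell", values_to = "designed_tpm") |>
    tidyr::separate_wider_delim("cell", "@", names = c("lineage", "stage"))

  truth <- des$truth
  attr(truth, "designed") <- designed
  attr(truth, "designed_equilibrium") <- designed_equilibria(U, cells, grid)
  attr(truth, "config") <- config
  list(study = study, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits counts.tsv, tpm.tsv, samples.csv and truth.tsv into `dir`.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "tpm.tsv", "samples.csv", "truth.tsv"))
  readr::write_tsv(tibble::as_tibble(sim$study$counts, rownames = "gene_id"), paths[1])
  readr::write_tsv(tibble::as_tibble(sim$study$tpm, rownames = "gene_id"), paths[2])
  readr::write_csv(sim$study$sheet, paths[3])
  readr::write_tsv(sim$truth, paths[4])
  invisible(paths)
}
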