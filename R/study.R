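#' Stage grid for a developmental time course
#'
#' A stage grid binds ordered stage labels (e.g. Nieuwkoop--Faber stages) to
#' elapsed time in minutes, with the first stage defining time zero.
#'
#' @param labels Character vector of unique, ordered stage labels.
#' @param minutes Numeric vector of elapsed minutes per stage; strictly
#'   increasing, first value 0.
#' @return A tibble with columns `stage` and `minutes`.
#' @examples
#' stage_grid(c("9", "10", "13"), c(0, 75, 435))
#' @export
stage_grid <- function(labels, minutes) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("stage labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(labels) != length(minutes)) {
    stop("labels and minutes must have equal length")
  }
  if (length(minutes) && minutes[1] != 0) {
    stop("first stage must be at 0 minutes (time origin)")
  }
  if (any(diff(minutes) <= 0)) {
    stop("minutes must be strictly increasing")
  }
  tibble::tibble(stage = labels, minutes = as.numeric(minutes))
}

#' Default six-stage blastula-to-neurula grid
#'
#' NF stages 9 through 13 at 0, 75, 150, 225, 315 and 435 minutes after
#' stage 9, the sampling design used for explant time courses spanning late
#' blastula to neural plate.
#'
#' @return A stage-grid tibble.
#' @export
nf_stage_grid <- function() {
  stage_grid(c("9", "10", "10.5", "11", "12", "13"),
             c(0, 75, 150, 225, 315, 435))
}

validate_sheet <- function(sheet, grid) {
  need <- c("sample_id", "lineage", "stage", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sheet <- tibble::as_tibble(sheet)
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$lineage <- as.character(sheet$lineage)
  sheet$stage <- as.character(sheet$stage)
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  }
  if (any(sheet$replicate < 1L)) stop("replicate numbers must be positive integers")
  key <- paste(sheet$lineage, sheet$stage, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (lineage, stage, replicate) triples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bad <- setdiff(sheet$stage, grid$stage)
  if (length(bad)) {
    stop("sample sheet stages absent from the stage grid: ",
         paste(bad, collapse = ", "))
  }
  sheet
}

check_matrix <- function(m, what) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene id in ", what, " matrix: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (!is.numeric(m)) stop(what, " matrix must be numeric")
  if (any(!is.finite(m))) stop(what, " matrix contains non-finite values")
  if (any(m < 0)) stop(what, " matrix contains negative values")
  m
}

#' Construct a validated expression study
#'
#' Binds a raw-count matrix and a TPM matrix (genes x samples) to a sample
#' sheet and a stage grid. Columns are reordered to the sheet's sample order;
#' both matrices must share gene and sample axes exactly.
#'
#' @param counts,tpm Numeric matrices, genes x samples, non-negative, with
#'   gene rownames and sample colnames.
#' @param sheet Data frame with columns `sample_id`, `lineage`, `stage`,
#'   `replicate`.
#' @param grid Stage grid from [stage_grid()].
#' @return An `expression_study` object.
#' @export
expression_study <- function(counts, tpm, sheet, grid) {
  counts <- check_matrix(as.matrix(counts), "counts")
  tpm <- check_matrix(as.matrix(tpm), "tpm")
  grid <- stage_grid(grid$stage, grid$minutes)
  sheet <- validate_sheet(sheet, grid)
  if (!identical(rownames(counts), rownames(tpm))) {
    stop("counts and tpm gene ids differ")
  }
  miss <- setdiff(sheet$sample_id, colnames(counts))
  if (length(miss)) {
    stop("sample sheet samples missing from counts matrix: ",
         paste(miss, collapse = ", "))
  }
  miss <- setdiff(sheet$sample_id, colnames(tpm))
  if (length(miss)) {
    stop("sample sheet samples missing from tpm matrix: ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(colnames(counts), sheet$sample_id)
  if (length(extra)) {
    stop("matrix samples absent from the sample sheet: ",
         paste(extra, collapse = ", "))
  }
  counts <- counts[, sheet$sample_id, drop = FALSE]
  tpm <- tpm[, sheet$sample_id, drop = FALSE]
  structure(
    list(counts = counts, tpm = tpm, sheet = sheet, grid = grid),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  lineages: ", paste(unique(x$sheet$lineage), collapse = ", "), "\n", sep = "")
  cat("  stages:   ", paste(x$grid$stage, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$counts)

read_matrix_tsv <- function(path, what) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") {
    stop(what, " file ", path, ": first column must be 'gene_id', got '",
         names(df)[1], "'")
  }
  for (j in seq(2L, ncol(df))) {
    if (!is.numeric(df[[j]])) {
      stop(what, " file ", path, ": non-numeric values in column '",
           names(df)[j], "'")
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$gene_id)
  m
}

#' Load an expression study from files on disk
#'
#' Reads a counts TSV and a TPM TSV (first column `gene_id`, one column per
#' sample) plus a CSV sample sheet, and validates them against a stage grid.
#'
#' @param counts_path,tpm_path Paths to tab-separated matrices.
#' @param sheet_path Path to a CSV with columns sample_id, lineage, stage,
#'   replicate.
#' @param grid Stage grid tibble (see [stage_grid()]).
#' @return An `expression_study`.
#' @export
load_study <- function(counts_path, tpm_path, sheet_path, grid) {
  for (p in c(counts_path, tpm_path, sheet_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  counts <- read_matrix_tsv(counts_path, "counts")
  tpm <- read_matrix_tsv(tpm_path, "tpm")
  sheet <- readr::read_csv(sheet_path, show_col_types = FALSE, progress = FALSE)
  expression_study(counts, tpm, sheet, grid)
}

#' Merge L/S homeolog pairs
#'
#' Allotetraploid genomes carry two subgenome copies of most genes, named with
#' terminal `.L` / `.S` suffixes. Genes sharing a base name after stripping
#' exactly one terminal `.L` or `.S` (case-sensitive) are summed -- counts and
#' TPM independently -- so downstream analyses see combined homeolog
#' expression. Suffix-less ids pass through unchanged; any other dotted suffix
#' is treated as part of the gene name.
#'
#' @param study An `expression_study`.
#' @return An `expression_study` with merged gene ids.
#' @export
merge_homeologs <- function(study) {
  ids <- rownames(study$counts)
  base <- sub("\\.[LS]$", "", ids)
  suffixed <- base != ids
  clash <- intersect(ids[!suffixed], base[suffixed])
  if (length(clash)) {
    stop("homeolog merge collision with existing suffix-less id: ",
         paste(clash, collapse = ", "))
  }
  counts <- rowsum(study$counts, group = base, reorder = FALSE)
  tpm <- rowsum(study$tpm, group = base, reorder = FALSE)
  expression_study(counts, tpm, study$sheet, study$grid)
}

#' Filter genes by a minimum raw read count
#'
#' Keeps exactly the genes whose raw count reaches `threshold` in at least one
#' sample (i.e. in any lineage at any stage); counts and TPM rows are filtered
#' identically. The boundary is inclusive.
#'
#' @param study An `expression_study`.
#' @param threshold Minimum count, default 15.
#' @return Filtered `expression_study`.
#' @export
filter_min_count <- function(study, threshold = 15) {
  stopifnot(threshold >= 0)
  keep <- apply(study$counts, 1L, max) >= threshold
  if (!any(keep)) {
    warning("no genes pass the minimum count filter (threshold ", threshold, ")")
  }
  study$counts <- study$counts[keep, , drop = FALSE]
  study$tpm <- study$tpm[keep, , drop = FALSE]
  study
}

#' Remove an explicit gene list from a study
#'
#' Used e.g. to restrict to zygotically expressed genes by excluding a
#' user-supplied maternal transcript list. Absent ids are ignored (with a
#' message).
#'
#' @param study An `expression_study`.
#' @param exclusion Character vector of gene ids to drop.
#' @return Filtered `expression_study`.
#' @export
exclude_genes <- function(study, exclusion) {
  exclusion <- unique(as.character(exclusion))
  absent <- setdiff(exclusion, rownames(study$counts))
  if (length(absent)) {
    message(length(absent), " exclusion ids not present in the study; ignored")
  }
  keep <- !(rownames(study$counts) %in% exclusion)
  if (!any(keep)) warning("exclusion list removes every gene in the study")
  study$counts <- study$counts[keep, , drop = FALSE]
  study$tpm <- study$tpm[keep, , drop = FALSE]
  study
}

#' Replicate-level summary of TPM per gene, lineage and stage
#'
#' Mean and SEM of TPM over biological replicates for every
#' (gene, lineage, stage) cell. SEM uses the sample (n-1) standard deviation
#' divided by sqrt(n), and is 0 for single replicates.
#'
#' @param study An `expression_study` (typically after homeolog merging).
#' @return A tibble with columns `gene_id`, `lineage`, `stage`, `minutes`,
#'   `mean_tpm`, `sem_tpm`, `n`, carrying class `summarized_expression`.
#' @export
summarize_replicates <- function(study) {
  long <- tibble::as_tibble(study$tpm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "tpm") |>
    dplyr::left_join(study$sheet, by = "sample_id")
  out <- long |>
    dplyr::group_by(.data$gene_id, .data$lineage, .data$stage) |>
    dplyr::summarise(
      mean_tpm = mean(.data$tpm),
      sem_tpm = if (dplyr::n() > 1L) stats::sd(.data$tpm) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(study$grid, by = "stage") |>
    dplyr::arrange(.data$lineage, .data$minutes, .data$gene_id) |>
    dplyr::relocate("minutes", .after = "stage")
  attr(out, "grid") <- study$grid
  class(out) <- c("summarized_expression", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, fields set name, description, then
#'   tab-separated member ids.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}
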