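#' Differential-expression count profile over successive transitions
#'
#' Counts of significant genes (padj at or below `alpha`) per lineage per
#' successive-stage transition, split by fold-change sign. Genes with log2FC
#' exactly 0 but significant padj are counted as up, so up + down always
#' equals the total.
#'
#' @param scan A `de_scan` from [run_de_scan()].
#' @param alpha padj threshold; defaults to the scan's recorded alpha.
#' @return A `dynamics_profile` tibble: lineage, stage_from, stage_to,
#'   transition, n_up, n_down, n_total.
#' @export
de_count_profile <- function(scan, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(scan, "alpha") %||% 0.05
  grid <- attr(scan, "grid")
  tmp <- dplyr::filter(tibble::as_tibble(scan), .data$type == "temporal")
  if (!nrow(tmp)) stop("scan contains no temporal contrasts")
  out <- tmp |>
    dplyr::group_by(.data$lineage, .data$stage_from, .data$stage_to) |>
    dplyr::summarise(
      n_up = sum(.data$padj <= alpha & .data$log2FC >= 0, na.rm = TRUE),
      n_down = sum(.data$padj <= alpha & .data$log2FC < 0, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_total = .data$n_up + .data$n_down,
      transition = paste0(.data$stage_from, "-", .data$stage_to)
    ) |>
    dplyr::arrange(.data$lineage, match(.data$stage_from, grid$stage)) |>
    dplyr::relocate("lineage", "transition")
  attr(out, "alpha") <- alpha
  attr(out, "grid") <- grid
  class(out) <- c("dynamics_profile", class(out))
  out
}

#' Detect the equilibrium stage of each lineage
#'
#' The equilibrium stage is the left endpoint of the earliest transition from
#' which every subsequent transition changes fewer than `theta` genes
#' (a suffix condition, so one late burst resets the call); `"none"` if the
#' final transition still moves at least `theta` genes.
#'
#' @param profile A `dynamics_profile` from [de_count_profile()].
#' @param theta Gene-count threshold, default 100.
#' @return Tibble: lineage, equilibrium_stage (label or "none"), theta.
#' @export
detect_equilibrium <- function(profile, theta = 100) {
  grid <- attr(profile, "grid")
  profile |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$lineage) |>
    dplyr::arrange(match(.data$stage_from, grid$stage), .by_group = TRUE) |>
    dplyr::summarise(equilibrium_stage = {
      tot <- .data$n_total
      eq <- "none"
      for (i in seq_along(tot)) {
        if (all(tot[i:length(tot)] < theta)) { eq <- .data$stage_from[i]; break }
      }
      eq
    }, .groups = "drop") |>
    dplyr::mutate(theta = theta)
}

#' Exact multi-set overlap partition
#'
#' Membership-combination cells (UpSet-style) for up to six named gene sets:
#' every non-empty combination with its count and member list, plus pairwise
#' shared fractions in both directions (shared / |set A| and shared /
#' |set B|).
#'
#' @param sets Named list (2 to 6) of character vectors.
#' @return An `overlap_partition` list: `cells` tibble (one row per
#'   combination, disjoint, counts summing to the union size) and `pairwise`
#'   tibble.
#' @export
overlap_partition <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (length(sets) > 6L) stop("overlap partition limited to 6 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("sets must be named")
  sets <- lapply(sets, unique)
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  cells <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    pat <- as.logical(combos[i, ])
    hit <- apply(member, 1L, function(m) identical(unname(m), pat))
    lab <- paste(names(sets)[pat], collapse = "&")
    tibble::tibble(combination = lab, n = sum(hit), genes = list(genes[hit]))
  })
  cells <- dplyr::bind_cols(cells, tibble::as_tibble(combos))
  pairwise <- purrr::map_dfr(utils::combn(names(sets), 2L, simplify = FALSE),
    function(pr) {
      shared <- length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
      tibble::tibble(
        set_a = pr, set_b = rev(pr), shared = shared,
        fraction_of_a = shared / c(length(sets[[pr[1]]]), length(sets[[pr[2]]]))
      )
    })
  structure(list(cells = cells, pairwise = pairwise, set_sizes = lengths(sets)),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("<overlap_partition> ", length(x$set_sizes), " sets, union ",
      sum(x$cells$n), " genes\n", sep = "")
  print(dplyr::select(x$cells, "combination", "n"))
  invisible(x)
}

#' Genes expressed above a TPM threshold at one stage, per lineage
#'
#' @param summary A `summarized_expression` from [summarize_replicates()].
#' @param stage Stage label.
#' @param threshold_tpm Inclusive mean-TPM threshold, default 10.
#' @param restrict Optional gene list (e.g. transcription factors); genes
#'   outside it are excluded regardless of expression.
#' @return Named list: lineage -> character vector of gene ids.
#' @export
expressed_sets <- function(summary, stage, threshold_tpm = 10, restrict = NULL) {
  if (!stage %in% summary$stage) stop("stage not present: ", stage)
  df <- dplyr::filter(tibble::as_tibble(summary), .data$stage == !!stage,
                      .data$mean_tpm >= threshold_tpm)
  if (!is.null(restrict)) df <- dplyr::filter(df, .data$gene_id %in% restrict)
  split(df$gene_id, df$lineage)
}

#' Hypergeometric overrepresentation trace of a gene set
#'
#' For every temporal contrast, the upper-tail hypergeometric probability of
#' drawing at least the observed overlap between the significant genes and
#' the gene set, from a universe of the genes tested in that contrast
#' (or a user-supplied universe).
#'
#' @param scan A `de_scan`.
#' @param gene_set Character vector of member gene ids.
#' @param universe Optional character vector; default: genes with a defined
#'   p-value in each contrast.
#' @param alpha padj threshold defining the significant draw.
#' @return An `enrichment_trace` tibble: lineage, stage_from, stage_to, N, K,
#'   n, k, p, neg_log10_p.
#' @export
set_enrichment_trace <- function(scan, gene_set, universe = NULL, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(scan, "alpha") %||% 0.05
  gene_set <- unique(gene_set)
  tmp <- dplyr::filter(tibble::as_tibble(scan), .data$type == "temporal")
  out <- tmp |>
    dplyr::group_by(.data$lineage, .data$stage_from, .data$stage_to) |>
    dplyr::group_modify(function(df, key) {
      uni <- if (is.null(universe)) df$gene_id[!is.na(df$pvalue)]
             else intersect(universe, df$gene_id)
      N <- length(uni)
      de <- df$gene_id[!is.na(df$padj) & df$padj <= alpha & df$gene_id %in% uni]
      n <- length(de)
      if (n > N) stop("inconsistent universe: more significant genes than universe")
      K <- length(intersect(gene_set, uni))
      k <- length(intersect(de, gene_set))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      tibble::tibble(N = N, K = K, n = n, k = k, p = p,
                     neg_log10_p = -log10(p))
    }) |>
    dplyr::ungroup()
  attr(out, "grid") <- attr(scan, "grid")
  class(out) <- c("enrichment_trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
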