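#' Plot sample scores on the first two principal components
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_result <- function(object, ...) {
  df <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE],
                          rownames = "sample_id") |>
    dplyr::left_join(object$sheet, by = "sample_id")
  pct <- round(100 * object$var_fraction[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$lineage,
                                   shape = .data$stage)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                  y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Plot differential-expression counts per successive transition
#'
#' @param object A `dynamics_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dynamics_profile <- function(object, ...) {
  grid <- attr(object, "grid")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      transition = factor(.data$transition,
                                          levels = unique(.data$transition[
                                            order(match(.data$stage_from,
                                                        grid$stage))])))
  ggplot2::ggplot(df, ggplot2::aes(.data$transition, .data$n_total,
                                   colour = .data$lineage,
                                   group = .data$lineage)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stage transition", y = "differentially expressed genes") +
    ggplot2::theme_minimal()
}

#' Plot a gene-set overrepresentation trace
#'
#' @param object An `enrichment_trace`.
#' @param ... Unused.
#' @return A ggplot of -log10 hypergeometric p per transition and lineage.
#' @export
autoplot.enrichment_trace <- function(object, ...) {
  grid <- attr(object, "grid")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      transition = paste0(.data$stage_from, "-", .data$stage_to))
  df$transition <- factor(df$transition, levels = unique(df$transition[
    order(match(df$stage_from, grid$stage))]))
  ggplot2::ggplot(df, ggplot2::aes(.data$transition, .data$neg_log10_p,
                                   colour = .data$lineage,
                                   group = .data$lineage)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "stage transition", y = "-log10 hypergeometric p") +
    ggplot2::theme_minimal()
}

#' Plot replicate-mean expression traces with SEM ribbons
#'
#' The standard stage-course display: per-lineage mean combined TPM across
#' stages with a ribbon of plus/minus one SEM.
#'
#' @param summary A `summarized_expression`.
#' @param genes Gene ids to plot (faceted).
#' @return A ggplot.
#' @export
plot_gene_traces <- function(summary, genes) {
  df <- dplyr::filter(tibble::as_tibble(summary), .data$gene_id %in% genes)
  if (!nrow(df)) stop("none of the requested genes are present")
  ggplot2::ggplot(df, ggplot2::aes(.data$minutes, .data$mean_tpm,
                                   colour = .data$lineage,
                                   fill = .data$lineage)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_tpm - .data$sem_tpm,
                                      ymax = .data$mean_tpm + .data$sem_tpm),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "minutes after the first stage", y = "mean TPM (S+L)") +
    ggplot2::theme_minimal()
}

#' Plot module eigengene trajectories
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param sheet Sample sheet covering the eigengene rows.
#' @param grid Stage grid.
#' @return A ggplot of eigengene value against minutes per lineage.
#' @export
plot_eigengenes <- function(eigengenes, sheet, grid) {
  df <- tibble::as_tibble(eigengenes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module",
                        values_to = "eigengene") |>
    dplyr::left_join(sheet, by = "sample_id") |>
    dplyr::left_join(grid, by = "stage")
  ggplot2::ggplot(df, ggplot2::aes(.data$minutes, .data$eigengene,
                                   colour = .data$lineage)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~module) +
    ggplot2::theme_minimal()
}
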