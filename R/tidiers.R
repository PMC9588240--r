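#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCA result into a long scores table
#'
#' @param x A `pca_result`.
#' @param n_components Components to keep (default 10 or fewer).
#' @param ... Unused.
#' @return Tibble: sample_id, lineage, stage, replicate, minutes, component,
#'   score.
#' @export
tidy.pca_result <- function(x, n_components = min(10L, ncol(x$scores)), ...) {
  tibble::as_tibble(x$scores[, seq_len(n_components), drop = FALSE],
                    rownames = "sample_id") |>
    dplyr::left_join(x$sheet, by = "sample_id") |>
    dplyr::left_join(x$grid, by = "stage") |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score")
}

#' One-row-per-component PCA summary
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble: component, variance_fraction, cumulative.
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$var_fraction)),
                 variance_fraction = x$var_fraction,
                 cumulative = cumsum(x$var_fraction))
}

#' @export
tidy.de_scan <- function(x, ...) tibble::as_tibble(x)

#' Per-contrast summary of a DE scan
#'
#' @param x A `de_scan`.
#' @param alpha padj threshold (default: the scan's).
#' @param ... Unused.
#' @return Tibble: contrast, type, n_tested, n_significant.
#' @export
glance.de_scan <- function(x, alpha = NULL, ...) {
  if (is.null(alpha)) alpha <- attr(x, "alpha") %||% 0.05
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$contrast, .data$type) |>
    dplyr::summarise(n_tested = sum(!is.na(.data$pvalue)),
                     n_significant = sum(.data$padj <= alpha, na.rm = TRUE),
                     .groups = "drop")
}

#' @export
tidy.trend_fit <- function(x, ...) tibble::as_tibble(x)

#' Moderation summary of a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble per lineage: df_residual, df_prior, s2_prior.
#' @export
glance.trend_fit <- function(x, ...) {
  meta <- attr(x, "meta")
  purrr::imap_dfr(meta, function(m, ln) {
    tibble::tibble(lineage = ln, df_residual = m$df_residual,
                   df_prior = m$df_prior, s2_prior = m$s2_prior)
  })
}

#' @export
tidy.module_assignment <- function(x, ...) tibble::as_tibble(x)

#' Module size summary
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return Tibble: module, n_genes.
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
}
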