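#' Principal component analysis of a study
#'
#' Samples are decomposed in log2(TPM + 1) space with genes centered (not
#' scaled), via singular value decomposition. Components are ordered by
#' decreasing variance; all non-degenerate components are retained (at most
#' samples - 1 with centering). Component signs follow a deterministic
#' convention: the largest-magnitude gene loading of each component is
#' positive.
#'
#' @param study An [expression_study()].
#' @param sample_subset,gene_subset Optional character vectors restricting
#'   samples / genes.
#' @return A `pca_result`: scores (samples x k), loadings (genes x k),
#'   `var_fraction`, the transform descriptor, and the sheet rows used.
#' @export
run_pca <- function(study, sample_subset = NULL, gene_subset = NULL) {
  tpm <- study$tpm
  if (!is.null(gene_subset)) tpm <- tpm[rownames(tpm) %in% gene_subset, , drop = FALSE]
  if (!is.null(sample_subset)) tpm <- tpm[, colnames(tpm) %in% sample_subset, drop = FALSE]
  if (ncol(tpm) < 2L) stop("PCA needs at least 2 samples")
  x <- t(log2(tpm + 1))                      # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  keep <- sv$d > sv$d[1] * 1e-12
  if (!any(keep)) keep[1] <- TRUE        # constant data: keep one null axis
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  loadings <- sv$v[, keep, drop = FALSE]
  for (k in seq_len(ncol(loadings))) {       # deterministic sign convention
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(d)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_along(d)))
  structure(list(
    scores = scores, loadings = loadings, centered_data = x,
    var_fraction = if (sum(sv$d^2) > 0) d^2 / sum(sv$d^2) else rep(1, length(d)),
    transform = list(log_base = 2, pseudocount = 1, centered = TRUE),
    center = attr(x, "scaled:center"),
    sheet = study$sheet[match(rownames(x), study$sheet$sample_id), ],
    grid = study$grid
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components; PC1+PC2 variance ",
      round(100 * sum(x$var_fraction[1:min(2, length(x$var_fraction))]), 1),
      "%\n", sep = "")
  invisible(x)
}

#' Association of a principal component with developmental time
#'
#' Spearman correlation (and p-value) between a component's scores and stage
#' minutes, computed per lineage. Components whose scores vary monotonically
#' with time (|rho| at or above `monotone_threshold`) are labelled monotonic;
#' constant scores are reported as rho 0 with a degenerate flag.
#'
#' @param pca A `pca_result`.
#' @param component Component number (default 1).
#' @param monotone_threshold |rho| threshold for the monotonic label.
#' @return Tibble: lineage, component, rho, p, monotonic, degenerate.
#' @export
pc_time_association <- function(pca, component = 1L, monotone_threshold = 0.8) {
  if (component > ncol(pca$scores)) stop("component not retained: ", component)
  sheet <- pca$sheet
  minutes <- pca$grid$minutes[match(sheet$stage, pca$grid$stage)]
  score <- pca$scores[, component]
  purrr::map_dfr(unique(sheet$lineage), function(ln) {
    i <- sheet$lineage == ln
    if (stats::sd(score[i]) == 0) {
      return(tibble::tibble(lineage = ln, component = component, rho = 0,
                            p = NA_real_, monotonic = FALSE, degenerate = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(score[i], minutes[i],
                                           method = "spearman", exact = FALSE))
    tibble::tibble(lineage = ln, component = component,
                   rho = unname(ct$estimate), p = ct$p.value,
                   monotonic = abs(ct$estimate) >= monotone_threshold,
                   degenerate = FALSE)
  })
}

traj_points <- function(pca, space) {
  # full = centered log-expression data; distances equal the all-PC distances
  if (space == "pcs") pca$scores else pca$centered_data
}

#' Replicate-pair trajectory distances between two stages
#'
#' Euclidean distance between every start-stage replicate and every end-stage
#' replicate of a lineage (n_start x n_end pairs, e.g. 9 for triplicates), in
#' either the space of all retained principal components or the centered full
#' log-expression space (the two agree: an orthogonal transform preserves
#' Euclidean distance). Mean and SEM are taken over the pairs.
#'
#' @param x A `pca_result` (from [run_pca()]) or an [expression_study()]
#'   (converted internally).
#' @param lineage Lineage name.
#' @param start_stage,end_stage Stage labels.
#' @param space `"pcs"` or `"full"`.
#' @return One-row tibble: lineage, stages, space, n_pairs, mean, sem, and a
#'   list column `distances`.
#' @export
trajectory_distance <- function(x, lineage, start_stage, end_stage,
                                space = c("pcs", "full")) {
  space <- match.arg(space)
  pca <- if (inherits(x, "expression_study")) run_pca(x) else x
  stopifnot(inherits(pca, "pca_result"))
  for (st in c(start_stage, end_stage)) {
    if (!st %in% pca$grid$stage) stop("unknown stage: ", st)
  }
  pts <- traj_points(pca, space)
  sheet <- pca$sheet
  i0 <- which(sheet$lineage == lineage & sheet$stage == start_stage)
  i1 <- which(sheet$lineage == lineage & sheet$stage == end_stage)
  if (!length(i0) || !length(i1)) {
    stop("no samples for lineage ", lineage, " at the requested stages")
  }
  d <- as.vector(outer(i0, i1, Vectorize(function(a, b) {
    sqrt(sum((pts[a, ] - pts[b, ])^2))
  })))
  tibble::tibble(
    lineage = lineage, start_stage = start_stage, end_stage = end_stage,
    space = space, n_pairs = length(d), mean = mean(d),
    sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0,
    distances = list(d)
  )
}

#' Trajectory distances for every lineage
#'
#' @inheritParams trajectory_distance
#' @return Tibble with one row per lineage (see [trajectory_distance()]).
#' @export
trajectory_distances <- function(x, start_stage, end_stage,
                                 space = c("pcs", "full")) {
  space <- match.arg(space)
  pca <- if (inherits(x, "expression_study")) run_pca(x) else x
  purrr::map_dfr(unique(pca$sheet$lineage), function(ln) {
    trajectory_distance(pca, ln, start_stage, end_stage, space)
  })
}

#' Nonparametric tests on trajectory distances
#'
#' Pairwise two-sided Wilcoxon rank-sum tests between the per-lineage
#' distance sets (exact when both groups have at most 25 values), plus a
#' two-sided Kolmogorov--Smirnov test comparing all between-type and
#' within-type pairwise sample distances in PC space, where a sample's type
#' is its (lineage, stage) label.
#'
#' @param dists Tibble from [trajectory_distances()].
#' @param pca The `pca_result` the distances were computed from.
#' @return A `distance_tests` list: `wilcoxon` (lineage_a, lineage_b, p,
#'   symmetric by construction) and `ks` (statistic, p, pair counts).
#' @export
distance_tests <- function(dists, pca) {
  if (nrow(dists) < 2L) stop("need distances for at least 2 lineages")
  pairs <- utils::combn(dists$lineage, 2L)
  wil <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    da <- dists$distances[[which(dists$lineage == pairs[1, k])]]
    db <- dists$distances[[which(dists$lineage == pairs[2, k])]]
    ex <- length(da) <= 25 && length(db) <= 25
    p <- suppressWarnings(stats::wilcox.test(da, db, exact = ex)$p.value)
    tibble::tibble(lineage_a = pairs[1, k], lineage_b = pairs[2, k], p = p)
  })

  pts <- pca$scores
  type <- paste(pca$sheet$lineage, pca$sheet$stage, sep = "@")
  dm <- as.matrix(stats::dist(pts))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  same <- type[idx[, 1]] == type[idx[, 2]]
  between <- dm[idx][!same]
  within <- dm[idx][same]
  ks <- suppressWarnings(stats::ks.test(between, within, exact = FALSE))
  structure(list(
    wilcoxon = wil,
    ks = tibble::tibble(statistic = unname(ks$statistic), p = ks$p.value,
                        n_between = length(between), n_within = length(within))
  ), class = "distance_tests")
}

#' @export
print.distance_tests <- function(x, ...) {
  cat("<distance_tests>\n  KS between vs within type: D =",
      signif(x$ks$statistic, 3), ", p =", signif(x$ks$p, 3), "\n")
  print(x$wilcoxon)
  invisible(x)
}
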