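#' Network construction parameters
#'
#' @param power Soft-threshold power (integer, at least 1).
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param merge_height Eigengene merge cut height in (0, 1) (default 0.25):
#'   modules whose eigengenes correlate above 1 - merge_height are merged.
#' @param target_r2 Scale-free topology fit target for power selection.
#' @return A validated `network_params` list.
#' @export
network_params <- function(power = 6L, min_module_size = 30L,
                           merge_height = 0.25, target_r2 = 0.8) {
  stopifnot(power >= 1, power == round(power), min_module_size >= 2,
            merge_height > 0, merge_height < 1)
  structure(list(power = as.integer(power),
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height, target_r2 = target_r2,
                 signed = TRUE),
            class = "network_params")
}

#' Genes in scope for network analysis
#'
#' Reproduces the scope rule: genes whose mean TPM exceeds `min_tpm` in any
#' of the designated lineages at any of the designated stages.
#'
#' @param summary A `summarized_expression`.
#' @param lineages,stages Scope of the rule.
#' @param min_tpm Strict lower bound (default 15, i.e. TPM > 15).
#' @return Character vector of gene ids.
#' @export
filter_network_genes <- function(summary, lineages, stages, min_tpm = 15) {
  tibble::as_tibble(summary) |>
    dplyr::filter(.data$lineage %in% lineages, .data$stage %in% stages,
                  .data$mean_tpm > min_tpm) |>
    dplyr::pull("gene_id") |>
    unique()
}

#' Signed adjacency matrix
#'
#' a_ij = ((1 + cor(i, j)) / 2)^power, Pearson correlation across samples,
#' zero diagonal. Perfect anticorrelation maps to 0 for every power.
#'
#' @param x Genes x samples matrix (log2 TPM).
#' @param power Soft-threshold power.
#' @return Genes x genes adjacency in `[0, 1]`.
#' @export
signed_adjacency <- function(x, power) {
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene rows excluded from the network")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  a <- ((1 + r) / 2)^power
  diag(a) <- 0
  a
}

scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < n_bins) return(c(r2 = 0, slope = NA_real_))
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) return(c(r2 = 0, slope = NA_real_))
  bin <- cut(k, br, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  width <- diff(br)
  dens <- cnt / (sum(cnt) * width)
  mk <- tapply(k, bin, mean)
  ok <- cnt > 0 & dens > 0
  fit <- stats::lm(log10(dens[ok]) ~ log10(mk[ok]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (is.na(slope) || slope >= 0) r2 <- 0       # negative-slope requirement
  c(r2 = r2, slope = slope)
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the signed adjacency and connectivity
#' k_i = sum_j a_ij are computed; the scale-free fit R^2 is the r-squared of
#' log10 connectivity-bin density against log10 mean bin connectivity over
#' equal-count bins, zeroed when the slope is non-negative. The chosen power
#' is the smallest reaching `target_r2`, or the argmax with a warning.
#'
#' @param x Genes x samples log2-TPM matrix (at least 20 genes).
#' @param powers Candidate powers.
#' @param target_r2 Fit target, default 0.8.
#' @return List: `power`, `fit_table` tibble (power, r2, slope, mean_k,
#'   max_k).
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.8) {
  if (nrow(x) < 20L) stop("need at least 20 genes to assess scale-free fit")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene rows excluded")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  base <- (1 + r) / 2
  diag(base) <- 0
  tab <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(base^b)
    sf <- scale_free_r2(k)
    tibble::tibble(power = b, r2 = sf[["r2"]], slope = sf[["slope"]],
                   mean_k = mean(k), max_k = max(k))
  })
  hit <- which(tab$r2 >= target_r2)
  if (length(hit)) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$r2)]
    warning("no candidate power reaches R^2 = ", target_r2,
            "; using the best fit (power ", power, ")")
  }
  list(power = power, fit_table = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with unit
#' diagonal, measuring shared-neighbour similarity on top of direct
#' adjacency.
#'
#' @param adjacency Symmetric matrix, zero diagonal, entries in `[0, 1]`.
#' @return Symmetric TOM matrix with entries in `[0, 1]`, diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM, cut
#' statically at the height that maximizes the number of clusters reaching
#' `min_module_size` (ties resolved toward the higher cut); clusters below
#' the size threshold become `"unassigned"`. When an expression matrix is
#' supplied, modules whose eigengenes correlate above 1 - merge_height are
#' merged iteratively until stable. Modules are labelled M1, M2, ... by
#' decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param params A [network_params()].
#' @param exprs Optional genes x samples log2-TPM matrix (same genes as
#'   `tom`) enabling the eigengene merge step.
#' @return A `module_assignment`: tibble gene_id, module; attribute `params`.
#' @export
detect_modules <- function(tom, params = network_params(), exprs = NULL) {
  stopifnot(nrow(tom) == ncol(tom))
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  hts <- sort(unique(hc$height))
  cuts <- c((c(0, hts) + c(hts, max(hts) + 1e-9)) / 2)
  best_n <- -1L; best_lab <- NULL
  for (h in cuts) {
    lab <- stats::cutree(hc, h = h)
    n_big <- sum(table(lab) >= params$min_module_size)
    if (n_big >= best_n) { best_n <- n_big; best_lab <- lab }   # >=: prefer higher cut
  }
  lab <- best_lab
  sizes <- table(lab)
  lab[lab %in% as.integer(names(sizes)[sizes < params$min_module_size])] <- 0L

  if (!is.null(exprs) && length(unique(lab[lab != 0])) > 1L) {
    repeat {
      mods <- sort(unique(lab[lab != 0]))
      me <- module_eigengenes(exprs, stats::setNames(as.character(lab), genes))
      cn <- as.integer(sub("^M?", "", colnames(me)))
      if (ncol(me) < 2L) break
      cm <- stats::cor(me)
      diag(cm) <- -Inf
      i <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      if (max(cm) <= 1 - params$merge_height) break
      lab[lab == cn[i[2]]] <- cn[i[1]]
    }
  }

  # relabel by decreasing size
  mods <- sort(table(lab[lab != 0]), decreasing = TRUE)
  map <- stats::setNames(paste0("M", seq_along(mods)), names(mods))
  module <- ifelse(lab == 0L, "unassigned", map[as.character(lab)])
  out <- tibble::tibble(gene_id = genes, module = unname(module))
  attr(out, "params") <- params
  class(out) <- c("module_assignment", class(out))
  out
}

#' Module eigengenes
#'
#' First principal component of each module's standardized member-gene
#' submatrix (unit-norm over samples), sign-oriented to correlate positively
#' with the mean member profile.
#'
#' @param exprs Genes x samples log2-TPM matrix.
#' @param labels Named character vector or `module_assignment` tibble mapping
#'   gene to module ("unassigned"/"0" skipped).
#' @return Samples x modules matrix; attribute `var_explained`.
#' @export
module_eigengenes <- function(exprs, labels) {
  if (inherits(labels, "data.frame")) {
    labels <- stats::setNames(labels$module, labels$gene_id)
  }
  labels <- labels[!labels %in% c("unassigned", "0")]
  mods <- sort(unique(labels))
  me <- matrix(NA_real_, ncol(exprs), length(mods),
               dimnames = list(colnames(exprs), paste0(
                 ifelse(grepl("^M", mods), "", "M"), mods)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    g <- intersect(names(labels)[labels == mods[i]], rownames(exprs))
    if (length(g) < 2L) stop("module ", mods[i], " has fewer than 2 genes")
    z <- t(scale(t(exprs[g, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    sv <- svd(z)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    me[, i] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- stats::setNames(ve, colnames(me))
  me
}

#' Module--trait correlations
#'
#' Pearson correlation and p-value between each module eigengene and each
#' numeric trait (e.g. minutes, a 0/1 lineage indicator). Constant traits are
#' reported with r = 0 and a degenerate flag.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param traits Data frame of numeric traits, rows matching the samples.
#' @return Tibble: module, trait, r, p, degenerate.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == nrow(eigengenes))
  purrr::map_dfr(colnames(eigengenes), function(m) {
    purrr::map_dfr(names(traits), function(tr) {
      v <- as.numeric(traits[[tr]])
      if (stats::sd(v) == 0 || stats::sd(eigengenes[, m]) == 0) {
        return(tibble::tibble(module = m, trait = tr, r = 0, p = NA_real_,
                              degenerate = TRUE))
      }
      ct <- stats::cor.test(eigengenes[, m], v)
      tibble::tibble(module = m, trait = tr, r = unname(ct$estimate),
                     p = ct$p.value, degenerate = FALSE)
    })
  })
}
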