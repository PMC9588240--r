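#' Median-of-ratios size factors
#'
#' For each sample j, s_j is the median over reference genes of
#' count_gj / geometric-mean_g(counts), where reference genes are those with
#' strictly positive counts in every sample; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  eligible <- rowSums(counts <= 0) == 0
  if (!any(eligible)) {
    stop("no reference genes with nonzero counts in every sample; ",
         "apply a minimum-count filter first")
  }
  lg <- log(counts[eligible, , drop = FALSE])
  ref <- rowMeans(lg)                      # log geometric mean per gene
  s <- apply(lg - ref, 2L, function(z) exp(stats::median(z)))
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

#' Per-gene dispersion estimation with trend shrinkage
#'
#' Method-of-moments gene dispersions on size-factor normalized counts pooled
#' within replicate groups (alpha_hat = max(0, (s^2 - mu) / mu^2)), a
#' log-linear mean--dispersion trend fitted across genes, and a final value
#' combining gene estimate and trend on the log scale (weighted geometric
#' mean, weight `shrink_weight` on the trend).
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Output of [estimate_size_factors()].
#' @param groups Factor/character of replicate-group membership per sample.
#' @param shrink_weight Weight on the trend in the geometric combination,
#'   default 0.5.
#' @return Tibble: gene_id, mean_norm, alpha_gene, alpha_trend, alpha_final.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts), length(size_factors) == ncol(counts))
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2L]
  if (!length(rep_groups)) stop("no replicated groups; cannot estimate dispersion")
  norm <- sweep(counts, 2L, size_factors, `/`)

  df_tot <- 0
  num <- rep(0, nrow(counts))
  for (g in rep_groups) {
    j <- which(groups == g)
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- rowSums((norm[, j, drop = FALSE] - m)^2) / (length(j) - 1L)
    num <- num + (length(j) - 1L) * v
    df_tot <- df_tot + (length(j) - 1L)
  }
  s2 <- unname(num / df_tot)
  mu <- unname(rowMeans(norm[, groups %in% rep_groups, drop = FALSE]))
  alpha_gene <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  pos <- alpha_gene > 0 & mu > 0
  floor_a <- 1e-8
  if (sum(pos) >= 10) {
    # log-linear trend fitted as a gamma GLM with log link: mean-unbiased for
    # the skewed moment estimates, unlike least squares on log(alpha)
    fit <- stats::glm(alpha_gene[pos] ~ log(mu[pos]),
                      family = stats::Gamma(link = "log"))
    alpha_trend <- pmax(exp(stats::coef(fit)[1] + stats::coef(fit)[2] * log(pmax(mu, 1e-8))),
                        floor_a)
  } else {
    alpha_trend <- rep(max(stats::median(alpha_gene[pos]), floor_a, na.rm = TRUE),
                       length(alpha_gene))
    if (!sum(pos)) alpha_trend <- rep(floor_a, length(alpha_gene))
  }
  w <- shrink_weight
  # a zero moment estimate is uninformative below the trend scale: such genes
  # take the trend rather than collapsing the geometric mean toward Poisson.
  # Positive estimates get the chi-square log-scale bias correction
  # (E[log(chisq_d/d)] = digamma(d/2) - log(d/2)) so the geometric
  # combination is centred on the true dispersion.
  logbias <- digamma(df_tot / 2) - log(df_tot / 2)
  gene_term <- ifelse(alpha_gene > 0, alpha_gene * exp(-logbias), alpha_trend)
  alpha_final <- exp(w * log(alpha_trend) + (1 - w) * log(pmax(gene_term, floor_a)))
  tibble::tibble(
    gene_id = rownames(counts), mean_norm = mu,
    alpha_gene = alpha_gene, alpha_trend = as.numeric(alpha_trend),
    alpha_final = as.numeric(alpha_final)
  )
}

# vectorised Fisher-scoring fit of one NB group mean on the log scale.
# Returns list(log_q, info, converged); q is the normalized-scale mean so that
# fitted mu_j = s_j * q.
fit_nb_group <- function(y, s, alpha, tol = 1e-8, max_iter = 100L) {
  n_gene <- nrow(y)
  tot <- unname(rowSums(y))
  x <- log(ifelse(tot > 0, tot, 0.5) / sum(s))   # half-count floor for all-zero groups
  zero <- tot == 0
  converged <- rep(TRUE, n_gene)
  active <- !zero                                # floored genes are held fixed
  if (any(active)) {
    conv_active <- rep(FALSE, sum(active))
    xa <- x[active]; ya <- y[active, , drop = FALSE]; aa <- alpha[active]
    for (it in seq_len(max_iter)) {
      mu <- exp(xa) %o% s
      denom <- 1 + aa * mu
      score <- rowSums((ya - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      xa <- pmin(pmax(xa + step, log(1e-12)), log(1e12))
      if (all(abs(step) < tol)) { conv_active[] <- TRUE; break }
    }
    if (it == max_iter) conv_active <- abs(step) < tol
    x[active] <- xa
    converged[active] <- conv_active
  }
  mu <- exp(x) %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  list(log_q = x, info = info, converged = converged, zero = zero)
}

#' Two-group negative-binomial Wald contrast
#'
#' Fits a two-group NB GLM with log link and size-factor offsets per gene
#' (Fisher scoring to convergence, tolerance 1e-8, at most 100 iterations; the
#' two-group design separates into one scoring problem per group). log2FC is
#' the log2 ratio of fitted means B/A, the standard error comes from the
#' information at the fit, and the p-value is a two-sided Wald test. Genes
#' with zero counts in every sample of both groups are reported with NA
#' statistics; a group whose counts are all zero receives a half-count floor
#' on its total so turn-on/turn-off genes remain testable.
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Size factors (all samples in `counts`).
#' @param dispersions Tibble from [estimate_dispersions()] or a numeric vector
#'   of final dispersions aligned to genes.
#' @param group_a,group_b Sample ids (or column indices) of the two groups;
#'   the fold change is B over A.
#' @return Tibble: gene_id, baseMean, log2FC, lfcSE, stat, pvalue, converged.
#' @export
nb_wald_contrast <- function(counts, size_factors, dispersions,
                             group_a, group_b) {
  counts <- as.matrix(counts)
  ja <- if (is.character(group_a)) match(group_a, colnames(counts)) else group_a
  jb <- if (is.character(group_b)) match(group_b, colnames(counts)) else group_b
  if (!length(ja) || !length(jb) || anyNA(ja) || anyNA(jb)) {
    stop("both groups must name samples present in the count matrix")
  }
  alpha <- if (is.data.frame(dispersions)) {
    dispersions$alpha_final[match(rownames(counts), dispersions$gene_id)]
  } else rep_len(dispersions, nrow(counts))
  if (anyNA(alpha)) stop("missing dispersion for some genes")

  ya <- counts[, ja, drop = FALSE]; yb <- counts[, jb, drop = FALSE]
  sa <- size_factors[ja]; sb <- size_factors[jb]
  fa <- fit_nb_group(ya, sa, alpha)
  fb <- fit_nb_group(yb, sb, alpha)

  all_zero <- fa$zero & fb$zero
  log2fc <- (fb$log_q - fa$log_q) / log(2)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  conv <- fa$converged & fb$converged
  if (any(!conv & !all_zero)) {
    warning(sum(!conv & !all_zero), " genes did not converge; p set to 1")
    p[!conv] <- 1
  }
  base_mean <- unname(rowMeans(sweep(counts[, c(ja, jb), drop = FALSE], 2L,
                                     size_factors[c(ja, jb)], `/`)))
  out <- tibble::tibble(
    gene_id = rownames(counts), baseMean = base_mean,
    log2FC = log2fc, lfcSE = se, stat = stat, pvalue = p, converged = conv
  )
  out[all_zero, c("log2FC", "lfcSE", "stat", "pvalue")] <- NA_real_
  out
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); NaN inputs propagate as
#' NaN and are excluded from the effective test count.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- p
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Full differential-expression scan over a study
#'
#' Runs one NB Wald contrast per successive stage pair within each lineage
#' (temporal contrasts, later vs earlier stage) and one per lineage pair at
#' each matched stage (cross contrasts, second vs first lineage). BH
#' adjustment is applied within each contrast; no fold-change cutoff is
#' imposed. Size factors and dispersions are estimated once on the full
#' matrix, with replicate groups defined by (lineage, stage).
#'
#' @param study An [expression_study()] (after count filtering / homeolog
#'   merging).
#' @param alpha Significance level recorded on the result (padj threshold),
#'   default 0.05.
#' @param shrink_weight Dispersion shrinkage weight, see
#'   [estimate_dispersions()].
#' @return A `de_scan` tibble: contrast, type, lineage / lineage_a+b, stages,
#'   and per-gene statistics with `padj`.
#' @export
run_de_scan <- function(study, alpha = 0.05, shrink_weight = 0.5) {
  sheet <- study$sheet
  grid <- study$grid
  sf <- estimate_size_factors(study$counts)
  disp <- estimate_dispersions(study$counts, sf,
                               paste(sheet$lineage, sheet$stage, sep = "@"),
                               shrink_weight = shrink_weight)
  lineages <- unique(sheet$lineage)
  samples_of <- function(ln, st) sheet$sample_id[sheet$lineage == ln & sheet$stage == st]

  res <- list()
  for (ln in lineages) {
    for (i in seq_len(nrow(grid) - 1L)) {
      a <- samples_of(ln, grid$stage[i]); b <- samples_of(ln, grid$stage[i + 1L])
      id <- paste0(ln, ":", grid$stage[i], "-", grid$stage[i + 1L])
      if (!length(a) || !length(b)) {
        warning("temporal contrast skipped (missing samples): ", id)
        next
      }
      de <- nb_wald_contrast(study$counts, sf, disp, a, b)
      de$padj <- bh_adjust(de$pvalue)
      res[[id]] <- dplyr::mutate(de, contrast = id, type = "temporal",
                                 lineage = ln, lineage_a = NA_character_,
                                 lineage_b = NA_character_,
                                 stage_from = grid$stage[i],
                                 stage_to = grid$stage[i + 1L],
                                 stage = NA_character_)
    }
  }
  if (length(lineages) >= 2L) {
    pairs <- utils::combn(lineages, 2L)
    for (k in seq_len(ncol(pairs))) {
      l1 <- pairs[1L, k]; l2 <- pairs[2L, k]
      for (st in grid$stage) {
        a <- samples_of(l1, st); b <- samples_of(l2, st)
        id <- paste0(l2, "_vs_", l1, "@", st)
        if (!length(a) || !length(b)) {
          warning("cross contrast skipped (missing samples): ", id)
          next
        }
        de <- nb_wald_contrast(study$counts, sf, disp, a, b)
        de$padj <- bh_adjust(de$pvalue)
        res[[id]] <- dplyr::mutate(de, contrast = id, type = "cross",
                                   lineage = NA_character_,
                                   lineage_a = l1, lineage_b = l2,
                                   stage_from = NA_character_,
                                   stage_to = NA_character_, stage = st)
      }
    }
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::relocate("contrast", "type")
  attr(out, "alpha") <- alpha
  attr(out, "grid") <- grid
  attr(out, "size_factors") <- sf
  class(out) <- c("de_scan", class(out))
  out
}

#' @export
print.de_scan <- function(x, ...) {
  cat("<de_scan> ", length(unique(x$contrast)), " contrasts x ",
      length(unique(x$gene_id)), " genes (padj threshold ",
      attr(x, "alpha"), ")\n", sep = "")
  NextMethod()
}
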