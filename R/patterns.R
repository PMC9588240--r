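#' Orthogonal-polynomial trend fits with empirical-Bayes moderation
#'
#' Per gene and lineage, replicate-level log2(TPM + 1) values are regressed
#' on orthonormal polynomials (degrees 1 to `max_degree`) of the minutes
#' axis, orthogonalized on the actual unequal stage spacing. Per-gene
#' residual variances are moderated toward a moment-matched prior
#' (posterior variance (d0 s0^2 + d s^2) / (d0 + d), via
#' [limma::squeezeVar()]), giving moderated t statistics and p-values per
#' coefficient with d0 + d degrees of freedom.
#'
#' @param study An [expression_study()] (after homeolog merging).
#' @param lineages Lineages to fit; default all.
#' @param max_degree Highest polynomial degree (default 3); must be at most
#'   the number of stages minus 2.
#' @return A `trend_fit` tibble: gene_id, lineage, degree, coef, t, p, s2,
#'   var_post; attributes `df_residual`, `df_prior`, `s2_prior` (per lineage).
#' @export
fit_trends <- function(study, lineages = NULL, max_degree = 3L) {
  grid <- study$grid
  if (max_degree >= nrow(grid) - 1L) {
    stop("max_degree must be at most the number of stages minus 2")
  }
  sheet <- study$sheet
  if (is.null(lineages)) lineages <- unique(sheet$lineage)
  res <- list(); meta <- list()
  for (ln in lineages) {
    sid <- sheet$sample_id[sheet$lineage == ln]
    minutes <- grid$minutes[match(sheet$stage[match(sid, sheet$sample_id)],
                                  grid$stage)]
    y <- t(log2(study$tpm[, sid, drop = FALSE] + 1))   # samples x genes
    P <- stats::poly(minutes, degree = max_degree)     # orthonormal columns
    coef <- t(P) %*% sweep(y, 2L, colMeans(y))         # projections
    fitted <- P %*% coef
    resid <- sweep(y, 2L, colMeans(y)) - fitted
    df <- length(sid) - (max_degree + 1L)
    s2 <- colSums(resid^2) / df
    sq <- limma::squeezeVar(s2, df)
    tmat <- sweep(coef, 2L, sqrt(sq$var.post), `/`)    # unit design norm
    df_tot <- sq$df.prior + df
    pmat <- 2 * stats::pt(-abs(tmat), df = df_tot)
    res[[ln]] <- tibble::tibble(
      gene_id = rep(colnames(y), each = max_degree),
      lineage = ln,
      degree = rep(seq_len(max_degree), times = ncol(y)),
      coef = as.vector(coef), t = as.vector(tmat), p = as.vector(pmat),
      s2 = rep(s2, each = max_degree),
      var_post = rep(sq$var.post, each = max_degree),
      intercept = rep(colMeans(y), each = max_degree)
    )
    meta[[ln]] <- list(df_residual = df, df_prior = sq$df.prior,
                       s2_prior = sq$var.prior,
                       poly_basis = P, minutes = minutes)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "meta") <- meta
  attr(out, "grid") <- grid
  attr(out, "max_degree") <- max_degree
  class(out) <- c("trend_fit", class(out))
  out
}

#' Classify gene dynamics per lineage
#'
#' Each (gene, lineage) is labelled `flat` when no polynomial coefficient is
#' significant (moderated p at or above `alpha` after BH adjustment across
#' genes, per lineage and degree); otherwise `transient_peak` /
#' `transient_trough` when the interior extremum of the fitted degree-2 curve
#' exceeds both endpoints by `margin` times the fitted range; otherwise
#' `monotone_up` / `monotone_down` by the sign of the net fitted change.
#'
#' @param fit A `trend_fit` from [fit_trends()].
#' @param alpha BH-adjusted significance threshold, default 0.05.
#' @param margin Transient margin as a fraction of the fitted range,
#'   default 0.2.
#' @return Tibble: gene_id, lineage, class.
#' @export
classify_dynamics <- function(fit, alpha = 0.05, margin = 0.2) {
  df <- tibble::as_tibble(fit) |>
    dplyr::group_by(.data$lineage, .data$degree) |>
    dplyr::mutate(padj = bh_adjust(.data$p)) |>
    dplyr::ungroup()
  wide <- df |>
    dplyr::group_by(.data$gene_id, .data$lineage) |>
    dplyr::summarise(
      any_sig = any(.data$padj < alpha),
      c1 = .data$coef[.data$degree == 1][1],
      c2 = if (any(.data$degree == 2)) .data$coef[.data$degree == 2][1] else 0,
      intercept = .data$intercept[1],
      .groups = "drop"
    )
  meta <- attr(fit, "meta")
  out <- wide |>
    dplyr::group_by(.data$lineage) |>
    dplyr::group_modify(function(d, key) {
      m <- meta[[key$lineage]]
      tt <- seq(min(m$minutes), max(m$minutes), length.out = 101L)
      Pg <- stats::predict(m$poly_basis, tt)[, 1:2, drop = FALSE]
      curves <- Pg %*% rbind(d$c1, d$c2)               # grid x genes
      n <- nrow(curves)
      f0 <- curves[1, ]; fT <- curves[n, ]
      fmax <- apply(curves, 2L, max); fmin <- apply(curves, 2L, min)
      rng <- fmax - fmin
      hi <- pmax(f0, fT); lo <- pmin(f0, fT)
      cls <- ifelse(!d$any_sig, "flat",
             ifelse(fmax > hi + margin * rng, "transient_peak",
             ifelse(fmin < lo - margin * rng, "transient_trough",
             ifelse(fT >= f0, "monotone_up", "monotone_down"))))
      tibble::tibble(gene_id = d$gene_id, class = cls)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("gene_id")
  out
}

#' Monotonically decreasing high-fold pluripotency-like genes
#'
#' Genes whose stage-mean combined TPM is non-increasing across every
#' successive stage in every lineage in scope, with a start/end ratio of at
#' least `fold` and an end value at most `end_cap`. A zero end value counts
#' as an infinite ratio.
#'
#' @param summary A `summarized_expression`.
#' @param lineages Lineages that must all satisfy the rule; default all.
#' @param fold Minimum start/end fold, default 25.
#' @param end_cap Maximum final-stage TPM, default 20.
#' @return Character vector of passing gene ids.
#' @export
monotonic_decrease_filter <- function(summary, lineages = NULL,
                                      fold = 25, end_cap = 20) {
  stopifnot(fold > 1)
  grid <- attr(summary, "grid")
  df <- tibble::as_tibble(summary)
  if (!is.null(lineages)) df <- dplyr::filter(df, .data$lineage %in% lineages)
  stats_tbl <- df |>
    dplyr::group_by(.data$gene_id, .data$lineage) |>
    dplyr::arrange(match(.data$stage, grid$stage), .by_group = TRUE) |>
    dplyr::summarise(
      monotone = all(diff(.data$mean_tpm) <= 0),
      ratio = ifelse(dplyr::last(.data$mean_tpm) == 0, Inf,
                     dplyr::first(.data$mean_tpm) / dplyr::last(.data$mean_tpm)),
      end_val = dplyr::last(.data$mean_tpm),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(pass = all(.data$monotone & .data$ratio >= fold &
                                  .data$end_val <= end_cap), .groups = "drop")
  stats_tbl$gene_id[stats_tbl$pass]
}

#' Expression-onset stages
#'
#' Earliest grid stage at which a gene's mean combined TPM reaches
#' `threshold_tpm`, per lineage; `"none"` if never reached.
#'
#' @param summary A `summarized_expression`.
#' @param threshold_tpm Inclusive onset threshold (default 30).
#' @return Tibble: gene_id, lineage, onset_stage; attribute `threshold`.
#' @export
onset_stages <- function(summary, threshold_tpm = 30) {
  stopifnot(threshold_tpm > 0)
  grid <- attr(summary, "grid")
  out <- tibble::as_tibble(summary) |>
    dplyr::group_by(.data$gene_id, .data$lineage) |>
    dplyr::arrange(match(.data$stage, grid$stage), .by_group = TRUE) |>
    dplyr::summarise(onset_stage = {
      i <- which(.data$mean_tpm >= threshold_tpm)
      if (length(i)) .data$stage[i[1]] else "none"
    }, .groups = "drop")
  attr(out, "threshold") <- threshold_tpm
  out
}

#' Nominate regulatory-network candidate genes
#'
#' Ranks genes by the moderated-t magnitude of their differential linear and
#' quadratic dynamics between a target lineage and a control lineage
#' (sqrt(t1^2 + t2^2) of the coefficient differences), then applies the
#' candidate rule: peak mean TPM at or above `floor_tpm` in a target lineage,
#' non-flat dynamics occurring only in target lineages, and absence from the
#' known-network gene list. Every clause is recorded.
#'
#' @param fit A `trend_fit` covering all lineages.
#' @param summary A `summarized_expression`.
#' @param known_grn Character vector of known network members.
#' @param target_lineages Lineages in which candidate dynamics may occur.
#' @param control_lineage Reference lineage for the differential ranking.
#' @param floor_tpm Minimum peak mean TPM, default 30.
#' @param alpha,margin Passed to [classify_dynamics()].
#' @param n_top Length of the nominated short list (top-scoring genes among
#'   those passing every clause; default 20). `NULL` disables truncation.
#' @return Tibble ranked by score: gene_id, score, class columns, clause
#'   flags, `nominated`.
#' @export
nominate_candidates <- function(fit, summary, known_grn, target_lineages,
                                control_lineage, floor_tpm = 30,
                                alpha = 0.05, margin = 0.2, n_top = 20L) {
  lineages <- unique(fit$lineage)
  if (!control_lineage %in% lineages) {
    stop("control lineage not present in the trend fit: ", control_lineage)
  }
  df <- tibble::as_tibble(fit) |> dplyr::filter(.data$degree <= 2)
  ctrl <- dplyr::filter(df, .data$lineage == control_lineage)
  tgt <- dplyr::filter(df, .data$lineage %in% target_lineages)
  joined <- dplyr::inner_join(
    tgt, ctrl, by = c("gene_id", "degree"), suffix = c("_t", "_c")
  ) |>
    dplyr::mutate(t_diff = (.data$coef_t - .data$coef_c) /
                    sqrt(.data$var_post_t + .data$var_post_c)) |>
    dplyr::group_by(.data$gene_id, .data$lineage_t) |>
    dplyr::summarise(score_l = sqrt(sum(.data$t_diff^2)), .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(score = max(.data$score_l), .groups = "drop")

  cls <- classify_dynamics(fit, alpha = alpha, margin = margin)
  cls_w <- cls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      nonflat_target = paste(sort(.data$lineage[.data$class != "flat" &
                                    .data$lineage %in% target_lineages]),
                             collapse = ","),
      any_target_nonflat = any(.data$class != "flat" &
                                 .data$lineage %in% target_lineages),
      other_flat = all(.data$class[!.data$lineage %in% target_lineages] == "flat"),
      class_target = {
        z <- .data$class[.data$lineage %in% target_lineages & .data$class != "flat"]
        if (length(z)) z[1] else "flat"
      },
      .groups = "drop"
    )
  peaks <- tibble::as_tibble(summary) |>
    dplyr::filter(.data$lineage %in% target_lineages) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(peak_tpm = max(.data$mean_tpm), .groups = "drop")

  out <- joined |>
    dplyr::left_join(cls_w, by = "gene_id") |>
    dplyr::left_join(peaks, by = "gene_id") |>
    dplyr::mutate(
      floor_pass = .data$peak_tpm >= floor_tpm,
      unique_pass = .data$any_target_nonflat & .data$other_flat,
      known_member = .data$gene_id %in% known_grn,
      nominated = .data$floor_pass & .data$unique_pass & !.data$known_member
    ) |>
    dplyr::arrange(dplyr::desc(.data$score))
  if (!is.null(n_top)) {
    keep <- out$nominated
    keep[which(keep)[-seq_len(min(n_top, sum(keep)))]] <- FALSE
    out$nominated <- keep
  }
  out
}

#' Top cross-lineage responder genes
#'
#' Genes significantly higher in a treated lineage than a control lineage at
#' any of the requested stages, ranked by their maximal log2 fold change over
#' those stages, filtered to a minimum mean TPM at a relevant stage that also
#' exceeds the gene's first-stage level in the treated lineage. The top
#' `n_top` genes are returned with a per-gene z-scored stage-mean trace.
#'
#' @param scan A `de_scan` with cross contrasts.
#' @param summary A `summarized_expression`.
#' @param treated_lineage,control_lineage Lineage names.
#' @param stages Stage labels to consider (default: all with a contrast).
#' @param n_top Number of genes returned, default 50.
#' @param floor_tpm Minimum mean TPM at a relevant stage, default 10.
#' @param alpha padj threshold.
#' @return Tibble: gene_id, max_log2fc, best_stage, z trace list column.
#' @export
select_top_responders <- function(scan, summary, treated_lineage,
                                  control_lineage, stages = NULL,
                                  n_top = 50, floor_tpm = 10, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(scan, "alpha") %||% 0.05
  grid <- attr(scan, "grid")
  cross <- tibble::as_tibble(scan) |>
    dplyr::filter(.data$type == "cross",
                  (.data$lineage_a == control_lineage &
                     .data$lineage_b == treated_lineage) |
                  (.data$lineage_a == treated_lineage &
                     .data$lineage_b == control_lineage))
  if (!nrow(cross)) stop("no cross contrasts between the requested lineages")
  if (is.null(stages)) stages <- unique(cross$stage)
  cross <- cross |>
    dplyr::filter(.data$stage %in% stages) |>
    dplyr::mutate(lfc_treated = ifelse(.data$lineage_b == treated_lineage,
                                       .data$log2FC, -.data$log2FC))
  hits <- cross |>
    dplyr::filter(!is.na(.data$padj), .data$padj <= alpha, .data$lfc_treated > 0)

  tr <- tibble::as_tibble(summary) |>
    dplyr::filter(.data$lineage == treated_lineage)
  first_stage <- grid$stage[1]
  base <- tr |> dplyr::filter(.data$stage == first_stage) |>
    dplyr::select("gene_id", base_tpm = "mean_tpm")
  rel <- tr |>
    dplyr::filter(.data$stage %in% stages) |>
    dplyr::left_join(base, by = "gene_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(relevant_ok = any(.data$mean_tpm >= floor_tpm &
                                         .data$mean_tpm > .data$base_tpm),
                     .groups = "drop")

  ranked <- hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(max_log2fc = max(.data$lfc_treated),
                     best_stage = .data$stage[which.max(.data$lfc_treated)],
                     .groups = "drop") |>
    dplyr::left_join(rel, by = "gene_id") |>
    dplyr::filter(.data$relevant_ok %in% TRUE) |>
    dplyr::arrange(dplyr::desc(.data$max_log2fc)) |>
    dplyr::slice_head(n = n_top)

  traces <- tr |>
    dplyr::filter(.data$gene_id %in% ranked$gene_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(match(.data$stage, grid$stage), .by_group = TRUE) |>
    dplyr::summarise(z_trace = list({
      v <- .data$mean_tpm
      s <- stats::sd(v)
      z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
      stats::setNames(z, .data$stage)
    }), .groups = "drop")
  dplyr::left_join(ranked, traces, by = "gene_id")
}

#' Dorsal/ventral response scoring and sample clustering
#'
#' Fraction of each gene set significantly upregulated (padj at or below
#' 0.05 and positive fold change toward the treated lineage) in treated vs
#' control cross contrasts, plus a per-gene z-scored log2(TPM + 1) matrix of
#' the set members over the two lineages' samples with complete-linkage
#' hierarchical clustering of the samples (Euclidean distance).
#'
#' @param scan A `de_scan`.
#' @param study The [expression_study()] behind the scan.
#' @param dorsal_set,ventral_set Character vectors of gene ids.
#' @param treated_lineage,control_lineage Lineage names.
#' @param stages Stage subset, default all.
#' @param alpha padj threshold, default 0.05.
#' @return List: `fractions` tibble (set, n_set, n_tested, n_up, fraction,
#'   undefined flag), `matrix` (z-scored genes x samples), `hclust`.
#' @export
dorsoventral_score <- function(scan, study, dorsal_set, ventral_set,
                               treated_lineage, control_lineage,
                               stages = NULL, alpha = 0.05) {
  stopifnot(length(dorsal_set) > 0, length(ventral_set) > 0)
  cross <- tibble::as_tibble(scan) |>
    dplyr::filter(.data$type == "cross",
                  (.data$lineage_a == control_lineage &
                     .data$lineage_b == treated_lineage) |
                  (.data$lineage_a == treated_lineage &
                     .data$lineage_b == control_lineage))
  if (!is.null(stages)) cross <- dplyr::filter(cross, .data$stage %in% stages)
  cross <- dplyr::mutate(cross,
    lfc_treated = ifelse(.data$lineage_b == treated_lineage,
                         .data$log2FC, -.data$log2FC))
  up_genes <- cross |>
    dplyr::filter(!is.na(.data$padj), .data$padj <= alpha,
                  .data$lfc_treated > 0) |>
    dplyr::pull("gene_id") |> unique()
  tested <- unique(cross$gene_id[!is.na(cross$pvalue)])

  frac_row <- function(name, set) {
    set <- unique(set)
    n_tested <- length(intersect(set, tested))
    n_up <- length(intersect(set, up_genes))
    tibble::tibble(set = name, n_set = length(set), n_tested = n_tested,
                   n_up = n_up,
                   fraction = if (n_tested > 0) n_up / n_tested else NA_real_,
                   undefined = n_tested == 0)
  }
  fractions <- dplyr::bind_rows(frac_row("dorsal", dorsal_set),
                                frac_row("ventral", ventral_set))
  if (any(fractions$undefined)) {
    warning("a gene set shares no genes with the tested contrasts; ",
            "its fraction is undefined")
  }

  sheet <- study$sheet
  sid <- sheet$sample_id[sheet$lineage %in% c(treated_lineage, control_lineage)]
  members <- intersect(unique(c(dorsal_set, ventral_set)), rownames(study$tpm))
  m <- log2(study$tpm[members, sid, drop = FALSE] + 1)
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0
  hc <- stats::hclust(stats::dist(t(z)), method = "complete")
  list(fractions = fractions, matrix = z, hclust = hc)
}
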