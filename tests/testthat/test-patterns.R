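# study whose log2(TPM+1) traces are exact polynomials of minutes, plus a
# pinch of noise so residual variances are positive
poly_study <- function(coefs, n_flat = 50, reps = 3, noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  g <- grid6()
  minutes <- rep(rep(g$minutes, each = reps), 1)
  P <- stats::poly(minutes, degree = 3)
  logv <- rbind(
    t(P %*% t(coefs)) + 5,
    matrix(5, n_flat, length(minutes))
  )
  logv <- logv + matrix(rnorm(length(logv), 0, noise_sd), nrow(logv))
  tpm <- 2^t(logv) - 1
  tpm <- t(pmax(tpm, 0))
  rownames(tpm) <- c(paste0("p", seq_len(nrow(coefs))), paste0("f", seq_len(n_flat)))
  toy_study(round(tpm * 10), stages = g$stage, reps = reps, tpm = tpm,
            minutes = g$minutes)
}

test_that("the polynomial design is orthonormal on the replicated minutes grid", {
  sim <- default_sim(seed = 2)
  st <- preprocess(sim$study)
  fit <- fit_trends(st, lineages = "neural")
  P <- attr(fit, "meta")$neural$poly_basis
  expect_equal(crossprod(P), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("noise-free polynomial traces are recovered coefficient by coefficient", {
  coefs <- rbind(c(2, 0, 0), c(0, -1.5, 0), c(0.5, 0.3, 0.8))
  st <- poly_study(coefs, noise_sd = 1e-6)
  fit <- fit_trends(st)
  genes <- paste0("p", 1:3)
  w <- tidyr::pivot_wider(fit[fit$gene_id %in% genes,
                              c("gene_id", "degree", "coef")],
                          names_from = "degree", values_from = "coef")
  w <- w[match(genes, w$gene_id), ]
  expect_lt(max(abs(as.matrix(w[, -1]) - coefs)), 1e-4)
  # pure linear trace: higher-degree terms vanish
  expect_lt(abs(w$`2`[1]), 1e-4)
  expect_lt(abs(w$`3`[1]), 1e-4)
  expect_error(fit_trends(st, max_degree = 5), "minus 2")
})

test_that("moderated variances lie between the gene variance and the prior", {
  sim <- default_sim(seed = 3)
  st <- preprocess(sim$study)
  fit <- fit_trends(st, lineages = "endoderm")
  meta <- attr(fit, "meta")$endoderm
  one <- fit[fit$degree == 1, ]
  lo <- pmin(one$s2, meta$s2_prior); hi <- pmax(one$s2, meta$s2_prior)
  expect_true(all(one$var_post >= lo - 1e-12 & one$var_post <= hi + 1e-12))
})

test_that("dynamics classes follow the fitted-curve rules", {
  coefs <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, -4, 0), c(0, 4, 0))
  st <- poly_study(coefs, noise_sd = 0.05, seed = 4)
  cls <- classify_dynamics(fit_trends(st))
  lab <- setNames(cls$class, cls$gene_id)
  expect_equal(unname(lab[paste0("p", 1:4)]),
               c("monotone_up", "monotone_down", "transient_peak",
                 "transient_trough"))
  expect_true(all(lab[startsWith(names(lab), "f")] == "flat"))
})

test_that("the monotone-decrease rule matches its worked examples", {
  traces <- rbind(pass = c(100, 80, 60, 40, 20, 2),
                  nonmono = c(100, 120, 60, 40, 20, 2),
                  weak = c(500, 400, 300, 200, 100, 25),
                  tozero = c(100, 80, 60, 40, 20, 0))
  g <- grid6()
  st <- toy_study(traces[, rep(1:6, each = 1)], stages = g$stage, reps = 1,
                  minutes = g$minutes)
  hits <- monotonic_decrease_filter(summarize_replicates(st))
  # ratio 50 and end 2 passes; the rise fails; ratio 20 < 25 fails;
  # a zero end value counts as infinite fold and passes
  expect_setequal(hits, c("pass", "tozero"))
})

test_that("onset stages use the inclusive 30 TPM boundary", {
  traces <- rbind(mid = c(5, 12, 31, 80, 100, 90),
                  never = c(5, 10, 20, 29.9, 25, 12),
                  immediate = c(30, 40, 50, 60, 70, 80))
  g <- grid6()
  st <- toy_study(traces, stages = g$stage, reps = 1, minutes = g$minutes)
  on <- onset_stages(summarize_replicates(st), threshold_tpm = 30)
  lab <- setNames(on$onset_stage, on$gene_id)
  expect_equal(unname(lab[c("mid", "never", "immediate")]),
               c("10.5", "none", "9"))
})

test_that("candidate nomination applies every clause and records evidence", {
  sim <- default_sim(seed = 1)
  st <- preprocess(sim$study)
  summ <- summarize_replicates(st)
  truth <- sim$truth
  fit <- fit_trends(st)
  known <- truth$gene_id[grepl("known_grn", truth$sets)]
  cand <- nominate_candidates(fit, summ, known,
                              target_lineages = c("endoderm", "ventral_mesoderm"),
                              control_lineage = "epidermis", n_top = NULL)
  tp <- truth$gene_id[grepl("grn_novel", truth$sets)]
  top <- cand[cand$nominated, ]
  expect_gt(mean(tp %in% top$gene_id), 0.8)
  # a designed novel gene passes all clauses
  one <- cand[cand$gene_id == tp[1], ]
  expect_true(one$floor_pass); expect_true(one$unique_pass)
  expect_false(one$known_member)
  # the same gene listed as a known member is excluded
  cand2 <- nominate_candidates(fit, summ, c(known, tp[1]),
                               target_lineages = c("endoderm", "ventral_mesoderm"),
                               control_lineage = "epidermis", n_top = NULL)
  expect_true(cand2$known_member[cand2$gene_id == tp[1]])
  expect_false(cand2$nominated[cand2$gene_id == tp[1]])
  # known endoderm-program genes fail the known-member clause, not the others
  kn <- cand[cand$gene_id %in% known[1], ]
  expect_true(kn$known_member)
  expect_error(nominate_candidates(fit, summ, known, "endoderm", "not_a_lineage"),
               "control lineage")
})

test_that("top responders respect floor, baseline and z-scaling rules", {
  g <- grid6()
  # one real responder, one below the TPM floor, one below its stage-9 level
  tpm_t <- rbind(resp = c(5, 10, 40, 80, 90, 95),
                 low = c(1, 2, 5, 9, 9, 9),
                 down = c(200, 150, 100, 80, 60, 50))
  tpm_c <- tpm_t * 0 + 5
  counts <- cbind(tpm_t, tpm_c) * 10
  tpm <- cbind(tpm_t, tpm_c)
  colnames(counts) <- colnames(tpm) <- NULL
  sheet <- expand.grid(stage = g$stage, lineage = c("treated", "control"),
                       stringsAsFactors = FALSE)
  sheet$replicate <- 1L
  sheet$sample_id <- paste0(sheet$lineage, "_", sheet$stage)
  colnames(counts) <- colnames(tpm) <- sheet$sample_id
  st <- expression_study(counts, tpm, sheet, g)
  summ <- summarize_replicates(st)
  # synthetic scan marking all three significantly up at stage 11
  df <- tibble::tibble(contrast = "treated_vs_control@11", type = "cross",
                       lineage = NA_character_, lineage_a = "control",
                       lineage_b = "treated", stage_from = NA_character_,
                       stage_to = NA_character_, stage = "11",
                       gene_id = rownames(tpm), baseMean = 50,
                       log2FC = c(4, 1, 3), lfcSE = 0.2, stat = 5,
                       pvalue = 1e-4, padj = c(1e-3, 1e-3, 1e-3))
  scan <- fake_scan(df)
  top <- select_top_responders(scan, summ, "treated", "control",
                               stages = "11", n_top = 10, floor_tpm = 10)
  expect_equal(top$gene_id, "resp")   # floor excludes "low", baseline "down"
  z <- top$z_trace[[1]]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("dorsal/ventral fractions count upregulated members", {
  sim <- default_sim(seed = 2)
  st <- preprocess(sim$study)
  scan <- suppressWarnings(run_de_scan(st))
  cross <- tidy(scan)
  cross <- cross[cross$type == "cross" & cross$lineage_a == "endoderm" &
                   cross$lineage_b == "ventral_mesoderm", ]
  up <- unique(cross$gene_id[!is.na(cross$padj) & cross$padj <= 0.05 &
                               cross$log2FC > 0])
  notup <- setdiff(unique(cross$gene_id[!is.na(cross$pvalue)]), up)
  dorsal <- c(up[1:3], notup[1:7])       # 3 of 10 upregulated
  ventral <- notup[8:17]                 # none upregulated
  res <- dorsoventral_score(scan, st, dorsal, ventral,
                            treated_lineage = "ventral_mesoderm",
                            control_lineage = "endoderm")
  fr <- setNames(res$fractions$fraction, res$fractions$set)
  expect_equal(unname(fr["dorsal"]), 0.3)
  expect_equal(unname(fr["ventral"]), 0)
  expect_warning(
    dorsoventral_score(scan, st, c("absent1", "absent2"), ventral,
                       "ventral_mesoderm", "endoderm"),
    "undefined")
})

test_that("samples with opposite set signatures split at the clustering root", {
  set.seed(9)
  g <- grid2()
  n <- 30
  up_in_a <- matrix(rep(c(100, 100, 5, 5), each = n), n) +
    matrix(rnorm(4 * n, 0, 1), n)
  up_in_b <- matrix(rep(c(5, 5, 100, 100), each = n), n) +
    matrix(rnorm(4 * n, 0, 1), n)
  tpm <- pmax(rbind(up_in_a, up_in_b), 0)
  rownames(tpm) <- paste0("g", seq_len(2 * n))
  st <- toy_study(round(tpm), lineages = c("a", "b"), stages = "1", reps = 2,
                  minutes = 0, tpm = tpm)
  df <- tibble::tibble(contrast = "b_vs_a@1", type = "cross",
                       lineage = NA_character_, lineage_a = "a", lineage_b = "b",
                       stage_from = NA_character_, stage_to = NA_character_,
                       stage = "1", gene_id = rownames(tpm), baseMean = 50,
                       log2FC = rep(c(-4, 4), each = n), lfcSE = 0.2, stat = 1,
                       pvalue = 1e-4, padj = 1e-3)
  res <- dorsoventral_score(fake_scan(df, grid = stage_grid("1", 0)), st,
                            dorsal_set = rownames(tpm)[1:n],
                            ventral_set = rownames(tpm)[(n + 1):(2 * n)],
                            treated_lineage = "b", control_lineage = "a")
  cut2 <- stats::cutree(res$hclust, k = 2)
  sheet_ln <- st$sheet$lineage[match(names(cut2), st$sheet$sample_id)]
  expect_equal(length(unique(paste(cut2, sheet_ln))), 2L)  # groups = lineages
})
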