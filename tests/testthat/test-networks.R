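# block-structured expression: genes within a block share a smooth profile
block_exprs <- function(sizes, n_samples = 36, noise = 0.3, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n_samples)
  shapes <- list(t, (t - 0.5)^2 * 4 - 0.3, sin(2 * pi * t) / 2)
  x <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    amp <- runif(sizes[b], 1.5, 3)
    outer(amp, shapes[[(b - 1) %% 3 + 1]]) +
      matrix(rnorm(sizes[b] * n_samples, 0, noise), sizes[b])
  }))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- paste0("s", seq_len(n_samples))
  x + 8
}

test_that("signed adjacency maps correlation extremes to 1 and 0", {
  t <- 1:10
  x <- rbind(a = t, b = 2 * t + 3, c = -t)
  for (beta in c(1, 4, 9)) {
    a <- signed_adjacency(x, beta)
    expect_equal(a["a", "b"], 1)   # perfect correlation
    expect_equal(a["a", "c"], 0)   # perfect anticorrelation
    expect_equal(diag(a), c(a = 0, b = 0, c = 0))
  }
  xc <- rbind(x, d = rep(1, 10))
  expect_warning(signed_adjacency(xc, 2), "constant")
})

test_that("TOM matches the hand case and the brute-force oracle", {
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(tom_similarity(a2)[1, 2], 1)    # (0 + 1) / (1 + 1 - 1)

  a0 <- matrix(0, 3, 3)
  expect_equal(unique(tom_similarity(a0)[upper.tri(a0)]), 0)

  set.seed(8)
  for (n in c(5, 12, 30)) {
    r <- matrix(runif(n * n), n); r <- (r + t(r)) / 2; diag(r) <- 0
    tom <- tom_similarity(r)
    expect_equal(tom, tom_oracle(r), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  bad <- matrix(c(0, 2, 2, 0), 2)
  expect_error(tom_similarity(bad), "\\[0, 1\\]")
})

test_that("soft-threshold fit statistics are reproduced by an independent oracle", {
  x <- block_exprs(c(60, 60, 60), seed = 3)
  sft <- suppressWarnings(pick_soft_threshold(x, powers = c(2, 4, 6)))
  # recompute one row of the fit table from the definition
  r <- stats::cor(t(x))
  base <- (1 + r) / 2; diag(base) <- 0
  for (i in seq_len(nrow(sft$fit_table))) {
    b <- sft$fit_table$power[i]
    k <- rowSums(base^b)
    br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11)))
    bin <- cut(k, br, include.lowest = TRUE)
    cnt <- tabulate(bin, nbins = nlevels(bin))
    dens <- cnt / (sum(cnt) * diff(br))
    ok <- cnt > 0
    fit <- stats::lm(log10(dens[ok]) ~ log10(tapply(k, bin, mean)[ok]))
    r2 <- summary(fit)$r.squared
    if (is.na(stats::coef(fit)[2]) || stats::coef(fit)[2] >= 0) r2 <- 0
    expect_equal(sft$fit_table$r2[i], r2, tolerance = 1e-10)
    expect_equal(sft$fit_table$mean_k[i], mean(k), tolerance = 1e-10)
  }
  expect_error(pick_soft_threshold(x[1:5, ]), "20 genes")
})

test_that("module detection respects block structure, size floor and merging", {
  x <- block_exprs(c(50, 50), seed = 2)
  tom <- tom_similarity(signed_adjacency(x, 6))
  mods <- detect_modules(tom, network_params(min_module_size = 30), exprs = x)
  assigned <- mods$module[mods$module != "unassigned"]
  expect_equal(length(unique(assigned)), 2L)
  # blocks land in distinct modules
  m1 <- mods$module[1:50]; m2 <- mods$module[51:100]
  expect_equal(length(unique(m1)), 1L)
  expect_equal(length(unique(m2)), 1L)
  expect_false(m1[1] == m2[1])

  # a 10-gene block cannot reach the 30-gene size floor
  xs <- block_exprs(10, n_samples = 20, seed = 4)
  toms <- tom_similarity(signed_adjacency(xs, 6))
  ms <- detect_modules(toms, network_params(min_module_size = 30), exprs = xs)
  expect_true(all(ms$module == "unassigned"))

  # two identical blocks (eigengene correlation 1) merge into one module
  set.seed(5)
  shared <- sin(seq(0, 2 * pi, length.out = 24))
  xx <- outer(runif(80, 1, 2), shared) + matrix(rnorm(80 * 24, 0, 0.1), 80)
  rownames(xx) <- paste0("g", 1:80)
  colnames(xx) <- paste0("s", 1:24)
  tomx <- tom_similarity(signed_adjacency(xx, 6))
  mx <- detect_modules(tomx, network_params(min_module_size = 30), exprs = xx)
  expect_equal(length(unique(mx$module[mx$module != "unassigned"])), 1L)
})

test_that("module eigengenes are unit-norm first components", {
  # identical standardized genes: eigengene equals the shared profile
  prof <- c(1, 3, 2, 5, 4, 6)
  x <- outer(rep(2, 10), prof) + 1
  rownames(x) <- paste0("g", 1:10); colnames(x) <- paste0("s", 1:6)
  me <- module_eigengenes(x, setNames(rep("M1", 10), rownames(x)))
  expect_equal(sum(me[, 1]^2), 1)
  expect_equal(attr(me, "var_explained")[["M1"]], 1)
  zprof <- scale(prof)[, 1]; zprof <- zprof / sqrt(sum(zprof^2))
  expect_equal(unname(me[, 1]), zprof, tolerance = 1e-10)

  # random module: variance fraction matches an independent decomposition
  set.seed(6)
  xr <- matrix(rnorm(20 * 12), 20, dimnames = list(paste0("g", 1:20),
                                                   paste0("s", 1:12)))
  mer <- module_eigengenes(xr, setNames(rep("M1", 20), rownames(xr)))
  z <- t(scale(t(xr)))
  ev <- svd(z)$d^2
  expect_equal(attr(mer, "var_explained")[["M1"]], ev[1] / sum(ev),
               tolerance = 1e-10)
  expect_error(module_eigengenes(xr, setNames(c("M1", rep("M2", 19)),
                                              rownames(xr))), "fewer than 2")
})

test_that("module-trait correlations behave at their extremes", {
  minutes <- rep(c(0, 75, 150), each = 2)
  me <- cbind(M1 = minutes / stats::sd(minutes),
              M2 = rep(c(1, -1), 3))
  rownames(me) <- paste0("s", 1:6)
  traits <- data.frame(time = minutes, constant = 5)
  res <- module_trait_correlation(me, traits)
  expect_equal(res$r[res$module == "M1" & res$trait == "time"], 1)
  expect_lt(abs(res$r[res$module == "M2" & res$trait == "time"]), 0.3)
  cst <- res[res$trait == "constant", ]
  expect_true(all(cst$degenerate))
  expect_true(all(cst$r == 0))
})

test_that("a lineage-specific module correlates best with its lineage indicator", {
  # 40 genes jointly upregulated in endoderm samples with a mild shared
  # temporal trend; the eigengene should track the lineage indicator more
  # closely than time or the other lineage
  g <- grid6()
  sheet <- expand.grid(replicate = 1:3, stage = g$stage,
                       lineage = c("endoderm", "ventral_mesoderm"),
                       stringsAsFactors = FALSE)
  minutes <- g$minutes[match(sheet$stage, g$stage)]
  is_endo <- as.integer(sheet$lineage == "endoderm")
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    amp <- runif(40, 1, 2)
    x <- outer(amp, is_endo + 0.2 * minutes / max(minutes)) +
      matrix(rnorm(40 * nrow(sheet), 0, 0.4), 40) + 6
    rownames(x) <- paste0("g", 1:40)
    colnames(x) <- paste0(sheet$lineage, "_", sheet$stage, "_", sheet$replicate)
    me <- module_eigengenes(x, setNames(rep("M1", 40), rownames(x)))
    traits <- data.frame(minutes = minutes, endoderm = is_endo,
                         ventral_mesoderm = 1L - is_endo)
    ct <- module_trait_correlation(me, traits)
    ct <- ct[!ct$degenerate, ]
    if (ct$trait[which.max(abs(ct$r))] == "endoderm") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("network scope filtering uses a strict TPM bound", {
  m <- rbind(inscope = c(16, 1), edge = c(15, 1), out = c(1, 1))
  st <- toy_study(m, lineages = "endoderm", stages = c("10", "11"), reps = 1,
                  minutes = c(0, 75))
  s <- summarize_replicates(st)
  got <- filter_network_genes(s, "endoderm", c("10", "11"), min_tpm = 15)
  expect_equal(got, "inscope")      # 15 is not > 15
})
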