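test_that("median-of-ratios size factors match hand computation", {
  # second sample exactly doubles the first
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m) <- paste0("g", 1:3)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical samples
  m2 <- cbind(a = c(5, 8), b = c(5, 8), c = c(5, 8))
  rownames(m2) <- c("g1", "g2")
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1, 1))

  # three samples scaled 1:2:4 -> factors 1/2, 1, 2 after geometric rescale
  m3 <- cbind(a = c(10, 100), b = c(20, 200), c = c(40, 400))
  rownames(m3) <- c("g1", "g2")
  expect_equal(unname(estimate_size_factors(m3)), c(0.5, 1, 2))

  expect_equal(exp(mean(log(estimate_size_factors(m)))), 1)

  # every gene has a zero somewhere -> no reference genes
  m4 <- cbind(a = c(0, 5), b = c(5, 0))
  rownames(m4) <- c("g1", "g2")
  expect_error(estimate_size_factors(m4), "reference")
})

test_that("dispersion estimation recovers designed regimes", {
  # identical replicates within groups -> zero gene dispersion
  m <- cbind(7, 7, 7, 12, 12, 12)[rep(1, 4), ] * (1:4)
  rownames(m) <- paste0("g", 1:4)
  colnames(m) <- paste0("s", 1:6)
  d <- estimate_dispersions(m, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(d$alpha_gene, rep(0, 4))

  # Poisson counts: median final dispersion near zero
  cfg <- sim_config(specs = list(flat = archetype_spec("flat", 2000, baseline = 20)),
                    lineages = "a", grid = grid2(), replicates = 3,
                    dispersion = 0, lib_factor_sd = 0.1, count_scale = 5,
                    homeolog_split = FALSE, seed = 6)
  st <- simulate_study(cfg)$study
  d0 <- estimate_dispersions(st$counts, estimate_size_factors(st$counts),
                             st$sheet$stage)
  expect_lte(median(d0$alpha_final), 0.01)

  # NB alpha = 0.1 at n = 6: median final within (0.05, 0.2)
  cfg1 <- sim_config(specs = list(flat = archetype_spec("flat", 2000, baseline = 20)),
                     lineages = "a", grid = grid2(), replicates = 3,
                     dispersion = 0.1, lib_factor_sd = 0.1, count_scale = 5,
                     homeolog_split = FALSE, seed = 5)
  st1 <- simulate_study(cfg1)$study
  d1 <- estimate_dispersions(st1$counts, estimate_size_factors(st1$counts),
                             st1$sheet$stage)
  expect_gt(median(d1$alpha_final), 0.05)
  expect_lt(median(d1$alpha_final), 0.2)

  expect_error(estimate_dispersions(m, rep(1, 6), paste0("s", 1:6)),
               "no replicated groups")
})

test_that("the NB Wald contrast handles null, strong and degenerate genes", {
  set.seed(42)
  mu <- cbind(matrix(500, 4, 3), matrix(c(500, 500, 2000, 2000), 4, 3))
  y <- matrix(rpois(length(mu), mu), nrow(mu),
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  y <- rbind(y, allzero = 0)
  de <- nb_wald_contrast(y, rep(1, 6), rep(1e-6, 5), paste0("s", 1:3),
                         paste0("s", 4:6))
  expect_equal(de$log2FC[1:2], c(0, 0), tolerance = 0.2)       # null genes
  expect_gt(min(de$pvalue[1:2]), 0.05)
  expect_equal(de$log2FC[3:4], c(2, 2), tolerance = 0.1)       # designed 4-fold
  expect_lt(max(de$pvalue[3:4]), 1e-10)
  expect_true(is.na(de$pvalue[5]))                             # all-zero gene
})

test_that("the Wald test is antisymmetric under group swap", {
  sim <- default_sim(seed = 2)
  st <- preprocess(sim$study)
  sheet <- st$sheet
  a <- sheet$sample_id[sheet$lineage == "epidermis" & sheet$stage == "9"]
  b <- sheet$sample_id[sheet$lineage == "epidermis" & sheet$stage == "10"]
  sf <- estimate_size_factors(st$counts)
  disp <- estimate_dispersions(st$counts, sf,
                               paste(sheet$lineage, sheet$stage))
  ab <- nb_wald_contrast(st$counts, sf, disp, a, b)
  ba <- nb_wald_contrast(st$counts, sf, disp, b, a)
  ok <- !is.na(ab$log2FC)
  expect_equal(ab$log2FC[ok], -ba$log2FC[ok], tolerance = 1e-10)
  expect_equal(ab$stat[ok], -ba$stat[ok], tolerance = 1e-10)
  expect_equal(ab$pvalue[ok], ba$pvalue[ok], tolerance = 1e-10)
})

test_that("with zero dispersion the fit reproduces the Poisson GLM closed form", {
  set.seed(11)
  y <- matrix(rpois(60, 50), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  s <- c(0.8, 1, 1.2, 0.9, 1.1, 1)
  de <- nb_wald_contrast(y, s, rep(0, 10), paste0("s", 1:3), paste0("s", 4:6))
  qa <- unname(rowSums(y[, 1:3])) / sum(s[1:3])  # closed-form two-group MLE
  qb <- unname(rowSums(y[, 4:6])) / sum(s[4:6])
  expect_equal(de$log2FC, log2(qb / qa), tolerance = 1e-8)
  expect_equal(de$lfcSE, sqrt(1 / (qa * sum(s[1:3])) + 1 / (qb * sum(s[4:6]))) / log(2),
               tolerance = 1e-8)
})

test_that("BH adjustment equals the step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_true(is.nan(bh_adjust(c(0.5, NaN))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(99)
  for (i in 1:20) {
    n <- sample(c(3, 10, 100, 5000), 1)
    p <- round(runif(n), sample(c(1, 3, 6), 1))  # rounding induces ties
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("the DE scan enumerates temporal and cross contrasts", {
  sim <- default_sim(seed = 1)
  st <- preprocess(sim$study)
  scan <- suppressWarnings(run_de_scan(st))
  contrasts <- unique(scan[, c("contrast", "type")])
  expect_equal(sum(contrasts$type == "temporal"), 4 * 5)
  expect_equal(sum(contrasts$type == "cross"), 6 * 6)
  expect_true(all(scan$padj >= scan$pvalue - 1e-12, na.rm = TRUE))
  expect_true(all(scan$padj <= 1, na.rm = TRUE))
})

test_that("a single gene changing at one transition is found exactly there", {
  set.seed(21)
  n_gene <- 200
  base <- matrix(rpois(n_gene * 12, 300), n_gene, 12)
  base[1, 7:12] <- rpois(6, 2400)              # 8-fold jump at the 2nd transition
  rownames(base) <- paste0("g", seq_len(n_gene))
  st <- toy_study(base, stages = c("1", "2", "3", "4"), reps = 3,
                  minutes = c(0, 75, 150, 225))
  scan <- suppressWarnings(run_de_scan(st))
  hit <- scan[scan$gene_id == "g1" & scan$type == "temporal", ]
  sig <- hit$contrast[!is.na(hit$padj) & hit$padj <= 0.05]
  expect_equal(sig, "a:2-3")
})

test_that("contrasts without samples are skipped with a warning", {
  sim <- simulate_study(sim_config(
    specs = list(flat = archetype_spec("flat", 60, baseline = 30)),
    lineages = c("a", "b"), grid = grid6(), replicates = 2,
    homeolog_split = FALSE, seed = 2))
  st <- sim$study
  keep <- !(st$sheet$lineage == "b" & st$sheet$stage == "13")
  st$counts <- st$counts[, keep]; st$tpm <- st$tpm[, keep]
  st$sheet <- st$sheet[keep, ]
  w <- capture_warnings(scan <- run_de_scan(st))
  expect_true(any(grepl("skipped", w)))
  expect_false("b:12-13" %in% scan$contrast)
  expect_true("a:12-13" %in% scan$contrast)
})
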