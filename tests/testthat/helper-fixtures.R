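# Shared fixtures and independent oracles.

grid6 <- function() nf_stage_grid()
grid2 <- function() stage_grid(c("1", "2"), c(0, 75))

# small fully-specified study: genes x (lineage x stage x replicate)
toy_study <- function(counts, lineages = "a", stages = c("1", "2"),
                      reps = 1L, tpm = NULL,
                      minutes = seq(0, by = 75, length.out = length(stages))) {
  sheet <- expand.grid(replicate = seq_len(reps), stage = stages,
                       lineage = lineages, stringsAsFactors = FALSE)
  sheet$sample_id <- paste0(sheet$lineage, "_s", sheet$stage, "_r", sheet$replicate)
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(sheet))
  colnames(counts) <- sheet$sample_id
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(tpm)) tpm <- counts
  tpm <- as.matrix(tpm)
  dimnames(tpm) <- dimnames(counts)
  expression_study(counts, tpm, sheet, stage_grid(stages, minutes))
}

# de_scan-shaped tibble built directly from per-contrast statistics
fake_scan <- function(df, grid = grid6(), alpha = 0.05) {
  out <- tibble::as_tibble(df)
  attr(out, "alpha") <- alpha
  attr(out, "grid") <- grid
  class(out) <- c("de_scan", class(out))
  out
}

fake_profile <- function(lineage, totals, grid = grid6()) {
  n <- length(totals)
  out <- tibble::tibble(
    lineage = lineage,
    transition = paste0(grid$stage[seq_len(n)], "-", grid$stage[seq_len(n) + 1L]),
    stage_from = grid$stage[seq_len(n)], stage_to = grid$stage[seq_len(n) + 1L],
    n_up = ceiling(totals / 2), n_down = floor(totals / 2), n_total = totals
  )
  attr(out, "grid") <- grid
  attr(out, "alpha") <- 0.05
  class(out) <- c("dynamics_profile", class(out))
  out
}

# --- independent oracles -----------------------------------------------------

# Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# upper-tail hypergeometric by enumerating every n-subset of the universe
hyper_upper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inset <- colSums(draws <= K)       # first K elements are the gene set
  mean(inset >= k)
}

# TOM by the brute-force triple loop
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2L, function(i) sum(r[i])) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

default_sim <- function(seed = 1, ...) simulate_study(sim_config(seed = seed, ...))

preprocess <- function(study) merge_homeologs(filter_min_count(study, 15))

# compact two-lineage pipeline configuration for end-to-end runs
small_cfg <- function(out_dir, seed = 2, ...) {
  specs <- list(
    flat = archetype_spec("flat", 260,
                          baseline = stats::qlnorm(stats::ppoints(260), log(25), 0.8)),
    decay = archetype_spec("pluripotency_decay", 25, baseline = 100, fold = 50),
    upA = archetype_spec("lineage_monotonic_up", 40, baseline = 30, fold = 16,
                         lineages = "a"),
    upB = archetype_spec("lineage_monotonic_up", 40, baseline = 30, fold = 16,
                         lineages = "b"),
    mod1 = archetype_spec("module_member", 35, baseline = 60, lineages = c("a", "b"),
                          module = 1L, shape_degree = 1L, amp = 1.5),
    mod2 = archetype_spec("module_member", 35, baseline = 60, lineages = c("a", "b"),
                          module = 2L, shape_degree = 2L, amp = 1.5)
  )
  input <- sim_config(specs = specs, lineages = c("a", "b"), grid = grid6(),
                      replicates = 3, seed = seed)
  pipeline_config(input, out_dir, network_lineages = c("a", "b"), ...)
}
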