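test_that("identical configuration reproduces counts bit-identically", {
  cfg <- simulation_config(n_genes = 200, seed = 99)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$air, s2$truth$air)
  p1 <- simulate_promoters(s1$truth, cfg)
  p2 <- simulate_promoters(s2$truth, cfg)
  expect_identical(p1$sequences, p2$sequences)
})

test_that("AIR labels are always a subset of LPS-up labels", {
  for (mode in c("specific", "shared")) {
    cfg <- simulation_config(n_genes = 400, air_mode = mode, seed = 3)
    truth <- simulate_counts(cfg)$truth
    expect_true(all(truth$lps_up[truth$air]))
    # eosinophils mount no IL-10 response: no AIR, no IL-10 induction
    expect_false(any(truth$air[, "eosinophil"]))
    expect_false(any(truth$il10_up[, "eosinophil"]))
  }
})

test_that("with all effects disabled, treatment groups are exchangeable", {
  cfg <- simulation_config(n_genes = 1000, cell_types = "macrophage",
                           n_replicates = 4, lps_common_frac = 0,
                           lps_specific_frac = 0, il10_up_frac = 0,
                           celltype_frac = 0, seed = 21)
  cm <- simulate_counts(cfg)$counts
  a <- cm$samples$treatment == "ctrl"
  b <- cm$samples$treatment == "LPS"
  p <- vapply(seq_len(nrow(cm$counts)), function(g)
    suppressWarnings(stats::wilcox.test(cm$counts[g, a],
                                        cm$counts[g, b])$p.value),
    numeric(1L))
  expect_gte(mean(p > 0.01, na.rm = TRUE), 0.98)
})

test_that("zero dispersion gives Poisson-like variance", {
  cfg <- simulation_config(n_genes = 500, cell_types = "macrophage",
                           treatments = "ctrl", n_replicates = 30,
                           dispersion = 0, lps_common_frac = 0,
                           lps_specific_frac = 0, il10_up_frac = 0,
                           celltype_frac = 0,
                           library_size_factors = rep(1, 30),
                           baseline_mean_range = c(50, 50), seed = 8)
  cm <- simulate_counts(cfg)$counts
  ratio <- apply(cm$counts, 1L, var) / rowMeans(cm$counts)
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("planted LPS effect is recovered by empirical group means", {
  cfg <- simulation_config(n_genes = 1000, cell_types = "macrophage",
                           n_replicates = 3, lps_effect = 6,
                           library_size_factors = rep(1, 12), seed = 7)
  sim <- simulate_counts(cfg)
  cm <- sim$counts
  up <- sim$truth$lps_up[, "macrophage"]
  m_lps <- rowMeans(cm$counts[up, cm$samples$treatment == "LPS"])
  m_ctrl <- rowMeans(cm$counts[up, cm$samples$treatment == "ctrl"])
  expect_equal(mean(m_lps) / mean(m_ctrl), 6, tolerance = 0.2)
})

test_that("planted log2 fold-change grows with the configured effect", {
  est <- vapply(c(2, 4, 8), function(eff) {
    cfg <- simulation_config(n_genes = 600, cell_types = "macrophage",
                             n_replicates = 3, lps_effect = eff,
                             library_size_factors = rep(1, 12), seed = 13)
    sim <- simulate_counts(cfg)
    up <- sim$truth$lps_up[, "macrophage"]
    m_lps <- rowMeans(sim$counts$counts[up,
                        sim$counts$samples$treatment == "LPS"])
    m_ctrl <- rowMeans(sim$counts$counts[up,
                         sim$counts$samples$treatment == "ctrl"])
    mean(log2((m_lps + 1) / (m_ctrl + 1)))
  }, numeric(1L))
  expect_true(all(diff(est) > 0))
})

test_that("promoter generator separates CpG classes and plants the consensus", {
  cfg <- simulation_config(n_genes = 500, seed = 17)
  sim <- simulate_counts(cfg)
  prom <- simulate_promoters(sim$truth, cfg)
  win <- extract_windows(prom)
  expect_true(all(nchar(win$sequence[!win$truncated]) == 500))
  cg <- cg_count(win)
  cls <- sim$truth$cpg_class[win$gene]
  expect_gte(mean(cg[cls == "rich"]), 2 * mean(cg[cls == "poor"]))
  expect_lt(stats::wilcox.test(cg[cls == "rich"],
                               cg[cls == "poor"])$p.value, 0.01)
  # every motif-carrying gene contains the exact consensus in its window
  carriers <- win$gene[!is.na(sim$truth$planted_motif[win$gene])]
  expect_gt(length(carriers), 10)
  hits <- grepl(cfg$planted_consensus,
                win$sequence[match(carriers, win$gene)], fixed = TRUE)
  expect_true(all(hits))
})

test_that("simulated PWM library flags the planted motif and normalizes decoys", {
  cfg <- simulation_config(n_genes = 50, n_decoy_pwms = 3, seed = 2)
  lib <- make_pwm_library(cfg)
  expect_length(lib, 4L)
  expect_true(lib$planted1$planted)
  expect_false(any(vapply(lib[-1L], `[[`, logical(1L), "planted")))
  expect_identical(pwm_consensus(lib$planted1), cfg$planted_consensus)
  for (p in lib)
    expect_true(all(abs(rowSums(p$matrix) - 1) < 1e-9))
  # planted matrix is sharp: mean information content above 1 bit/position
  ic <- rowSums(lib$planted1$matrix *
                  log2(pmax(lib$planted1$matrix, 1e-12) / 0.25))
  expect_gt(mean(ic), 1)
})

test_that("family table uses at most 20 labels concentrated in LPS-up genes", {
  cfg <- simulation_config(n_genes = 800, seed = 4)
  truth <- simulate_counts(cfg)$truth
  fam <- make_family_table(truth, cfg)
  expect_lte(length(unique(fam$family)), 20L)
  expect_equal(nrow(fam), cfg$n_family_genes)
  lps_any <- rownames(truth$lps_up)[rowSums(truth$lps_up) > 0]
  expect_gte(mean(fam$gene %in% lps_any), 0.6)
  # empty truth gives an empty table
  cfg0 <- simulation_config(n_genes = 10, n_family_genes = 0, seed = 4)
  truth0 <- simulate_counts(cfg0)$truth
  expect_equal(nrow(make_family_table(truth0, cfg0)), 0L)
})

test_that("invalid module fractions are rejected", {
  expect_error(simulation_config(lps_common_frac = 0.6,
                                 lps_specific_frac = 0.3,
                                 il10_up_frac = 0.2),
               "sum to more than 1")
  expect_error(simulation_config(lps_effect = 1), "> 1")
  expect_error(simulation_config(dispersion = -0.1), ">= 0")
})
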