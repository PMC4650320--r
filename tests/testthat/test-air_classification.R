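# hand-built DE table builder for regulation-call tests
de_row <- function(cell_type, gene, log2fc, qvalue,
                   contrast = "LPS_vs_ctrl") {
  data.frame(cell_type = cell_type, contrast = contrast, gene = gene,
             base_mean = 100, log2fc = log2fc, pvalue = qvalue,
             qvalue = qvalue, tested = TRUE, stringsAsFactors = FALSE)
}

test_that("relaxation marks a significant-elsewhere gene above 1.5-fold", {
  de <- rbind(de_row("macrophage", "g1", log2(4), 0.01),
              de_row("neutrophil", "g1", log2(1.6), 0.3))
  reg <- call_regulation(de)
  neu <- reg[reg$cell_type == "neutrophil", ]
  expect_equal(neu$call, "up")
  expect_equal(neu$basis, "relaxed")
  mac <- reg[reg$cell_type == "macrophage", ]
  expect_equal(mac$call, "up")
  expect_equal(mac$basis, "significant")
})

test_that("relaxation threshold is strict: fold-change exactly 1.5 stays unchanged", {
  de <- rbind(de_row("macrophage", "g1", log2(4), 0.01),
              de_row("neutrophil", "g1", log2(1.5), 0.3))
  reg <- call_regulation(de)
  expect_equal(reg$call[reg$cell_type == "neutrophil"], "unchanged")
})

test_that("without a significant anchor no relaxation happens", {
  de <- rbind(de_row("macrophage", "g1", log2(4), 0.5),
              de_row("neutrophil", "g1", log2(3), 0.4))
  reg <- call_regulation(de)
  expect_true(all(reg$call == "unchanged"))
})

test_that("relaxation requires matching direction", {
  de <- rbind(de_row("macrophage", "g1", log2(4), 0.01),   # sig UP
              de_row("neutrophil", "g1", -log2(3), 0.3))   # strong DOWN
  reg <- call_regulation(de)
  expect_equal(reg$call[reg$cell_type == "neutrophil"], "unchanged")
})

test_that("AIR classification applies the inclusive 2-fold decline rule", {
  expr <- matrix(c(100, 40, 100, 50, 100, 80), 1,
                 dimnames = list("g1", NULL))
  # three scenarios for one gene via separate calls
  mk <- function(lps, il10lps, pc = 1) {
    e <- matrix(c(lps, il10lps), 1,
                dimnames = list("g1", c("macrophage.LPS",
                                        "macrophage.IL10_LPS")))
    classify_air(list(macrophage = "g1"), e,
                 analysis_params(pseudocount = pc))
  }
  # (100+1)/(40+1) = 2.46 -> AIR
  expect_identical(mk(100, 40)$macrophage$air, "g1")
  # ratio exactly 2 with pc = 0 -> AIR (inclusive "at least 2-fold")
  p0 <- mk(100, 50, pc = 0)
  expect_identical(p0$macrophage$air, "g1")
  # (100+1)/(80+1) = 1.25 -> not-AIR
  expect_identical(mk(100, 80)$macrophage$not_air, "g1")
})

test_that("genes outside the LPS-up set are not classified; eosinophils are excluded", {
  e <- matrix(c(100, 10, 100, 10), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("eosinophil.LPS", "eosinophil.IL10_LPS")))
  colnames(e) <- c("eosinophil.LPS", "eosinophil.IL10_LPS")
  part <- classify_air(list(eosinophil = c("g1", "g2")), e)
  expect_length(part, 0L)
  e2 <- matrix(c(100, 10), 1,
               dimnames = list("g1", c("mast.LPS", "mast.IL10_LPS")))
  part2 <- classify_air(list(mast = "g1"), e2)
  expect_false("g2" %in% c(part2$mast$air, part2$mast$not_air))
})

test_that("venn partition enumerates exclusive categories", {
  p <- venn_partition(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                           C = "3"))
  expect_identical(p$categories[["unique-A"]], "1")
  expect_identical(p$categories[["unique-B"]], "4")
  expect_length(p$categories[["unique-C"]], 0L)
  expect_identical(p$categories[["exactly-2"]], "2")
  expect_identical(p$categories[["all-3"]], "3")
  # identical sets put everything in all-k
  p2 <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_setequal(p2$categories[["all-2"]], c("x", "y"))
  expect_equal(sum(p2$counts), p2$n_union)
})

test_that("venn partition matches the brute-force membership oracle", {
  set.seed(19)
  for (i in 1:100) {
    k <- sample(2:5, 1L)
    univ <- sprintf("g%02d", 1:30)
    sets <- setNames(lapply(seq_len(k), function(j)
      sample(univ, sample(0:20, 1L))), LETTERS[seq_len(k)])
    if (!length(unlist(sets))) next
    p <- venn_partition(sets)
    oracle <- brute_venn(sets)
    expect_equal(sum(p$counts), length(unique(unlist(sets))))
    for (nm in names(p$categories)) {
      ref <- if (is.null(oracle[[nm]])) character(0) else oracle[[nm]]
      expect_setequal(p$categories[[nm]], ref)
    }
  }
})

test_that("cell-type-specific AIR removes genes AIR in two or more cell types", {
  part <- structure(list(
    macrophage = list(air = c("a", "b", "c"), not_air = character(0)),
    neutrophil = list(air = c("b", "d"), not_air = character(0)),
    sDC = list(air = c("c", "e"), not_air = character(0))),
    class = "air_partition")
  sp <- celltype_specific_air(part)
  expect_identical(sp$macrophage, "a")
  expect_identical(sp$neutrophil, "d")
  expect_identical(sp$sDC, "e")
})

test_that("cell-type-specific AIR sets are pairwise disjoint on random partitions", {
  set.seed(23)
  for (i in 1:50) {
    univ <- sprintf("g%02d", 1:40)
    part <- structure(lapply(setNames(nm = c("macrophage", "neutrophil",
                                             "sDC", "mast")), function(ct)
      list(air = sample(univ, sample(5:25, 1L)),
           not_air = character(0))), class = "air_partition")
    sp <- celltype_specific_air(part)
    all_g <- unlist(sp, use.names = FALSE)
    expect_false(anyDuplicated(all_g) > 0)
  }
})

test_that("relaxed-target marking is inclusive at 1.5-fold and records missing genes", {
  de <- rbind(de_row("macrophage", "g1", log2(1.5), 0.5, "IL10_vs_ctrl"),
              de_row("macrophage", "g2", log2(1.49), 0.5, "IL10_vs_ctrl"))
  m <- mark_relaxed_targets(de, c("g1", "g2", "g3"))
  expect_true(m["g1", "macrophage"])
  expect_false(m["g2", "macrophage"])
  expect_true(is.na(m["g3", "macrophage"]))
})

test_that("IL-10-up sets recover planted IL-10-induced genes", {
  cfg <- simulation_config(n_genes = 800,
                           cell_types = c("macrophage", "neutrophil"),
                           n_replicates = 3, il10_up_frac = 0.1,
                           il10_effect = 4, seed = 41)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts)
  sets <- il10_up_sets(de)
  planted <- rownames(sim$truth$il10_up)[sim$truth$il10_up[, "macrophage"]]
  sens <- mean(planted %in% sets$macrophage)
  expect_gte(sens, 0.85)
  # empty DE table gives empty sets; all q = 1 gives empty sets
  expect_length(il10_up_sets(de[0, ]), 0L)
  de1 <- de[de$contrast == "IL10_vs_ctrl", ]
  de1$qvalue <- 1
  expect_true(all(lengths(il10_up_sets(de1)) == 0L))
})

test_that("AIR partition invariant holds on a full simulated run", {
  cfg <- simulation_config(n_genes = 500, seed = 51)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts)
  reg <- call_regulation(de)
  lps_up <- regulation_sets(reg, "LPS_vs_ctrl", "up")
  expr <- condition_means(sim$counts, attr(de, "size_factors"))
  part <- classify_air(lps_up, expr, responsive = sim$truth$il10_responsive)
  expect_true(check_air_partition(part, lps_up[names(part)]))
})
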