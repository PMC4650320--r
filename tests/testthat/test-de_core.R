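test_that("median-of-ratios size factors match hand computations", {
  # identical columns -> (1, 1)
  m <- matrix(c(5L, 10L, 20L, 5L, 10L, 20L), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # column b = 2 x column a -> (1/sqrt(2), sqrt(2)) after geomean rescale
  m2 <- matrix(c(5L, 10L, 20L, 10L, 20L, 40L), 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # single sample -> 1
  m3 <- m[, 1L, drop = FALSE]
  expect_equal(unname(size_factors(m3)), 1)
})

test_that("size factors are gene-order invariant, scale-invariant, geomean 1", {
  set.seed(42)
  m <- matrix(rpois(600, 50), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  sf <- size_factors(m)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), sf)
  expect_equal(size_factors(m * 3L), sf, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rnbinom(2000, mu = 80, size = 10) *
                rep(c(1L, 2L, 1L, 3L), each = 500), 500, 4, byrow = FALSE,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:4)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  # tiny discrepancy allowed: the reference takes the median on the log
  # scale, which differs from the ratio-scale median only at even counts
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-5)
})

test_that("dispersion estimation recovers known parameters", {
  # constant counts within groups -> raw alpha 0
  m <- matrix(rep(c(10L, 40L), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  d <- estimate_dispersion(m, rep(1, 4), groups = rep("a", 4))
  expect_equal(unname(d$raw), c(0, 0))
  # Poisson data: median working dispersion stays near zero at n = 6
  set.seed(11)
  mp <- matrix(rpois(3000 * 6, 100), 3000, 6,
               dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:6)))
  dp <- estimate_dispersion(mp, rep(1, 6), groups = rep("a", 6))
  expect_lte(median(dp$shrunk), 0.05)
  # NB alpha = 0.2 at mu = 100, 8 replicates: median raw in [0.1, 0.3]
  set.seed(12)
  mn <- matrix(rnbinom(2000 * 8, mu = 100, size = 5), 2000, 8,
               dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:8)))
  dn <- estimate_dispersion(mn, rep(1, 8), groups = rep("a", 8))
  expect_gte(median(dn$raw), 0.1)
  expect_lte(median(dn$raw), 0.3)
  # all-singleton groups are rejected with guidance
  expect_error(estimate_dispersion(m, rep(1, 4), groups = paste0("g", 1:4)),
               "pooled-null")
})

test_that("contrast swap negates log2fc and preserves p-values", {
  set.seed(3)
  m <- matrix(rnbinom(200 * 6, mu = 60, size = 10), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = rep(c("a", "b"), each = 3))
  ab <- test_contrast(m, sf, d, 1:3, 4:6)
  ba <- test_contrast(m, sf, d, 4:6, 1:3)
  expect_equal(ba$log2fc, -ab$log2fc, tolerance = 1e-12)
  expect_equal(ba$pvalue, ab$pvalue, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(5)
  p <- runif(200)
  q <- p.adjust(p, method = "BH")
  expect_true(all(q >= 0 & q <= 1))
  # q is monotone non-decreasing in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("all-zero genes are flagged untested with p = 1 and log2fc = 0", {
  m <- matrix(c(0L, 0L, 0L, 0L, 5L, 9L, 7L, 6L), 2, 4, byrow = TRUE,
              dimnames = list(c("gz", "gx"), paste0("s", 1:4)))
  res <- test_contrast(m, rep(1, 4), 0.1, 1:2, 3:4)
  expect_false(res$tested[1L])
  expect_equal(res$pvalue[1L], 1)
  expect_equal(res$log2fc[1L], 0)
  expect_true(res$tested[2L])
})

test_that("Wald p-values agree with the exact conditional test within 10x", {
  # small-count two-group cases; the oracle is the conditional binomial
  # given the total (equal size-factor sums)
  cases <- list(c(3, 12), c(5, 15), c(8, 20), c(2, 10), c(10, 25),
                c(4, 4), c(6, 14), c(9, 9), c(1, 8), c(7, 21),
                c(12, 28), c(5, 5), c(3, 9), c(15, 30), c(6, 18),
                c(2, 6), c(10, 10), c(4, 16), c(8, 8), c(5, 20))
  split3 <- function(k) {
    b <- rep(k %/% 3, 3)
    if (k %% 3) b[seq_len(k %% 3)] <- b[seq_len(k %% 3)] + 1L
    b
  }
  for (cs in cases) {
    m <- matrix(c(split3(cs[1L]), split3(cs[2L])), 1, 6,
                dimnames = list("g1", paste0("s", 1:6)))
    wald <- test_contrast(m, rep(1, 6), 0, 1:3, 4:6,
                          exact_max_count = 0)$pvalue
    exact <- binom.test(cs[2L], sum(cs), 0.5)$p.value
    expect_lte(abs(log10(wald / exact)), 1)
  }
})

test_that("exact conditional branch replaces Wald at zero dispersion", {
  m <- matrix(c(1L, 0L, 1L, 4L, 6L, 5L), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  res <- test_contrast(m, rep(1, 6), 0, 1:3, 4:6)
  expect_equal(res$pvalue, binom.test(15, 17, 0.5)$p.value,
               tolerance = 1e-12)
})

test_that("run_de covers all cell types and contrasts with planted recovery", {
  cfg <- simulation_config(n_genes = 400,
                           cell_types = c("macrophage", "neutrophil"),
                           seed = 31)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts)
  expect_setequal(unique(de$contrast),
                  c("LPS_vs_ctrl", "IL10_vs_ctrl", "IL10LPS_vs_LPS"))
  expect_setequal(unique(de$cell_type), c("macrophage", "neutrophil"))
  sub <- de[de$cell_type == "macrophage" & de$contrast == "LPS_vs_ctrl", ]
  up <- sim$truth$lps_up[, "macrophage"]
  sens <- mean(sub$qvalue[up] < 0.1 & sub$log2fc[up] > 0)
  expect_gte(sens, 0.8)
  fpr <- mean(sub$qvalue[!up] < 0.1)
  expect_lte(fpr, 0.05)
})
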