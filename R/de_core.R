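#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of that sample's count to the gene's geometric mean across samples,
#' computed over genes with all-positive counts; the factors are then
#' rescaled to geometric mean 1.  If no gene is positive in every sample,
#' each sample falls back to the genes positive in that sample (geometric
#' means over positive entries).
#'
#' @param cm a [count_matrix()] or a bare counts matrix.
#' @return named numeric vector of positive per-sample multipliers with
#'   geometric mean 1.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    sub <- counts[allpos, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    sf <- apply(sub / gm, 2L, stats::median)
  } else {
    lgm <- apply(counts, 1L, function(r) {
      p <- r[r > 0]
      if (length(p)) mean(log(p)) else NA_real_
    })
    sf <- vapply(seq_len(ncol(counts)), function(s) {
      ok <- counts[, s] > 0 & !is.na(lgm)
      if (!any(ok))
        stop("sample ", colnames(counts)[s],
             " has no positive counts usable for size-factor estimation")
      stats::median(exp(log(counts[ok, s]) - lgm[ok]))
    }, numeric(1L))
    names(sf) <- colnames(counts)
  }
  sf / geomean(sf)
}

#' Method-of-moments dispersion estimation with a conservative trend
#'
#' Per-gene raw dispersion is the pooled method-of-moments estimate from
#' within-group normalized counts, `alpha = max(0, (s2 - m) / m^2)` with
#' `s2` the pooled within-group variance and `m` the mean of group means
#' over groups with at least two replicates.  A mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` is least-squares fitted over genes with base
#' mean above `mean_floor`, and the working (shrunk) dispersion is the
#' maximum of the raw value and the fitted trend, echoing the conservative
#' sharing of classic NB differential-expression tools.
#'
#' @param cm a [count_matrix()] or counts matrix.
#' @param sf size factors from [size_factors()].
#' @param groups factor/character of group labels per sample; defaults to
#'   `cell_type:treatment` when `cm` carries metadata.
#' @param mean_floor minimum base mean for genes entering the trend fit.
#' @return an object of class `dispersion_estimate`: list with `raw`,
#'   `shrunk`, `trend` (a0, a1) and `base_mean` per gene.
#' @export
estimate_dispersion <- function(cm, sf, groups = NULL, mean_floor = 5) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(groups)) {
    if (!inherits(cm, "count_matrix"))
      stop("groups must be given when cm is a bare matrix")
    groups <- interaction(cm$samples$cell_type, cm$samples$treatment,
                          drop = TRUE)
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one label per sample")
  norm <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)

  rep_groups <- names(which(table(groups) >= 2L))
  if (!length(rep_groups))
    stop("no group has >= 2 replicates; dispersion cannot be estimated ",
         "(use a pooled-null design)")
  ssq <- 0; df <- 0; msum <- 0; nm <- 0
  for (g in rep_groups) {
    sub <- norm[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    ssq <- ssq + v * (ncol(sub) - 1L)
    df <- df + (ncol(sub) - 1L)
    msum <- msum + m
    nm <- nm + 1L
  }
  s2 <- ssq / df
  mbar <- msum / nm
  raw <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)

  fit_ok <- base_mean >= mean_floor
  if (sum(fit_ok) >= 10) {
    x <- 1 / mbar[fit_ok]
    co <- stats::coef(stats::lm(raw[fit_ok] ~ x))
    a0 <- max(0, co[[1L]]); a1 <- max(0, co[[2L]])
  } else {
    a0 <- stats::median(raw[raw > 0], na.rm = TRUE)
    if (!is.finite(a0)) a0 <- 0
    a1 <- 0
  }
  trend_val <- a0 + a1 / pmax(mbar, 1e-8)
  shrunk <- pmax(raw, trend_val)
  structure(list(raw = raw, shrunk = shrunk, trend = c(a0 = a0, a1 = a1),
                 base_mean = base_mean),
            class = "dispersion_estimate")
}

# exact conditional two-Poisson test: conditional on the total, counts in
# group B are binomial with probability S_B / (S_A + S_B)
exact_conditional_p <- function(kA, kB, SA, SB) {
  tot <- kA + kB
  if (tot == 0) return(1)
  stats::binom.test(kB, tot, p = SB / (SA + SB))$p.value
}

#' Two-group negative-binomial contrast test
#'
#' Reports, per gene: the normalized base mean, `log2fc =
#' log2((mean_B + pc) / (mean_A + pc))` on normalized condition means, a
#' two-sided p-value from a Wald test of the difference of log means with
#' variance propagated from the working NB dispersion (an exact
#' conditional Poisson/binomial test replaces the Wald test when the
#' working dispersion is zero and total counts are small), and the
#' Benjamini-Hochberg q-value across all tested genes of the contrast.
#' Genes with zero counts in both groups are flagged untested with
#' `p = 1`, `log2fc = 0`.
#'
#' @param cm a [count_matrix()] or counts matrix.
#' @param sf size factors.
#' @param dispersion a `dispersion_estimate` (or a single numeric alpha
#'   recycled to all genes).
#' @param groupA,groupB disjoint character vectors of sample ids (or
#'   column indices): the contrast is B versus A.
#' @param pseudocount pseudocount for the reported fold-change (testing
#'   does not use it).
#' @param exact_max_count largest A+B total count for which the exact
#'   conditional test replaces the Wald test when dispersion is zero;
#'   set 0 to force Wald everywhere.
#' @return data.frame with columns `gene`, `base_mean`, `log2fc`,
#'   `pvalue`, `qvalue`, `tested`.
#' @export
test_contrast <- function(cm, sf, dispersion, groupA, groupB,
                          pseudocount = 1, exact_max_count = 50) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.character(groupA)) groupA <- match(groupA, colnames(counts))
  if (is.character(groupB)) groupB <- match(groupB, colnames(counts))
  if (anyNA(groupA) || anyNA(groupB))
    stop("unknown sample id in contrast groups")
  if (length(intersect(groupA, groupB)))
    stop("contrast groups must be disjoint")
  if (!length(groupA) || !length(groupB))
    stop("contrast groups must be nonempty")
  alpha <- if (inherits(dispersion, "dispersion_estimate"))
    dispersion$shrunk else rep(dispersion, nrow(counts))

  sfA <- sf[groupA]; sfB <- sf[groupB]
  nA <- length(groupA); nB <- length(groupB)
  normA <- sweep(counts[, groupA, drop = FALSE], 2L, sfA, "/")
  normB <- sweep(counts[, groupB, drop = FALSE], 2L, sfB, "/")
  mA <- rowMeans(normA); mB <- rowMeans(normB)
  base_mean <- (nA * mA + nB * mB) / (nA + nB)

  log2fc <- log2((mB + pseudocount) / (mA + pseudocount))
  tested <- rowSums(counts[, c(groupA, groupB), drop = FALSE]) > 0

  # delta-method variance of log group means; means are floored at half a
  # normalized count so genes observed in only one group stay testable
  floor_m <- 0.5
  mAe <- pmax(mA, floor_m); mBe <- pmax(mB, floor_m)
  varA <- (mAe * sum(1 / sfA) / nA^2) + alpha * mAe^2 / nA
  varB <- (mBe * sum(1 / sfB) / nB^2) + alpha * mBe^2 / nB
  z <- (log(mBe) - log(mAe)) / sqrt(varA / mAe^2 + varB / mBe^2)
  pvalue <- 2 * stats::pnorm(-abs(z))

  if (exact_max_count > 0) {
    kA <- rowSums(counts[, groupA, drop = FALSE])
    kB <- rowSums(counts[, groupB, drop = FALSE])
    small <- tested & (alpha < 1e-8) & (kA + kB <= exact_max_count)
    if (any(small)) {
      SA <- sum(sfA); SB <- sum(sfB)
      pvalue[small] <- vapply(which(small), function(g)
        exact_conditional_p(kA[g], kB[g], SA, SB), numeric(1L))
    }
  }

  pvalue[!tested] <- 1
  log2fc[!tested] <- 0
  qvalue <- rep(1, nrow(counts))
  qvalue[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, pvalue = pvalue, qvalue = qvalue,
             tested = tested, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' The study's three within-cell-type contrasts
#' @return data.frame with columns `contrast`, `treatment_A`, `treatment_B`.
#' @export
standard_contrasts <- function() {
  data.frame(contrast = c("LPS_vs_ctrl", "IL10_vs_ctrl",
                          "IL10LPS_vs_LPS"),
             treatment_A = c("ctrl", "ctrl", "LPS"),
             treatment_B = c("LPS", "IL10", "IL10_LPS"),
             stringsAsFactors = FALSE)
}

#' Run all standard contrasts in every cell type
#'
#' Normalizes, estimates dispersion once across all design groups, and
#' tests LPS vs ctrl, IL10 vs ctrl and IL10_LPS vs LPS within each cell
#' type that carries both conditions.
#'
#' @param cm a [count_matrix()].
#' @param params [analysis_params()].
#' @param contrasts contrast table as from [standard_contrasts()].
#' @return an object of class `de_results`: a long data.frame with columns
#'   `cell_type`, `contrast`, `gene`, `base_mean`, `log2fc`, `pvalue`,
#'   `qvalue`, `tested`, carrying the size factors and dispersion as
#'   attributes.
#' @export
run_de <- function(cm, params = analysis_params(),
                   contrasts = standard_contrasts()) {
  stopifnot(inherits(cm, "count_matrix"))
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  out <- list()
  for (ct in unique(cm$samples$cell_type)) {
    for (i in seq_len(nrow(contrasts))) {
      a <- cm$samples$sample_id[cm$samples$cell_type == ct &
                                  cm$samples$treatment ==
                                    contrasts$treatment_A[i]]
      b <- cm$samples$sample_id[cm$samples$cell_type == ct &
                                  cm$samples$treatment ==
                                    contrasts$treatment_B[i]]
      if (!length(a) || !length(b)) next
      res <- test_contrast(cm, sf, disp, a, b,
                           pseudocount = params$pseudocount)
      res$cell_type <- ct
      res$contrast <- contrasts$contrast[i]
      out[[paste(ct, contrasts$contrast[i], sep = ".")]] <- res
    }
  }
  de <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  de <- de[, c("cell_type", "contrast", "gene", "base_mean", "log2fc",
               "pvalue", "qvalue", "tested")]
  attr(de, "size_factors") <- sf
  attr(de, "dispersion") <- disp
  class(de) <- c("de_results", "data.frame")
  de
}

#' Normalized condition means per cell type and treatment
#'
#' @param cm a [count_matrix()].
#' @param sf size factors; computed when `NULL`.
#' @return numeric matrix, genes x `celltype.treatment` columns.
#' @export
condition_means <- function(cm, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2L, sf, "/")
  grp <- paste(cm$samples$cell_type, cm$samples$treatment, sep = ".")
  out <- sapply(unique(grp), function(g)
    rowMeans(norm[, grp == g, drop = FALSE]))
  rownames(out) <- rownames(cm$counts)
  out
}
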