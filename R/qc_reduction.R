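# log2(normalized count + 1), the transformation used by every QC stage
log_norm <- function(cm, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(cm)
  log2(sweep(cm$counts, 2L, sf, "/") + 1)
}

#' Pearson correlation between biological replicates
#'
#' Computes Pearson r on log2(normalized count + 1) for every
#' within-(cell type, treatment) sample pair, with a QC flag for pairs
#' below `r_floor` (replicate correlations of good libraries fall in
#' roughly 0.7-0.9, mostly above 0.8).
#'
#' @param cm a [count_matrix()].
#' @param sf optional size factors.
#' @param r_floor QC threshold (default 0.7).
#' @return data.frame: `cell_type`, `treatment`, `sample_a`, `sample_b`,
#'   `r`, `flag_low`; zero rows (with a warning) when no group is
#'   replicated.
#' @export
replicate_correlation <- function(cm, sf = NULL, r_floor = 0.7) {
  ln <- log_norm(cm, sf)
  out <- list()
  grp <- paste(cm$samples$cell_type, cm$samples$treatment, sep = ".")
  for (g in unique(grp)) {
    ids <- cm$samples$sample_id[grp == g]
    if (length(ids) < 2L) next
    prs <- utils::combn(ids, 2L)
    for (j in seq_len(ncol(prs))) {
      r <- stats::cor(ln[, prs[1L, j]], ln[, prs[2L, j]])
      meta <- cm$samples[cm$samples$sample_id == prs[1L, j], ]
      out[[paste(g, j)]] <-
        data.frame(cell_type = meta$cell_type,
                   treatment = meta$treatment,
                   sample_a = prs[1L, j], sample_b = prs[2L, j], r = r,
                   flag_low = r < r_floor, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no replicated (cell_type, treatment) group; ",
            "replicate correlation not computable")
    return(data.frame(cell_type = character(0), treatment = character(0),
                      sample_a = character(0), sample_b = character(0),
                      r = numeric(0), flag_low = logical(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pairwise coefficient-of-determination matrix with clustering order
#'
#' R-squared is the squared Pearson correlation of log2(normalized + 1)
#' expression between sample pairs; samples are then average-linkage
#' clustered on the 1 - R^2 distance.  Constant samples yield `NA`
#' entries, recorded in `$missing`.
#'
#' @param cm a [count_matrix()].
#' @param sf optional size factors.
#' @return list with `r2` (samples x samples), `order` (leaf order of the
#'   clustering), `hclust`, and `missing` (constant samples).
#' @export
r2_matrix <- function(cm, sf = NULL) {
  if (ncol(cm$counts) < 3L) stop("r2_matrix needs at least 3 samples")
  ln <- log_norm(cm, sf)
  const <- apply(ln, 2L, function(x) stats::sd(x) == 0)
  r2 <- suppressWarnings(stats::cor(ln))^2
  diag(r2) <- 1
  usable <- !const
  hc <- NULL; ord <- colnames(ln)
  if (sum(usable) >= 2L) {
    d <- stats::as.dist(1 - r2[usable, usable, drop = FALSE])
    hc <- stats::hclust(d, method = "average")
    ord <- colnames(ln)[usable][hc$order]
  }
  list(r2 = r2, order = ord, hclust = hc,
       missing = colnames(ln)[const])
}

#' PCA of expression libraries with treatment-axis detection
#'
#' Runs PCA on centered log2(normalized + 1) expression over the
#' expressed gene set, reports explained-variance fractions, scores and
#' loadings (sign-fixed so the largest-magnitude loading of each
#' component is positive), and, for every component, the point-biserial
#' correlation of its scores with the LPS indicator (treatment LPS or
#' IL10_LPS) and with the IL-10 indicator (IL10 or IL10_LPS).  The
#' treatment axis is the lowest-index component whose absolute LPS
#' correlation exceeds `axis_cor_threshold`; `NA` when none does.  No
#' IL-10 axis is forced: IL-10 correlations are reported for all
#' components and its absence is an observable outcome.
#'
#' @param cm a [count_matrix()].
#' @param sf optional size factors.
#' @param params [analysis_params()].
#' @param n_top number of top-loading genes reported for the treatment
#'   axis.
#' @return an object of class `pca_result`: list with `scores`,
#'   `loadings`, `explained`, `association` (per-component LPS/IL-10
#'   correlations), `lps_axis`, `il10_axis`, `top_genes`.
#' @export
pca_treatment_axis <- function(cm, sf = NULL, params = analysis_params(),
                               n_top = 50) {
  if (is.null(sf)) sf <- size_factors(cm)
  ln <- log_norm(cm, sf)
  expressed <- rowMeans(sweep(cm$counts, 2L, sf, "/")) >=
    params$expression_floor
  x <- t(ln[expressed, , drop = FALSE])
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- ncol(pc$x)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  lps_ind <- as.numeric(cm$samples$treatment %in% c("LPS", "IL10_LPS"))
  il10_ind <- as.numeric(cm$samples$treatment %in% c("IL10", "IL10_LPS"))
  pb <- function(ind, j) {
    if (stats::sd(ind) == 0 || stats::sd(pc$x[, j]) == 0)
      return(NA_real_)
    stats::cor(pc$x[, j], ind)
  }
  assoc <- data.frame(component = seq_len(k),
                      explained = expl[seq_len(k)],
                      r_lps = vapply(seq_len(k), pb, numeric(1L),
                                     ind = lps_ind),
                      r_il10 = vapply(seq_len(k), pb, numeric(1L),
                                      ind = il10_ind))
  hit <- which(abs(assoc$r_lps) > params$axis_cor_threshold)
  lps_axis <- if (length(hit)) min(hit) else NA_integer_
  hit10 <- which(abs(assoc$r_il10) > params$axis_cor_threshold)
  il10_axis <- if (length(hit10)) min(hit10) else NA_integer_
  top_genes <- if (!is.na(lps_axis)) {
    ld <- pc$rotation[, lps_axis]
    names(sort(abs(ld), decreasing = TRUE))[seq_len(min(n_top,
                                                        length(ld)))]
  } else character(0)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = expl, association = assoc,
                 lps_axis = lps_axis, il10_axis = il10_axis,
                 top_genes = top_genes, center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("LPS axis:", ifelse(is.na(x$lps_axis), "none",
                          paste0("PC", x$lps_axis)),
      " IL-10 axis:", ifelse(is.na(x$il10_axis), "none",
                             paste0("PC", x$il10_axis)), "\n")
  invisible(x)
}
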