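#' Family fold-change distribution versus the transcriptome
#'
#' For one contrast in one cell type, compares the log2 fold-changes of a
#' cytokine family's expressed members against all other expressed genes
#' by a two-sided Mann-Whitney U test, with significance flags at the two
#' `mwu_alpha` levels.  "Expressed" means normalized base mean at or
#' above `expression_floor`.  Families with fewer than 3 expressed
#' members are not computed (recorded with `p = NA`).
#'
#' @param de_contrast rows of a `de_results` table for a single
#'   (cell type, contrast).
#' @param families data.frame with columns `gene`, `family`.
#' @param family family label to test.
#' @param params [analysis_params()].
#' @return list with `family`, `n`, `median_lfc`, `mean_lfc`, `U`, `p`,
#'   `sig_05`, `sig_01`, `computed`.
#' @export
family_fc_test <- function(de_contrast, families, family,
                           params = analysis_params()) {
  expressed <- de_contrast[de_contrast$base_mean >=
                             params$expression_floor, , drop = FALSE]
  members <- families$gene[families$family == family]
  in_fam <- expressed$gene %in% members
  x <- expressed$log2fc[in_fam]
  y <- expressed$log2fc[!in_fam]
  res <- list(family = family, n = length(x),
              median_lfc = stats::median(x), mean_lfc = mean(x))
  if (length(x) < 3L || length(y) < 1L) {
    res$U <- NA_real_; res$p <- NA_real_
    res$sig_05 <- NA; res$sig_01 <- NA; res$computed <- FALSE
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided"))
  res$U <- unname(wt$statistic); res$p <- wt$p.value
  res$sig_05 <- res$p < params$mwu_alpha[1L]
  res$sig_01 <- res$p < params$mwu_alpha[2L]
  res$computed <- TRUE
  res
}

#' Family-annotated genes up-regulated in several cell types
#'
#' Selects family-annotated genes with an `up` call in at least
#' `min_celltypes` cell types for the given contrast, ordered by overall
#' fold-change, defined as the mean per-cell-type log2 fold-change,
#' descending.
#'
#' @param regulation a `regulation_table`.
#' @param families data.frame with columns `gene`, `family`.
#' @param min_celltypes minimum number of cell types with an `up` call
#'   (default 2).
#' @param contrast contrast name (default `"LPS_vs_ctrl"`).
#' @return data.frame: `gene`, `family`, `n_celltypes_up`, `overall_lfc`,
#'   ordered by `overall_lfc` descending.
#' @export
shared_cytokines <- function(regulation, families, min_celltypes = 2,
                             contrast = "LPS_vs_ctrl") {
  sub <- regulation[regulation$contrast == contrast, , drop = FALSE]
  sub <- sub[sub$gene %in% families$gene, , drop = FALSE]
  up <- sub[sub$call == "up", , drop = FALSE]
  n_up <- table(up$gene)
  keep <- names(n_up)[n_up >= min_celltypes]
  if (!length(keep))
    return(data.frame(gene = character(0), family = character(0),
                      n_celltypes_up = integer(0),
                      overall_lfc = numeric(0), stringsAsFactors = FALSE))
  lfc <- tapply(sub$log2fc[sub$gene %in% keep],
                sub$gene[sub$gene %in% keep], mean)
  out <- data.frame(gene = keep,
                    family = families$family[match(keep, families$gene)],
                    n_celltypes_up = as.integer(n_up[keep]),
                    overall_lfc = as.numeric(lfc[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$overall_lfc, out$gene), , drop = FALSE]
}

#' Transcription-factor family expression-change summary
#'
#' For configured TF families (e.g. Irf and Nfkb gene lists), reports each
#' member's log2 fold-change for a contrast (default the IL-10 suppression
#' contrast, IL10_LPS vs LPS) in every cell type, the family median, and a
#' down-flag when the median linear fold-change is below `1 / relax_fc`.
#' Members absent from the DE tables are listed in `$missing`.
#'
#' @param de a `de_results` table.
#' @param gene_families named list of gene id vectors (e.g.
#'   `list(Irf = ..., Nfkb = ...)`).
#' @param params [analysis_params()].
#' @param contrast contrast name.
#' @return list with `members` (long data.frame), `summary` (per family
#'   per cell type median and down-flag) and `missing`.
#' @export
tf_family_changes <- function(de, gene_families,
                              params = analysis_params(),
                              contrast = "IL10LPS_vs_LPS") {
  if (!length(gene_families) ||
      any(!vapply(gene_families, length, integer(1L))))
    stop("every TF family must contain at least one gene")
  sub <- de[de$contrast == contrast, , drop = FALSE]
  if (!nrow(sub)) stop("contrast ", contrast, " absent from DE results")
  members <- list(); summaries <- list(); missing <- list()
  for (fam in names(gene_families)) {
    genes <- gene_families[[fam]]
    for (ct in unique(sub$cell_type)) {
      s <- sub[sub$cell_type == ct, ]
      i <- match(genes, s$gene)
      found <- !is.na(i)
      if (any(!found))
        missing[[paste(fam, ct)]] <-
          data.frame(family = fam, cell_type = ct,
                     gene = genes[!found], stringsAsFactors = FALSE)
      if (!any(found)) next
      lfc <- s$log2fc[i[found]]
      members[[paste(fam, ct)]] <-
        data.frame(family = fam, cell_type = ct, gene = genes[found],
                   log2fc = lfc, stringsAsFactors = FALSE)
      med <- stats::median(lfc)
      summaries[[paste(fam, ct)]] <-
        data.frame(family = fam, cell_type = ct, n = sum(found),
                   median_log2fc = med,
                   down_flag = 2^med < 1 / params$relax_fc,
                   stringsAsFactors = FALSE)
    }
  }
  list(members = if (length(members))
         do.call(rbind, c(members, list(make.row.names = FALSE)))
       else NULL,
       summary = if (length(summaries))
         do.call(rbind, c(summaries, list(make.row.names = FALSE)))
       else NULL,
       missing = if (length(missing))
         do.call(rbind, c(missing, list(make.row.names = FALSE)))
       else NULL)
}
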