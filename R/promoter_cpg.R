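#' Extract strand-oriented promoter windows around the TSS
#'
#' With the default geometry the window spans `[TSS - 450, TSS + 50)`
#' (0-based, half-open) in gene orientation: for `+` genes the contig
#' substring `[tss - 450, tss + 50)`, for `-` genes the reverse complement
#' of `[tss - 49, tss + 451)`.  Windows truncated at contig edges are
#' flagged and carry `NA` sequence; downstream statistics exclude them.
#'
#' @param promoters a `promoter_set` from [read_promoters()] or
#'   [simulate_promoters()].
#' @param params [analysis_params()].
#' @return an object of class `promoter_windows`: data.frame with columns
#'   `gene`, `sequence` (length `promoter_upstream +
#'   promoter_downstream`, 5'->3' of the gene) and `truncated`.
#' @export
extract_windows <- function(promoters, params = analysis_params()) {
  ann <- promoters$annot
  up <- params$promoter_upstream; down <- params$promoter_downstream
  seqs <- promoters$sequences
  n <- nrow(ann)
  sequence <- rep(NA_character_, n)
  truncated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    contig <- seqs[[ann$sequence_id[i]]]
    L <- nchar(contig)
    tss <- ann$tss[i]
    if (ann$strand[i] == "+") {
      a <- tss - up; b <- tss + down          # 0-based [a, b)
    } else {
      a <- tss - down + 1L; b <- tss + up + 1L
    }
    if (a < 0L || b > L) {
      truncated[i] <- TRUE
      next
    }
    w <- substr(contig, a + 1L, b)
    if (ann$strand[i] == "-") w <- revcomp(w)
    sequence[i] <- w
  }
  structure(data.frame(gene = ann$gene, sequence = sequence,
                       truncated = truncated, stringsAsFactors = FALSE),
            class = c("promoter_windows", "data.frame"))
}

#' Count CG dinucleotides in promoter windows
#'
#' Counts positions `i` with `seq[i] == "C"` and `seq[i+1] == "G"`; pairs
#' containing `N` never count.  (CG is its own reverse complement at the
#' dinucleotide level, so the count is strand-symmetric.)
#'
#' @param x character vector of sequences, or a `promoter_windows` object
#'   (truncated windows yield `NA`).
#' @return integer vector of CG counts.
#' @export
cg_count <- function(x) {
  if (inherits(x, "promoter_windows")) {
    out <- rep(NA_integer_, nrow(x))
    ok <- !x$truncated & !is.na(x$sequence)
    out[ok] <- cg_count(x$sequence[ok])
    names(out) <- x$gene
    return(out)
  }
  if (!length(x)) return(integer(0))
  Biostrings::vcountPattern("CG", Biostrings::DNAStringSet(x))
}

#' Compare promoter CpG content between AIR and not-AIR genes
#'
#' Reports per-group mean CG counts per promoter and a two-sided
#' Mann-Whitney U test between the AIR and not-AIR distributions (exact
#' for small untied samples; normal approximation with tie and continuity
#' correction otherwise), with significance flags at the two `mwu_alpha`
#' levels.  The CpG-island-like reference frequency (`cpg_ref_freq`,
#' default 0.75) is echoed for display.  Groups smaller than 3 yield
#' `p = NA` (not computed).
#'
#' @param air_counts,notair_counts numeric CG counts per promoter for the
#'   two groups (`NA` dropped).
#' @param background_counts optional CG counts of the whole promoter
#'   universe, summarized alongside.
#' @param params [analysis_params()].
#' @return list with means, group sizes, `U`, `p`, significance flags and
#'   the reference frequency.
#' @export
cpg_compare <- function(air_counts, notair_counts,
                        background_counts = NULL,
                        params = analysis_params()) {
  air_counts <- air_counts[!is.na(air_counts)]
  notair_counts <- notair_counts[!is.na(notair_counts)]
  res <- list(n_air = length(air_counts),
              n_not_air = length(notair_counts),
              mean_air = mean(air_counts),
              mean_not_air = mean(notair_counts),
              mean_background = if (!is.null(background_counts))
                mean(background_counts, na.rm = TRUE) else NA_real_,
              cpg_ref_freq = params$cpg_ref_freq)
  if (length(air_counts) < 3L || length(notair_counts) < 3L) {
    res$U <- NA_real_; res$p <- NA_real_
    res$sig_05 <- NA; res$sig_01 <- NA
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(air_counts, notair_counts,
                                            alternative = "two.sided"))
  res$U <- unname(wt$statistic)
  res$p <- wt$p.value
  res$sig_05 <- res$p < params$mwu_alpha[1L]
  res$sig_01 <- res$p < params$mwu_alpha[2L]
  res
}

#' CpG comparison across an AIR partition
#'
#' Runs [cpg_compare()] for every cell type of an `air_partition` against
#' the full promoter universe.
#'
#' @param partition an `air_partition`.
#' @param windows a `promoter_windows` object covering the analysis
#'   universe.
#' @param params [analysis_params()].
#' @return data.frame with one row per cell type.
#' @export
cpg_compare_partition <- function(partition, windows,
                                  params = analysis_params()) {
  counts <- cg_count(windows)
  out <- list()
  for (ct in names(partition)) {
    cc <- cpg_compare(counts[intersect(partition[[ct]]$air,
                                       names(counts))],
                      counts[intersect(partition[[ct]]$not_air,
                                       names(counts))],
                      counts, params)
    out[[ct]] <- data.frame(cell_type = ct, n_air = cc$n_air,
                            n_not_air = cc$n_not_air,
                            mean_air = cc$mean_air,
                            mean_not_air = cc$mean_not_air,
                            mean_background = cc$mean_background,
                            U = cc$U, p = cc$p, sig_05 = cc$sig_05,
                            sig_01 = cc$sig_01,
                            cpg_ref_freq = cc$cpg_ref_freq,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
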