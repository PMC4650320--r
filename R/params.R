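#' Known cell types and treatments
#'
#' The five myeloid cell types and four treatment conditions of the study
#' design: untreated control, IL-10 alone (4 h), LPS alone (4 h), and IL-10
#' pre-treatment followed by LPS ("IL10_LPS").
#'
#' @name design-constants
#' @keywords internal
NULL

CELL_TYPES <- c("macrophage", "neutrophil", "sDC", "mast", "eosinophil")
TREATMENTS <- c("ctrl", "IL10", "LPS", "IL10_LPS")

#' Analysis parameters
#'
#' Container for the thresholds used throughout the pipeline.
#'
#' @param q_threshold BH q-value significance cutoff for differential
#'   expression calls (default 0.1).
#' @param relax_fc linear fold-change for the cross-cell-type relaxation rule:
#'   a gene significant in one cell type is marked regulated in another when
#'   its fold-change there is strictly greater than this (default 1.5).
#' @param air_fc linear fold-change for AIR classification: an LPS-induced
#'   gene is AIR when its expression declines at least this much (inclusive)
#'   upon IL-10 pre-treatment (default 2).
#' @param promoter_upstream,promoter_downstream promoter window extent in bp
#'   around the TSS (defaults 450 and 50, i.e. a 500 bp window).
#' @param cpg_ref_freq display reference for CpG-island-like CG frequency
#'   (default 0.75); echoed in summaries, never used as a classifier.
#' @param pseudocount added to normalized condition means when forming
#'   fold-change ratios so that ratios stay finite (default 1).
#' @param mwu_alpha two significance flags for Mann-Whitney comparisons
#'   (default c(0.05, 0.01)).
#' @param expression_floor minimum normalized base mean for a gene to count
#'   as "expressed" in family and PCA analyses (default 5).
#' @param axis_cor_threshold absolute point-biserial correlation above which
#'   a principal component is called a treatment axis (default 0.7).
#'
#' @return an object of class `analysis_params` (a validated list).
#' @export
analysis_params <- function(q_threshold = 0.1,
                            relax_fc = 1.5,
                            air_fc = 2,
                            promoter_upstream = 450,
                            promoter_downstream = 50,
                            cpg_ref_freq = 0.75,
                            pseudocount = 1,
                            mwu_alpha = c(0.05, 0.01),
                            expression_floor = 5,
                            axis_cor_threshold = 0.7) {
  p <- list(q_threshold = q_threshold, relax_fc = relax_fc, air_fc = air_fc,
            promoter_upstream = promoter_upstream,
            promoter_downstream = promoter_downstream,
            cpg_ref_freq = cpg_ref_freq, pseudocount = pseudocount,
            mwu_alpha = mwu_alpha, expression_floor = expression_floor,
            axis_cor_threshold = axis_cor_threshold)
  num <- c("q_threshold", "relax_fc", "air_fc", "promoter_upstream",
           "promoter_downstream", "cpg_ref_freq", "pseudocount",
           "expression_floor", "axis_cor_threshold")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("analysis_params: '", f, "' must be a single finite number")
  }
  if (p$q_threshold <= 0 || p$q_threshold > 1)
    stop("analysis_params: q_threshold must be in (0, 1]")
  if (p$relax_fc <= 0 || p$air_fc <= 0)
    stop("analysis_params: fold-change thresholds must be > 0")
  if (p$promoter_upstream < 0 || p$promoter_downstream < 0 ||
      p$promoter_upstream + p$promoter_downstream <= 0)
    stop("analysis_params: promoter window must have positive length")
  if (length(p$mwu_alpha) != 2L || any(p$mwu_alpha <= 0 | p$mwu_alpha >= 1))
    stop("analysis_params: mwu_alpha must be two probabilities")
  p$window_length <- p$promoter_upstream + p$promoter_downstream
  structure(p, class = "analysis_params")
}

# deterministic per-stage substream seed: the global seed plus a stable hash
# of the stage name, kept below .Machine$integer.max so set.seed() accepts it
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) + h * 1009) %% 2147483647L)
}

# short stable hash of an R object (FNV-1a over its deparsed form), used to
# stamp outputs with the configuration they came from
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((h + ch) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

geomean <- function(x) exp(mean(log(x)))
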