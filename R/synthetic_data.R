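#' Simulation configuration
#'
#' Defines the study design emulated by the count simulator: 5 myeloid cell
#' types x 4 treatments x 2 biological replicates of negative-binomial gene
#' counts, with planted gene modules (a shared LPS-induced module,
#' cell-type-specific LPS modules, IL-10-suppressed AIR subsets of the
#' LPS-induced genes, IL-10-induced genes, and cell-identity modules), plus
#' promoter CpG classes and planted motifs.
#'
#' Eosinophils do not mount an IL-10 response (`il10_responsive` default);
#' their AIR and IL-10 effects are disabled.
#'
#' @param n_genes number of genes.
#' @param cell_types,treatments subsets of the supported design levels.
#' @param n_replicates biological replicates per condition (default 2).
#' @param baseline_mean_range NB baseline mean range; baselines are drawn
#'   log-uniformly within it.
#' @param dispersion NB dispersion alpha, `var = mu + alpha * mu^2`
#'   (single value for all genes; 0 gives Poisson counts).
#' @param lps_common_frac fraction of genes LPS-induced in every cell type.
#' @param lps_specific_frac total fraction of genes LPS-induced in exactly
#'   one cell type (split evenly across cell types).
#' @param air_frac_of_lps fraction of each cell type's LPS-up genes that are
#'   IL-10-suppressed (AIR) there.
#' @param il10_up_frac fraction of genes induced by IL-10 in all responsive
#'   cell types.
#' @param celltype_frac total fraction of genes forming cell-identity
#'   modules (elevated baseline in exactly one cell type, all treatments).
#' @param lps_effect,air_suppression,il10_effect,celltype_effect linear
#'   fold-changes of the planted modules (all > 1; `air_suppression` divides
#'   the mean in the IL10_LPS condition).
#' @param air_mode `"specific"` plants largely disjoint per-cell-type AIR
#'   sets (the structure the divergence analysis detects); `"shared"` plants
#'   one AIR set common to all responsive cell types.
#' @param library_size_factors per-sample depth multipliers; `NULL` draws
#'   them log-normally (sdlog 0.15) from the seed substream.
#' @param il10_responsive named logical per cell type; defaults to `TRUE`
#'   everywhere except eosinophil.
#' @param cpg_rich_rate,cpg_poor_rate CG-dinucleotide block probabilities of
#'   the promoter generator's rich and poor classes.
#' @param cpg_rich_prob probability that a non-AIR gene is CpG-rich (AIR
#'   genes are always CpG-poor).
#' @param promoter_pad bp of flanking sequence added on each side of the
#'   promoter window in simulated contigs.
#' @param planted_consensus consensus sequence embedded in AIR-gene
#'   promoters (an NF-kB-like decamer by default).
#' @param n_decoy_pwms decoy motifs in the simulated PWM library.
#' @param n_family_genes genes receiving a cytokine-family label.
#' @param seed integer seed; every stage derives its own substream from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              cell_types = CELL_TYPES,
                              treatments = TREATMENTS,
                              n_replicates = 2,
                              baseline_mean_range = c(20, 200),
                              dispersion = 0.1,
                              lps_common_frac = 0.10,
                              lps_specific_frac = 0.10,
                              air_frac_of_lps = 0.30,
                              il10_up_frac = 0.05,
                              celltype_frac = 0.15,
                              lps_effect = 6,
                              air_suppression = 4,
                              il10_effect = 4,
                              celltype_effect = 8,
                              air_mode = c("specific", "shared"),
                              library_size_factors = NULL,
                              il10_responsive = NULL,
                              cpg_rich_rate = 0.15,
                              cpg_poor_rate = 0.01,
                              cpg_rich_prob = 0.6,
                              promoter_pad = 100,
                              planted_consensus = "GGGACTTTCC",
                              n_decoy_pwms = 9,
                              n_family_genes = 150,
                              seed = 1) {
  air_mode <- match.arg(air_mode)
  cell_types <- match.arg(cell_types, CELL_TYPES, several.ok = TRUE)
  treatments <- match.arg(treatments, TREATMENTS, several.ok = TRUE)
  if (is.null(il10_responsive))
    il10_responsive <- stats::setNames(cell_types != "eosinophil",
                                       cell_types)
  fr <- c(lps_common_frac, lps_specific_frac, il10_up_frac, celltype_frac)
  if (any(fr < 0 | fr > 1) || air_frac_of_lps < 0 || air_frac_of_lps > 1)
    stop("module fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop("module fractions sum to more than 1")
  eff <- c(lps_effect, air_suppression, il10_effect, celltype_effect)
  if (any(eff <= 1)) stop("planted effects must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              treatments = treatments,
              n_replicates = as.integer(n_replicates),
              baseline_mean_range = baseline_mean_range,
              dispersion = dispersion,
              lps_common_frac = lps_common_frac,
              lps_specific_frac = lps_specific_frac,
              air_frac_of_lps = air_frac_of_lps,
              il10_up_frac = il10_up_frac, celltype_frac = celltype_frac,
              lps_effect = lps_effect, air_suppression = air_suppression,
              il10_effect = il10_effect, celltype_effect = celltype_effect,
              air_mode = air_mode,
              library_size_factors = library_size_factors,
              il10_responsive = il10_responsive,
              cpg_rich_rate = cpg_rich_rate, cpg_poor_rate = cpg_poor_rate,
              cpg_rich_prob = cpg_rich_prob,
              promoter_pad = as.integer(promoter_pad),
              planted_consensus = toupper(planted_consensus),
              n_decoy_pwms = as.integer(n_decoy_pwms),
              n_family_genes = as.integer(n_family_genes),
              seed = as.integer(seed))
  structure(cfg, class = "simulation_config")
}

# assign planted module membership; returns the ground-truth object
build_truth <- function(config) {
  ng <- config$n_genes
  cts <- config$cell_types
  genes <- sprintf("gene%04d", seq_len(ng))
  mk <- function() matrix(FALSE, ng, length(cts),
                          dimnames = list(genes, cts))
  lps_up <- mk(); air <- mk(); il10_up <- mk()
  celltype_gene <- mk()

  n_common <- round(config$lps_common_frac * ng)
  n_specific <- round(config$lps_specific_frac * ng)
  n_il10 <- round(config$il10_up_frac * ng)
  n_ident <- round(config$celltype_frac * ng)

  idx <- seq_len(ng)
  common <- idx[seq_len(n_common)]
  specific_pool <- idx[n_common + seq_len(n_specific)]
  il10_pool <- idx[n_common + n_specific + seq_len(n_il10)]
  ident_pool <- idx[n_common + n_specific + n_il10 + seq_len(n_ident)]

  spec_by_ct <- split_even(specific_pool, length(cts))
  ident_by_ct <- split_even(ident_pool, length(cts))
  resp <- config$il10_responsive[cts]

  for (k in seq_along(cts)) {
    lps_up[common, k] <- TRUE
    lps_up[spec_by_ct[[k]], k] <- TRUE
    celltype_gene[ident_by_ct[[k]], k] <- TRUE
    if (resp[k]) il10_up[il10_pool, k] <- TRUE
  }

  # AIR subsets: always a subset of the cell type's LPS-up genes, and only
  # in IL-10-responsive cell types
  resp_idx <- which(resp)
  if (config$air_mode == "shared") {
    n_air <- round(config$air_frac_of_lps *
                     (n_common + length(spec_by_ct[[1L]])))
    shared_air <- common[seq_len(min(n_air, length(common)))]
    for (k in resp_idx) air[shared_air, k] <- TRUE
  } else {
    # disjoint per-cell-type AIR: the cell type's own specific module plus a
    # private slice of the common module
    slices <- split_even(common, length(resp_idx))
    for (j in seq_along(resp_idx)) {
      k <- resp_idx[j]
      n_lps_k <- n_common + length(spec_by_ct[[k]])
      n_air_k <- round(config$air_frac_of_lps * n_lps_k)
      take <- c(spec_by_ct[[k]],
                slices[[j]][seq_len(max(0L, min(n_air_k -
                  length(spec_by_ct[[k]]), length(slices[[j]]))))])
      air[take, k] <- TRUE
    }
  }

  # promoter CpG class: AIR genes are CpG-poor; the rest of the
  # transcriptome is mostly CpG-rich, as for mammalian promoters
  air_any <- rowSums(air) > 0
  cpg <- rep("poor", ng)
  rich_draw <- stats::runif(ng) < config$cpg_rich_prob
  cpg[!air_any & rich_draw] <- "rich"

  planted_motif <- rep(NA_character_, ng)
  planted_motif[air_any] <- "planted1"

  structure(list(genes = genes, lps_up = lps_up, air = air,
                 il10_up = il10_up, celltype_gene = celltype_gene,
                 cpg_class = stats::setNames(cpg, genes),
                 planted_motif = stats::setNames(planted_motif, genes),
                 il10_responsive = resp),
            class = "ground_truth")
}

split_even <- function(x, k) {
  if (!length(x)) return(rep(list(integer(0)), k))
  split(x, factor(rep(seq_len(k), length.out = length(x)),
                  levels = seq_len(k)))
}

#' Simulate a count matrix with planted regulatory modules
#'
#' Counts are drawn as `NB(sf_s * mu_{g,c,t}, alpha)` where the mean
#' multiplies the gene baseline by `lps_effect` when the gene is LPS-up in
#' the cell type and the treatment includes LPS, divides by
#' `air_suppression` when the gene is AIR there and the treatment is
#' IL10_LPS, multiplies by `il10_effect` when the gene is IL-10-induced and
#' the treatment includes IL-10, and multiplies by `celltype_effect` for
#' cell-identity genes.  Identical configurations (including the seed)
#' give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (the
#'   `ground_truth` object: logical gene x cell-type matrices `lps_up`,
#'   `air`, `il10_up`, plus promoter CpG classes and planted-motif labels).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "counts"))
  truth <- build_truth(config)
  ng <- config$n_genes
  cts <- config$cell_types
  trs <- config$treatments
  nrep <- config$n_replicates

  r <- log(config$baseline_mean_range)
  baseline <- exp(stats::runif(ng, r[1L], r[2L]))

  samples <- expand.grid(replicate = seq_len(nrep), treatment = trs,
                         cell_type = cts, stringsAsFactors = FALSE)
  samples <- samples[, c("cell_type", "treatment", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$cell_type,
                               samples$treatment, samples$replicate)
  ns <- nrow(samples)
  sf <- config$library_size_factors
  if (is.null(sf)) sf <- exp(stats::rnorm(ns, 0, 0.15))
  if (length(sf) != ns) stop("library_size_factors must have one value per sample")

  counts <- matrix(0L, ng, ns, dimnames = list(truth$genes,
                                               samples$sample_id))
  for (s in seq_len(ns)) {
    ct <- samples$cell_type[s]; tr <- samples$treatment[s]
    mu <- baseline
    mu <- mu * ifelse(truth$celltype_gene[, ct], config$celltype_effect, 1)
    if (tr %in% c("LPS", "IL10_LPS"))
      mu <- mu * ifelse(truth$lps_up[, ct], config$lps_effect, 1)
    if (tr == "IL10_LPS")
      mu <- mu / ifelse(truth$air[, ct], config$air_suppression, 1)
    if (tr %in% c("IL10", "IL10_LPS"))
      mu <- mu * ifelse(truth$il10_up[, ct], config$il10_effect, 1)
    mu <- mu * sf[s]
    counts[, s] <- if (config$dispersion > 0)
      stats::rnbinom(ng, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(ng, mu)
  }
  list(counts = count_matrix(counts,
                             samples[, c("sample_id", "cell_type",
                                         "treatment", "replicate")]),
       truth = truth)
}

# sample n promoter windows of length len with a given CG-block rate:
# each sequence is len/2 iid dinucleotide blocks, where the CG block has
# probability `cg_rate` and the remaining mass is spread over the other
# 15 dinucleotides
sample_promoter_windows <- function(n, len, cg_rate) {
  stopifnot(len %% 2L == 0L)
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  pr <- rep((1 - cg_rate) / 15, 16)
  pr[dinucs == "CG"] <- cg_rate
  nblock <- len %/% 2L
  blocks <- sample(dinucs, n * nblock, replace = TRUE, prob = pr)
  apply(matrix(blocks, nblock, n), 2L, paste, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate promoter contigs matching a ground truth
#'
#' Generates one contig per gene containing a promoter window of length
#' `promoter_upstream + promoter_downstream` with class-controlled CpG
#' density (CpG-rich windows have a strongly elevated CG dinucleotide
#' rate), flanked by `promoter_pad` bp on each side.  Genes carrying a
#' planted motif get one exact copy of the consensus embedded at a uniform
#' random offset within the window.  Strands are assigned at random; for
#' `-` genes the contig stores the reverse complement of the window so
#' that strand-aware extraction is exercised.
#'
#' @param truth a `ground_truth` from [simulate_counts()].
#' @param config the [simulation_config()].
#' @param params [analysis_params()] supplying the window geometry.
#' @return a `promoter_set` (see [read_promoters()]).
#' @export
simulate_promoters <- function(truth, config, params = analysis_params()) {
  set.seed(stage_seed(config$seed, "promoters"))
  len <- params$window_length
  if (len %% 2L != 0L) stop("promoter window length must be even")
  pad <- config$promoter_pad
  genes <- truth$genes
  n <- length(genes)

  rate <- ifelse(truth$cpg_class[genes] == "rich",
                 config$cpg_rich_rate, config$cpg_poor_rate)
  windows <- character(n)
  for (cls in unique(rate)) {
    i <- which(rate == cls)
    windows[i] <- sample_promoter_windows(length(i), len, cls)
  }

  motif <- config$planted_consensus
  has_motif <- !is.na(truth$planted_motif[genes])
  if (any(has_motif)) {
    w <- nchar(motif)
    off <- sample.int(len - w + 1L, sum(has_motif), replace = TRUE)
    windows[has_motif] <- mapply(function(s, o) {
      substr(s, o, o + w - 1L) <- motif
      s
    }, windows[has_motif], off, USE.NAMES = FALSE)
  }

  strand <- sample(c("+", "-"), n, replace = TRUE)
  flank5 <- sample_promoter_windows(n, pad + pad %% 2L, 1 / 16)
  flank3 <- sample_promoter_windows(n, pad + pad %% 2L, 1 / 16)
  flank5 <- substr(flank5, 1L, pad); flank3 <- substr(flank3, 1L, pad)

  placed <- ifelse(strand == "+", windows, revcomp(windows))
  contigs <- paste0(flank5, placed, flank3)
  seqid <- paste0("contig_", genes)
  names(contigs) <- seqid

  # window occupies 0-based [pad, pad + len); with upstream u and
  # downstream d: "+" tss = pad + u; "-" tss = pad + d - 1
  tss <- ifelse(strand == "+", pad + params$promoter_upstream,
                pad + params$promoter_downstream - 1L)
  ann <- data.frame(gene = genes, sequence_id = seqid,
                    tss = as.integer(tss), strand = strand,
                    stringsAsFactors = FALSE)
  structure(list(sequences = contigs, annot = ann,
                 missing = character(0)), class = "promoter_set")
}

# sharp PWM from a consensus string: probability `p` on the consensus base
sharp_pwm <- function(id, consensus, p = 0.91, planted = TRUE) {
  bases <- c("A", "C", "G", "T")
  letters <- strsplit(consensus, "")[[1L]]
  m <- matrix((1 - p) / 3, length(letters), 4,
              dimnames = list(NULL, bases))
  m[cbind(seq_along(letters), match(letters, bases))] <- p
  pwm(id, paste0("planted_", consensus), m, planted = planted)
}

#' Simulated PWM library: planted motif plus Dirichlet decoys
#'
#' Returns the sharp PWM of the planted consensus (average information
#' content above 1 bit per position) followed by `n_decoy_pwms` decoy
#' matrices whose positions are drawn from a flat Dirichlet.
#'
#' @param config a [simulation_config()].
#' @return named list of [pwm()] objects; planted motifs have
#'   `$planted = TRUE`.
#' @export
make_pwm_library <- function(config) {
  set.seed(stage_seed(config$seed, "pwms"))
  out <- list(planted1 = sharp_pwm("planted1", config$planted_consensus))
  for (i in seq_len(config$n_decoy_pwms)) {
    w <- sample(8:12, 1L)
    g <- matrix(stats::rexp(w * 4), w, 4)   # Dirichlet(1,1,1,1) rows
    m <- g / rowSums(g)
    id <- sprintf("decoy%02d", i)
    out[[id]] <- pwm(id, id, m, planted = FALSE)
  }
  out
}

#' Simulated cytokine-family table
#'
#' Assigns up to 20 signaling-factor family labels (interleukins,
#' chemokines, TNF-family members, growth factors, ...), concentrating the
#' labeled genes among LPS-induced ones as for real cytokine loci, with
#' interleukin/chemokine/TNF labels the most frequent.
#'
#' @param truth a `ground_truth`.
#' @param config the [simulation_config()].
#' @return data.frame with columns `gene`, `family`.
#' @export
make_family_table <- function(truth, config) {
  set.seed(stage_seed(config$seed, "families"))
  n <- min(config$n_family_genes, length(truth$genes))
  if (n == 0L)
    return(data.frame(gene = character(0), family = character(0),
                      stringsAsFactors = FALSE))
  fams <- c("interleukin", "chemokine", "tnf_family", "growth_factor",
            "interferon", "csf", "tgf_family", "bmp", "fgf", "egf",
            "pdgf", "vegf", "wnt", "hedgehog", "notch_ligand", "semaphorin",
            "ephrin", "angiopoietin", "netrin", "complement")
  wts <- c(8, 8, 6, rep(1, 17))
  lps_any <- rowSums(truth$lps_up) > 0
  pool_up <- which(lps_any); pool_other <- which(!lps_any)
  n_up <- min(length(pool_up), round(0.8 * n))
  pick <- c(sample(pool_up, n_up),
            sample(pool_other, min(n - n_up, length(pool_other))))
  data.frame(gene = truth$genes[sort(pick)],
             family = sample(fams, length(pick), replace = TRUE,
                             prob = wts / sum(wts)),
             stringsAsFactors = FALSE)
}

#' Write ground-truth tables as TSV
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if needed).
#' @return invisible `NULL`.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("lps_up", "air", "il10_up")) {
    m <- truth[[nm]]
    utils::write.table(data.frame(gene = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(gene = truth$genes,
                                cpg_class = truth$cpg_class[truth$genes],
                                planted_motif =
                                  truth$planted_motif[truth$genes]),
                     file.path(dir, "truth_promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
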