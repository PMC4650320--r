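#' Pipeline run configuration
#'
#' Either real input paths (counts + sample sheet, and optionally
#' promoters, PWMs and a family table) or a [simulation_config()] — never
#' neither.  The seed and a configuration hash are recorded in every
#' output's metadata.
#'
#' @param out_dir output directory.
#' @param simulation a [simulation_config()], or `NULL` when real inputs
#'   are given.
#' @param inputs named list of paths (`counts`, `samples`, and optionally
#'   `promoter_fasta`, `promoter_annot`, `pwms`, `families`).
#' @param params [analysis_params()].
#' @param seed integer; defaults to the simulation seed when simulating.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "de", "classify", "cpg", "motifs", "families", "qc",
#'   "report")`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, simulation = NULL, inputs = NULL,
                       params = analysis_params(), seed = NULL,
                       stages = c("simulate", "de", "classify", "cpg",
                                  "motifs", "families", "qc", "report")) {
  if (is.null(simulation) && is.null(inputs))
    stop("run_config needs either a simulation config or input paths")
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    stop("simulation must be a simulation_config")
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  known <- c("simulate", "de", "classify", "cpg", "motifs", "families",
             "qc", "report")
  stages <- match.arg(stages, known, several.ok = TRUE)
  if (is.null(simulation)) stages <- setdiff(stages, "simulate")
  structure(list(out_dir = out_dir, simulation = simulation,
                 inputs = inputs, params = params,
                 seed = as.integer(seed), stages = stages),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order: simulate (counts,
#' promoters, PWMs, family table, ground truth) or load the real inputs;
#' differential expression (all standard contrasts per cell type);
#' regulation calls and AIR/not-AIR classification with overlap
#' partitions; promoter CpG comparison; motif enrichment; family
#' summaries; QC and PCA; and a machine-readable report.  All stochastic
#' stages derive deterministic substreams from the single seed, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly; all outputs are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  stages <- config$stages
  log <- list()
  t0 <- proc.time()[["elapsed"]]
  meta <- list(seed = config$seed, config_hash = config_hash(
    config[c("simulation", "inputs", "params", "seed")]))

  stamp <- function(stage) {
    log[[stage]] <<- list(stage = stage,
                          elapsed_s = round(proc.time()[["elapsed"]] - t0,
                                            3))
  }

  truth <- NULL; pwms <- NULL; promoters <- NULL; families <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_counts(config$simulation)
    cm <- sim$counts; truth <- sim$truth
    promoters <- simulate_promoters(truth, config$simulation, params)
    pwms <- make_pwm_library(config$simulation)
    families <- make_family_table(truth, config$simulation)
    write_counts(cm, file.path(config$out_dir, "counts.tsv"),
                 file.path(config$out_dir, "samples.tsv"))
    write_promoters(promoters, file.path(config$out_dir, "promoters.fa"),
                    file.path(config$out_dir, "promoters.bed"))
    write_pwms(pwms, file.path(config$out_dir, "pwms.txt"))
    write_tsv(families, file.path(config$out_dir, "families.tsv"))
    write_truth(truth, config$out_dir)
    stamp("simulate")
  } else {
    inp <- config$inputs
    cm <- read_counts(inp$counts, inp$samples)
    if (!is.null(inp$promoter_fasta))
      promoters <- read_promoters(inp$promoter_fasta, inp$promoter_annot)
    if (!is.null(inp$pwms)) pwms <- read_pwms(inp$pwms)
    if (!is.null(inp$families)) families <- read_family_table(inp$families)
  }

  de <- NULL; regulation <- NULL; partition <- NULL; lps_up <- NULL
  windows <- NULL
  if ("de" %in% stages) {
    de <- run_de(cm, params)
    write_tsv(de, file.path(config$out_dir, "de_results.tsv"))
    stamp("de")
  }

  if ("classify" %in% stages) {
    if (is.null(de)) stop("stage 'classify' requires stage 'de'")
    regulation <- call_regulation(de, params)
    lps_up <- regulation_sets(regulation, "LPS_vs_ctrl", "up")
    responsive <- if (!is.null(truth)) truth$il10_responsive else NULL
    expr <- condition_means(cm, attr(de, "size_factors"))
    partition <- classify_air(lps_up, expr, params, responsive)
    check_air_partition(partition, lps_up[names(partition)])
    specific <- celltype_specific_air(partition)
    il10_up <- il10_up_sets(de, params)
    air_venn <- venn_partition(lapply(partition, `[[`, "air"))
    notair_venn <- venn_partition(lapply(partition, `[[`, "not_air"))
    write_tsv(regulation, file.path(config$out_dir, "regulation.tsv"))
    write_gene_sets(c(stats::setNames(lapply(partition, `[[`, "air"),
                                      paste0("air_", names(partition))),
                      stats::setNames(lapply(partition, `[[`, "not_air"),
                                      paste0("not_air_",
                                             names(partition))),
                      stats::setNames(specific,
                                      paste0("specific_air_",
                                             names(specific))),
                      stats::setNames(il10_up,
                                      paste0("il10_up_",
                                             names(il10_up)))),
                    file.path(config$out_dir, "gene_sets.tsv"))
    jsonlite::write_json(
      c(meta, list(air_partition = lapply(air_venn$counts, unname),
                   not_air_partition = lapply(notair_venn$counts,
                                              unname))),
      file.path(config$out_dir, "partition_summary.json"),
      auto_unbox = TRUE, pretty = TRUE)
    stamp("classify")
  }

  cpg_tab <- NULL
  if ("cpg" %in% stages && !is.null(promoters)) {
    if (is.null(partition)) stop("stage 'cpg' requires stage 'classify'")
    windows <- extract_windows(promoters, params)
    cg <- cg_count(windows)
    write_tsv(data.frame(gene = names(cg), cg_count = cg,
                         truncated = windows$truncated),
              file.path(config$out_dir, "cpg_counts.tsv"))
    cpg_tab <- cpg_compare_partition(partition, windows, params)
    jsonlite::write_json(c(meta, list(cpg = cpg_tab)),
                         file.path(config$out_dir, "cpg_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    stamp("cpg")
  }

  motif_tab <- NULL
  if ("motifs" %in% stages && !is.null(promoters) && !is.null(pwms)) {
    if (is.null(partition))
      stop("stage 'motifs' requires stage 'classify'")
    if (is.null(windows)) windows <- extract_windows(promoters, params)
    mo <- enrich_partition(pwms, partition, windows)
    motif_tab <- mo$results
    if (!is.null(motif_tab))
      write_tsv(motif_tab,
                file.path(config$out_dir, "motif_enrichment.tsv"))
    stamp("motifs")
  }

  fam_tab <- NULL
  if ("families" %in% stages && !is.null(families) &&
      !is.null(regulation)) {
    fam_tab <- shared_cytokines(regulation, families, 2, "LPS_vs_ctrl")
    write_tsv(fam_tab, file.path(config$out_dir, "shared_cytokines.tsv"))
    stamp("families")
  }

  qc <- NULL; pca <- NULL
  if ("qc" %in% stages) {
    sf <- size_factors(cm)
    qc <- replicate_correlation(cm, sf)
    write_tsv(qc, file.path(config$out_dir, "replicate_correlation.tsv"))
    pca <- pca_treatment_axis(cm, sf, params)
    jsonlite::write_json(
      c(meta, list(explained = pca$explained,
                   association = pca$association,
                   lps_axis = pca$lps_axis, il10_axis = pca$il10_axis)),
      file.path(config$out_dir, "pca_summary.json"), auto_unbox = TRUE,
      pretty = TRUE, na = "null")
    stamp("qc")
  }

  report <- NULL
  if ("report" %in% stages) {
    report <- build_report(meta, cm, truth, de, regulation, partition,
                           cpg_tab, motif_tab, fam_tab, qc, pca, params)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    writeLines(render_report_md(report),
               file.path(config$out_dir, "report.md"))
    stamp("report")
  }
  jsonlite::write_json(c(meta, list(stages = unname(log))),
                       file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

# one-set-per-line TSV: set_name, n, comma-joined genes
write_gene_sets <- function(sets, path) {
  tab <- data.frame(set_name = names(sets),
                    n = vapply(sets, length, integer(1L)),
                    genes = vapply(sets, paste, character(1L),
                                   collapse = ","),
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

build_report <- function(meta, cm, truth, de, regulation, partition,
                         cpg_tab, motif_tab, fam_tab, qc, pca, params) {
  rep <- c(meta, list(
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    cell_types = unique(cm$samples$cell_type),
    treatments = unique(cm$samples$treatment)))
  if (!is.null(partition)) {
    rep$air_sizes <- lapply(partition, function(p)
      list(air = length(p$air), not_air = length(p$not_air)))
    vp <- venn_partition(lapply(partition, `[[`, "air"))
    rep$air_partition_counts <- as.list(vp$counts)
  }
  if (!is.null(cpg_tab)) rep$cpg <- cpg_tab
  if (!is.null(motif_tab)) {
    sig <- motif_tab[motif_tab$q < 0.05, , drop = FALSE]
    rep$top_motifs <- sig[order(sig$p),
                          c("cell_type", "side", "pwm", "z", "q")]
  }
  if (!is.null(fam_tab)) rep$n_shared_cytokines <- nrow(fam_tab)
  if (!is.null(qc) && nrow(qc))
    rep$replicate_r <- list(min = min(qc$r), median = stats::median(qc$r))
  if (!is.null(pca))
    rep$pca <- list(lps_axis = pca$lps_axis, il10_axis = pca$il10_axis)
  # truth-vs-called confusion matrices for simulated runs
  if (!is.null(truth) && !is.null(partition)) {
    conf <- list()
    for (ct in names(partition)) {
      called <- rownames(truth$air) %in% partition[[ct]]$air
      true_air <- truth$air[, ct]
      conf[[ct]] <- list(tp = sum(called & true_air),
                         fp = sum(called & !true_air),
                         fn = sum(!called & true_air),
                         tn = sum(!called & !true_air))
    }
    rep$air_confusion <- conf
  }
  rep
}

render_report_md <- function(report) {
  lines <- c("# Pipeline run report", "",
             sprintf("- seed: %s, config hash: %s", report$seed,
                     report$config_hash),
             sprintf("- %d genes x %d samples", report$n_genes,
                     report$n_samples))
  if (!is.null(report$air_sizes)) {
    lines <- c(lines, "", "## AIR partition")
    for (ct in names(report$air_sizes))
      lines <- c(lines, sprintf("- %s: %d AIR / %d not-AIR", ct,
                                report$air_sizes[[ct]]$air,
                                report$air_sizes[[ct]]$not_air))
  }
  if (!is.null(report$pca))
    lines <- c(lines, "",
               sprintf("- LPS-associated PC: %s; IL-10-associated PC: %s",
                       ifelse(is.na(report$pca$lps_axis), "none",
                              report$pca$lps_axis),
                       ifelse(is.na(report$pca$il10_axis), "none",
                              report$pca$il10_axis)))
  lines
}

#' Summarize a completed run directory
#'
#' Reads `report.json` from a finished [run_pipeline()] output directory.
#'
#' @param run_dir output directory of a completed run.
#' @return the report list.
#' @export
run_report <- function(run_dir) {
  path <- file.path(run_dir, "report.json")
  if (!file.exists(path))
    stop("no report.json in ", run_dir, "; run the pipeline first")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
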