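#' Cross-cell-type regulation calls with the relaxation rule
#'
#' A gene is called `up` in a cell type when it is significant there
#' (`q < q_threshold` and `log2fc > 0`; basis `"significant"`), or, by the
#' relaxation rule, when it is significant in the same direction in at
#' least one other cell type for the same contrast and its linear
#' fold-change here is strictly greater than `relax_fc` (basis
#' `"relaxed"`).  `down` is symmetric (fold-change strictly below
#' `1 / relax_fc`).  Everything else is `unchanged`.
#'
#' @param de a `de_results` table from [run_de()] (any subset of
#'   contrasts).
#' @param params [analysis_params()].
#' @return an object of class `regulation_table`: data.frame with columns
#'   `cell_type`, `contrast`, `gene`, `log2fc`, `qvalue`, `call`
#'   (up/down/unchanged) and `basis` (significant/relaxed/none).
#' @export
call_regulation <- function(de, params = analysis_params()) {
  stopifnot(is.data.frame(de))
  qt <- params$q_threshold
  lfc_relax <- log2(params$relax_fc)
  out <- list()
  for (ctr in unique(de$contrast)) {
    sub <- de[de$contrast == ctr, , drop = FALSE]
    cts <- unique(sub$cell_type)
    sig_up <- sig_down <- list()
    for (ct in cts) {
      s <- sub[sub$cell_type == ct, ]
      sig_up[[ct]] <- s$gene[s$qvalue < qt & s$log2fc > 0 & s$tested]
      sig_down[[ct]] <- s$gene[s$qvalue < qt & s$log2fc < 0 & s$tested]
    }
    for (ct in cts) {
      s <- sub[sub$cell_type == ct, ]
      anchor_up <- unique(unlist(sig_up[setdiff(cts, ct)]))
      anchor_down <- unique(unlist(sig_down[setdiff(cts, ct)]))
      call <- rep("unchanged", nrow(s))
      basis <- rep("none", nrow(s))
      is_sig_up <- s$gene %in% sig_up[[ct]]
      is_sig_down <- s$gene %in% sig_down[[ct]]
      relax_up <- !is_sig_up & !is_sig_down & s$gene %in% anchor_up &
        s$log2fc > lfc_relax
      relax_down <- !is_sig_up & !is_sig_down & s$gene %in% anchor_down &
        s$log2fc < -lfc_relax
      call[is_sig_up | relax_up] <- "up"
      call[is_sig_down | relax_down] <- "down"
      basis[is_sig_up | is_sig_down] <- "significant"
      basis[relax_up | relax_down] <- "relaxed"
      out[[paste(ct, ctr, sep = ".")]] <-
        data.frame(cell_type = ct, contrast = ctr, gene = s$gene,
                   log2fc = s$log2fc, qvalue = s$qvalue, call = call,
                   basis = basis, stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(reg) <- c("regulation_table", "data.frame")
  reg
}

#' Per-cell-type gene sets with a given call
#'
#' @param regulation a `regulation_table`.
#' @param contrast contrast name.
#' @param direction `"up"` or `"down"`.
#' @return named list of character vectors, one per cell type.
#' @export
regulation_sets <- function(regulation, contrast, direction = "up") {
  sub <- regulation[regulation$contrast == contrast &
                      regulation$call == direction, , drop = FALSE]
  cts <- unique(regulation$cell_type[regulation$contrast == contrast])
  stats::setNames(lapply(cts, function(ct)
    sub$gene[sub$cell_type == ct]), cts)
}

#' Partition LPS-induced genes into AIR and not-AIR
#'
#' Among each cell type's LPS-up genes, a gene is AIR when its normalized
#' expression declines at least `air_fc`-fold (inclusive) from the LPS to
#' the IL10_LPS condition, i.e. `(mean_LPS + pc) / (mean_IL10_LPS + pc)
#' >= air_fc`; otherwise it is not-AIR.  Cell types flagged
#' non-IL-10-responsive are excluded from the AIR analysis entirely.
#'
#' @param lps_up named list of per-cell-type LPS-up gene sets.
#' @param expr condition-mean matrix from [condition_means()].
#' @param params [analysis_params()].
#' @param responsive named logical per cell type; defaults to `TRUE` for
#'   every cell type except eosinophil.
#' @return an object of class `air_partition`: per responsive cell type a
#'   list with `air` and `not_air` gene sets.
#' @export
classify_air <- function(lps_up, expr, params = analysis_params(),
                         responsive = NULL) {
  cts <- names(lps_up)
  if (is.null(responsive))
    responsive <- stats::setNames(cts != "eosinophil", cts)
  pc <- params$pseudocount
  out <- list()
  for (ct in cts) {
    if (!isTRUE(responsive[[ct]])) next
    genes <- lps_up[[ct]]
    cl <- paste0(ct, ".LPS"); ci <- paste0(ct, ".IL10_LPS")
    if (!(cl %in% colnames(expr)) || !(ci %in% colnames(expr)))
      stop("condition means missing for cell type ", ct)
    genes <- intersect(genes, rownames(expr))
    ratio <- (expr[genes, cl] + pc) / (expr[genes, ci] + pc)
    out[[ct]] <- list(air = genes[ratio >= params$air_fc],
                      not_air = genes[ratio < params$air_fc])
  }
  structure(out, class = "air_partition")
}

#' @export
print.air_partition <- function(x, ...) {
  for (ct in names(x))
    cat(sprintf("%-12s AIR %4d  not-AIR %4d  (%.0f%% AIR)\n", ct,
                length(x[[ct]]$air), length(x[[ct]]$not_air),
                100 * length(x[[ct]]$air) /
                  max(1L, length(x[[ct]]$air) + length(x[[ct]]$not_air))))
  invisible(x)
}

#' IL-10-induced gene sets per cell type
#'
#' Genes called `up` (significant or relaxed) for the IL10 vs ctrl
#' contrast.
#'
#' @param de a `de_results` table.
#' @param params [analysis_params()].
#' @return named list of character vectors per cell type.
#' @export
il10_up_sets <- function(de, params = analysis_params()) {
  sub <- de[de$contrast == "IL10_vs_ctrl", , drop = FALSE]
  if (!nrow(sub))
    return(stats::setNames(list(), character(0)))
  reg <- call_regulation(sub, params)
  regulation_sets(reg, "IL10_vs_ctrl", "up")
}

#' Exclusive overlap partition of named gene sets
#'
#' Assigns every member of the union to exactly one category by its
#' membership count: `unique-<set>` for genes in exactly one set,
#' `exactly-2`, `exactly-3`, ... for intermediate counts, and `all-<k>`
#' for genes in every set.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return an object of class `geneset_partition`: list with `categories`
#'   (named list of gene vectors) and `counts`.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L) stop("venn_partition needs at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  k <- length(sets)
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s,
                   logical(length(univ)))
  if (!is.matrix(member))
    member <- matrix(member, nrow = length(univ), ncol = k,
                     dimnames = list(NULL, names(sets)))
  cnt <- rowSums(member)
  cats <- list()
  for (nm in names(sets))
    cats[[paste0("unique-", nm)]] <-
      univ[cnt == 1L & member[, nm]]
  if (k > 2L)
    for (m in 2:(k - 1L))
      cats[[paste0("exactly-", m)]] <- univ[cnt == m]
  cats[[paste0("all-", k)]] <- univ[cnt == k]
  structure(list(categories = cats,
                 counts = vapply(cats, length, integer(1L)),
                 n_union = length(univ)),
            class = "geneset_partition")
}

#' @export
print.geneset_partition <- function(x, ...) {
  for (nm in names(x$counts))
    cat(sprintf("%-20s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("%-20s %d\n", "union", x$n_union))
  invisible(x)
}

#' Cell-type-specific AIR sets
#'
#' Each cell type's AIR set minus every gene that is AIR in two or more
#' cell types (removal of the "any 2" category); no other constraint is
#' applied.
#'
#' @param partition an `air_partition`.
#' @return named list of pairwise-disjoint character vectors.
#' @export
celltype_specific_air <- function(partition) {
  stopifnot(inherits(partition, "air_partition"))
  air_sets <- lapply(partition, `[[`, "air")
  all_genes <- unlist(air_sets, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  lapply(air_sets, setdiff, y = shared)
}

#' Mark genes reaching a fold-change in each cell type
#'
#' Inclusive threshold: `TRUE` when the linear fold-change of the named
#' contrast is at least `fc`; genes absent from a cell type's table are
#' `NA` (recorded as missing, not `FALSE`).
#'
#' @param de a `de_results` table.
#' @param genes character vector of gene ids.
#' @param contrast contrast name (default the IL-10 program,
#'   `"IL10_vs_ctrl"`).
#' @param fc inclusive linear fold-change threshold (default 1.5).
#' @return logical matrix genes x cell types with `NA` for missing genes.
#' @export
mark_relaxed_targets <- function(de, genes, contrast = "IL10_vs_ctrl",
                                 fc = 1.5) {
  sub <- de[de$contrast == contrast, , drop = FALSE]
  cts <- unique(sub$cell_type)
  out <- matrix(NA, length(genes), length(cts),
                dimnames = list(genes, cts))
  for (ct in cts) {
    s <- sub[sub$cell_type == ct, ]
    i <- match(genes, s$gene)
    out[, ct] <- s$log2fc[i] >= log2(fc)
  }
  out
}

#' Assert the AIR-partition invariant
#'
#' Checks `air` and `not_air` are disjoint and their union equals the
#' LPS-up set for every cell type; stops otherwise.
#'
#' @param partition an `air_partition`.
#' @param lps_up the per-cell-type LPS-up sets it was built from.
#' @return invisible `TRUE`.
#' @export
check_air_partition <- function(partition, lps_up) {
  for (ct in names(partition)) {
    a <- partition[[ct]]$air; n <- partition[[ct]]$not_air
    if (length(intersect(a, n)))
      stop("air and not_air overlap in ", ct)
    if (!setequal(union(a, n), unique(lps_up[[ct]])))
      stop("air + not_air does not equal the LPS-up set in ", ct)
  }
  invisible(TRUE)
}
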