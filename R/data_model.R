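#' Construct a validated count matrix
#'
#' Bundles an integer gene-by-sample count matrix with its sample metadata.
#' Columns of `counts` must line up with rows of `samples` (matched by
#' `sample_id`).
#'
#' @param counts numeric matrix of non-negative integer counts, genes in
#'   rows (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `treatment`, `replicate`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id in count matrix: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  req <- c("sample_id", "cell_type", "treatment", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  samples <- as.data.frame(samples)[, req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$cell_type <- as.character(samples$cell_type)
  samples$treatment <- as.character(samples$treatment)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad_ct <- setdiff(samples$cell_type, CELL_TYPES)
  if (length(bad_ct)) stop("unknown cell type: ", bad_ct[1L])
  bad_tr <- setdiff(samples$treatment, TREATMENTS)
  if (length(bad_tr)) stop("unknown treatment: ", bad_tr[1L])
  if (any(samples$replicate < 1L))
    stop("replicate ids must be positive integers")
  grp <- interaction(samples$cell_type, samples$treatment, drop = TRUE)
  if (any(tapply(samples$replicate, grp, anyDuplicated) > 0))
    stop("replicate ids must be unique within a (cell_type, treatment) group")
  missing <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing))
    stop("sample in sheet absent from count matrix: ", missing[1L])
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra))
    stop("sample in count matrix absent from sheet: ", extra[1L])
  counts <- counts[, samples$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  cell types:", paste(unique(x$samples$cell_type), collapse = ", "),
      "\n  treatments:", paste(unique(x$samples$treatment), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and sample sheet from TSV files
#'
#' The counts file is tab-delimited with a header row of sample ids and a
#' first column named `gene`; the sample sheet has columns `sample_id`,
#' `cell_type`, `treatment`, `replicate`.
#'
#' @param path counts TSV path.
#' @param sample_sheet sample sheet TSV path.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene")
    stop("counts file must have 'gene' as its first column")
  cm <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(cm) <- as.character(tab$gene)
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  count_matrix(cm, sheet)
}

#' Write a count matrix (and optionally its sample sheet) as TSV
#'
#' @param cm a [count_matrix()].
#' @param path counts TSV output path.
#' @param sheet_path optional sample sheet TSV output path.
#' @return `cm`, invisibly.
#' @export
write_counts <- function(cm, path, sheet_path = NULL) {
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path))
    utils::write.table(cm$samples, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(cm)
}

#' Construct a position weight matrix object
#'
#' @param id,name identifier and display name.
#' @param matrix numeric width x 4 matrix of probabilities (columns A,C,G,T);
#'   each row (position) must sum to 1 within 1e-9.
#' @param background base background probabilities (default uniform).
#' @param planted logical; `TRUE` for simulator-planted motifs.
#' @return an object of class `pwm`.
#' @export
pwm <- function(id, name = id, matrix, background = rep(0.25, 4),
                planted = FALSE) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("pwm matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1L) stop("pwm matrix must have at least one position")
  colnames(matrix) <- c("A", "C", "G", "T")
  if (any(matrix < 0) || any(!is.finite(matrix)))
    stop("pwm probabilities must be finite and non-negative")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("pwm rows must each sum to 1")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 probabilities summing to 1")
  structure(list(id = as.character(id), name = as.character(name),
                 matrix = matrix, background = as.numeric(background),
                 planted = isTRUE(planted)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$id, " (", x$name, "), width ", nrow(x$matrix),
      if (x$planted) ", planted" else "", "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param x a [pwm()].
#' @return character string of length `nrow(x$matrix)`.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$matrix)[apply(x$matrix, 1L, which.max)], collapse = "")
}

# normalize one 4 x w block of counts/probabilities into row-probabilities
normalize_pwm_block <- function(block, pseudocount) {
  # block: 4 rows (A,C,G,T) x w positions, as parsed
  if (any(colSums(block) <= 0))
    stop("PWM has a position with all-zero weights")
  sums <- colSums(block)
  if (all(abs(sums - 1) < 1e-6)) {
    probs <- sweep(block, 2L, sums, "/")  # already probabilities
  } else {
    probs <- sweep(block + pseudocount, 2L, sums + 4 * pseudocount, "/")
  }
  t(probs)  # -> w x 4
}

#' Read a JASPAR-style PWM library
#'
#' Parses a text file of motifs with `>ID NAME` headers followed by four
#' rows (A, C, G, T) of counts or probabilities, with or without the
#' bracketed JASPAR row syntax (`A [ 1 2 3 ]`).  Count matrices are
#' converted to probabilities with additive pseudocount regularization,
#' `(c + pseudocount) / (sum + 4 * pseudocount)` per position; matrices
#' whose columns already sum to 1 are taken as probabilities.
#'
#' @param path PWM text file.
#' @param pseudocount regularization pseudocount for count matrices
#'   (default 0.5).
#' @return list of [pwm()] objects, named by id.
#' @export
read_pwms <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no PWM headers ('>') found in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L)
      stop("PWM block must have exactly 4 rows (A,C,G,T), got ",
           length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t:|]*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t,]+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L)
      stop("PWM rows have unequal lengths")
    if (any(vapply(rows, function(r) any(is.na(r)), logical(1L))))
      stop("non-numeric value in PWM block")
    block <- do.call(rbind, rows)  # 4 x w, rows A,C,G,T
    head_fields <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1L]]
    id <- head_fields[1L]
    nm <- if (length(head_fields) > 1L)
      paste(head_fields[-1L], collapse = " ") else id
    out[[id]] <- pwm(id, nm, normalize_pwm_block(block, pseudocount))
  }
  out
}

#' Write a PWM library in JASPAR-style text
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @return `pwms`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[, b], digits = 10,
                                      trim = TRUE), collapse = " ")), con)
  }
  invisible(pwms)
}

#' Read promoter sequences with TSS annotations
#'
#' Loads a FASTA of contig sequences and a 6-column BED-like annotation
#' (`sequence_id, start, end, gene, score, strand`; 0-based half-open).
#' The TSS is `start` for `+` genes and `end - 1` for `-` genes.  Genes
#' whose `sequence_id` is absent from the FASTA are reported in
#' `$missing`, not silently dropped.  Sequences are uppercased; only
#' A/C/G/T/N are permitted.
#'
#' @param fasta FASTA path.
#' @param annot BED-like TSV path (no header).
#' @return an object of class `promoter_set`: list with `sequences`
#'   (named character vector of contigs), `annot` (data.frame with
#'   `gene`, `sequence_id`, `tss`, `strand`) and `missing` (gene ids).
#' @export
read_promoters <- function(fasta, annot) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         names(seqs)[bad][1L])
  tab <- utils::read.delim(annot, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("annotation must have 6 BED-like columns")
  names(tab)[1:6] <- c("sequence_id", "start", "end", "gene", "score",
                       "strand")
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1L)
  ann <- data.frame(gene = as.character(tab$gene),
                    sequence_id = as.character(tab$sequence_id),
                    tss = as.integer(tss), strand = tab$strand,
                    stringsAsFactors = FALSE)
  missing <- ann$gene[!(ann$sequence_id %in% names(seqs))]
  ann <- ann[ann$sequence_id %in% names(seqs), , drop = FALSE]
  structure(list(sequences = seqs, annot = ann, missing = missing),
            class = "promoter_set")
}

#' Write promoter sequences and annotations
#'
#' Inverse of [read_promoters()]: writes the contigs as FASTA and the
#' annotation as a 6-column BED-like TSV.
#'
#' @param promoters a `promoter_set`.
#' @param fasta,annot output paths.
#' @return `promoters`, invisibly.
#' @export
write_promoters <- function(promoters, fasta, annot) {
  ss <- Biostrings::DNAStringSet(promoters$sequences)
  Biostrings::writeXStringSet(ss, fasta, width = 80L)
  a <- promoters$annot
  # single-base anchor interval [tss, tss + 1): start is the TSS on "+",
  # end - 1 is the TSS on "-", so the same interval serves both strands
  bed <- data.frame(a$sequence_id, a$tss, a$tss + 1L, a$gene, 0L, a$strand)
  utils::write.table(bed, annot, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(promoters)
}

#' Read a gene-to-family table
#'
#' @param path TSV with columns `gene` and `family`.
#' @return data.frame with character columns `gene` and `family`.
#' @export
read_family_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "family") %in% names(tab)))
    stop("family table must have columns gene, family")
  data.frame(gene = as.character(tab$gene),
             family = as.character(tab$family), stringsAsFactors = FALSE)
}
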