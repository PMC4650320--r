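# sequence encoding for the scanner: A=1, C=2, G=3, T=4, N=5
encode_seq <- function(s) {
  code <- match(strsplit(toupper(s), "")[[1L]],
                c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

# log2-odds score matrix with epsilon flooring; 5th column (-Inf) makes any
# window containing N score -Inf, i.e. skipped by the maximization
pwm_logodds <- function(pwm, eps = 1e-3) {
  m <- pmax(pwm$matrix, eps)
  lo <- log2(sweep(m, 2L, pwm$background, "/"))
  cbind(lo, N = -Inf)
}

# attainable score extremes of the floored log-odds matrix
pwm_score_range <- function(lo) {
  w <- nrow(lo)
  c(min = sum(apply(lo[, 1:4, drop = FALSE], 1L, min)),
    max = sum(apply(lo[, 1:4, drop = FALSE], 1L, max)))
}

#' Best-hit PWM score of a promoter window
#'
#' Scans every offset of the window on both strands with the log2-odds
#' matrix `log2(p / background)` (matrix probabilities floored at
#' `eps = 1e-3`), takes the maximum, and normalizes it to `[0, 1]` by the
#' PWM's attainable extremes, `(s - s_min) / (s_max - s_min)`.
#' Subsequences containing `N` are skipped.  A degenerate PWM whose
#' extremes coincide (e.g. the uniform matrix under a uniform background)
#' returns the 0.5 convention.  Windows shorter than the PWM, or with no
#' N-free subsequence, return `NA`.
#'
#' @param pwm a [pwm()].
#' @param window sequence string (or character vector of windows).
#' @param eps probability floor.
#' @return numeric best normalized score per window (`NA` where
#'   unscorable).
#' @export
best_score <- function(pwm, window, eps = 1e-3) {
  lo <- pwm_logodds(pwm, eps)
  rng <- pwm_score_range(lo)
  vapply(window, function(s) {
    if (is.na(s)) return(NA_real_)
    raw <- best_raw_score(lo, encode_seq(s))
    normalize_score(raw, rng)
  }, numeric(1L), USE.NAMES = FALSE)
}

normalize_score <- function(raw, rng) {
  if (!is.finite(raw)) return(NA_real_)
  if (rng["max"] - rng["min"] < 1e-12) return(0.5)
  unname((raw - rng["min"]) / (rng["max"] - rng["min"]))
}

# maximum raw log-odds over offsets and strands for one encoded sequence
best_raw_score <- function(lo, code) {
  w <- nrow(lo)
  L <- length(code)
  if (L < w) return(-Inf)
  best <- -Inf
  for (cd in list(code, rev(5L - code + ifelse(code == 5L, 5L, 0L)))) {
    noff <- L - w + 1L
    acc <- numeric(noff)
    for (j in seq_len(w))
      acc <- acc + lo[j, cd[j:(j + noff - 1L)]]
    best <- max(best, max(acc))
  }
  best
}

# scores for many equal-length windows at once (row-stacked scan); NA rows
# allowed and returned as NA
score_windows <- function(pwm, windows, eps = 1e-3) {
  lo <- pwm_logodds(pwm, eps)
  rng <- pwm_score_range(lo)
  ok <- !is.na(windows)
  lens <- unique(nchar(windows[ok]))
  out <- rep(NA_real_, length(windows))
  for (L in lens) {
    idx <- which(ok & nchar(windows) == L)
    w <- nrow(lo)
    if (L < w) next
    codes <- matrix(match(unlist(strsplit(toupper(windows[idx]), "")),
                          c("A", "C", "G", "T", "N")),
                    nrow = length(idx), byrow = TRUE)
    if (anyNA(codes))
      stop("sequence contains characters outside {A,C,G,T,N}")
    comp <- 5L - codes
    comp[codes == 5L] <- 5L
    codes_rc <- comp[, rev(seq_len(L)), drop = FALSE]
    noff <- L - w + 1L
    best <- rep(-Inf, length(idx))
    for (cm in list(codes, codes_rc)) {
      for (o in seq_len(noff)) {
        acc <- lo[1L, cm[, o]]
        for (j in seq_len(w - 1L))
          acc <- acc + lo[j + 1L, cm[, o + j]]
        best <- pmax(best, acc)
      }
    }
    out[idx] <- vapply(best, normalize_score, numeric(1L), rng = rng)
  }
  out
}

#' PSCAN-style motif enrichment of a gene set
#'
#' Compares the mean best-hit score of foreground promoters with the full
#' promoter background: `z = (mean_fg - mean_bg) / (sd_bg / sqrt(n_fg))`,
#' one-sided upper p-value from the normal tail.
#'
#' @param pwm a [pwm()].
#' @param fg_windows named character vector (or `promoter_windows`) of
#'   foreground promoter sequences; at least 5 scorable windows.
#' @param all_windows the background: every analyzed promoter.
#' @param precomputed optional named numeric vector of background scores
#'   (names = genes) to avoid rescanning.
#' @return one-row data.frame: `pwm`, `n_fg`, `mean_fg`, `mean_bg`,
#'   `sd_bg`, `z`, `p`, `degenerate`.
#' @export
enrich <- function(pwm, fg_windows, all_windows, precomputed = NULL) {
  fg <- as_window_vector(fg_windows)
  bg <- as_window_vector(all_windows)
  scores <- if (is.null(precomputed))
    stats::setNames(score_windows(pwm, bg), names(bg)) else precomputed
  fg_scores <- scores[names(fg)]
  fg_scores <- fg_scores[!is.na(fg_scores)]
  bg_scores <- scores[!is.na(scores)]
  if (length(fg_scores) < 5L)
    stop("foreground must contain at least 5 scorable promoters")
  mean_fg <- mean(fg_scores); mean_bg <- mean(bg_scores)
  sd_bg <- stats::sd(bg_scores)
  degenerate <- !is.finite(sd_bg) || sd_bg < 1e-12
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (mean_fg - mean_bg) / (sd_bg / sqrt(length(fg_scores)))
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  data.frame(pwm = pwm$id, n_fg = length(fg_scores), mean_fg = mean_fg,
             mean_bg = mean_bg, sd_bg = sd_bg, z = z, p = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

as_window_vector <- function(x) {
  if (inherits(x, "promoter_windows"))
    return(stats::setNames(ifelse(x$truncated, NA_character_, x$sequence),
                           x$gene))
  if (is.null(names(x))) stop("windows must be named by gene")
  x
}

#' Enrichment of a PWM library over a foreground set
#'
#' Runs [enrich()] for every PWM and applies BH correction across the
#' library.
#'
#' @param pwms list of [pwm()] objects.
#' @param fg_windows,all_windows as in [enrich()].
#' @return data.frame, one row per PWM, with `q` added.
#' @export
enrich_library <- function(pwms, fg_windows, all_windows) {
  bg <- as_window_vector(all_windows)
  rows <- lapply(pwms, function(p) {
    sc <- stats::setNames(score_windows(p, bg), names(bg))
    enrich(p, fg_windows, all_windows, precomputed = sc)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Motif enrichment across an AIR partition
#'
#' For every cell type, tests each PWM against the AIR and the not-AIR
#' foreground separately (BH across the library within each side), so
#' that a motif's side of over-representation is visible.  Sides with
#' fewer than 5 scorable promoters are skipped with a record.
#'
#' @param pwms list of [pwm()] objects.
#' @param partition an `air_partition`.
#' @param windows a `promoter_windows` covering the analysis universe.
#' @return list with `results` (data.frame: `cell_type`, `side`, `pwm`,
#'   `n_fg`, `mean_fg`, `mean_bg`, `sd_bg`, `z`, `p`, `q`) and `skipped`
#'   (data.frame of skipped sides).
#' @export
enrich_partition <- function(pwms, partition, windows) {
  bg <- as_window_vector(windows)
  score_cache <- lapply(pwms, function(p)
    stats::setNames(score_windows(p, bg), names(bg)))
  results <- list(); skipped <- list()
  for (ct in names(partition)) {
    for (side in c("AIR", "not-AIR")) {
      genes <- if (side == "AIR") partition[[ct]]$air
               else partition[[ct]]$not_air
      fg <- bg[intersect(genes, names(bg))]
      if (sum(!is.na(fg)) < 5L) {
        skipped[[paste(ct, side)]] <-
          data.frame(cell_type = ct, side = side,
                     n_fg = sum(!is.na(fg)),
                     reason = "fewer than 5 scorable promoters",
                     stringsAsFactors = FALSE)
        next
      }
      rows <- lapply(seq_along(pwms), function(i)
        enrich(pwms[[i]], fg, bg, precomputed = score_cache[[i]]))
      tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      tab$q <- stats::p.adjust(tab$p, method = "BH")
      tab <- cbind(cell_type = ct, side = side, tab,
                   stringsAsFactors = FALSE)
      results[[paste(ct, side)]] <- tab
    }
  }
  list(results = if (length(results))
         do.call(rbind, c(results, list(make.row.names = FALSE)))
       else NULL,
       skipped = if (length(skipped))
         do.call(rbind, c(skipped, list(make.row.names = FALSE)))
       else NULL)
}
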