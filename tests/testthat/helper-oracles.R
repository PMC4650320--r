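# Independent brute-force oracles and tiny fixture builders shared by the
# suite.  These deliberately avoid the package's own vectorized code paths.

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""),
    character(1L))
}

# position-by-position CG scan
brute_cg_count <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 2L) return(0L)
  sum(ch[-length(ch)] == "C" & ch[-1L] == "G")
}

brute_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
}

# exhaustive offset x strand maximization of the floored log2-odds score,
# normalized by the PWM's attainable extremes
brute_best_score <- function(pw, window, eps = 1e-3) {
  m <- pmax(pw$matrix, eps)
  lo <- log2(sweep(m, 2L, pw$background, "/"))
  w <- nrow(lo)
  score_at <- function(s, o) {
    sub <- strsplit(substr(s, o, o + w - 1L), "")[[1L]]
    if (any(sub == "N")) return(-Inf)
    sum(lo[cbind(seq_len(w), match(sub, c("A", "C", "G", "T")))])
  }
  best <- -Inf
  for (s in c(window, brute_revcomp(window)))
    for (o in seq_len(nchar(window) - w + 1L))
      best <- max(best, score_at(s, o))
  smin <- sum(apply(lo, 1L, min)); smax <- sum(apply(lo, 1L, max))
  if (!is.finite(best)) return(NA_real_)
  if (smax - smin < 1e-12) return(0.5)
  (best - smin) / (smax - smin)
}

# exclusive partition by explicit per-gene membership patterns
brute_venn <- function(sets) {
  univ <- unique(unlist(sets))
  k <- length(sets)
  cats <- list()
  for (g in univ) {
    inset <- names(sets)[vapply(sets, function(s) g %in% s, logical(1L))]
    key <- if (length(inset) == 1L) paste0("unique-", inset)
           else if (length(inset) == k) paste0("all-", k)
           else paste0("exactly-", length(inset))
    cats[[key]] <- c(cats[[key]], g)
  }
  cats
}

# small count matrix with metadata for plumbing tests
toy_count_matrix <- function() {
  m <- matrix(c(10L, 20L, 30L, 12L, 18L, 33L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  count_matrix(m, data.frame(sample_id = c("s1", "s2"),
                             cell_type = "macrophage",
                             treatment = c("ctrl", "LPS"),
                             replicate = c(1L, 1L)))
}
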