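# Independent brute-force reference implementations used to validate the
# package's interval and set logic. These deliberately share no code with
# the package: plain loops over data frames of 0-based half-open intervals.

o_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# nearest gene by |anchor - tss| with lexicographic tie-break
o_nearest_tss <- function(anchor, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(list(gene_id = NA_character_, d = NA_integer_))
  d <- abs(g$tss - anchor)
  best <- min(d)
  list(gene_id = min(g$gene_id[d == best]), d = best)
}

# gene x peak exhaustive scan for the TSS-window binding rule
o_bound_genes <- function(genes, anchors, window_bp) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(anchors$chrom == genes$chrom[i] &
          abs(anchors$pos - genes$tss[i]) <= window_bp)
  }, logical(1))
  sort(genes$gene_id[hit])
}

# brute-force merged clusters (overlapping or book-ended) of a bed frame
o_merge <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- df[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(df))[-1]) {
    row <- df[i, ]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row[, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# brute-force 7-class partition over merged clusters of the 3-set union
o_venn3 <- function(A, B, C) {
  union_df <- rbind(A[, c("chrom", "start", "end")],
                    B[, c("chrom", "start", "end")],
                    C[, c("chrom", "start", "end")])
  clusters <- o_merge(union_df)
  touches <- function(set, cl)
    any(set$chrom == cl$chrom & o_overlaps(set$start, set$end, cl$start, cl$end))
  cls <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    paste0(if (nrow(A) && touches(A, cl)) "A" else "",
           if (nrow(B) && touches(B, cl)) "B" else "",
           if (nrow(C) && touches(C, cl)) "C" else "")
  }, character(1))
  counts <- table(factor(cls, levels = c("A", "B", "C", "AB", "AC", "BC", "ABC")))
  stats::setNames(as.integer(counts),
                  c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"))
}

# number of A intervals overlapped by >= 1 B interval (pairwise loops)
o_overlap_count <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  sum(vapply(seq_len(nrow(A)), function(i) {
    any(B$chrom == A$chrom[i] &
          o_overlaps(A$start[i], A$end[i], B$start, B$end))
  }, logical(1)))
}

# exact hypergeometric upper tail by enumerating all C(N, n) draws
o_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# random bed frame on a small genome
rand_bed <- function(n, chroms = c("chr1", "chr2"), L = 1000, max_len = 60) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

bed_to_rs <- function(df, label = "x") {
  region_set(df$chrom, df$start, df$end, label = label)
}

rand_genes <- function(n, chroms = c("chr1", "chr2"), L = 100000) {
  gene_table(sprintf("g%03d", seq_len(n)),
             sample(chroms, n, replace = TRUE),
             sample.int(L, n) - 1L,
             sample(c("+", "-"), n, replace = TRUE))
}
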