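# strip to bare ranges on a shared seqlevel set so cross-set operations
# neither warn nor depend on seqinfo bookkeeping
.unify <- function(...) {
  grs <- lapply(list(...), function(g) {
    g <- granges(g)
    GenomeInfoDb::seqinfo(g) <- GenomeInfoDb::Seqinfo(seqnames = seqlevels(g))
    g
  })
  lev <- sort(unique(unlist(lapply(grs, seqlevels))))
  lapply(grs, function(g) {
    seqlevels(g) <- lev
    g
  })
}

#' Asymmetric region co-occupancy
#'
#' Fraction of query regions sharing at least 1 bp with at least one
#' subject region (book-ended regions do not overlap under the half-open
#' convention). Asymmetric by design: "x% of Runx1-bound regions are
#' co-occupied by MyoD" is `cooccupancy(runx1, myod)`.
#'
#' @param query,subject Region sets.
#' @return List: `n_query`, `n_overlapping`, `fraction`.
#' @export
cooccupancy <- function(query, subject) {
  if (length(query) == 0L) .stopf("empty query: co-occupancy fraction undefined")
  u <- .unify(query, subject)
  n_ov <- sum(IRanges::overlapsAny(u[[1L]], u[[2L]], ignore.strand = TRUE))
  list(n_query = length(query), n_overlapping = n_ov,
       fraction = n_ov / length(query))
}

#' Three-way overlap partition of merged clusters
#'
#' The union of the three inputs is collapsed into maximal merged clusters
#' ([merge_regions()] semantics); each cluster's membership class is the
#' set of inputs contributing at least one interval to it. This is the
#' region-level Venn used for triple co-occupancy.
#'
#' @param A,B,C Region sets.
#' @return List with `counts` (named: `A_only`, `B_only`, `C_only`, `AB`,
#'   `AC`, `BC`, `ABC`), `n_clusters`, `labels` (input labels), and
#'   `clusters` (the merged `GRanges` with logical membership columns
#'   `in_A`, `in_B`, `in_C`).
#' @export
venn3 <- function(A, B, C) {
  u <- .unify(A, B, C)
  pool <- c(u[[1L]], u[[2L]], u[[3L]])
  clusters <- GenomicRanges::reduce(pool, ignore.strand = TRUE,
                                    min.gapwidth = 1L)
  inA <- IRanges::overlapsAny(clusters, u[[1L]], ignore.strand = TRUE)
  inB <- IRanges::overlapsAny(clusters, u[[2L]], ignore.strand = TRUE)
  inC <- IRanges::overlapsAny(clusters, u[[3L]], ignore.strand = TRUE)
  cls <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""), ifelse(inC, "C", ""))
  key <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  counts <- stats::setNames(integer(7),
                            c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"))
  tab <- table(factor(cls, levels = key))
  counts[] <- as.integer(tab)
  mcols(clusters)$in_A <- inA
  mcols(clusters)$in_B <- inB
  mcols(clusters)$in_C <- inC
  names(clusters) <- if (length(clusters))
    paste0("cluster:", seq_along(clusters)) else character()
  list(counts = counts, n_clusters = length(clusters),
       labels = c(A = region_label(A), B = region_label(B), C = region_label(C)),
       clusters = clusters)
}

# Count of A intervals overlapped by >=1 B interval, all coordinates already
# mapped onto one concatenated axis (0-based half-open). Sorted sweep:
# A_i is hit iff some B has start < A_end and end > A_start.
.sweep_overlap_count <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) return(0L)
  o <- order(b_start)
  s <- b_start[o]
  e <- cummax(b_end[o])
  k <- findInterval(a_end - 1L, s)
  sum(k > 0L & e[pmax(k, 1L)] > a_start)
}

.chrom_offsets <- function(sizes) {
  off <- cumsum(c(0, as.numeric(sizes) + 1))[seq_along(sizes)]
  stats::setNames(off, names(sizes))
}

#' Bootstrap test for region-set overlap
#'
#' Tests whether the observed number of `A` regions overlapped by `B`
#' exceeds chance, against a null in which every `B` interval is
#' independently relocated uniformly within its own chromosome (length and
#' per-chromosome counts preserved; relocated intervals may overlap each
#' other). The empirical p-value uses the add-one rule
#' `(1 + #(null >= observed)) / (1 + n_iter)`, so it is never exactly zero
#' and the smallest reportable value is `1/(n_iter + 1)`; claiming
#' p < 1e-4 therefore needs `n_iter >= 10000`.
#'
#' @param A,B Region sets.
#' @param sizes Named chromosome lengths; every chromosome used by `B`
#'   must be present and at least as long as its longest `B` interval.
#' @param n_iter Number of null relocations (>= 1).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return List: `observed` (count of A regions overlapped), `n_query`,
#'   `fraction`, `p_empirical`, and `null` (a list with `n_iter`, `seed`,
#'   `statistics`).
#' @export
bootstrap_overlap_test <- function(A, B, sizes, n_iter = 10000L, seed = 1L) {
  sizes <- validate_chrom_sizes(sizes)
  if (n_iter < 1L) .stopf("n_iter must be >= 1")
  b_chrom <- as.character(seqnames(B))
  miss <- setdiff(unique(b_chrom), names(sizes))
  if (length(miss)) .stopf("chromosome '%s' missing from sizes", miss[1L])
  b_len <- GenomicRanges::width(B)
  if (any(b_len > sizes[b_chrom]))
    .stopf("an interval of '%s' is longer than its chromosome",
           region_label(B))
  off <- .chrom_offsets(sizes)
  a_chrom <- as.character(seqnames(A))
  a_keep <- a_chrom %in% names(sizes)
  a_start <- (GenomicRanges::start(A)[a_keep] - 1L) + off[a_chrom[a_keep]]
  a_end <- GenomicRanges::end(A)[a_keep] + off[a_chrom[a_keep]]
  b_start0 <- (GenomicRanges::start(B) - 1L) + off[b_chrom]
  b_end0 <- GenomicRanges::end(B) + off[b_chrom]
  observed <- .sweep_overlap_count(a_start, a_end, b_start0, b_end0)
  n_slots <- as.numeric(sizes[b_chrom]) - b_len + 1  # valid 0-based starts
  b_off <- off[b_chrom]
  stats_null <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      s <- floor(stats::runif(length(b_len)) * n_slots) + b_off
      .sweep_overlap_count(a_start, a_end, s, s + b_len)
    }, numeric(1))
  })
  p <- (1 + sum(stats_null >= observed)) / (1 + n_iter)
  list(observed = observed,
       n_query = length(A),
       fraction = if (length(A)) observed / length(A) else NA_real_,
       p_empirical = p,
       null = list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                   statistics = stats_null))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the overlap of a size-`n` draw with a size-`K` category
#' in a universe of `N` items; the exact tail sum of the hypergeometric
#' mass (returns 1 when `k = 0`).
#'
#' @param N Universe size.
#' @param K Category size (`0 <= K <= N`).
#' @param n Draw size (`0 <= n <= N`).
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @return Upper-tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (K < 0 || n < 0 || K > N || n > N) .stopf("need 0 <= K, n <= N")
  if (k < 0 || k > min(K, n)) .stopf("infeasible overlap k = %g", k)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Monte Carlo test for gene-set intersection
#'
#' Empirical upper-tail probability of the observed `|A intersect B|` under
#' a null drawing `|A|` and `|B|` genes uniformly without replacement from
#' the universe, independently, each iteration. The null mean is
#' `|A||B|/N`. Uses the same add-one p-value rule as
#' [bootstrap_overlap_test()].
#'
#' @param universe,setA,setB `gene_set`s (or character vectors);
#'   `setA`, `setB` must be subsets of `universe`.
#' @param n_iter Iterations (>= 1).
#' @param seed Integer seed.
#' @return List: `observed`, `p_empirical`, `null` (with `n_iter`, `seed`,
#'   `statistics`).
#' @export
monte_carlo_set_test <- function(universe, setA, setB, n_iter = 10000L,
                                 seed = 1L) {
  ids <- function(x) if (inherits(x, "gene_set")) x$ids else unique(as.character(x))
  u <- ids(universe); a <- ids(setA); b <- ids(setB)
  if (n_iter < 1L) .stopf("n_iter must be >= 1")
  if (length(setdiff(a, u)) || length(setdiff(b, u)))
    .stopf("setA and setB must be contained in the universe")
  observed <- length(intersect(a, b))
  N <- length(u); nA <- length(a); nB <- length(b)
  stats_null <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      inA <- logical(N)
      inA[sample.int(N, nA)] <- TRUE
      sum(inA[sample.int(N, nB)])
    }, numeric(1))
  })
  p <- (1 + sum(stats_null >= observed)) / (1 + n_iter)
  list(observed = observed, p_empirical = p,
       null = list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                   statistics = stats_null))
}

#' Dump a null distribution for audit
#'
#' Writes the statistics of a resampling null (from
#' [bootstrap_overlap_test()] or [monte_carlo_set_test()]) as a
#' single-column TSV with a `#`-prefixed header carrying `n_iter` and seed.
#'
#' @param null The `null` component of a test result.
#' @param path Output path.
#' @export
write_null_distribution <- function(null, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# n_iter=%d seed=%d", null$n_iter, null$seed),
               format(null$statistics, trim = TRUE)), con)
  invisible(path)
}
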