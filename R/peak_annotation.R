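#' Peak anchor coordinate
#'
#' The single base-pair coordinate used for every peak-to-TSS distance:
#' the narrowPeak summit when one is recorded, otherwise the interval
#' midpoint `floor((start + end) / 2)` in 0-based half-open coordinates.
#'
#' @param rs A region set.
#' @param anchor `"summit"` (summit when available, midpoint otherwise),
#'   `"midpoint"` (always the midpoint).
#' @return Integer vector of 0-based anchor coordinates, one per region.
#' @export
peak_anchor <- function(rs, anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  s0 <- GenomicRanges::start(rs) - 1L
  e0 <- GenomicRanges::end(rs)
  mid <- (s0 + e0) %/% 2L
  if (anchor == "summit" && !is.null(mcols(rs)$summit)) {
    su <- mcols(rs)$summit
    mid[!is.na(su)] <- su[!is.na(su)]
  }
  as.integer(mid)
}

#' Nearest TSS per peak
#'
#' For each region, the gene on the same chromosome whose TSS is closest to
#' the peak anchor (unsigned distance). Equidistant genes are resolved to
#' the lexicographically smallest `gene_id` so the assignment is
#' deterministic. Peaks on chromosomes absent from the annotation are
#' returned with `NA` gene and distance (unassigned), never dropped.
#'
#' @param rs A region set.
#' @param genes A [gene_table()].
#' @param anchor Passed to [peak_anchor()].
#' @return data.frame: `region_id`, `gene_id`, `distance_bp`.
#' @export
nearest_tss <- function(rs, genes, anchor = "summit") {
  a <- peak_anchor(rs, anchor)
  chrom <- as.character(seqnames(rs))
  out <- data.frame(region_id = names(rs),
                    gene_id = NA_character_,
                    distance_bp = NA_integer_,
                    stringsAsFactors = FALSE)
  if (length(rs) == 0L || nrow(genes) == 0L) return(out)
  for (ch in intersect(unique(chrom), unique(genes$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # representative (smallest) gene id per distinct TSS position
    rep_id <- vapply(split(g$gene_id, g$tss), min, character(1))
    u <- as.integer(names(rep_id))
    o <- order(u); u <- u[o]; rep_id <- rep_id[o]
    idx <- which(chrom == ch)
    k <- findInterval(a[idx], u)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(u))
    d_lo <- abs(a[idx] - u[lo]); d_hi <- abs(a[idx] - u[hi])
    d_lo[k < 1L] <- NA_integer_; d_hi[k >= length(u)] <- NA_integer_
    d <- pmin(d_lo, d_hi, na.rm = TRUE)
    pick_lo <- !is.na(d_lo) & d_lo == d
    pick_hi <- !is.na(d_hi) & d_hi == d
    gid <- ifelse(pick_lo & pick_hi,
                  pmin(rep_id[lo], rep_id[hi]),
                  ifelse(pick_lo, rep_id[lo], rep_id[hi]))
    out$gene_id[idx] <- gid
    out$distance_bp[idx] <- as.integer(d)
  }
  out
}

#' Classify a peak by TSS distance
#'
#' Distance bins follow the promoter definition of 1 kb up/downstream of an
#' annotated TSS, a proximal band to 10 kb, a distal band to 100 kb, and
#' "gene desert" beyond 100 kb from any TSS. Bounds are inclusive on the
#' left bin: `d <= 1000` is promoter, `1000 < d <= 10000` proximal,
#' `10000 < d <= 100000` distal, `d > 100000` gene desert.
#'
#' @param distance_bp Non-negative integer vector of unsigned anchor-to-TSS
#'   distances.
#' @return Factor with levels `promoter`, `proximal_1_10kb`,
#'   `distal_10_100kb`, `gene_desert` (`NA` distances stay `NA`).
#' @export
classify_location <- function(distance_bp) {
  if (any(distance_bp < 0, na.rm = TRUE))
    .stopf("distance must be >= 0")
  cut(distance_bp, breaks = c(-1, 1000, 10000, 100000, Inf),
      labels = c("promoter", "proximal_1_10kb", "distal_10_100kb",
                 "gene_desert"))
}

#' Peak location distribution relative to TSS
#'
#' Fractions of assignable peaks per distance category, plus the cumulative
#' fractions within 100 kb and within 200 kb of a TSS (the usual summary of
#' how much binding is promoter-proximal vs distal).
#'
#' @inheritParams nearest_tss
#' @return List: `fractions` (named, sums to 1 over assignable peaks),
#'   `counts`, `n_assignable`, `n_unassigned`, `frac_within_100kb`,
#'   `frac_within_200kb`.
#' @export
location_distribution <- function(rs, genes, anchor = "summit") {
  if (length(rs) == 0L) .stopf("empty region set: no distribution")
  nt <- nearest_tss(rs, genes, anchor = anchor)
  d <- nt$distance_bp[!is.na(nt$distance_bp)]
  if (length(d) == 0L) .stopf("no assignable peak (no gene shares a chromosome)")
  cat_ <- classify_location(d)
  counts <- table(cat_)
  list(fractions = stats::setNames(as.numeric(counts) / length(d),
                                   names(counts)),
       counts = stats::setNames(as.integer(counts), names(counts)),
       n_assignable = length(d),
       n_unassigned = sum(is.na(nt$distance_bp)),
       frac_within_100kb = mean(d <= 100000L),
       frac_within_200kb = mean(d <= 200000L))
}

#' Genes bound within a TSS window
#'
#' A gene is "bound" when at least one peak anchor lies within
#' `window_bp` of its TSS, boundary inclusive on both sides
#' (`|anchor - tss| <= window_bp`). With `anchor = "edge"` the whole peak
#' interval is tested for overlap with the window instead, to allow the
#' edge reading of "within 200 kb".
#'
#' @inheritParams nearest_tss
#' @param window_bp Window half-width in bp (default 200,000).
#' @param anchor `"summit"`, `"midpoint"` or `"edge"`.
#' @param label Label for the resulting gene set.
#' @return A [gene_set()]; `attr(, "support")` maps each bound gene to its
#'   supporting region ids.
#' @export
bound_genes <- function(rs, genes, window_bp = 200000L,
                        anchor = c("summit", "midpoint", "edge"),
                        label = NULL) {
  anchor <- match.arg(anchor)
  if (window_bp <= 0) .stopf("window_bp must be positive")
  if (is.null(label)) label <- paste0(region_label(rs), "_bound")
  if (length(rs) == 0L || nrow(genes) == 0L) {
    gs <- gs_derive(character(), label, list(),
                    list(window_bp = window_bp, anchor = anchor))
    attr(gs, "support") <- list()
    return(gs)
  }
  if (anchor == "edge") {
    qry <- granges(rs)
  } else {
    a <- peak_anchor(rs, anchor)
    qry <- GenomicRanges::GRanges(seqnames(rs), IRanges::IRanges(a + 1L, a + 1L))
  }
  win_start1 <- pmax(genes$tss - window_bp, 0L) + 1L
  win_end1 <- genes$tss + window_bp + 1L
  lev <- union(GenomeInfoDb::seqlevels(qry), unique(genes$chrom))
  GenomeInfoDb::seqlevels(qry) <- lev
  win <- GenomicRanges::GRanges(factor(genes$chrom, levels = lev),
                                IRanges::IRanges(win_start1, win_end1))
  hits <- GenomicRanges::findOverlaps(qry, win, ignore.strand = TRUE)
  gi <- subjectHits(hits)
  bound <- unique(genes$gene_id[gi])
  support <- lapply(split(names(rs)[queryHits(hits)], genes$gene_id[gi]), unique)
  gs <- gs_derive(bound, label, list(),
                  list(window_bp = window_bp, anchor = anchor,
                       regions = region_label(rs)))
  attr(gs, "support") <- support
  gs
}

#' Write peak annotations as a TSV sidecar
#'
#' One row per peak: region id, nearest gene, unsigned distance and
#' distance category (`NA`s for unassigned peaks).
#'
#' @inheritParams nearest_tss
#' @param path Output path.
#' @export
write_peak_annotation <- function(rs, genes, path, anchor = "summit") {
  nt <- nearest_tss(rs, genes, anchor = anchor)
  nt$category <- as.character(classify_location(nt$distance_bp))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("region_id\tnearest_gene\tdistance_bp\tcategory",
               if (nrow(nt)) sprintf("%s\t%s\t%s\t%s", nt$region_id,
                                     nt$gene_id, nt$distance_bp, nt$category)),
             con)
  invisible(path)
}
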