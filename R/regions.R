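#' @import methods
#' @importFrom GenomicRanges GRanges granges reduce countOverlaps findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<- seqlevels<-
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct a labeled region set
#'
#' A region set is the package's container for one evidence track (a TF's
#' ChIP-seq peaks, a histone mark, ATAC open chromatin): a sorted
#' `GRanges` carrying a set label and stable per-region identifiers.
#' Coordinates are supplied in the BED convention (0-based, half-open
#' `[start, end)`) and converted once to the `GRanges` convention; all
#' writers convert back, so no other code path performs a conversion.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open interval bounds
#'   (`end > start >= 0`).
#' @param label Single string naming the evidence track; region ids are
#'   `label:i` with `i` the input (e.g. file line) order, and survive
#'   coordinate sorting.
#' @param name,score,strand Optional per-region BED fields. `strand` uses
#'   `"+"`, `"-"`, `"."`/`"*"` (unstranded).
#' @param summit Optional absolute 0-based summit coordinate (narrowPeak),
#'   `NA` where unknown.
#' @param extra Optional data.frame of additional per-region columns.
#' @param chrom_sizes Optional named integer vector of chromosome lengths;
#'   when supplied, every `chrom` must be present and every `end` must not
#'   exceed the declared length.
#' @return A sorted `GRanges` with names = region ids and
#'   `metadata()$label` set.
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(100L, 0L), c(200L, 50L), label = "tf")
#' names(rs)
#' @export
region_set <- function(chrom, start, end, label = "regions",
                       name = NULL, score = NULL, strand = NULL,
                       summit = NULL, extra = NULL, chrom_sizes = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    .stopf("chrom/start/end lengths differ")
  if (n > 0L) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      .stopf("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
      .stopf("interval bounds must be finite integers")
    if (any(start < 0L)) .stopf("negative start coordinate")
    bad <- which(end <= start)
    if (length(bad))
      .stopf("interval %d has end <= start (%d <= %d)",
             bad[1L], end[bad[1L]], start[bad[1L]])
  }
  if (is.null(strand)) strand <- rep("*", n)
  strand <- as.character(strand)
  strand[strand == "."] <- "*"
  if (n > 0L && !all(strand %in% c("+", "-", "*")))
    .stopf("strand must be one of '+', '-', '.', '*'")
  lev <- sort(unique(chrom))
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- validate_chrom_sizes(chrom_sizes)
    missing_chr <- setdiff(lev, names(chrom_sizes))
    if (length(missing_chr))
      .stopf("chromosome '%s' not present in chrom sizes", missing_chr[1L])
    lev <- names(chrom_sizes)
    too_long <- which(end > chrom_sizes[chrom])
    if (length(too_long))
      .stopf("interval %d extends past the end of %s",
             too_long[1L], chrom[too_long[1L]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = lev),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  if (!is.null(chrom_sizes)) seqlengths(gr) <- chrom_sizes[lev]
  names(gr) <- if (n) paste0(label, ":", seq_len(n)) else character()
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (!is.null(summit)) {
    summit <- as.integer(summit)
    ok <- is.na(summit) | (summit >= start & summit < end)
    if (n > 0L && !all(ok))
      .stopf("summit outside its interval at region %d", which(!ok)[1L])
    mcols(gr)$summit <- summit
  }
  if (!is.null(extra)) mcols(gr) <- cbind(mcols(gr), extra)
  metadata(gr)$label <- label
  sort_regions(gr)
}

#' @rdname region_set
#' @param rs A region set (`GRanges`).
#' @export
region_label <- function(rs) {
  lab <- metadata(rs)$label
  if (is.null(lab)) "regions" else lab
}

sort_regions <- function(gr) {
  o <- order(as.integer(seqnames(gr)), GenomicRanges::start(gr),
             GenomicRanges::end(gr), names(gr), method = "radix")
  gr[o]
}

#' View a region set as a BED-style data frame
#'
#' Converts back to 0-based half-open coordinates; the inverse of
#' [region_set()] up to column selection.
#'
#' @param rs A region set (`GRanges`).
#' @return A data.frame with columns `chrom`, `start`, `end`, `region_id`,
#'   `score`, `strand` plus any extra metadata columns (e.g. `summit`).
#' @export
region_frame <- function(rs) {
  df <- data.frame(
    chrom = as.character(seqnames(rs)),
    start = GenomicRanges::start(rs) - 1L,
    end = GenomicRanges::end(rs),
    region_id = if (is.null(names(rs))) rep(NA_character_, length(rs)) else names(rs),
    score = if (!is.null(mcols(rs)$score)) mcols(rs)$score else rep(0, length(rs)),
    strand = as.character(GenomicRanges::strand(rs)),
    stringsAsFactors = FALSE
  )
  keep <- setdiff(colnames(mcols(rs)), c("score", "name"))
  for (cn in keep) df[[cn]] <- mcols(rs)[[cn]]
  if (!is.null(mcols(rs)$name)) df$name <- mcols(rs)$name
  rownames(df) <- NULL
  df
}

.read_table_lines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_die <- function(x, what, lineno, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    .stopf("%s: line %d: non-numeric %s ('%s')",
           path, lineno[bad[1L]], what, x[bad[1L]])
  out
}

#' Read a peak/region file
#'
#' Parses BED3, BED6 or ENCODE narrowPeak into a region set. Coordinates in
#' these formats are 0-based half-open and are kept that way (see
#' [region_set()]). narrowPeak columns 7-10 (signalValue, pValue, qValue,
#' summit offset) are retained; the summit is stored as an absolute
#' coordinate (`start + offset`), `NA` when the offset is -1.
#'
#' @param path Path to the file. Comment/track/browser lines are ignored.
#' @param format One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param label Track label; defaults to the file name without extension.
#'   Region ids are `label:i` in file order.
#' @param chrom_sizes Optional named lengths for validation (see
#'   [region_set()]).
#' @return A region set (`GRanges`).
#' @export
read_regions <- function(path, format = c("bed3", "bed6", "narrowPeak"),
                         label = NULL, chrom_sizes = NULL) {
  format <- match.arg(format)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  tl <- .read_table_lines(path)
  if (length(tl$lines) == 0L)
    return(region_set(character(), integer(), integer(), label = label,
                      chrom_sizes = chrom_sizes))
  need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[format]]
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- which(nf < need)
  if (length(short))
    .stopf("%s: line %d has %d field(s); %s requires %d",
           path, tl$lineno[short[1L]], nf[short[1L]], format, need)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  start <- .num_or_die(col(2), "start", tl$lineno, path)
  end <- .num_or_die(col(3), "end", tl$lineno, path)
  if (any(start != floor(start)) || any(end != floor(end)))
    .stopf("%s: non-integer coordinates", path)
  bad <- which(end <= start)
  if (length(bad))
    .stopf("%s: line %d: end <= start", path, tl$lineno[bad[1L]])
  name <- score <- strand <- summit <- extra <- NULL
  if (format %in% c("bed6", "narrowPeak")) {
    name <- col(4)
    score <- .num_or_die(col(5), "score", tl$lineno, path)
    strand <- col(6)
  }
  if (format == "narrowPeak") {
    extra <- data.frame(
      signalValue = .num_or_die(col(7), "signalValue", tl$lineno, path),
      pValue = .num_or_die(col(8), "pValue", tl$lineno, path),
      qValue = .num_or_die(col(9), "qValue", tl$lineno, path)
    )
    off <- .num_or_die(col(10), "summit offset", tl$lineno, path)
    summit <- ifelse(off < 0, NA_integer_, as.integer(start + off))
  }
  region_set(chrom, start, end, label = label, name = name, score = score,
             strand = strand, summit = summit, extra = extra,
             chrom_sizes = chrom_sizes)
}

#' Merge overlapping and book-ended regions
#'
#' Collapses a region set into maximal intervals: regions that overlap by at
#' least 1 bp or touch end-to-start are merged (the usual interval-tool
#' semantics). Strand is ignored. Total covered length is preserved and the
#' operation is idempotent.
#'
#' @param rs A region set.
#' @return A region set with the same label; region ids are reassigned
#'   `label:1..n` in coordinate order.
#' @export
merge_regions <- function(rs) {
  merged <- GenomicRanges::reduce(granges(rs), ignore.strand = TRUE,
                                  min.gapwidth = 1L)
  names(merged) <- if (length(merged))
    paste0(region_label(rs), ":", seq_along(merged)) else character()
  metadata(merged)$label <- region_label(rs)
  merged
}

#' Write a region set as BED6
#'
#' Coordinates are emitted 0-based half-open; the name column holds the
#' region id (or the original `name` metadata when present), so
#' `read_regions(write_region_set(x))` round-trips coordinates and order.
#'
#' @param rs A region set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(rs, path) {
  df <- region_frame(rs)
  nm <- if (!is.null(mcols(rs)$name)) mcols(rs)$name else df$region_id
  strand <- df$strand
  strand[strand == "*"] <- "."
  lines <- if (nrow(df) == 0L) character() else
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end, nm,
            formatC(df$score, format = "fg"), strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Chromosome sizes
#'
#' A chromosome-sizes table is a named integer vector (name -> length in
#' bp), read from / written to the standard two-column `chrom.sizes` TSV.
#'
#' @param path Path to a two-column TSV (chromosome, length).
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tl <- .read_table_lines(path)
  if (length(tl$lines) == 0L) .stopf("%s: empty chrom sizes file", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) .stopf("%s: chrom sizes needs 2 columns", path)
  sizes <- as.integer(.num_or_die(vapply(fields, `[[`, character(1), 2),
                                  "length", tl$lineno, path))
  names(sizes) <- vapply(fields, `[[`, character(1), 1)
  validate_chrom_sizes(sizes)
}

#' @rdname read_chrom_sizes
#' @param sizes Named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  sizes <- validate_chrom_sizes(sizes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", names(sizes), sizes), con)
  invisible(path)
}

#' @rdname read_chrom_sizes
#' @export
validate_chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    .stopf("chrom sizes must be a named vector")
  if (anyDuplicated(names(sizes)))
    .stopf("duplicate chromosome in chrom sizes")
  nm <- names(sizes)
  sizes <- as.integer(round(sizes))
  names(sizes) <- nm
  if (any(is.na(sizes)) || any(sizes <= 0L))
    .stopf("chromosome lengths must be positive")
  sizes
}
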