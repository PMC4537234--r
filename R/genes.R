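#' Gene annotation table
#'
#' Genes are held as a plain data.frame with one row per gene:
#' `gene_id`, `chrom`, `tss` (0-based coordinate of the transcription start
#' site) and `strand` (`+`/`-`). The TSS is the anchor for every
#' peak-to-gene distance in the package.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome per gene.
#' @param tss 0-based TSS coordinate per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param chrom_sizes Optional named lengths; when given, every gene's
#'   chromosome must be declared and its TSS must lie within it.
#' @return A validated data.frame.
#' @export
gene_table <- function(gene_id, chrom, tss, strand, chrom_sizes = NULL) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   tss = as.integer(tss),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    .stopf("duplicate gene_id: %s", df$gene_id[duplicated(df$gene_id)][1L])
  if (nrow(df) > 0L) {
    if (any(is.na(df$tss)) || any(df$tss < 0L)) .stopf("TSS must be >= 0")
    if (!all(df$strand %in% c("+", "-")))
      .stopf("gene strand must be '+' or '-'")
    if (!is.null(chrom_sizes)) {
      chrom_sizes <- validate_chrom_sizes(chrom_sizes)
      miss <- setdiff(unique(df$chrom), names(chrom_sizes))
      if (length(miss)) .stopf("gene chromosome '%s' not declared", miss[1L])
      if (any(df$tss >= chrom_sizes[df$chrom]))
        .stopf("TSS beyond declared chromosome length")
    }
  }
  rownames(df) <- NULL
  df
}

#' Read gene annotation
#'
#' Reads genes from BED6 (name column = gene id; BED coordinates are
#' 0-based half-open, so TSS = `start` for `+` genes and `end - 1` for `-`
#' genes) or from GTF (`gene`/`transcript` features; GTF is 1-based
#' inclusive and is converted on read — the only place a coordinate
#' conversion happens for genes). For multi-transcript GTF genes the TSS is
#' the 5'-most transcript start on the gene's strand.
#'
#' @param path File path.
#' @param format `"bed6"` or `"gtf"`.
#' @param attribute GTF attribute key holding the gene identifier
#'   (default `"gene_id"`).
#' @param chrom_sizes Optional named lengths for validation.
#' @return A [gene_table()] data.frame.
#' @export
read_genes <- function(path, format = c("bed6", "gtf"),
                       attribute = "gene_id", chrom_sizes = NULL) {
  format <- match.arg(format)
  tl <- .read_table_lines(path)
  if (length(tl$lines) == 0L)
    return(gene_table(character(), character(), integer(), character()))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (format == "bed6") {
    short <- which(lengths(fields) < 6L)
    if (length(short))
      .stopf("%s: line %d: BED6 gene rows need 6 columns",
             path, tl$lineno[short[1L]])
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- as.integer(.num_or_die(vapply(fields, `[[`, character(1), 2),
                                    "start", tl$lineno, path))
    end <- as.integer(.num_or_die(vapply(fields, `[[`, character(1), 3),
                                  "end", tl$lineno, path))
    gene_id <- vapply(fields, `[[`, character(1), 4)
    strand <- vapply(fields, `[[`, character(1), 6)
    if (!all(strand %in% c("+", "-")))
      .stopf("%s: gene rows must carry '+' or '-' strand", path)
    if (anyDuplicated(gene_id))
      .stopf("%s: duplicate gene_id '%s'", path,
             gene_id[duplicated(gene_id)][1L])
    tss <- ifelse(strand == "+", start, end - 1L)
    return(gene_table(gene_id, chrom, tss, strand, chrom_sizes = chrom_sizes))
  }
  # GTF
  short <- which(lengths(fields) < 9L)
  if (length(short))
    .stopf("%s: line %d: GTF rows need 9 columns", path, tl$lineno[short[1L]])
  feat <- vapply(fields, `[[`, character(1), 3)
  keep <- feat %in% c("gene", "transcript")
  fields <- fields[keep]; lineno <- tl$lineno[keep]
  if (length(fields) == 0L)
    return(gene_table(character(), character(), integer(), character()))
  chrom <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.integer(.num_or_die(vapply(fields, `[[`, character(1), 4),
                                   "start", lineno, path))
  end1 <- as.integer(.num_or_die(vapply(fields, `[[`, character(1), 5),
                                 "end", lineno, path))
  strand <- vapply(fields, `[[`, character(1), 7)
  if (!all(strand %in% c("+", "-")))
    .stopf("%s: GTF gene/transcript rows must carry '+' or '-' strand", path)
  attrs <- vapply(fields, `[[`, character(1), 9)
  pat <- paste0(attribute, "[ =]+\"?([^\";]+)\"?")
  m <- regmatches(attrs, regexec(pat, attrs))
  got <- lengths(m) == 2L
  if (any(!got))
    .stopf("%s: line %d: missing attribute '%s'",
           path, lineno[which(!got)[1L]], attribute)
  gene_id <- vapply(m, `[[`, character(1), 2)
  # 5'-most transcript start per gene on its strand; 1-based -> 0-based
  tss0 <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
  out <- do.call(rbind, lapply(split(seq_along(gene_id), gene_id), function(i) {
    st <- unique(strand[i]); ch <- unique(chrom[i])
    if (length(st) > 1L)
      .stopf("%s: gene '%s' has conflicting strands", path, gene_id[i[1L]])
    if (length(ch) > 1L)
      .stopf("%s: gene '%s' spans chromosomes", path, gene_id[i[1L]])
    tss <- if (st == "+") min(tss0[i]) else max(tss0[i])
    data.frame(gene_id = gene_id[i[1L]], chrom = ch, tss = tss, strand = st,
               stringsAsFactors = FALSE)
  }))
  gene_table(out$gene_id, out$chrom, out$tss, out$strand,
             chrom_sizes = chrom_sizes)
}

#' Read a gene-level differential-expression table
#'
#' Expects a TSV with a header containing at least `gene_id`, `log2fc`
#' (log2 fold change, case vs control) and `qvalue` (FDR-adjusted, in
#' \[0, 1\]); extra columns are ignored.
#'
#' @param path File path.
#' @return data.frame with columns `gene_id`, `log2fc`, `qvalue`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "log2fc", "qvalue")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .stopf("%s: missing column '%s'", path, miss[1L])
  expression_table(df$gene_id,
                   .num_or_die(df$log2fc, "log2fc", seq_len(nrow(df)) + 1L, path),
                   .num_or_die(df$qvalue, "qvalue", seq_len(nrow(df)) + 1L, path))
}

#' @rdname read_expression_table
#' @param gene_id,log2fc,qvalue Column vectors.
#' @export
expression_table <- function(gene_id, log2fc, qvalue) {
  df <- data.frame(gene_id = as.character(gene_id),
                   log2fc = as.numeric(log2fc),
                   qvalue = as.numeric(qvalue),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    .stopf("duplicate gene_id in expression table: %s",
           df$gene_id[duplicated(df$gene_id)][1L])
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$log2fc))) .stopf("log2fc must be finite")
    if (any(is.na(df$qvalue)) || any(df$qvalue < 0) || any(df$qvalue > 1))
      .stopf("qvalue must lie in [0, 1]")
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_expression_table
#' @param tab Expression table.
#' @export
write_expression_table <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene_id\tlog2fc\tqvalue",
               if (nrow(tab)) sprintf("%s\t%.6f\t%.6g", tab$gene_id,
                                      tab$log2fc, tab$qvalue)), con)
  invisible(path)
}

#' Named gene sets with provenance
#'
#' A gene set is the currency of the evidence cascade: a label, a sorted
#' unique vector of gene ids, and a provenance list recording each
#' derivation step (stage name + parameters), sufficient to recompute the
#' set.
#'
#' @param ids Character vector of gene ids (de-duplicated, sorted).
#' @param label Stage name.
#' @param provenance List of records, each a `list(stage=, params=)`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(ids, label = "gene_set", provenance = list()) {
  structure(list(label = label,
                 ids = sort(unique(as.character(ids))),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes; %d provenance step(s)>\n",
              x$label, length(x$ids), length(x$provenance)))
  invisible(x)
}

gs_derive <- function(ids, label, parents, params = list()) {
  prov <- c(unlist(lapply(parents, function(p)
    if (inherits(p, "gene_set")) p$provenance else list()), recursive = FALSE),
    list(list(stage = label, params = params,
              parents = vapply(parents, function(p)
                if (inherits(p, "gene_set")) p$label else "regions",
                character(1)))))
  gene_set(ids, label = label, provenance = prov)
}

#' Write / read a gene set as single-column TSV
#'
#' The file carries `#`-prefixed provenance header lines followed by one
#' gene id per line in sorted order (deterministic output).
#'
#' @param gs A `gene_set`.
#' @param path File path.
#' @export
write_gene_set <- function(gs, path) {
  hdr <- c(sprintf("# gene_set\t%s\tn=%d", gs$label, length(gs$ids)),
           vapply(gs$provenance, function(p)
             sprintf("# stage\t%s", p$stage), character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, gs$ids), con)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path, label = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  lab <- label
  if (is.null(lab)) {
    lab <- "gene_set"
    if (any(hdr)) {
      m <- regmatches(lines[hdr][1], regexec("^# gene_set\t([^\t]+)", lines[hdr][1]))
      if (length(m[[1]]) == 2L) lab <- m[[1]][2]
    }
  }
  gene_set(lines[!hdr & nzchar(lines)], label = lab)
}
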