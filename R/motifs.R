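IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

#' Consensus motif
#'
#' A named IUPAC consensus (degenerate DNA string). Matching expands each
#' code to its base set; `N` in a scanned sequence never matches because
#' the expansion only contains A/C/G/T.
#'
#' @param name Motif name.
#' @param iupac IUPAC DNA string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return Object of class `consensus_motif`.
#' @export
consensus_motif <- function(name, iupac) {
  iupac <- toupper(iupac)
  if (!nzchar(iupac)) .stopf("empty motif")
  chars <- strsplit(iupac, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad)) .stopf("invalid IUPAC character '%s' in motif", bad[1L])
  structure(list(name = name, iupac = iupac, length = length(chars)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif %s: %s>\n", x$name, x$iupac))
  invisible(x)
}

#' Default motif library
#'
#' Conventional literature consensi for the factors relevant to the
#' myoblast cascade: RUNX (`TGYGGTY`), the MyoD E-box (`CAGCTG`) and AP-1
#' (`TGASTCA`). User-extensible via [read_motif_table()].
#'
#' @return Named list of [consensus_motif()]s.
#' @export
default_motifs <- function() {
  list(RUNX = consensus_motif("RUNX", "TGYGGTY"),
       MyoD = consensus_motif("MyoD", "CAGCTG"),
       AP1 = consensus_motif("AP1", "TGASTCA"))
}

#' @rdname default_motifs
#' @param path Two-column TSV (`name`, `iupac`), with header.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("name", "iupac") %in% colnames(df)))
    .stopf("%s: motif table needs columns 'name' and 'iupac'", path)
  stats::setNames(lapply(seq_len(nrow(df)),
                         function(i) consensus_motif(df$name[i], df$iupac[i])),
                  df$name)
}

#' Reverse complement of an IUPAC string
#'
#' @param x DNA/IUPAC string.
#' @return The reverse complement (degenerate codes mapped to their
#'   complementary sets).
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

.iupac_regex <- function(iupac) {
  paste0(IUPAC_CLASS[strsplit(iupac, "")[[1]]], collapse = "")
}

.scan_offsets <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

#' Scan a sequence for a consensus motif
#'
#' Reports every offset (0-based, overlapping matches included) where the
#' IUPAC pattern matches on the forward strand, and — when
#' `both_strands` — where its reverse complement matches, reported with
#' strand `-` at the forward-strand offset.
#'
#' @param sequence DNA string over A,C,G,T,N (case-insensitive). `N` never
#'   matches a non-N motif position.
#' @param motif A [consensus_motif()].
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return data.frame: `offset`, `strand`, `motif`.
#' @export
scan_consensus <- function(sequence, motif, both_strands = TRUE) {
  stopifnot(inherits(motif, "consensus_motif"))
  sequence <- toupper(as.character(sequence))
  fwd <- .scan_offsets(sequence, .iupac_regex(motif$iupac))
  out <- data.frame(offset = fwd,
                    strand = rep("+", length(fwd)),
                    motif = rep(motif$name, length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- .scan_offsets(sequence, .iupac_regex(reverse_complement(motif$iupac)))
    out <- rbind(out, data.frame(offset = rc,
                                 strand = rep("-", length(rc)),
                                 motif = rep(motif$name, length(rc)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Fetch region sequences
#'
#' Sequences can come from a genome source (named by chromosome; regions
#' are cut out by coordinate) or a per-region source (named by region id).
#'
#' @param rs A region set.
#' @param seqs A named `Biostrings::DNAStringSet` or named character
#'   vector. Names are chromosomes (genome mode) or region ids
#'   (per-region mode).
#' @return Named character vector of sequences, one per region.
#' @export
region_sequences <- function(rs, seqs) {
  sq <- stats::setNames(as.character(seqs), names(seqs))
  ids <- names(rs)
  if (length(rs) && all(ids %in% names(sq)))
    return(sq[ids])
  chrom <- as.character(seqnames(rs))
  miss <- setdiff(unique(chrom), names(sq))
  if (length(miss))
    .stopf("no sequence for chromosome or region '%s'", miss[1L])
  lens <- nchar(sq)
  if (any(GenomicRanges::end(rs) > lens[chrom]))
    .stopf("region extends beyond its sequence")
  stats::setNames(substring(sq[chrom], GenomicRanges::start(rs),
                            GenomicRanges::end(rs)), ids)
}

#' Fraction of regions containing a motif
#'
#' @inheritParams region_sequences
#' @param motif A [consensus_motif()].
#' @param both_strands Count matches on either strand (default TRUE).
#' @return Fraction of regions with >= 1 match.
#' @export
fraction_with_motif <- function(rs, seqs, motif, both_strands = TRUE) {
  if (length(rs) == 0L) .stopf("empty region set")
  sq <- region_sequences(rs, seqs)
  mean(.has_motif(toupper(sq), motif, both_strands))
}

.has_motif <- function(sq_upper, motif, both_strands = TRUE) {
  hit <- grepl(.iupac_regex(motif$iupac), sq_upper, perl = TRUE)
  if (both_strands) {
    hit <- hit | grepl(.iupac_regex(reverse_complement(motif$iupac)),
                       sq_upper, perl = TRUE)
  }
  hit
}

.motif_mids <- function(sq_upper, motif) {
  half <- motif$length / 2
  fwd <- .scan_offsets(sq_upper, .iupac_regex(motif$iupac))
  rev_ <- .scan_offsets(sq_upper, .iupac_regex(reverse_complement(motif$iupac)))
  c(fwd, rev_) + half
}

#' Shuffle sequences preserving composition
#'
#' Mononucleotide shuffle: each sequence is permuted independently, so the
#' exact nucleotide composition of every region is preserved. Used as the
#' null for [module_cooccurrence()]; seed-reproducible.
#'
#' @param seqs Character vector of sequences.
#' @param seed Integer seed.
#' @return Shuffled character vector, same names.
#' @export
shuffle_sequences <- function(seqs, seed) {
  withr::with_seed(seed, {
    vapply(seqs, function(s) {
      paste0(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = TRUE)
  })
}

#' Motif-module co-occurrence around an anchor motif
#'
#' A region contains the (anchor, partner) module when some partner-match
#' midpoint lies within `window_bp` of some anchor-match midpoint (either
#' strand). Significance comes from a per-region mononucleotide-shuffle
#' null: all sequences are shuffled `n_shuffles` times, the module count is
#' recomputed each time, `fold_enrichment` is observed / mean(null), and
#' the p-value uses the add-one empirical rule.
#'
#' @inheritParams region_sequences
#' @param anchor A [consensus_motif()] (e.g. RUNX).
#' @param partners List of partner [consensus_motif()]s.
#' @param window_bp Half-window around the anchor midpoint (default 50).
#' @param n_shuffles Null shuffles (default 999).
#' @param seed Integer seed.
#' @return data.frame, one row per partner: `anchor`, `partner`,
#'   `window_bp`, `n_regions_with_anchor`, `n_regions_with_module`,
#'   `fold_enrichment`, `p_empirical`.
#' @export
module_cooccurrence <- function(rs, seqs, anchor, partners,
                                window_bp = 50L, n_shuffles = 999L,
                                seed = 1L) {
  if (window_bp <= 0) .stopf("window_bp must be positive")
  if (inherits(partners, "consensus_motif")) partners <- list(partners)
  sq <- toupper(region_sequences(rs, seqs))
  count_modules <- function(sqs) {
    n_anchor <- 0L
    n_mod <- integer(length(partners))
    for (s in sqs) {
      am <- .motif_mids(s, anchor)
      if (length(am) == 0L) next
      n_anchor <- n_anchor + 1L
      for (j in seq_along(partners)) {
        pm <- .motif_mids(s, partners[[j]])
        if (length(pm) &&
            min(vapply(am, function(a) min(abs(pm - a)), numeric(1))) <= window_bp)
          n_mod[j] <- n_mod[j] + 1L
      }
    }
    list(anchor = n_anchor, modules = n_mod)
  }
  obs <- count_modules(sq)
  null_counts <- matrix(0L, nrow = n_shuffles, ncol = length(partners))
  shuffle_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max, n_shuffles)
  })
  for (i in seq_len(n_shuffles)) {
    shuf <- shuffle_sequences(sq, shuffle_seeds[i])
    null_counts[i, ] <- count_modules(shuf)$modules
  }
  out <- do.call(rbind, lapply(seq_along(partners), function(j) {
    observed <- obs$modules[j]
    null_j <- null_counts[, j]
    fold <- if (observed == 0L) 0 else if (mean(null_j) == 0) Inf else
      observed / mean(null_j)
    p <- if (obs$anchor == 0L) 1 else
      (1 + sum(null_j >= observed)) / (1 + n_shuffles)
    data.frame(anchor = anchor$name, partner = partners[[j]]$name,
               window_bp = as.integer(window_bp),
               n_regions_with_anchor = obs$anchor,
               n_regions_with_module = observed,
               fold_enrichment = fold, p_empirical = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
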