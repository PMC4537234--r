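#' Synthetic dataset configuration
#'
#' Parameters of the seeded toy-genome generator. Defaults mirror the
#' fractions reported for primary-myoblast data — MyoD co-occupancy 0.46
#' and c-Jun 0.47 at Runx1 peaks, active-enhancer marking at 70% and open
#' chromatin at 25% of peaks, a RUNX motif planted in 95% of peaks — so
#' that recovery tests against ground truth are meaningful.
#'
#' @param seed Integer seed (mandatory); a fixed seed regenerates the
#'   dataset byte-identically.
#' @param n_chroms,chrom_length Toy genome shape (default 2 x 10 Mb).
#' @param n_genes Genes, TSS placed uniformly with minimum spacing
#'   `tss_spacing_bp` (default 500 genes, 20 kb spacing).
#' @param n_runx1_peaks Runx1 peaks (default 1000).
#' @param peak_length_mean,peak_length_sd,peak_length_min Truncated-normal
#'   peak lengths (default 200 +/- 50, min 50).
#' @param p_myod_given_runx1,p_cjun_given_runx1 Probability that a MyoD /
#'   c-Jun peak is co-planted at a Runx1 peak (defaults 0.46, 0.47;
#'   independent draws, so triples arise at their product).
#' @param n_background_peaks Independent background peaks per partner TF
#'   (default 500).
#' @param jitter_bp Maximum center offset of a co-planted peak
#'   (default 100).
#' @param p_mark_given_peak Probability a Runx1 peak gets both H3K4me1 and
#'   H3K27ac peaks planted on it (default 0.7).
#' @param p_atac_given_peak Probability of a planted ATAC peak
#'   (default 0.25).
#' @param n_background_marks Background regions per mark/ATAC track
#'   (default 200).
#' @param mark_length_mean,mark_length_sd,atac_length_mean,atac_length_sd
#'   Lengths for mark / ATAC regions.
#' @param p_motif_anchor Probability a Runx1 peak carries a planted RUNX
#'   consensus at its center (default 0.95).
#' @param p_motif_partner_in_window Probability an anchor-bearing peak also
#'   carries a planted E-box partner within the module window
#'   (default 0.6).
#' @param motif_window_bp Module window (default 50).
#' @param p_responsive_bound,p_responsive_unbound Probability a gene is
#'   differentially expressed given it has / lacks a Runx1 peak anchor
#'   within `window_bp` of its TSS (defaults 0.30 / 0.05; the gap is the
#'   planted binding-expression link).
#' @param effect_size Mean |log2 fold change| of responsive genes
#'   (default 1.5).
#' @param lfc_se Standard error scaling log2fc into a z-statistic
#'   (default 0.25; the responsive z-shift is `effect_size / lfc_se`).
#' @param direction_bias,direction_bias_in_vivo Probability a responsive
#'   gene is upregulated, culture-like and in-vivo-like tables
#'   (defaults 0.75, 0.87).
#' @param window_bp TSS window for the planted binding-expression link
#'   (default 200,000).
#' @param tss_spacing_bp Minimum spacing between TSSs (default 20,000).
#' @param emit_sequences Generate the genome sequence (default TRUE; turn
#'   off for runs that do not touch motifs).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_chroms = 2L, chrom_length = 10000000L,
                             n_genes = 500L, n_runx1_peaks = 1000L,
                             peak_length_mean = 200, peak_length_sd = 50,
                             peak_length_min = 50,
                             p_myod_given_runx1 = 0.46,
                             p_cjun_given_runx1 = 0.47,
                             n_background_peaks = 500L,
                             jitter_bp = 100L,
                             p_mark_given_peak = 0.7,
                             p_atac_given_peak = 0.25,
                             n_background_marks = 200L,
                             mark_length_mean = 500, mark_length_sd = 100,
                             atac_length_mean = 250, atac_length_sd = 50,
                             p_motif_anchor = 0.95,
                             p_motif_partner_in_window = 0.6,
                             motif_window_bp = 50L,
                             p_responsive_bound = 0.30,
                             p_responsive_unbound = 0.05,
                             effect_size = 1.5, lfc_se = 0.25,
                             direction_bias = 0.75,
                             direction_bias_in_vivo = 0.87,
                             window_bp = 200000L,
                             tss_spacing_bp = 20000L,
                             emit_sequences = TRUE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    .stopf("synthetic_config requires a seed")
  cfg <- as.list(environment())
  probs <- c("p_myod_given_runx1", "p_cjun_given_runx1", "p_mark_given_peak",
             "p_atac_given_peak", "p_motif_anchor",
             "p_motif_partner_in_window", "p_responsive_bound",
             "p_responsive_unbound", "direction_bias",
             "direction_bias_in_vivo")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      .stopf("%s must be a probability in [0, 1] (got %g)", p, cfg[[p]])
  if (cfg$p_responsive_bound < cfg$p_responsive_unbound)
    .stopf("p_responsive_bound must be >= p_responsive_unbound")
  for (k in c("n_chroms", "chrom_length", "n_genes", "n_runx1_peaks"))
    if (cfg[[k]] < 1) .stopf("%s must be >= 1", k)
  # packing feasibility: genes with minimum spacing must fit every chromosome
  n_per <- .split_count(cfg$n_genes, cfg$n_chroms)
  margin <- 2000
  if (any(2 * margin + (n_per - 1) * cfg$tss_spacing_bp > cfg$chrom_length))
    .stopf("infeasible packing: %d genes at %d bp spacing exceed a %d bp chromosome",
           max(n_per), cfg$tss_spacing_bp, cfg$chrom_length)
  structure(cfg, class = "synthetic_config")
}

#' Null (zero-signal) configuration
#'
#' A [synthetic_config()] in which no dependence is planted: co-planting,
#' mark, open-chromatin and motif probabilities are 0 and the responsive
#' rate is identical for bound and unbound genes, so every evidence layer
#' is independent of every other. Used for calibration of the resampling
#' tests.
#'
#' @param seed Integer seed.
#' @param p_responsive Common responsive rate (default 0.3).
#' @param ... Overrides passed to [synthetic_config()].
#' @export
zero_signal_config <- function(seed, p_responsive = 0.3, ...) {
  args <- list(seed = seed,
               p_myod_given_runx1 = 0, p_cjun_given_runx1 = 0,
               p_mark_given_peak = 0, p_atac_given_peak = 0,
               p_motif_anchor = 0, p_motif_partner_in_window = 0,
               p_responsive_bound = p_responsive,
               p_responsive_unbound = p_responsive,
               emit_sequences = FALSE)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

.split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

.trunc_lengths <- function(n, mean, sd, min_len) {
  pmax(as.integer(min_len), as.integer(round(stats::rnorm(n, mean, sd))))
}

.uniform_regions <- function(n_total, sizes, len_mean, len_sd, len_min,
                             margin = 200) {
  n_per <- .split_count(n_total, length(sizes))
  chrom <- rep(names(sizes), n_per)
  L <- as.numeric(sizes[chrom])
  center <- floor(stats::runif(n_total) * (L - 2 * margin)) + margin
  len <- .trunc_lengths(n_total, len_mean, len_sd, len_min)
  start <- pmax(0, center - len %/% 2)
  end <- pmin(L, start + len)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             center = as.integer(center), stringsAsFactors = FALSE)
}

.planted_regions <- function(base, keep, jitter_bp, sizes,
                             len_mean, len_sd, len_min) {
  df <- base[keep, c("chrom", "center"), drop = FALSE]
  n <- nrow(df)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer()))
  jit <- if (jitter_bp > 0)
    sample.int(2L * jitter_bp + 1L, n, replace = TRUE) - jitter_bp - 1L
  else rep(0L, n)
  center <- df$center + jit
  len <- .trunc_lengths(n, len_mean, len_sd, len_min)
  L <- as.numeric(sizes[df$chrom])
  start <- pmax(0, center - len %/% 2)
  end <- pmin(L, start + len)
  data.frame(chrom = df$chrom, start = as.integer(start),
             end = as.integer(end), center = as.integer(center),
             stringsAsFactors = FALSE)
}

.df_to_regions <- function(df, label, sizes) {
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  region_set(df$chrom, df$start, df$end, label = label, chrom_sizes = sizes)
}

# any Runx1 center within window of each position, per chromosome
.near_any <- function(genes, centers_df, window_bp, subset = NULL) {
  keep <- if (is.null(subset)) rep(TRUE, nrow(centers_df)) else subset
  out <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    cs <- sort(centers_df$center[keep & centers_df$chrom == ch])
    gi <- which(genes$chrom == ch)
    if (length(cs) == 0L || length(gi) == 0L) next
    lo <- findInterval(genes$tss[gi] - window_bp - 1, cs)
    hi <- findInterval(genes$tss[gi] + window_bp, cs)
    out[gi] <- hi > lo
  }
  out
}

.simulate_expression <- function(genes, bound, p_bound, p_unbound,
                                 effect_size, lfc_se, direction_bias) {
  n <- nrow(genes)
  responsive <- stats::runif(n) < ifelse(bound, p_bound, p_unbound)
  up <- stats::runif(n) < direction_bias
  z0 <- stats::rnorm(n)
  shift <- effect_size / lfc_se
  z <- ifelse(responsive, ifelse(up, 1, -1) * (shift + z0), z0)
  log2fc <- z * lfc_se
  pval <- 2 * stats::pnorm(-abs(z))
  qval <- stats::p.adjust(pval, method = "BH")
  list(table = expression_table(genes$gene_id, log2fc, qval),
       responsive = responsive, up = up)
}

RUNX_INSTANCE <- "TGTGGTT"  # concrete realization of the RUNX consensus
EBOX_INSTANCE <- "CAGCTG"   # MyoD E-box, its own consensus

#' Generate a synthetic multi-evidence dataset
#'
#' Builds a toy genome with genes, three TF peak sets with planted
#' pairwise/triple co-occupancy, histone-mark and ATAC tracks
#' preferentially at Runx1 peaks, a genome sequence with consensus motifs
#' planted at peak centers, and two expression tables (culture-like and
#' in-vivo-like) in which genes near Runx1 peaks are enriched for
#' significant changes. Expression significance is simulated through
#' z-statistics whose two-sided normal p-values are Benjamini-Hochberg
#' adjusted into the emitted q-value column, so q-values have realistic
#' rank structure. All randomness flows from `config$seed`; regeneration
#' under the same seed is byte-identical.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional directory; when given, all files (chrom.sizes,
#'   BED6 tracks, genes.bed, genome.fa, expression TSVs,
#'   ground_truth.json) are written there and a `files` manifest is
#'   attached to the result.
#' @return List: `config`, `dataset_id`, `chrom_sizes`, `genes`,
#'   `regions` (list of six region sets), `genome` (named character,
#'   `NULL` unless `emit_sequences`), `expression`, `expression_in_vivo`,
#'   `truth` (per-peak and per-gene planted labels plus motif positions),
#'   and `files` when `outdir` was used.
#' @export
generate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- withr::with_seed(config$seed, .generate_dataset_impl(config))
  if (!is.null(outdir)) out <- .write_dataset(out, outdir)
  out
}

.generate_dataset_impl <- function(config) {
  sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                               config$n_chroms),
                           paste0("chr", seq_len(config$n_chroms)))
  margin <- 2000L

  # genes: uniform TSS with minimum spacing
  n_per <- .split_count(config$n_genes, config$n_chroms)
  tss <- integer(); chrom <- character()
  for (i in seq_along(sizes)) {
    n_c <- n_per[i]
    if (n_c == 0L) next
    slack <- config$chrom_length - 2 * margin -
      (n_c - 1) * config$tss_spacing_bp
    u <- sort(floor(stats::runif(n_c) * (slack + 1)))
    tss <- c(tss, as.integer(margin + u +
                               (seq_len(n_c) - 1L) * config$tss_spacing_bp))
    chrom <- c(chrom, rep(names(sizes)[i], n_c))
  }
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- gene_table(sprintf("g%04d", seq_len(config$n_genes)),
                      chrom, tss, strand, chrom_sizes = sizes)

  # Runx1 peaks (coordinate-sorted so truth labels align with region ids)
  runx1_df <- .uniform_regions(config$n_runx1_peaks, sizes,
                               config$peak_length_mean,
                               config$peak_length_sd,
                               config$peak_length_min, margin = margin)
  runx1_df <- runx1_df[order(runx1_df$chrom, runx1_df$start, runx1_df$end), ,
                       drop = FALSE]
  rownames(runx1_df) <- NULL
  n_pk <- nrow(runx1_df)
  runx1 <- .df_to_regions(runx1_df, "Runx1", sizes)

  co_myod <- stats::runif(n_pk) < config$p_myod_given_runx1
  co_cjun <- stats::runif(n_pk) < config$p_cjun_given_runx1
  marked <- stats::runif(n_pk) < config$p_mark_given_peak
  open_ <- stats::runif(n_pk) < config$p_atac_given_peak

  partner_peaks <- function(keep, len_mean, len_sd, len_min, n_bg) {
    planted <- .planted_regions(runx1_df, keep, config$jitter_bp, sizes,
                                len_mean, len_sd, len_min)
    bg <- .uniform_regions(n_bg, sizes, len_mean, len_sd, len_min,
                           margin = margin)
    rbind(planted, bg)
  }
  myod_df <- partner_peaks(co_myod, config$peak_length_mean,
                           config$peak_length_sd, config$peak_length_min,
                           config$n_background_peaks)
  cjun_df <- partner_peaks(co_cjun, config$peak_length_mean,
                           config$peak_length_sd, config$peak_length_min,
                           config$n_background_peaks)
  k4_df <- partner_peaks(marked, config$mark_length_mean,
                         config$mark_length_sd, 100, config$n_background_marks)
  k27_df <- partner_peaks(marked, config$mark_length_mean,
                          config$mark_length_sd, 100, config$n_background_marks)
  atac_df <- partner_peaks(open_, config$atac_length_mean,
                           config$atac_length_sd, 100, config$n_background_marks)

  regions <- list(
    runx1 = runx1,
    myod = .df_to_regions(myod_df, "MyoD", sizes),
    cjun = .df_to_regions(cjun_df, "cJun", sizes),
    h3k4me1 = .df_to_regions(k4_df, "H3K4me1", sizes),
    h3k27ac = .df_to_regions(k27_df, "H3K27ac", sizes),
    atac = .df_to_regions(atac_df, "ATAC", sizes))

  # genome sequence with planted motifs
  genome <- NULL
  has_anchor <- rep(FALSE, n_pk)
  has_partner <- rep(FALSE, n_pk)
  motif_rows <- list()
  if (config$emit_sequences) {
    base_raw <- charToRaw("ACGT")
    genome_raw <- lapply(sizes, function(L)
      base_raw[sample.int(4L, L, replace = TRUE)])
    has_anchor <- stats::runif(n_pk) < config$p_motif_anchor
    has_partner <- has_anchor &
      stats::runif(n_pk) < config$p_motif_partner_in_window
    plant <- function(ch, pos0, instance) {
      # pos0 is 0-based; raw vector is 1-based
      genome_raw[[ch]][(pos0 + 1L):(pos0 + nchar(instance))] <<-
        charToRaw(instance)
    }
    anchor_start <- runx1_df$center - 3L  # RUNX instance centered on the peak
    off_mag <- sample(10:40, n_pk, replace = TRUE)
    off_sign <- sample(c(-1L, 1L), n_pk, replace = TRUE)
    for (i in which(has_anchor)) {
      plant(runx1_df$chrom[i], anchor_start[i], RUNX_INSTANCE)
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(region_id = names(runx1)[i], motif = "RUNX",
                   chrom = runx1_df$chrom[i], pos = anchor_start[i],
                   stringsAsFactors = FALSE)
    }
    for (i in which(has_partner)) {
      p0 <- anchor_start[i] + off_sign[i] * off_mag[i]
      plant(runx1_df$chrom[i], p0, EBOX_INSTANCE)
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(region_id = names(runx1)[i], motif = "MyoD",
                   chrom = runx1_df$chrom[i], pos = p0,
                   stringsAsFactors = FALSE)
    }
    genome <- vapply(genome_raw, rawToChar, character(1))
  }

  # expression with binding-linked responsiveness
  bound <- .near_any(genes, runx1_df, config$window_bp)
  rmj_near <- .near_any(genes, runx1_df, config$window_bp,
                        subset = co_myod & co_cjun)
  hc_near <- .near_any(genes, runx1_df, config$window_bp,
                       subset = co_myod & co_cjun & marked & open_)
  ex <- .simulate_expression(genes, bound, config$p_responsive_bound,
                             config$p_responsive_unbound,
                             config$effect_size, config$lfc_se,
                             config$direction_bias)
  ex_vivo <- .simulate_expression(genes, bound, config$p_responsive_bound,
                                  config$p_responsive_unbound,
                                  config$effect_size, config$lfc_se,
                                  config$direction_bias_in_vivo)

  dataset_id <- sprintf("synth-seed%d-pk%d-g%d", config$seed,
                        config$n_runx1_peaks, config$n_genes)
  truth <- list(
    dataset_id = dataset_id,
    peaks = data.frame(region_id = names(runx1),
                       chrom = runx1_df$chrom, center = runx1_df$center,
                       co_myod = co_myod, co_cjun = co_cjun,
                       marked = marked, open = open_,
                       has_anchor_motif = has_anchor,
                       has_partner_motif = has_partner,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = genes$gene_id,
                       bound = bound, rmj_near = rmj_near, hc_near = hc_near,
                       responsive = ex$responsive, up = ex$up,
                       responsive_in_vivo = ex_vivo$responsive,
                       up_in_vivo = ex_vivo$up,
                       stringsAsFactors = FALSE),
    motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(region_id = character(), motif = character(),
                 chrom = character(), pos = integer(),
                 stringsAsFactors = FALSE))

  list(config = config, dataset_id = dataset_id, chrom_sizes = sizes,
       genes = genes, regions = regions, genome = genome,
       expression = ex$table, expression_in_vivo = ex_vivo$table,
       truth = truth)
}

.write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  files <- c(chrom_sizes = p("chrom.sizes"), genes = p("genes.bed"),
             runx1 = p("runx1.bed"), myod = p("myod.bed"),
             cjun = p("cjun.bed"), h3k4me1 = p("h3k4me1.bed"),
             h3k27ac = p("h3k27ac.bed"), atac = p("atac.bed"),
             expression = p("expression.tsv"),
             expression_in_vivo = p("expression_in_vivo.tsv"),
             ground_truth = p("ground_truth.json"))
  write_chrom_sizes(ds$chrom_sizes, files[["chrom_sizes"]])
  g <- ds$genes
  gene_start <- ifelse(g$strand == "+", g$tss, g$tss - 999L)
  gene_end <- ifelse(g$strand == "+", g$tss + 1000L, g$tss + 1L)
  con <- file(files[["genes"]], open = "wb")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, gene_start, gene_end,
                     g$gene_id, g$strand), con)
  close(con)
  for (nm in c("runx1", "myod", "cjun", "h3k4me1", "h3k27ac", "atac"))
    write_region_set(ds$regions[[nm]], files[[nm]])
  write_expression_table(ds$expression, files[["expression"]])
  write_expression_table(ds$expression_in_vivo, files[["expression_in_vivo"]])
  if (!is.null(ds$genome)) {
    files <- c(files, genome = p("genome.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ds$genome), files[["genome"]])
  }
  jsonlite::write_json(
    list(dataset_id = ds$dataset_id,
         config = unclass(ds$config),
         peaks = ds$truth$peaks, genes = ds$truth$genes,
         motifs = ds$truth$motifs),
    files[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ds$files <- files
  ds
}

#' Recovery of planted truth by the cascade
#'
#' Confusion counts of every cascade-derived gene set against the planted
#' labels of the generating dataset. The planted-positive definition per
#' stage: responsive = planted responsive; regulated = responsive and a
#' Runx1 peak within the window; RMJ-regulated = additionally a
#' triple-co-planted peak within the window; high-confidence =
#' additionally that peak is planted as marked and open.
#'
#' @param truth The `truth` component of [generate_dataset()] output.
#' @param report A `cascade_report` from [run_cascade()] run on the same
#'   dataset (matching `dataset_id`s are enforced when both are present).
#' @return data.frame: stage, n_true, n_predicted, tp/fp/fn/tn,
#'   sensitivity, specificity, and a `degenerate` flag set when a stage
#'   has no planted positives (sensitivity undefined, reported `NA`).
#' @export
recovery_report <- function(truth, report) {
  if (!is.null(truth$dataset_id) && !is.null(report$dataset_id) &&
      !identical(truth$dataset_id, report$dataset_id))
    .stopf("dataset mismatch: truth is '%s', report is '%s'",
           truth$dataset_id, report$dataset_id)
  tg <- truth$genes
  truth_sets <- list(
    responsive = tg$gene_id[tg$responsive],
    regulated = tg$gene_id[tg$responsive & tg$bound],
    rmj_regulated = tg$gene_id[tg$responsive & tg$bound & tg$rmj_near],
    high_confidence = tg$gene_id[tg$responsive & tg$bound & tg$hc_near])
  all_ids <- tg$gene_id
  out <- do.call(rbind, lapply(names(truth_sets), function(stage) {
    pos <- truth_sets[[stage]]
    pred <- report$gene_sets[[stage]]$ids
    tp <- length(intersect(pred, pos))
    fp <- length(setdiff(pred, pos))
    fn <- length(setdiff(pos, pred))
    tn <- length(all_ids) - tp - fp - fn
    degenerate <- length(pos) == 0L
    data.frame(stage = stage, n_true = length(pos), n_predicted = length(pred),
               tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = if (degenerate) NA_real_ else tp / length(pos),
               specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp),
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
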