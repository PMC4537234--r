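test_that("config validation rejects bad probabilities and packing", {
  expect_error(synthetic_config(), "requires a seed")
  expect_error(synthetic_config(seed = 1, p_myod_given_runx1 = 1.5),
               "probability")
  expect_error(synthetic_config(seed = 1, p_responsive_bound = 0.1,
                                p_responsive_unbound = 0.4),
               "p_responsive_bound")
  # 100 genes at 20 kb spacing cannot fit a 100 kb chromosome
  expect_error(synthetic_config(seed = 1, n_chroms = 1,
                                chrom_length = 100000, n_genes = 100),
               "infeasible packing")
})

test_that("regeneration under one seed is byte-identical; seeds differ", {
  cfg <- synthetic_config(seed = 11, n_chroms = 1, chrom_length = 300000,
                          n_genes = 10, n_runx1_peaks = 30,
                          n_background_peaks = 15, n_background_marks = 10,
                          tss_spacing_bp = 2000, window_bp = 10000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(cfg, outdir = d1)
  ds2 <- generate_dataset(cfg, outdir = d2)
  for (nm in names(ds1$files)) {
    expect_identical(readBin(ds1$files[[nm]], "raw", 1e6),
                     readBin(ds2$files[[nm]], "raw", 1e6),
                     label = sprintf("file %s regenerates identically", nm))
  }
  cfg3 <- synthetic_config(seed = 12, n_chroms = 1, chrom_length = 300000,
                           n_genes = 10, n_runx1_peaks = 30,
                           n_background_peaks = 15, n_background_marks = 10,
                           tss_spacing_bp = 2000, window_bp = 10000)
  ds3 <- generate_dataset(cfg3)
  expect_false(identical(region_frame(ds1$regions$runx1),
                         region_frame(ds3$regions$runx1)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_dataset(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("forced co-planting gives full co-occupancy; zero gives independence", {
  full <- generate_dataset(synthetic_config(
    seed = 21, n_chroms = 1, chrom_length = 500000, n_genes = 10,
    n_runx1_peaks = 50, p_myod_given_runx1 = 1, jitter_bp = 0,
    n_background_peaks = 0, n_background_marks = 0, tss_spacing_bp = 2000,
    window_bp = 10000, emit_sequences = FALSE))
  expect_equal(cooccupancy(full$regions$runx1, full$regions$myod)$fraction, 1)

  zero <- generate_dataset(zero_signal_config(
    seed = 22, n_chroms = 1, chrom_length = 500000, n_genes = 10,
    n_runx1_peaks = 50, n_background_peaks = 50, n_background_marks = 0,
    tss_spacing_bp = 2000, window_bp = 10000))
  expect_true(all(!zero$truth$peaks$co_myod))
  # background-only partner peaks: only chance overlap remains
  expect_lt(cooccupancy(zero$regions$runx1, zero$regions$myod)$fraction, 0.25)
})

test_that("emitted fractions converge to the planted rates (3 binomial SDs)", {
  ds <- generate_dataset(synthetic_config(seed = 31, n_runx1_peaks = 2000,
                                          emit_sequences = FALSE))
  tp <- ds$truth$peaks
  n <- nrow(tp)
  check <- function(observed, p) {
    expect_lt(abs(observed - p), 3 * sqrt(p * (1 - p) / n) + 1e-12,
              label = sprintf("rate %.3f vs planted %.2f", observed, p))
  }
  check(mean(tp$co_myod), 0.46)
  check(mean(tp$co_cjun), 0.47)
  check(mean(tp$marked), 0.70)
  check(mean(tp$open), 0.25)
  # and the measured overlap fractions agree with the planted labels
  co <- cooccupancy(ds$regions$runx1, ds$regions$myod)
  expect_lt(abs(co$fraction - mean(tp$co_myod)), 0.03)
})

test_that("expression q-values are BH-monotone in the latent p-values", {
  ds <- generate_dataset(synthetic_config(
    seed = 41, n_chroms = 1, chrom_length = 2000000, n_genes = 90,
    n_runx1_peaks = 60, tss_spacing_bp = 2000, window_bp = 20000,
    emit_sequences = FALSE))
  tab <- ds$expression
  # reconstruct the z-statistics and raw p-values from the emitted lfc
  z <- tab$log2fc / ds$config$lfc_se
  p <- 2 * pnorm(-abs(z))
  expect_equal(tab$qvalue, p.adjust(p, "BH"), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(tab$qvalue[o]) >= -1e-12))
  # responsive genes get large |lfc|
  resp <- ds$truth$genes$responsive
  if (any(resp) && any(!resp))
    expect_gt(mean(abs(tab$log2fc[resp])), mean(abs(tab$log2fc[!resp])))
})

test_that("planted motif positions are present in the emitted genome", {
  ds <- generate_dataset(synthetic_config(
    seed = 51, n_chroms = 1, chrom_length = 400000, n_genes = 10,
    n_runx1_peaks = 50, n_background_peaks = 0, n_background_marks = 0,
    tss_spacing_bp = 2000, window_bp = 10000))
  mo <- ds$truth$motifs
  expect_gt(nrow(mo), 0L)
  inst <- c(RUNX = "TGTGGTT", MyoD = "CAGCTG")
  for (i in seq_len(nrow(mo))) {
    got <- substr(ds$genome[[mo$chrom[i]]], mo$pos[i] + 1L,
                  mo$pos[i] + nchar(inst[[mo$motif[i]]]))
    expect_equal(got, unname(inst[[mo$motif[i]]]))
  }
  # planted anchors are recovered by the scanner at the planted rate
  fr <- fraction_with_motif(ds$regions$runx1, ds$genome,
                            consensus_motif("RUNX", "TGYGGTY"))
  expect_gte(fr, mean(ds$truth$peaks$has_anchor_motif))
})

test_that("recovery_report scores perfect and degenerate cases correctly", {
  # perfect signal: every probability 0 or 1
  ds <- generate_dataset(synthetic_config(
    seed = 61, n_chroms = 2, chrom_length = 1000000, n_genes = 40,
    n_runx1_peaks = 60, p_myod_given_runx1 = 1, p_cjun_given_runx1 = 1,
    p_mark_given_peak = 1, p_atac_given_peak = 1,
    p_responsive_bound = 1, p_responsive_unbound = 0,
    n_background_peaks = 0, n_background_marks = 0,
    tss_spacing_bp = 4000, window_bp = 20000, emit_sequences = FALSE))
  rep_ <- run_cascade(list(
    runx1 = ds$regions$runx1, myod = ds$regions$myod, cjun = ds$regions$cjun,
    h3k4me1 = ds$regions$h3k4me1, h3k27ac = ds$regions$h3k27ac,
    atac = ds$regions$atac, genes = ds$genes, expression = ds$expression,
    chrom_sizes = ds$chrom_sizes, window_bp = 20000,
    n_iter_bootstrap = 50, n_iter_monte_carlo = 50, seed = 5,
    dataset_id = ds$dataset_id))
  rec <- recovery_report(ds$truth, rep_)
  hc <- rec[rec$stage == "high_confidence", ]
  expect_equal(hc$sensitivity, 1)
  expect_equal(hc$specificity, 1)
  expect_false(any(rec$degenerate))

  # zero signal with p_responsive = 0: no planted positives -> flagged NA
  ds0 <- generate_dataset(zero_signal_config(
    seed = 62, p_responsive = 0, n_chroms = 1, chrom_length = 500000,
    n_genes = 20, n_runx1_peaks = 30, n_background_peaks = 30,
    n_background_marks = 10, tss_spacing_bp = 2000, window_bp = 10000))
  rep0 <- run_cascade(list(
    runx1 = ds0$regions$runx1, myod = ds0$regions$myod,
    cjun = ds0$regions$cjun, h3k4me1 = ds0$regions$h3k4me1,
    h3k27ac = ds0$regions$h3k27ac, atac = ds0$regions$atac,
    genes = ds0$genes, expression = ds0$expression,
    chrom_sizes = ds0$chrom_sizes, window_bp = 10000,
    n_iter_bootstrap = 50, n_iter_monte_carlo = 50, seed = 5,
    dataset_id = ds0$dataset_id))
  rec0 <- recovery_report(ds0$truth, rep0)
  expect_true(all(rec0$degenerate))
  expect_true(all(is.na(rec0$sensitivity)))

  # mismatched datasets refuse to be compared
  expect_error(recovery_report(ds$truth, rep0), "dataset mismatch")
})
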