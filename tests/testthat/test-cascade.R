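make_small_dataset <- function(seed = 404, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length = 1000000,
               n_genes = 60, n_runx1_peaks = 120, n_background_peaks = 60,
               n_background_marks = 30, tss_spacing_bp = 4000,
               window_bp = 20000)
  over <- list(...)
  args[names(over)] <- over
  generate_dataset(do.call(synthetic_config, args))
}

small_config <- function(ds, ...) {
  cfg <- list(runx1 = ds$regions$runx1, myod = ds$regions$myod,
              cjun = ds$regions$cjun, h3k4me1 = ds$regions$h3k4me1,
              h3k27ac = ds$regions$h3k27ac, atac = ds$regions$atac,
              genes = ds$genes, expression = ds$expression,
              expression_in_vivo = ds$expression_in_vivo,
              chrom_sizes = ds$chrom_sizes,
              window_bp = ds$config$window_bp,
              n_iter_bootstrap = 100, n_iter_monte_carlo = 100,
              seed = 17, dataset_id = ds$dataset_id)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

test_that("responsive selection applies both thresholds strictly", {
  spec <- threshold_spec(0.1, 1.5)
  tab <- expression_table(paste0("g", 1:4),
                          c(1.0, 0.5, -1.2, 2.0),
                          c(0.05, 0.01, 0.09, 0.2))
  sel <- select_responsive(tab, spec)
  expect_equal(sel$up$ids, "g1")        # FC 2.0 > 1.5, q < 0.1
  expect_equal(sel$down$ids, "g3")      # FC 2.3 down, q < 0.1
  expect_equal(sel$responsive$ids, c("g1", "g3"))
  expect_length(intersect(sel$up$ids, sel$down$ids), 0L)

  # |log2fc| = 0.5 is FC 1.41 <= 1.5: excluded despite tiny q
  expect_false("g2" %in% sel$responsive$ids)
  # boundary: FC exactly 1.5 is excluded (strict), just above passes
  tb <- expression_table(c("a", "b"), c(log2(1.5), log2(1.5) + 1e-9),
                         c(0.01, 0.01))
  expect_equal(select_responsive(tb, spec)$up$ids, "b")
  expect_error(threshold_spec(0.1, 1.0), "exceed 1")
  expect_error(threshold_spec(0, 1.5), "q_max")
})

test_that("derive_regulated is the responsive/bound intersection", {
  resp <- gene_set(c("g1", "g2", "g3"), "responsive")
  bound <- gene_set(c("g2", "g3", "g4"), "bound")
  reg <- derive_regulated(resp, bound)
  expect_equal(reg$ids, c("g2", "g3"))
  expect_equal(attr(reg, "bound_fraction"), 2 / 3)

  expect_length(derive_regulated(gene_set(c("a", "b")), gene_set(c("c")))$ids, 0L)
  sub <- derive_regulated(gene_set("g2"), bound)
  expect_equal(sub$ids, "g2")
  expect_equal(attr(sub, "bound_fraction"), 1)
  expect_gt(length(reg$provenance), 0L)
})

test_that("rmj_regions returns exactly the triple-overlap clusters", {
  one <- region_set("chr1", 0L, 10L, label = "R")
  expect_length(rmj_regions(one, one, one), 1L)

  # pairwise-only overlaps: no ABC cluster
  A <- region_set("chr1", c(0L, 100L), c(10L, 110L), label = "A")
  B <- region_set("chr1", c(5L, 200L), c(15L, 210L), label = "B")
  C <- region_set("chr1", c(105L, 205L), c(115L, 215L), label = "C")
  expect_length(rmj_regions(A, B, C), 0L)

  withr::local_seed(52)
  for (rep_ in 1:25) {
    dA <- rand_bed(8); dB <- rand_bed(8); dC <- rand_bed(8)
    got <- rmj_regions(bed_to_rs(dA, "A"), bed_to_rs(dB, "B"),
                       bed_to_rs(dC, "C"))
    expect_length(got, unname(o_venn3(dA, dB, dC)["ABC"]))
  }
})

test_that("derive_rmj_regulated intersects responsive with near-RMJ genes", {
  genes <- gene_table(paste0("g", 1:5), rep("chr1", 5),
                      c(1000L, 5000L, 9000L, 13000L, 17000L), rep("+", 5))
  rmj <- region_set("chr1", c(900L, 12900L), c(1100L, 13100L), label = "RMJ")
  resp <- gene_set(c("g1", "g2", "g4"), "responsive")
  out <- derive_rmj_regulated(resp, rmj, genes, window_bp = 500L)
  expect_equal(out$ids, c("g1", "g4"))
  expect_lte(attr(out, "p_hypergeom"), 1)

  none <- derive_rmj_regulated(resp, bed_to_rs(rand_bed(0), "RMJ"), genes)
  expect_length(none$ids, 0L)
  expect_equal(attr(none, "p_hypergeom"), 1)

  # planted: RMJ regions directly at responsive TSSs recover all of them
  at_tss <- region_set("chr1", c(990L, 4990L, 12990L),
                       c(1010L, 5010L, 13010L), label = "RMJ")
  full <- derive_rmj_regulated(resp, at_tss, genes, window_bp = 500L)
  expect_equal(full$ids, resp$ids)
  # all 3 responsive genes drawn in a 3-gene near-RMJ sample of 5: 1/C(5,3)
  expect_equal(attr(full, "p_hypergeom"), 1 / choose(5, 3))
})

test_that("enhancer state needs both marks; open needs ATAC", {
  rs <- region_set("chr1", c(0L, 100L, 200L), c(50L, 150L, 250L), label = "q")
  k4 <- region_set("chr1", c(10L, 110L), c(20L, 120L), label = "k4")
  k27 <- region_set("chr1", 10L, 20L, label = "k27")
  atac <- region_set("chr1", 205L, 215L, label = "at")
  ann <- annotate_enhancer_state(rs, k4, k27, atac)
  df <- region_frame(ann)
  expect_equal(df$active_enhancer, c(TRUE, FALSE, FALSE))  # both marks needed
  expect_equal(df$open_chromatin, c(FALSE, FALSE, TRUE))
  fr <- attr(ann, "fractions")
  expect_equal(unname(fr["active_enhancer"]), 1 / 3)
  expect_equal(unname(fr["open_chromatin"]), 1 / 3)
})

test_that("derive_high_confidence honours the conjunction granularity", {
  genes <- gene_table(c("g1", "g2"), c("chr1", "chr1"), c(1000L, 50000L),
                      c("+", "+"))
  # two RMJ regions near g1: one marked-only, one open-only
  rmj <- region_set("chr1", c(900L, 1200L), c(1000L, 1300L), label = "RMJ")
  k4 <- region_set("chr1", 890L, 1010L, label = "k4")
  k27 <- region_set("chr1", 890L, 1010L, label = "k27")
  atac <- region_set("chr1", 1210L, 1290L, label = "at")
  fl <- annotate_enhancer_state(rmj, k4, k27, atac)
  rr <- gene_set(c("g1"), "rmj_regulated")
  # region-level conjunction: no single region is both -> empty
  strict <- derive_high_confidence(rr, fl, genes, window_bp = 500L,
                                   n_iter = 50, seed = 1)
  expect_length(strict$ids, 0L)
  # independent evidence layers: g1 qualifies
  loose <- derive_high_confidence(rr, fl, genes, window_bp = 500L,
                                  conjunction = "independent",
                                  n_iter = 50, seed = 1)
  expect_equal(loose$ids, "g1")
  # all regions flagged -> output equals rmj_regulated
  fl2 <- annotate_enhancer_state(rmj, k4, k27,
                                 region_set("chr1", 800L, 1400L, label = "at"))
  all_ <- derive_high_confidence(rr, fl2, genes, window_bp = 500L,
                                 n_iter = 50, seed = 1)
  expect_equal(all_$ids, rr$ids)
  expect_error(derive_high_confidence(rr, rmj, genes), "flags")
})

test_that("derive_in_vivo is a provenance-carrying intersection", {
  a <- gene_set(c("g1", "g2"), "rmj_regulated")
  expect_equal(derive_in_vivo(a, a)$ids, a$ids)
  expect_length(derive_in_vivo(a, gene_set("g9"))$ids, 0L)
  withr::local_seed(3)
  for (rep_ in 1:20) {
    x <- sample(letters, sample(0:20, 1))
    y <- sample(letters, sample(0:20, 1))
    expect_equal(derive_in_vivo(gene_set(x), gene_set(y))$ids,
                 sort(intersect(x, y)))
  }
})

test_that("run_cascade maintains nesting and reports complete counts", {
  ds <- make_small_dataset()
  rep_ <- run_cascade(small_config(ds))
  gs <- rep_$gene_sets
  expect_true(all(gs$high_confidence$ids %in% gs$rmj_regulated$ids))
  expect_true(all(gs$rmj_regulated$ids %in% gs$regulated$ids))
  expect_true(all(gs$regulated$ids %in% gs$responsive$ids))
  expect_true(all(gs$in_vivo$ids %in% gs$rmj_regulated$ids))
  expect_equal(unname(rep_$counts["responsive"]),
               unname(rep_$counts["up"] + rep_$counts["down"]))
  expect_equal(sum(rep_$venn3$counts), rep_$venn3$n_clusters)
  expect_true(all(!is.na(rep_$fractions)))
  # provenance allows recomputation of the final set
  expect_gt(length(gs$high_confidence$provenance), 1L)
})

test_that("identical config gives identical reports; missing inputs fail fast", {
  ds <- make_small_dataset()
  cfg <- small_config(ds)
  r1 <- run_cascade(cfg)
  r2 <- run_cascade(cfg)
  r1$config <- r2$config <- NULL
  expect_identical(r1[c("counts", "fractions", "tests", "venn3")],
                   r2[c("counts", "fractions", "tests", "venn3")])
  expect_identical(r1$gene_sets$high_confidence$ids,
                   r2$gene_sets$high_confidence$ids)

  bad <- small_config(ds, runx1 = "/nonexistent/runx1.bed")
  expect_error(run_cascade(bad), "not found")
  expect_error(run_cascade(small_config(ds, bogus_key = 1)), "unknown config key")
})

test_that("tightening any threshold never enlarges a derived set", {
  ds <- make_small_dataset()
  base <- run_cascade(small_config(ds))
  tight_q <- run_cascade(small_config(
    ds, thresholds = threshold_spec(0.02, 1.5)))
  tight_fc <- run_cascade(small_config(
    ds, thresholds = threshold_spec(0.1, 2.5)))
  tight_w <- run_cascade(small_config(ds, window_bp = 5000L))
  for (variant in list(tight_q, tight_fc, tight_w)) {
    for (nm in c("responsive", "regulated", "rmj_regulated",
                 "high_confidence")) {
      expect_true(all(variant$gene_sets[[nm]]$ids %in%
                        base$gene_sets[[nm]]$ids),
                  label = sprintf("%s shrinks under tightening", nm))
    }
  }
})

test_that("cascade runs identically from files and from memory", {
  ds <- make_small_dataset(seed = 812)
  outdir <- withr::local_tempdir()
  ds2 <- generate_dataset(ds$config, outdir = outdir)
  mem <- run_cascade(small_config(ds))
  f <- ds2$files
  file_cfg <- list(runx1 = f[["runx1"]], myod = f[["myod"]],
                   cjun = f[["cjun"]], h3k4me1 = f[["h3k4me1"]],
                   h3k27ac = f[["h3k27ac"]], atac = f[["atac"]],
                   genes = f[["genes"]], expression = f[["expression"]],
                   expression_in_vivo = f[["expression_in_vivo"]],
                   chrom_sizes = f[["chrom_sizes"]],
                   window_bp = ds$config$window_bp,
                   n_iter_bootstrap = 100, n_iter_monte_carlo = 100,
                   seed = 17, dataset_id = ds$dataset_id)
  from_files <- run_cascade(file_cfg)
  expect_identical(mem$counts, from_files$counts)
  expect_identical(mem$gene_sets$high_confidence$ids,
                   from_files$gene_sets$high_confidence$ids)
})

test_that("cascade reports serialize to JSON and back", {
  ds <- make_small_dataset(seed = 55)
  rep_ <- run_cascade(small_config(ds))
  path <- withr::local_tempfile(fileext = ".json")
  write_cascade_report(rep_, path)
  back <- read_cascade_report(path)
  expect_equal(back$counts$responsive, unname(rep_$counts["responsive"]))
  expect_equal(back$gene_sets$high_confidence$ids,
               rep_$gene_sets$high_confidence$ids)
  expect_equal(back$tests$hypergeom_rmj, rep_$tests$hypergeom_rmj)

  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = "\n"), 1, 120),
             trunc_path)
  expect_error(read_cascade_report(trunc_path), "valid report JSON")
  writeLines('{"schema": "other/v9"}', trunc_path)
  expect_error(read_cascade_report(trunc_path), "schema")
})
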