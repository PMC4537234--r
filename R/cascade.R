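#' Differential-expression threshold specification
#'
#' Selection thresholds for "responsive" genes: FDR q-value strictly below
#' `q_max` and linear fold change strictly above `fc_min`
#' (`|log2fc| > log2(fc_min)`), as the thresholds are usually printed
#' ("q < 0.1 and > 1.5-fold").
#'
#' @param q_max Maximum q-value, in (0, 1].
#' @param fc_min Minimum linear fold change, > 1.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(q_max, fc_min) {
  if (!is.numeric(q_max) || q_max <= 0 || q_max > 1)
    .stopf("q_max must lie in (0, 1]")
  if (!is.numeric(fc_min) || fc_min <= 1)
    .stopf("fc_min must exceed 1 (linear fold change)")
  structure(list(q_max = q_max, fc_min = fc_min), class = "threshold_spec")
}

#' Select responsive genes from an expression table
#'
#' Splits the table into up- and down-regulated gene sets under a
#' [threshold_spec()]; the two sets are disjoint by construction.
#'
#' @param tab Expression table ([read_expression_table()]).
#' @param spec A [threshold_spec()].
#' @param label Prefix for the derived set labels.
#' @return List of `gene_set`s: `up`, `down`, `responsive` (their union).
#' @export
select_responsive <- function(tab, spec, label = "responsive") {
  stopifnot(inherits(spec, "threshold_spec"))
  lfc_min <- log2(spec$fc_min)
  sig <- tab$qvalue < spec$q_max
  up_ids <- tab$gene_id[sig & tab$log2fc > lfc_min]
  down_ids <- tab$gene_id[sig & tab$log2fc < -lfc_min]
  params <- list(q_max = spec$q_max, fc_min = spec$fc_min)
  list(up = gs_derive(up_ids, paste0(label, "_up"), list(), params),
       down = gs_derive(down_ids, paste0(label, "_down"), list(), params),
       responsive = gs_derive(c(up_ids, down_ids), label, list(), params))
}

#' Regulated genes: responsive AND bound
#'
#' Intersection of the responsive set with the factor-bound set, with the
#' bound fraction of responsive genes reported.
#'
#' @param responsive,bound `gene_set`s.
#' @param label Label for the derived set.
#' @return A `gene_set`; `attr(, "bound_fraction")` is the fraction of
#'   responsive genes that are bound.
#' @export
derive_regulated <- function(responsive, bound, label = "regulated") {
  ids <- intersect(responsive$ids, bound$ids)
  gs <- gs_derive(ids, label, list(responsive, bound))
  attr(gs, "bound_fraction") <- if (length(responsive$ids))
    length(ids) / length(responsive$ids) else 0
  gs
}

#' Triple-co-occupied (RMJ) regions
#'
#' The merged union clusters that receive at least one interval from each
#' of the three input sets (the ABC class of [venn3()]), returned as a
#' region set labeled `"RMJ"`.
#'
#' @param runx1,myod,cjun Region sets.
#' @return A region set of triple-occupied clusters.
#' @export
rmj_regions <- function(runx1, myod, cjun) {
  v <- venn3(runx1, myod, cjun)
  cl <- v$clusters
  rmj <- cl[mcols(cl)$in_A & mcols(cl)$in_B & mcols(cl)$in_C]
  mcols(rmj) <- NULL
  names(rmj) <- if (length(rmj)) paste0("RMJ:", seq_along(rmj)) else character()
  metadata(rmj)$label <- "RMJ"
  rmj
}

#' RMJ-regulated genes
#'
#' Responsive genes with at least one triple-occupied region anchor within
#' the TSS window; enrichment of the intersection is scored with
#' [hypergeom_tail()] over the full annotation as universe.
#'
#' @param responsive A `gene_set`.
#' @param rmj RMJ region set ([rmj_regions()]).
#' @param genes A [gene_table()] (also defines the test universe).
#' @param window_bp TSS window (default 200,000).
#' @param anchor Anchor mode for [bound_genes()].
#' @return A `gene_set`; attributes `p_hypergeom` and `rmj_bound` (the
#'   near-RMJ gene set).
#' @export
derive_rmj_regulated <- function(responsive, rmj, genes,
                                 window_bp = 200000L, anchor = "summit") {
  if (length(rmj) == 0L) {
    gs <- gs_derive(character(), "rmj_regulated", list(responsive),
                    list(window_bp = window_bp))
    attr(gs, "p_hypergeom") <- 1
    attr(gs, "rmj_bound") <- gene_set(character(), "rmj_bound")
    return(gs)
  }
  near <- bound_genes(rmj, genes, window_bp = window_bp, anchor = anchor,
                      label = "rmj_bound")
  ids <- intersect(responsive$ids, near$ids)
  gs <- gs_derive(ids, "rmj_regulated", list(responsive, near),
                  list(window_bp = window_bp, anchor = anchor))
  attr(gs, "p_hypergeom") <- hypergeom_tail(nrow(genes),
                                            length(responsive$ids),
                                            length(near$ids),
                                            length(ids))
  attr(gs, "rmj_bound") <- near
  gs
}

#' Annotate regions with enhancer / open-chromatin state
#'
#' `active_enhancer` requires overlap with at least one H3K4me1 region AND
#' at least one H3K27ac region (both marks together indicate an active
#' enhancer); `open_chromatin` requires overlap with at least one ATAC
#' region (nucleosome-free).
#'
#' @param rs Region set to annotate.
#' @param h3k4me1,h3k27ac,atac Mark / open-chromatin region sets.
#' @return `rs` with logical metadata columns `active_enhancer` and
#'   `open_chromatin`; `attr(, "fractions")` holds the summary fractions.
#' @export
annotate_enhancer_state <- function(rs, h3k4me1, h3k27ac, atac) {
  u <- .unify(rs, h3k4me1, h3k27ac, atac)
  k4 <- IRanges::overlapsAny(u[[1L]], u[[2L]], ignore.strand = TRUE)
  k27 <- IRanges::overlapsAny(u[[1L]], u[[3L]], ignore.strand = TRUE)
  op <- IRanges::overlapsAny(u[[1L]], u[[4L]], ignore.strand = TRUE)
  mcols(rs)$active_enhancer <- k4 & k27
  mcols(rs)$open_chromatin <- op
  attr(rs, "fractions") <- c(
    active_enhancer = if (length(rs)) mean(k4 & k27) else NA_real_,
    open_chromatin = if (length(rs)) mean(op) else NA_real_,
    active_and_open = if (length(rs)) mean(k4 & k27 & op) else NA_real_)
  rs
}

#' High-confidence regulated genes
#'
#' RMJ-regulated genes supported by chromatin evidence. With
#' `conjunction = "region"` (default, the stricter reading) a single
#' supporting RMJ region must be both an active enhancer and open
#' chromatin; with `"independent"` the histone-marked region and the open
#' region may be different RMJ regions near the same gene.
#'
#' @param rmj_regulated A `gene_set`.
#' @param rmj_flagged RMJ regions annotated by [annotate_enhancer_state()].
#' @param genes A [gene_table()].
#' @param window_bp TSS window.
#' @param anchor Anchor mode for [bound_genes()].
#' @param conjunction `"region"` or `"independent"`.
#' @param n_iter,seed Monte Carlo settings for the reported set test.
#' @return A `gene_set`; attribute `p_monte_carlo`.
#' @export
derive_high_confidence <- function(rmj_regulated, rmj_flagged, genes,
                                   window_bp = 200000L, anchor = "summit",
                                   conjunction = c("region", "independent"),
                                   n_iter = 10000L, seed = 1L) {
  conjunction <- match.arg(conjunction)
  fl <- mcols(rmj_flagged)
  if (is.null(fl$active_enhancer) || is.null(fl$open_chromatin))
    .stopf("rmj_flagged must carry enhancer-state flags; run annotate_enhancer_state first")
  near_ids <- function(sub, lab) {
    if (length(sub) == 0L) return(gene_set(character(), lab))
    bound_genes(sub, genes, window_bp = window_bp, anchor = anchor, label = lab)
  }
  if (conjunction == "region") {
    supported <- near_ids(rmj_flagged[fl$active_enhancer & fl$open_chromatin],
                          "active_open_bound")
  } else {
    near_active <- near_ids(rmj_flagged[fl$active_enhancer], "active_bound")
    near_open <- near_ids(rmj_flagged[fl$open_chromatin], "open_bound")
    supported <- gene_set(intersect(near_active$ids, near_open$ids),
                          "active_open_bound")
  }
  ids <- intersect(rmj_regulated$ids, supported$ids)
  gs <- gs_derive(ids, "high_confidence", list(rmj_regulated, supported),
                  list(window_bp = window_bp, conjunction = conjunction))
  universe <- gene_set(genes$gene_id, "universe")
  mc <- monte_carlo_set_test(universe, rmj_regulated, supported,
                             n_iter = n_iter, seed = seed)
  attr(gs, "p_monte_carlo") <- mc$p_empirical
  attr(gs, "monte_carlo") <- mc[c("observed", "p_empirical")]
  gs
}

#' In-vivo cross of a regulated subset
#'
#' Intersection of a cascade-derived gene set (by default the
#' RMJ-regulated set) with an independently derived in-vivo responsive
#' set, with provenance recording both parents.
#'
#' @param regulated,in_vivo_responsive `gene_set`s.
#' @return A `gene_set` labeled `in_vivo`.
#' @export
derive_in_vivo <- function(regulated, in_vivo_responsive) {
  gs_derive(intersect(regulated$ids, in_vivo_responsive$ids), "in_vivo",
            list(regulated, in_vivo_responsive))
}

.as_regions <- function(x, format, label, chrom_sizes = NULL) {
  if (methods::is(x, "GRanges")) return(x)
  read_regions(x, format = format, label = label, chrom_sizes = chrom_sizes)
}

#' Run the full evidence-integration cascade
#'
#' Executes the staged selection: (I) responsive genes from the
#' differential-expression table; (II) regulated = responsive genes with a
#' Runx1 peak anchor within the TSS window; (III) RMJ-regulated =
#' stage-II genes near a triple Runx1/MyoD/c-Jun co-occupied region, with
#' a hypergeometric enrichment p; (IV) high-confidence = stage-III genes
#' whose supporting RMJ region is an active enhancer and open chromatin,
#' with a Monte Carlo set-test p; optionally the in-vivo cross of
#' stage III against a second (in-vivo) expression contrast. Also reports
#' peak location distribution, pairwise co-occupancy with bootstrap
#' p-values, the three-way region partition and enhancer-state fractions.
#'
#' @param config A list (see [cascade_config()]) naming every input
#'   (in-memory object or file path), thresholds, window, iteration counts
#'   and seed. All file inputs are checked before any computation starts.
#' @return A `cascade_report` list; two runs with an identical config are
#'   identical.
#' @export
run_cascade <- function(config) {
  config <- cascade_config(config)
  paths <- Filter(is.character, config[c("runx1", "myod", "cjun", "h3k4me1",
                                         "h3k27ac", "atac", "genes",
                                         "expression", "expression_in_vivo",
                                         "chrom_sizes")])
  missing_files <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_files))
    .stopf("input file not found: %s", missing_files[[1L]])

  sizes <- if (is.character(config$chrom_sizes))
    read_chrom_sizes(config$chrom_sizes) else
      validate_chrom_sizes(config$chrom_sizes)
  fmt <- config$peak_format
  runx1 <- .as_regions(config$runx1, fmt, "Runx1", sizes)
  myod <- .as_regions(config$myod, fmt, "MyoD", sizes)
  cjun <- .as_regions(config$cjun, fmt, "cJun", sizes)
  h3k4me1 <- .as_regions(config$h3k4me1, fmt, "H3K4me1", sizes)
  h3k27ac <- .as_regions(config$h3k27ac, fmt, "H3K27ac", sizes)
  atac <- .as_regions(config$atac, fmt, "ATAC", sizes)
  genes <- if (is.character(config$genes))
    read_genes(config$genes, format = config$gene_format) else config$genes
  expr <- if (is.character(config$expression))
    read_expression_table(config$expression) else config$expression
  expr_vivo <- if (is.null(config$expression_in_vivo)) NULL else
    if (is.character(config$expression_in_vivo))
      read_expression_table(config$expression_in_vivo) else
        config$expression_in_vivo

  w <- config$window_bp
  anchor <- config$anchor

  # Stage I: responsive
  sel <- select_responsive(expr, config$thresholds, label = "responsive")

  # Stage II: regulated (Runx1-bound responsive)
  runx1_bound <- bound_genes(runx1, genes, window_bp = w, anchor = anchor,
                             label = "runx1_bound")
  regulated <- derive_regulated(sel$responsive, runx1_bound)

  # Region-level descriptives and co-occupancy tests
  locdist <- location_distribution(runx1, genes, anchor = anchor)
  co_myod <- cooccupancy(runx1, myod)
  co_cjun_runx1 <- cooccupancy(cjun, runx1)
  bt_myod <- bootstrap_overlap_test(runx1, myod, sizes,
                                    n_iter = config$n_iter_bootstrap,
                                    seed = config$seed)
  v3 <- venn3(runx1, myod, cjun)

  # Stage III: RMJ-regulated
  if (config$rmj_mode == "cluster") {
    rmj <- rmj_regions(runx1, myod, cjun)
    rmj_step <- derive_rmj_regulated(sel$responsive, rmj, genes,
                                     window_bp = w, anchor = anchor)
  } else {
    each <- Reduce(intersect, list(
      bound_genes(runx1, genes, w, anchor, label = "runx1_bound")$ids,
      bound_genes(myod, genes, w, anchor, label = "myod_bound")$ids,
      bound_genes(cjun, genes, w, anchor, label = "cjun_bound")$ids))
    near <- gene_set(each, "rmj_bound")
    rmj <- rmj_regions(runx1, myod, cjun)
    ids <- intersect(sel$responsive$ids, near$ids)
    rmj_step <- gs_derive(ids, "rmj_regulated", list(sel$responsive, near),
                          list(window_bp = w, mode = "independent"))
    attr(rmj_step, "p_hypergeom") <- hypergeom_tail(
      nrow(genes), length(sel$responsive$ids), length(near$ids), length(ids))
    attr(rmj_step, "rmj_bound") <- near
  }
  # stage-wise refinement: RMJ-regulated genes are by definition Runx1-bound
  rmj_regulated <- gene_set(intersect(rmj_step$ids, regulated$ids),
                            "rmj_regulated", rmj_step$provenance)
  attr(rmj_regulated, "p_hypergeom") <- attr(rmj_step, "p_hypergeom")

  # Stage IV: chromatin-supported high confidence
  rmj_flagged <- annotate_enhancer_state(rmj, h3k4me1, h3k27ac, atac)
  runx1_flagged <- annotate_enhancer_state(runx1, h3k4me1, h3k27ac, atac)
  high_conf <- derive_high_confidence(rmj_regulated, rmj_flagged, genes,
                                      window_bp = w, anchor = anchor,
                                      conjunction = config$conjunction,
                                      n_iter = config$n_iter_monte_carlo,
                                      seed = config$seed)

  # Optional in-vivo cross
  in_vivo <- NULL
  sel_vivo <- NULL
  if (!is.null(expr_vivo)) {
    sel_vivo <- select_responsive(expr_vivo, config$thresholds_in_vivo,
                                  label = "in_vivo_responsive")
    in_vivo <- derive_in_vivo(rmj_regulated, sel_vivo$responsive)
  }

  report <- list(
    config = config[setdiff(names(config), c("thresholds", "thresholds_in_vivo"))],
    thresholds = unclass(config$thresholds),
    thresholds_in_vivo = unclass(config$thresholds_in_vivo),
    dataset_id = config$dataset_id,
    n_genes_annotation = nrow(genes),
    counts = c(
      responsive = length(sel$responsive$ids),
      up = length(sel$up$ids),
      down = length(sel$down$ids),
      runx1_bound = length(runx1_bound$ids),
      regulated = length(regulated$ids),
      rmj_regulated = length(rmj_regulated$ids),
      high_confidence = length(high_conf$ids),
      in_vivo_responsive = if (is.null(sel_vivo)) NA_integer_ else
        length(sel_vivo$responsive$ids),
      in_vivo = if (is.null(in_vivo)) NA_integer_ else length(in_vivo$ids)),
    fractions = c(
      responsive_bound = attr(regulated, "bound_fraction"),
      cooccupancy_runx1_myod = co_myod$fraction,
      cooccupancy_cjun_runx1 = co_cjun_runx1$fraction,
      runx1_active_enhancer = attr(runx1_flagged, "fractions")[["active_enhancer"]],
      runx1_open_chromatin = attr(runx1_flagged, "fractions")[["open_chromatin"]],
      rmj_active_enhancer = attr(rmj_flagged, "fractions")[["active_enhancer"]],
      rmj_open_chromatin = attr(rmj_flagged, "fractions")[["open_chromatin"]]),
    location = locdist,
    venn3 = list(counts = v3$counts, n_clusters = v3$n_clusters,
                 labels = v3$labels),
    n_rmj_regions = length(rmj),
    tests = list(
      bootstrap_runx1_myod = list(observed = bt_myod$observed,
                                  fraction = bt_myod$fraction,
                                  p_empirical = bt_myod$p_empirical,
                                  n_iter = bt_myod$null$n_iter,
                                  seed = bt_myod$null$seed),
      hypergeom_rmj = attr(rmj_regulated, "p_hypergeom"),
      monte_carlo_high_confidence = attr(high_conf, "monte_carlo")),
    gene_sets = list(responsive = sel$responsive, up = sel$up, down = sel$down,
                     runx1_bound = runx1_bound, regulated = regulated,
                     rmj_regulated = rmj_regulated,
                     high_confidence = high_conf,
                     in_vivo_responsive = if (is.null(sel_vivo)) NULL else
                       sel_vivo$responsive,
                     in_vivo = in_vivo),
    regions = list(rmj = rmj_flagged, runx1 = runx1_flagged))
  class(report) <- "cascade_report"
  .check_nesting(report)
  report
}

.check_nesting <- function(report) {
  gs <- report$gene_sets
  sub <- function(a, b) all(a$ids %in% b$ids)
  if (!sub(gs$regulated, gs$responsive) ||
      !sub(gs$rmj_regulated, gs$regulated) ||
      !sub(gs$high_confidence, gs$rmj_regulated))
    .stopf("internal error: cascade nesting invariant violated")
  if (!is.null(gs$in_vivo) && !sub(gs$in_vivo, gs$rmj_regulated))
    .stopf("internal error: in-vivo set escapes the RMJ-regulated set")
  invisible(TRUE)
}

#' Cascade configuration
#'
#' Normalizes and validates the configuration list for [run_cascade()].
#' Region/gene/expression inputs may be in-memory objects or file paths.
#'
#' @param config Named list. Recognized keys: `runx1`, `myod`, `cjun`,
#'   `h3k4me1`, `h3k27ac`, `atac`, `genes`, `expression`,
#'   `expression_in_vivo` (optional), `chrom_sizes`, `peak_format`
#'   (default `"bed6"`), `gene_format` (default `"bed6"`), `thresholds`
#'   (default q < 0.1, > 1.5-fold), `thresholds_in_vivo` (default
#'   q < 0.05, > 1.7-fold), `window_bp` (default 200,000), `anchor`
#'   (default `"summit"`), `rmj_mode` (`"cluster"` or `"independent"`),
#'   `conjunction` (`"region"` or `"independent"`), `n_iter_bootstrap`,
#'   `n_iter_monte_carlo` (defaults 10,000), `seed`, `dataset_id`.
#' @return Validated config list.
#' @export
cascade_config <- function(config) {
  defaults <- list(peak_format = "bed6", gene_format = "bed6",
                   thresholds = threshold_spec(0.1, 1.5),
                   thresholds_in_vivo = threshold_spec(0.05, 1.7),
                   window_bp = 200000L, anchor = "summit",
                   rmj_mode = "cluster", conjunction = "region",
                   n_iter_bootstrap = 10000L, n_iter_monte_carlo = 10000L,
                   seed = 1L, dataset_id = NULL, expression_in_vivo = NULL)
  unknown <- setdiff(names(config),
                     c(names(defaults), "runx1", "myod", "cjun", "h3k4me1",
                       "h3k27ac", "atac", "genes", "expression", "chrom_sizes"))
  if (length(unknown)) .stopf("unknown config key: %s", unknown[1L])
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  need <- c("runx1", "myod", "cjun", "h3k4me1", "h3k27ac", "atac", "genes",
            "expression", "chrom_sizes")
  miss <- need[vapply(need, function(k) is.null(config[[k]]), logical(1))]
  if (length(miss)) .stopf("config is missing required input '%s'", miss[1L])
  if (!inherits(config$thresholds, "threshold_spec"))
    config$thresholds <- do.call(threshold_spec, as.list(config$thresholds))
  if (!inherits(config$thresholds_in_vivo, "threshold_spec"))
    config$thresholds_in_vivo <-
      do.call(threshold_spec, as.list(config$thresholds_in_vivo))
  if (!config$rmj_mode %in% c("cluster", "independent"))
    .stopf("rmj_mode must be 'cluster' or 'independent'")
  if (!config$conjunction %in% c("region", "independent"))
    .stopf("conjunction must be 'region' or 'independent'")
  if (config$window_bp <= 0) .stopf("window_bp must be positive")
  config
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Evidence-integration cascade report\n")
  cat(sprintf("  annotation genes: %d\n", x$n_genes_annotation))
  cnt <- x$counts
  for (nm in names(cnt))
    if (!is.na(cnt[[nm]])) cat(sprintf("  %-20s %d\n", nm, cnt[[nm]]))
  cat(sprintf("  RMJ regions: %d of %d merged clusters\n",
              x$n_rmj_regions, x$venn3$n_clusters))
  cat(sprintf("  bootstrap p (Runx1 x MyoD overlap): %.3g\n",
              x$tests$bootstrap_runx1_myod$p_empirical))
  cat(sprintf("  hypergeometric p (RMJ x responsive): %.3g\n",
              x$tests$hypergeom_rmj))
  cat(sprintf("  Monte Carlo p (high confidence): %.3g\n",
              x$tests$monte_carlo_high_confidence$p_empirical))
  invisible(x)
}

#' Serialize / restore a cascade report
#'
#' The JSON form contains every count, fraction, p-value, seed and
#' parameter plus the gene-set memberships — enough to recompute or audit
#' a run. Region-level objects are summarized, not serialized.
#'
#' @param report A `cascade_report`.
#' @param path Output path.
#' @export
write_cascade_report <- function(report, path) {
  gs_json <- lapply(Filter(Negate(is.null), report$gene_sets), function(g)
    list(label = g$label, n = length(g$ids), ids = g$ids))
  out <- list(
    schema = "rmjcascade/report/v1",
    dataset_id = report$dataset_id,
    config = Filter(function(x) is.character(x) || is.numeric(x) || is.logical(x),
                    report$config),
    thresholds = report$thresholds,
    thresholds_in_vivo = report$thresholds_in_vivo,
    n_genes_annotation = report$n_genes_annotation,
    counts = as.list(report$counts),
    fractions = as.list(report$fractions),
    location = report$location[c("fractions", "counts", "n_assignable",
                                 "n_unassigned", "frac_within_100kb",
                                 "frac_within_200kb")],
    venn3 = list(counts = as.list(report$venn3$counts),
                 n_clusters = report$venn3$n_clusters,
                 labels = as.list(report$venn3$labels)),
    n_rmj_regions = report$n_rmj_regions,
    tests = report$tests,
    gene_sets = gs_json)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cascade_report
#' @export
read_cascade_report <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  rep_ <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     .stopf("%s: not a valid report JSON (%s)", path,
                            conditionMessage(e)))
  if (is.null(rep_$schema) || !identical(rep_$schema, "rmjcascade/report/v1"))
    .stopf("%s: unrecognized report schema '%s'", path,
           if (is.null(rep_$schema)) "<none>" else rep_$schema)
  rep_
}
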