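#' Read a pipeline run configuration from YAML
#'
#' Expected keys: `trait1`/`trait2` (each with `path`, optional `name` and
#' `column_map`), `ld` (path), optional `genes` (BED path), `out` (output
#' directory), and any of the analysis parameters accepted by [conjfdr()]
#' (`thresholds`, `bin_edges`, `grid_size`, `max_log10p`, `n_sets`,
#' `r2_threshold`, `alpha`, `suggestive`, `seed`, `prune`, `monotone`,
#' `average`, `gc_correct`).
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (t in c("trait1", "trait2")) {
    if (is.null(cfg[[t]]$path)) stop("run config must give ", t, "$path")
  }
  if (is.null(cfg$ld)) stop("run config must give an ld path")
  if (is.null(cfg$out)) stop("run config must give an output directory")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline from files to files
#'
#' Reads the two summary-statistics tables and the LD table, fits the
#' cross-trait conjunctional FDR analysis, and writes: a per-SNP conjFDR
#' table (`persnp.tsv`), the locus report in published-table layout
#' (`loci.tsv`), stratified Q-Q and fold-enrichment curve tables
#' (`qq_curves.tsv`, `fold_enrichment.tsv`), both cFDR lookup tables
#' (`lookup_*.tsv`), and a JSON run summary (`summary.json`) recording
#' lambda values, SNP counts at each filter, the seed and the package
#' version.  On error, partially written outputs are removed.
#'
#' @param config A `run_config`, a YAML path, or a named list with the same
#'   fields.
#' @return The `conjfdr` fit, invisibly, with attribute `outputs` (paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  read_trait <- function(spec, default_name) {
    read_sumstats(spec$path,
                  column_map = unlist(spec$column_map),
                  trait_name = spec$name %||% default_name)
  }
  panel_a <- read_trait(config$trait1, "trait1")
  panel_b <- read_trait(config$trait2, "trait2")
  ld <- read_ld(config$ld)

  grid <- cfdr_grid(config$grid_size %||% 301L, config$max_log10p %||% 7.5)
  fit <- conjfdr(panel_a, panel_b, ld,
                 gc_correct = config$gc_correct %||% TRUE,
                 thresholds = config$thresholds %||% c(1, 0.1, 0.01, 0.001),
                 bin_edges = config$bin_edges %||% 0:4,
                 grid = grid,
                 n_sets = config$n_sets %||% 100L,
                 r2_threshold = config$r2_threshold %||% 0.1,
                 alpha = config$alpha %||% 0.05,
                 suggestive = config$suggestive %||% 0.1,
                 seed = config$seed %||% 1L,
                 prune = config$prune %||% TRUE,
                 monotone = config$monotone %||% TRUE,
                 average = config$average %||% "counts")

  if (!is.null(config$genes)) {
    fit$loci <- annotate_nearest_gene(fit$loci, read_bed(config$genes))
  }

  outputs <- file.path(out_dir, c("persnp.tsv", "loci.tsv", "qq_curves.tsv",
                                  "fold_enrichment.tsv",
                                  "lookup_1_given_2.tsv",
                                  "lookup_2_given_1.tsv", "summary.json"))
  names(outputs) <- c("persnp", "loci", "qq", "fold", "lookup12", "lookup21",
                      "summary")
  tryCatch({
    write.table(fit$snp_stats, outputs[["persnp"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_locus_report(fit$loci, outputs[["loci"]])
    write.table(fit$enrichment$qq, outputs[["qq"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fit$enrichment$fold, outputs[["fold"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_cfdr_lookup(attr(fit$snp_stats, "lookup_1_given_2"),
                      outputs[["lookup12"]])
    write_cfdr_lookup(attr(fit$snp_stats, "lookup_2_given_1"),
                      outputs[["lookup21"]])
    summary_json <- list(
      traits = as.list(setNames(fit$trait_names, c("trait1", "trait2"))),
      n_snps = list(trait1 = nrow(panel_a), trait2 = nrow(panel_b),
                    harmonized = nrow(fit$merged)),
      harmonization = as.list(attr(fit$merged, "harmonization")),
      lambda_gc = if (!is.null(fit$gc)) {
        list(trait1 = fit$gc[[1]]$lambda_gc, trait2 = fit$gc[[2]]$lambda_gc,
             raw = c(fit$gc[[1]]$lambda_raw, fit$gc[[2]]$lambda_raw),
             n_intergenic = fit$gc[[1]]$n_intergenic)
      },
      n_pruned_sets = fit$params$n_sets,
      seed = fit$params$seed,
      n_loci = nrow(fit$loci),
      n_significant = sum(fit$loci$significant),
      n_suggestive = sum(fit$loci$suggestive),
      package_version = as.character(utils::packageVersion("conjfdr"))
    )
    jsonlite::write_json(summary_json, outputs[["summary"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(outputs)
    stop("pipeline output stage failed (partial outputs removed): ",
         conditionMessage(e))
  })
  attr(fit, "outputs") <- outputs
  invisible(fit)
}

#' Region-exclusion enrichment re-analysis
#'
#' Re-runs the stratified enrichment analysis after removing a genomic
#' region and its LD partners ([exclude_region()]), to quantify how much of
#' the cross-trait enrichment a single locus drives.  Returns paired
#' fold-enrichment tables and a "driver share" diagnostic: the relative
#' attenuation of the fold enrichment above 1 at `driver_bin`,
#' `(fold_pre - fold_post) / (fold_pre - 1)`, per conditioning stratum.
#'
#' @param fit A `conjfdr` fit (its GC-corrected merged panel, LD table and
#'   pruning parameters are reused; the pruned sets are regenerated on the
#'   reduced panel with the same seed).
#' @param chrom,start,end Region to exclude (1-based closed interval).
#' @param driver_bin Cumulative bin at which the diagnostic is evaluated
#'   (default 3).
#' @return List of class `conjfdr_exclusion` with `pre`, `post` (enrichment
#'   summaries), `excluded` (counts), `driver_share` (named by stratum).
#' @export
run_exclusion_reanalysis <- function(fit, chrom, start, end, driver_bin = 3) {
  stopifnot(inherits(fit, "conjfdr"))
  p <- fit$params
  reduced <- exclude_region(fit$merged, chrom, start, end, fit$ld,
                            r2_threshold = p$r2_threshold)
  pruned <- if (p$prune) {
    random_prune(reduced, fit$ld, n_sets = p$n_sets, seed = p$seed,
                 r2_threshold = p$r2_threshold, max_dist = p$max_dist)
  } else {
    list(seq_len(nrow(reduced)))
  }
  pre <- fit$enrichment
  if (is.null(pre)) {
    pre <- stratified_enrichment(fit$merged, fit$pruned_sets,
                                 conditioning = 2L,
                                 thresholds = p$thresholds,
                                 bin_edges = p$bin_edges)
  }
  post <- stratified_enrichment(reduced, pruned, conditioning = 2L,
                                thresholds = p$thresholds,
                                bin_edges = p$bin_edges)
  fp <- pre$fold[pre$fold$bin == driver_bin, ]
  fq <- post$fold[post$fold$bin == driver_bin, ]
  stratum <- fp$stratum
  share <- ifelse(!is.na(fp$fold) & fp$fold > 1,
                  (fp$fold - fq$fold[match(stratum, fq$stratum)]) /
                    (fp$fold - 1),
                  NA_real_)
  structure(list(pre = pre, post = post,
                 excluded = attr(reduced, "excluded"),
                 driver_bin = driver_bin,
                 driver_share = setNames(share, stratum),
                 region = c(chrom = as.character(chrom), start = start,
                            end = end)),
            class = "conjfdr_exclusion")
}

#' @export
print.conjfdr_exclusion <- function(x, ...) {
  cat(sprintf("Exclusion re-analysis: chr%s:%s-%s (%d SNPs in region, %d LD partners removed)\n",
              x$region[["chrom"]], x$region[["start"]], x$region[["end"]],
              x$excluded[["in_region"]], x$excluded[["ld_partners"]]))
  fp <- x$pre$fold[x$pre$fold$bin == x$driver_bin, c("stratum", "fold")]
  fq <- x$post$fold[x$post$fold$bin == x$driver_bin, c("stratum", "fold")]
  tab <- merge(fp, fq, by = "stratum", suffixes = c("_pre", "_post"))
  tab$driver_share <-
    x$driver_share[match(as.character(tab$stratum), names(x$driver_share))]
  cat(sprintf("Fold enrichment at -log10 p >= %g:\n", x$driver_bin))
  print(tab[order(-tab$stratum), ], row.names = FALSE, digits = 3)
  invisible(x)
}
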