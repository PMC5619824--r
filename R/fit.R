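#' Fit a cross-trait conditional/conjunctional FDR analysis
#'
#' The main entry point of the package.  Runs the full analysis on two trait
#' panels and an LD table: allele harmonization onto a shared SNP set,
#' genomic-control correction of each trait from intergenic SNPs, random LD
#' pruning into near-independent SNP sets, stratified Q-Q / fold-enrichment
#' curves of the primary trait conditioned on the other, the bidirectional
#' empirical cFDR lookup tables with per-SNP interpolation, the conjunctional
#' FDR, and greedy LD clumping of the result into index-SNP loci with
#' significance calls.  Deterministic given `seed`.
#'
#' @param panel_a,panel_b Trait panels ([read_sumstats()] /
#'   [simulate_two_traits()]).  Trait 1 (`panel_a`) is the primary trait of
#'   the enrichment curves; trait 2 conditions them.
#' @param ld An `ld_matrix` ([read_ld()] / [simulate_ld()]).
#' @param gc_correct Apply genomic control per trait before any cross-trait
#'   statistic (default TRUE).
#' @param gc_clamp,min_intergenic Passed to [compute_lambda_gc()].
#' @param thresholds Conditioning strata, see [stratify()].
#' @param bin_edges Cumulative fold-enrichment bins (default `0:4`).
#' @param grid cFDR grid, see [cfdr_grid()].
#' @param qq_max_log10p Display limit of the Q-Q curves (default 7.3).
#' @param n_sets Number of random pruned sets (default 100).
#' @param r2_threshold LD threshold shared by pruning and clumping.
#' @param max_dist Maximum pruning-edge distance in bp (default 1 Mb).
#' @param alpha,suggestive Locus significance thresholds.
#' @param seed RNG seed for the pruning.
#' @param prune Use random LD-pruned sets for the curves and lookup tables
#'   (default TRUE); FALSE computes everything on the full SNP panel.
#' @param monotone,average Lookup-table options, see [build_cfdr_lookup()].
#' @param enrichment Compute the stratified enrichment summary (default
#'   TRUE).
#' @return An object of class `conjfdr`: list with `merged`, `gc` (per-trait
#'   `gc_result`s or NULL), `pruned_sets`, `enrichment`, `snp_stats` (the
#'   per-SNP `cfdr_result`), `loci`, `ld`, `params`, `call`.
#' @seealso [run_pipeline()] for the file-based wrapper,
#'   [run_exclusion_reanalysis()] for region-exclusion re-analysis.
#' @examples
#' cfg <- scenario_config("shared-concordant", m_snps = 2000, seed = 7,
#'                        n_shared = 4)
#' sim <- simulate_two_traits(cfg)
#' fit <- conjfdr(sim$panel1, sim$panel2, simulate_ld(cfg),
#'                n_sets = 20, seed = 7)
#' fit
#' head(loci(fit))
#' @export
conjfdr <- function(panel_a, panel_b, ld,
                    gc_correct = TRUE, gc_clamp = TRUE, min_intergenic = 1000,
                    thresholds = c(1, 0.1, 0.01, 0.001), bin_edges = 0:4,
                    grid = cfdr_grid(), qq_max_log10p = 7.3,
                    n_sets = 100L, r2_threshold = 0.1, max_dist = 1e6,
                    alpha = 0.05, suggestive = 0.1,
                    seed = 1L, prune = TRUE, monotone = TRUE,
                    average = c("counts", "values"), enrichment = TRUE) {
  average <- match.arg(average)
  merged <- harmonize_panels(panel_a, panel_b)

  gc <- NULL
  if (gc_correct) {
    gc <- list(
      compute_lambda_gc(merged$z1, merged$intergenic,
                        min_intergenic = min_intergenic, clamp = gc_clamp),
      compute_lambda_gc(merged$z2, merged$intergenic,
                        min_intergenic = min_intergenic, clamp = gc_clamp)
    )
    merged <- apply_gc(merged, gc[[1]], trait = 1L)
    merged <- apply_gc(merged, gc[[2]], trait = 2L)
  }

  pruned_sets <- if (prune) {
    random_prune(merged, ld, n_sets = n_sets, seed = seed,
                 r2_threshold = r2_threshold, max_dist = max_dist)
  } else {
    list(seq_len(nrow(merged)))
  }

  enr <- NULL
  if (enrichment) {
    enr <- stratified_enrichment(merged, pruned_sets, conditioning = 2L,
                                 thresholds = thresholds,
                                 bin_edges = bin_edges,
                                 qq_grid = seq(0, qq_max_log10p, by = 0.1))
  }

  snp_stats <- compute_conjfdr(merged, ld, grid = grid,
                               r2_threshold = r2_threshold,
                               max_dist = max_dist, monotone = monotone,
                               average = average, pruned_sets = pruned_sets,
                               seed = seed)
  loci <- call_significance(clump(snp_stats$conjfdr, ld, merged,
                                  r2_threshold = r2_threshold),
                            alpha = alpha, suggestive = suggestive)

  structure(list(merged = merged, gc = gc, pruned_sets = pruned_sets,
                 enrichment = enr, snp_stats = snp_stats, loci = loci,
                 ld = ld,
                 params = list(thresholds = thresholds,
                               bin_edges = bin_edges,
                               grid = grid, n_sets = length(pruned_sets),
                               r2_threshold = r2_threshold,
                               max_dist = max_dist, alpha = alpha,
                               suggestive = suggestive, seed = seed,
                               prune = prune, monotone = monotone,
                               average = average,
                               gc_correct = gc_correct),
                 trait_names = attr(merged, "trait_names"),
                 call = match.call()),
            class = "conjfdr")
}

#' Extract the clumped locus table from a fit
#'
#' @param fit A `conjfdr` fit.
#' @param significant_only Keep only loci with conjFDR below alpha.
#' @return A `locus_table`.
#' @export
loci <- function(fit, significant_only = FALSE) {
  stopifnot(inherits(fit, "conjfdr"))
  if (significant_only) fit$loci[fit$loci$significant, , drop = FALSE]
  else fit$loci
}

#' @export
print.conjfdr <- function(x, ...) {
  tn <- x$trait_names
  cat("Cross-trait conjunctional FDR analysis\n")
  cat(sprintf("  traits: %s vs %s; %d harmonized SNPs\n",
              tn[1], tn[2], nrow(x$merged)))
  if (!is.null(x$gc)) {
    cat(sprintf("  lambda_GC: %s = %.4f, %s = %.4f (intergenic n = %d)\n",
                tn[1], x$gc[[1]]$lambda_gc, tn[2], x$gc[[2]]$lambda_gc,
                x$gc[[1]]$n_intergenic))
  }
  cat(sprintf("  pruned sets: %d; cFDR grid: %d x %d over [0, %.2g]\n",
              x$params$n_sets, length(x$params$grid), length(x$params$grid),
              max(x$params$grid)))
  cat(sprintf("  loci: %d total, %d significant (conjFDR < %.3g), %d suggestive (< %.3g)\n",
              nrow(x$loci), sum(x$loci$significant), x$params$alpha,
              sum(x$loci$suggestive), x$params$suggestive))
  invisible(x)
}

#' @export
summary.conjfdr <- function(object, n_top = 10L, ...) {
  sig <- object$loci[object$loci$suggestive, , drop = FALSE]
  structure(list(fit = object,
                 fold = object$enrichment$fold,
                 top_loci = head(object$loci, n_top),
                 n_significant = sum(object$loci$significant),
                 n_suggestive = sum(object$loci$suggestive),
                 suggestive_loci = sig),
            class = "summary.conjfdr")
}

#' @export
print.summary.conjfdr <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fold)) {
    cat("\nFold enrichment by conditioning stratum (rows) and -log10 p bin:\n")
    ftab <- stats::xtabs(fold ~ stratum + bin, data = x$fold,
                         na.action = stats::na.pass)
    print(round(ftab[order(-as.numeric(rownames(ftab))), , drop = FALSE], 2))
  }
  if (nrow(x$suggestive_loci)) {
    cat("\nLoci with conjFDR < suggestive threshold:\n")
    cols <- c("locus", "index_snp", "chr", "pos", "p1", "p2", "conjfdr",
              "n_members", "significant")
    print(x$suggestive_loci[, cols], row.names = FALSE, digits = 3)
  } else {
    cat("\nNo loci below the suggestive threshold.\n")
  }
  invisible(x)
}

#' Plot method for conjfdr fits
#'
#' `type = "qq"` draws the stratified conditional Q-Q curves (empirical
#' `-log10 q` on x, nominal `-log10 p` on y; leftward shift of stricter
#' strata indicates cross-trait enrichment), `type = "fold"` the
#' fold-enrichment per cumulative bin, and `type = "manhattan"` the per-SNP
#' `-log10 conjFDR` by position with significant loci highlighted.
#'
#' @param x A `conjfdr` fit.
#' @param type One of `"qq"`, `"fold"`, `"manhattan"`.
#' @param ... Further base-graphics arguments.
#' @export
plot.conjfdr <- function(x, type = c("qq", "fold", "manhattan"), ...) {
  type <- match.arg(type)
  tn <- x$trait_names
  if (type %in% c("qq", "fold") && is.null(x$enrichment)) {
    stop("fit was computed with enrichment = FALSE")
  }
  if (type == "qq") {
    qq <- x$enrichment$qq
    strata <- sort(unique(qq$stratum), decreasing = TRUE)
    cols <- rainbow(length(strata), end = 0.7)
    plot(NA, xlim = range(qq$nlog10q), ylim = range(qq$nlog10p),
         xlab = expression(-log[10] ~ "empirical q"),
         ylab = expression(-log[10] ~ "nominal p"),
         main = sprintf("%s conditioned on %s", tn[1], tn[2]), ...)
    for (k in seq_along(strata)) {
      s <- qq[qq$stratum == strata[k], ]
      lines(s$nlog10q, s$nlog10p, col = cols[k], lwd = 2)
    }
    abline(0, 1, lty = 3)
    legend("bottomright", legend = paste("p <", strata), col = cols,
           lwd = 2, bty = "n")
  } else if (type == "fold") {
    fd <- x$enrichment$fold
    strata <- sort(unique(fd$stratum), decreasing = TRUE)
    cols <- rainbow(length(strata), end = 0.7)
    plot(NA, xlim = range(fd$bin), ylim = c(0, max(fd$fold, 1, na.rm = TRUE)),
         xlab = expression(-log[10] ~ "p bin"), ylab = "fold enrichment",
         main = sprintf("%s enrichment by %s stratum", tn[1], tn[2]), ...)
    for (k in seq_along(strata)) {
      s <- fd[fd$stratum == strata[k], ]
      lines(s$bin, s$fold, col = cols[k], lwd = 2, type = "b")
    }
    abline(h = 1, lty = 3)
    legend("topleft", legend = paste("p <", strata), col = cols,
           lwd = 2, bty = "n")
  } else {
    ss <- x$snp_stats
    nl <- -log10(ss$conjfdr)
    sig <- ss$conjfdr < x$params$alpha
    plot(x$merged$pos / 1e6, nl, pch = 16, cex = ifelse(sig, 0.8, 0.3),
         col = ifelse(sig, "firebrick", "grey50"),
         xlab = "position (Mb)", ylab = expression(-log[10] ~ "conjFDR"),
         main = "Conjunction Manhattan plot", ...)
    abline(h = -log10(x$params$alpha), lty = 3)
    idx <- match(x$loci$index_snp[x$loci$significant], ss$snp_id)
    if (length(idx)) points(x$merged$pos[idx] / 1e6, nl[idx], cex = 1.4)
  }
  invisible(x)
}
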