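#' Stratum masks by conditioning-trait significance
#'
#' Splits the merged panel into nested SNP strata by the p-value of the
#' conditioning trait: the baseline stratum (threshold 1) contains all SNPs,
#' and each stricter threshold keeps SNPs with conditioning p strictly below
#' it.
#'
#' @param merged A `merged_panel`.
#' @param conditioning Which trait (1 or 2) defines the strata; the other is
#'   the primary trait whose p-values are examined.  Default 2.
#' @param thresholds Descending cutoffs in (0, 1].  The baseline threshold 1
#'   is added if missing.
#' @return Named list of logical masks (names are the thresholds), nested
#'   from baseline outward.
#' @export
stratify <- function(merged, conditioning = 2L,
                     thresholds = c(1, 0.1, 0.01, 0.001)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("stratum thresholds must lie in (0, 1]")
  }
  if (!1 %in% thresholds) thresholds <- c(1, thresholds)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  p_cond <- if (conditioning == 2L) merged$p2 else merged$p1
  masks <- lapply(thresholds, function(t) {
    if (t >= 1) p_cond <= 1 else p_cond < t
  })
  names(masks) <- vapply(thresholds, format, character(1), scientific = FALSE)
  empty <- !vapply(masks, any, logical(1))
  if (any(empty)) {
    warning("empty strata at thresholds: ",
            paste(names(masks)[empty], collapse = ", "))
  }
  masks
}

#' Conditional (stratified) Q-Q curves
#'
#' For each stratum, sorts the primary trait's p-values ascending and pairs
#' each nominal `-log10(p)` with its empirical quantile `q = k/n` (the
#' fraction of stratum SNPs at least as significant).  Points with nominal
#' `-log10(p) >= max_log10p` are omitted so that the curves describe the
#' polygenic range below genome-wide significance.
#'
#' @param p_primary Per-SNP p-values of the primary trait.
#' @param masks Stratum masks from [stratify()].
#' @param max_log10p Display restriction on nominal `-log10(p)` (default 7.3).
#' @return A named list of `qq_curve` data frames with columns `nlog10p`
#'   (nominal), `q` (empirical quantile in (0, 1\]) and `nlog10q`; attributes
#'   `stratum_threshold`, `n_stratum` and `p_values` (the stratum's full
#'   p-vector, used downstream for fold enrichment).  Empty strata are
#'   skipped with a warning.
#' @export
conditional_qq <- function(p_primary, masks, max_log10p = 7.3) {
  out <- list()
  for (nm in names(masks)) {
    mask <- masks[[nm]]
    n <- sum(mask)
    if (n == 0L) {
      warning("skipping empty stratum ", nm)
      next
    }
    ps <- sort(p_primary[mask])
    q <- seq_len(n) / n
    nlp <- -log10(ps)
    keep <- nlp < max_log10p
    curve <- data.frame(nlog10p = nlp[keep], q = q[keep],
                        nlog10q = -log10(q[keep]))
    curve <- curve[order(curve$nlog10p), , drop = FALSE]
    rownames(curve) <- NULL
    out[[nm]] <- structure(curve, class = c("qq_curve", "data.frame"),
                           stratum_threshold = as.numeric(nm),
                           n_stratum = n,
                           p_values = p_primary[mask])
  }
  structure(out, class = "qq_curves")
}

#' Fold-enrichment curves over cumulative significance bins
#'
#' For each stratum and cumulative bin edge `b`, the fold enrichment is the
#' fraction of stratum SNPs with `-log10(p) >= b` divided by the same
#' fraction in the baseline stratum (all SNPs).  Reported as `NA` where the
#' baseline fraction is zero.  A conservative per-bin TDR
#' (`1 - min(1, 10^-b / stratum fraction)`) is included.
#'
#' @param curves Output of [conditional_qq()]; must contain the baseline
#'   stratum (threshold 1).
#' @param bin_edges Cumulative `-log10(p)` thresholds (default `0:4`).
#' @return Data frame with `stratum`, `bin`, `frac`, `baseline_frac`, `fold`,
#'   `tdr`.
#' @export
fold_enrichment <- function(curves, bin_edges = 0:4) {
  thr <- vapply(curves, attr, numeric(1), "stratum_threshold")
  base_i <- which(thr >= 1)
  if (length(base_i) == 0L) stop("baseline stratum (threshold 1) missing")
  tail_frac <- function(curve) {
    nlp <- -log10(attr(curve, "p_values"))
    vapply(bin_edges, function(b) mean(nlp >= b), numeric(1))
  }
  base_frac <- tail_frac(curves[[base_i[1]]])
  out <- lapply(names(curves), function(nm) {
    f <- tail_frac(curves[[nm]])
    fold <- ifelse(base_frac > 0, f / base_frac, NA_real_)
    data.frame(stratum = as.numeric(nm), bin = bin_edges,
               frac = f, baseline_frac = base_frac, fold = fold,
               tdr = ifelse(f > 0, 1 - pmin(1, 10^(-bin_edges) / f), NA_real_))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' True-discovery-rate values along a Q-Q curve
#'
#' At each curve point the FDR is conservatively estimated as
#' `min(1, p / q)` (null proportion taken as 1) and TDR = 1 - FDR.
#'
#' @param curve A `qq_curve`.
#' @return Numeric vector of TDR values, one per curve point.
#' @export
tdr_curve <- function(curve) {
  if (nrow(curve) == 0L) stop("empty Q-Q curve")
  1 - pmin(1, 10^(-curve$nlog10p) / curve$q)
}

#' Stratified enrichment summary over random LD-pruned sets
#'
#' Computes, for each stratum and each pruned SNP set, the empirical survival
#' fraction of the primary trait's `-log10(p)` on a nominal grid, averages
#' the fractions pointwise across sets (sets where a stratum is empty are
#' skipped for that stratum), and derives averaged conditional Q-Q curves and
#' fold-enrichment values at the requested cumulative bins.  Averaging the
#' fractions (rather than per-set fold ratios) keeps thin tail bins stable.
#'
#' @param merged A `merged_panel` (GC-corrected p-values recommended).
#' @param pruned_sets List of integer row-index vectors from [random_prune()],
#'   or NULL for a single set containing every SNP.
#' @param conditioning Conditioning trait (1 or 2; default 2).
#' @param thresholds Stratum cutoffs, see [stratify()].
#' @param bin_edges Cumulative bins for fold enrichment.
#' @param qq_grid Nominal `-log10(p)` grid for the averaged Q-Q curves.
#' @return List with `fold` (data frame `stratum`, `bin`, `frac`,
#'   `baseline_frac`, `fold`), `qq` (data frame `stratum`, `nlog10p`,
#'   `q`, `nlog10q`), `n_sets`, and `stratum_n` (mean stratum size per set).
#' @export
stratified_enrichment <- function(merged, pruned_sets = NULL,
                                  conditioning = 2L,
                                  thresholds = c(1, 0.1, 0.01, 0.001),
                                  bin_edges = 0:4,
                                  qq_grid = seq(0, 7.3, by = 0.1)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("stratum thresholds must lie in (0, 1]")
  }
  if (!1 %in% thresholds) thresholds <- c(1, thresholds)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  if (is.null(pruned_sets)) pruned_sets <- list(seq_len(nrow(merged)))
  p_primary <- if (conditioning == 2L) merged$p1 else merged$p2
  p_cond <- if (conditioning == 2L) merged$p2 else merged$p1
  nlp <- -log10(p_primary)

  grid <- sort(unique(c(qq_grid, bin_edges)))
  ng <- length(grid)
  nt <- length(thresholds)
  surv_sum <- matrix(0, nt, ng)
  n_nonempty <- numeric(nt)
  n_stratum <- numeric(nt)

  for (set in pruned_sets) {
    pc <- p_cond[set]
    x <- nlp[set]
    for (k in seq_len(nt)) {
      t <- thresholds[k]
      xm <- if (t >= 1) x else x[pc < t]
      n <- length(xm)
      if (n == 0L) next
      cnt <- tabulate(findInterval(xm, grid), nbins = ng)
      surv_sum[k, ] <- surv_sum[k, ] + rev(cumsum(rev(cnt))) / n
      n_nonempty[k] <- n_nonempty[k] + 1
      n_stratum[k] <- n_stratum[k] + n
    }
  }
  empty <- n_nonempty == 0
  if (any(empty)) {
    warning("strata empty in every pruned set: ",
            paste(thresholds[empty], collapse = ", "))
  }
  frac <- surv_sum / pmax(n_nonempty, 1)
  frac[empty, ] <- NA_real_

  base_k <- which(thresholds >= 1)[1]
  bins_i <- match(bin_edges, grid)
  fold <- do.call(rbind, lapply(seq_len(nt), function(k) {
    f <- frac[k, bins_i]
    bf <- frac[base_k, bins_i]
    data.frame(stratum = thresholds[k], bin = bin_edges, frac = f,
               baseline_frac = bf,
               fold = ifelse(!is.na(bf) & bf > 0, f / bf, NA_real_))
  }))
  qq <- do.call(rbind, lapply(seq_len(nt), function(k) {
    q <- frac[k, ]
    keep <- !is.na(q) & q > 0
    if (!any(keep)) return(NULL)
    data.frame(stratum = thresholds[k], nlog10p = grid[keep], q = q[keep],
               nlog10q = -log10(q[keep]))
  }))
  rownames(fold) <- rownames(qq) <- NULL
  list(fold = fold, qq = qq, n_sets = length(pruned_sets),
       stratum_n = setNames(n_stratum / pmax(n_nonempty, 1),
                            vapply(thresholds, format, character(1),
                                   scientific = FALSE)))
}
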