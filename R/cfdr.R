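#' Grid of -log10(p) bin centers for cFDR lookup tables
#'
#' @param size Number of equally spaced nodes per axis (default 301).
#' @param max_log10p Upper end of the grid in -log10(p) units (default 7.5).
#' @return Ascending numeric vector starting at 0.
#' @export
cfdr_grid <- function(size = 301L, max_log10p = 7.5) {
  stopifnot(size >= 2L, max_log10p > 0)
  seq(0, max_log10p, length.out = size)
}

#' Exact empirical conditional FDR at a query point
#'
#' The conditional FDR of trait 1 given trait 2 at observed p-values
#' `(u, v)` is estimated by counting:
#' `min(1, u * #\{p2 <= v\} / #\{p1 <= u & p2 <= v\})`.
#' It is the empirical posterior probability that a SNP is null for trait 1
#' given that both traits' p-values are at least as extreme as observed.  An
#' empty joint tail (denominator 0) returns 1: a SNP cannot gain
#' significance from an empty conditioning tail.  With `v = 1` the estimator
#' reduces to the unconditional empirical FDR `u * M / rank(u)`.
#'
#' @param u,v Query p-values in (0, 1] for trait 1 (primary) and trait 2
#'   (conditioning).
#' @param p1_all,p2_all Aligned per-SNP p-value vectors.
#' @return Conditional FDR estimate in (0, 1].
#' @export
conditional_fdr_exact <- function(u, v, p1_all, p2_all) {
  if (length(p1_all) == 0L || length(p1_all) != length(p2_all)) {
    stop("p-value vectors must be nonempty and of equal length")
  }
  stopifnot(u > 0, u <= 1, v > 0, v <= 1)
  num <- sum(p2_all <= v)
  den <- sum(p1_all <= u & p2_all <= v)
  if (den == 0L) return(1)
  min(1, u * num / den)
}

# Upper-tail joint count surface on the grid for one SNP subset:
# S[i, j] = #{ -log10 p1 >= grid[i] & -log10 p2 >= grid[j] }.
joint_tail_counts <- function(p1, p2, grid) {
  g <- length(grid)
  b1 <- findInterval(-log10(p1), grid)
  b2 <- findInterval(-log10(p2), grid)
  M <- matrix(tabulate(b1 + (b2 - 1L) * g, nbins = g * g), g, g)
  rev_cumsum2(M)
}

# Turn an averaged count surface into a cFDR node table for the direction
# whose primary axis is the rows of S.
counts_to_cfdr <- function(S, grid) {
  u <- 10^(-grid)
  num <- outer(u, S[1L, ])        # u_i * #{p_cond <= v_j}
  V <- num / S
  V[S == 0] <- 1                  # empty joint tail: no evidence
  pmin(V, 1)
}

#' Build a directional conditional-FDR lookup table
#'
#' Evaluates the empirical cFDR estimator of [conditional_fdr_exact()] on a
#' 2D grid of `-log10(p)` bin centers, within each random LD-pruned SNP set,
#' and combines the sets into one table.  With `average = "counts"` (the
#' default) the cumulative count surfaces are averaged across sets and the
#' estimator is formed from the averaged counts — stable even when single
#' pruned sets are small; with `average = "values"` the per-set estimator
#' values (1 where a set's joint tail is empty) are averaged instead.  A
#' monotone pass (running minimum toward more significant primary p) can be
#' applied to suppress interpolation artifacts in sparse tails.
#'
#' @param merged A `merged_panel`.
#' @param direction `"1|2"` (trait 1 conditioned on trait 2) or `"2|1"`.
#' @param grid Grid from [cfdr_grid()]; fewer than 10 nodes per axis triggers
#'   a warning.
#' @param pruned_sets List of integer row-index vectors ([random_prune()]),
#'   or NULL for a single set of all SNPs.
#' @param monotone Apply the column-wise running-minimum pass (default TRUE).
#' @param average `"counts"` or `"values"`, see above.
#' @return A `cfdr_lookup`: list with `grid`, `values` (matrix, rows indexed
#'   by the primary trait's `-log10 p`, columns by the conditioning trait's),
#'   `direction`, `n_sets`, `monotone`, `average`.
#' @export
build_cfdr_lookup <- function(merged, direction = c("1|2", "2|1"),
                              grid = cfdr_grid(),
                              pruned_sets = NULL, monotone = TRUE,
                              average = c("counts", "values")) {
  direction <- match.arg(direction)
  average <- match.arg(average)
  if (length(grid) < 10L) {
    warning("cFDR grid has fewer than 10 nodes per axis; interpolation will ",
            "be coarse")
  }
  if (is.null(pruned_sets)) pruned_sets <- list(seq_len(nrow(merged)))
  if (length(pruned_sets) == 0L) stop("need at least one pruned set")
  pp <- if (direction == "1|2") merged$p1 else merged$p2
  pc <- if (direction == "1|2") merged$p2 else merged$p1

  if (average == "counts") {
    Ssum <- 0
    for (set in pruned_sets) {
      Ssum <- Ssum + joint_tail_counts(pp[set], pc[set], grid)
    }
    V <- counts_to_cfdr(Ssum / length(pruned_sets), grid)
  } else {
    V <- 0
    for (set in pruned_sets) {
      S <- joint_tail_counts(pp[set], pc[set], grid)
      V <- V + counts_to_cfdr(S, grid)
    }
    V <- V / length(pruned_sets)
  }
  if (monotone) V <- apply(V, 2L, cummin)
  structure(list(grid = grid, values = V, direction = direction,
                 n_sets = length(pruned_sets), monotone = monotone,
                 average = average),
            class = "cfdr_lookup")
}

#' @export
print.cfdr_lookup <- function(x, ...) {
  cat(sprintf("cFDR lookup (%s): %d x %d grid over [0, %.2f], %d pruned set%s, %s-averaged%s\n",
              x$direction, length(x$grid), length(x$grid), max(x$grid),
              x$n_sets, if (x$n_sets == 1) "" else "s", x$average,
              if (x$monotone) ", monotone" else ""))
  invisible(x)
}

#' Interpolate a cFDR lookup table at observed p-value pairs
#'
#' Bilinear interpolation in `(-log10 u, -log10 v)` space; queries beyond the
#' grid edge are clamped to the edge value and flagged.
#'
#' @param lookup A `cfdr_lookup`.
#' @param u Primary-trait p-values (the trait named first in the lookup's
#'   direction).
#' @param v Conditioning-trait p-values.
#' @return Numeric vector of interpolated cFDR values with attribute
#'   `clamped` (logical: query beyond the grid edge in either coordinate).
#' @export
interpolate_cfdr <- function(lookup, u, v) {
  stopifnot(inherits(lookup, "cfdr_lookup"), length(u) == length(v))
  grid <- lookup$grid
  g <- length(grid)
  x <- -log10(u)
  y <- -log10(v)
  clamped <- x > grid[g] | y > grid[g]
  x <- pmin(pmax(x, grid[1]), grid[g])
  y <- pmin(pmax(y, grid[1]), grid[g])
  i <- pmin(pmax(findInterval(x, grid), 1L), g - 1L)
  j <- pmin(pmax(findInterval(y, grid), 1L), g - 1L)
  dx <- (x - grid[i]) / (grid[i + 1L] - grid[i])
  dy <- (y - grid[j]) / (grid[j + 1L] - grid[j])
  V <- lookup$values
  out <- V[cbind(i, j)] * (1 - dx) * (1 - dy) +
    V[cbind(i + 1L, j)] * dx * (1 - dy) +
    V[cbind(i, j + 1L)] * (1 - dx) * dy +
    V[cbind(i + 1L, j + 1L)] * dx * dy
  attr(out, "clamped") <- clamped
  out
}

#' @rdname interpolate_cfdr
#' @param object A `cfdr_lookup`.
#' @param ... Unused.
#' @export
predict.cfdr_lookup <- function(object, u, v, ...) interpolate_cfdr(object, u, v)

#' Conjunctional FDR from the two directional conditional FDRs
#'
#' Elementwise maximum: a SNP is called jointly associated only if it is
#' unlikely to be null in *either* conditioning direction.
#'
#' @param cfdr_a_given_b,cfdr_b_given_a Equal-length aligned cFDR vectors.
#' @return Per-SNP conjunctional FDR.
#' @export
conjunction <- function(cfdr_a_given_b, cfdr_b_given_a) {
  if (length(cfdr_a_given_b) != length(cfdr_b_given_a)) {
    stop("directional cFDR vectors differ in length")
  }
  pmax(cfdr_a_given_b, cfdr_b_given_a)
}

#' Per-SNP conjunctional FDR for a merged panel
#'
#' Generates random LD-pruned SNP sets, builds the two directional cFDR
#' lookup tables on them, scores every SNP in both directions by bilinear
#' interpolation, and takes the conjunction (elementwise maximum).  Fully
#' deterministic given `seed`.
#'
#' @param merged A `merged_panel` (GC-corrected recommended).
#' @param ld An `ld_matrix`.
#' @param n_sets Number of random pruned sets (default 100).
#' @param seed RNG seed for the pruning.
#' @param grid cFDR grid, see [cfdr_grid()].
#' @param r2_threshold LD-block edge threshold for pruning (default 0.1).
#' @param max_dist Maximum pair distance for pruning edges (default 1 Mb).
#' @param monotone,average Passed to [build_cfdr_lookup()].
#' @param pruned_sets Re-use pre-computed pruned sets instead of generating
#'   them (then `seed`/`n_sets` are ignored).
#' @return A `cfdr_result`: data frame `snp_id`, `p1`, `p2`, `cfdr12`
#'   (trait 1 given trait 2), `cfdr21`, `conjfdr`, `clamped`, with the two
#'   lookups, the pruned sets and the seed as attributes.
#' @export
compute_conjfdr <- function(merged, ld, n_sets = 100L, seed = 1L,
                            grid = cfdr_grid(), r2_threshold = 0.1,
                            max_dist = 1e6, monotone = TRUE,
                            average = c("counts", "values"),
                            pruned_sets = NULL) {
  average <- match.arg(average)
  if (is.null(pruned_sets)) {
    pruned_sets <- random_prune(merged, ld, n_sets = n_sets, seed = seed,
                                r2_threshold = r2_threshold,
                                max_dist = max_dist)
  }
  l12 <- build_cfdr_lookup(merged, "1|2", grid, pruned_sets,
                           monotone = monotone, average = average)
  l21 <- build_cfdr_lookup(merged, "2|1", grid, pruned_sets,
                           monotone = monotone, average = average)
  c12 <- interpolate_cfdr(l12, merged$p1, merged$p2)
  c21 <- interpolate_cfdr(l21, merged$p2, merged$p1)
  out <- data.frame(snp_id = merged$snp_id, p1 = merged$p1, p2 = merged$p2,
                    cfdr12 = as.numeric(c12), cfdr21 = as.numeric(c21),
                    conjfdr = conjunction(as.numeric(c12), as.numeric(c21)),
                    clamped = attr(c12, "clamped") | attr(c21, "clamped"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cfdr_result", "data.frame"),
            lookup_1_given_2 = l12, lookup_2_given_1 = l21,
            pruned_sets = pruned_sets, seed = seed)
}

#' Write a cFDR lookup table as a TSV grid
#' @param lookup A `cfdr_lookup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cfdr_lookup <- function(lookup, path) {
  M <- cbind(nlog10_primary = lookup$grid, lookup$values)
  colnames(M) <- c("nlog10_primary", sprintf("%.6g", lookup$grid))
  write.table(M, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
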