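#' Genomic-control inflation factor from intergenic SNPs
#'
#' Estimates the test-statistic inflation factor lambda_GC as the median of
#' z^2 over intergenic SNPs divided by the median of a 1-df chi-square
#' (0.4549364...).  Intergenic SNPs stand in for a null set, so polygenic
#' signal in genic regions does not inflate the estimate.  By default the
#' estimate is clamped below at 1 (statistics are never inflated); the raw
#' value is always retained.
#'
#' @param z Per-SNP signed test statistics.
#' @param intergenic Logical mask of the same length.
#' @param min_intergenic Minimum intergenic count for a trusted estimate;
#'   fewer triggers a warning.
#' @param clamp Clamp the estimate below at 1 (default TRUE).
#' @return A `gc_result`: list with `lambda_gc` (possibly clamped),
#'   `lambda_raw`, `clamped`, `n_intergenic`.
#' @export
compute_lambda_gc <- function(z, intergenic, min_intergenic = 1000,
                              clamp = TRUE) {
  stopifnot(length(z) == length(intergenic))
  intergenic <- intergenic & !is.na(z)
  n <- sum(intergenic)
  if (n == 0L) {
    stop("no intergenic SNPs: supply an intergenic annotation or disable ",
         "genomic control")
  }
  if (n < min_intergenic) {
    warning("only ", n, " intergenic SNPs (< ", min_intergenic,
            "); lambda_GC estimate may be unreliable")
  }
  raw <- median(z[intergenic]^2) / qchisq(0.5, df = 1)
  clamped <- clamp && raw < 1
  if (clamped) cj_log("lambda_GC raw value ", signif(raw, 4), " clamped to 1")
  structure(list(lambda_gc = if (clamped) 1 else raw,
                 lambda_raw = raw, clamped = clamped, n_intergenic = n),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("lambda_GC = %.4f (raw %.4f%s) from %d intergenic SNPs\n",
              x$lambda_gc, x$lambda_raw,
              if (x$clamped) ", clamped" else "", x$n_intergenic))
  invisible(x)
}

#' Apply genomic-control correction to a panel
#'
#' Divides the chi-square statistics of one trait by `lambda_gc`, i.e.
#' rescales `z` by `1/sqrt(lambda_gc)` (sign preserved) and recomputes the
#' two-sided p-value from the corrected statistic.  Reported effect sizes
#' (`beta`, `se`) are left untouched.  The correction is recorded on the
#' panel and a second application is an error.
#'
#' @param panel A `merged_panel` or `trait_panel`.
#' @param gc A `gc_result` computed on the same trait.
#' @param trait For a merged panel, which trait (1 or 2) to correct.
#' @return The corrected panel (same class).
#' @export
apply_gc <- function(panel, gc, trait = 1L) {
  stopifnot(inherits(gc, "gc_result"))
  lam <- gc$lambda_gc
  if (inherits(panel, "merged_panel")) {
    trait <- as.integer(trait)
    stopifnot(trait %in% c(1L, 2L))
    done <- attr(panel, "gc_applied")
    if (done[trait]) stop("genomic control already applied to trait ", trait)
    zc <- paste0("z", trait); pc <- paste0("p", trait)
    panel[[zc]] <- panel[[zc]] / sqrt(lam)
    panel[[pc]] <- 2 * pnorm(-abs(panel[[zc]]))
    done[trait] <- TRUE
    attr(panel, "gc_applied") <- done
  } else {
    if (isTRUE(attr(panel, "gc_applied"))) {
      stop("genomic control already applied to this panel")
    }
    panel$z <- panel$z / sqrt(lam)
    panel$p <- 2 * pnorm(-abs(panel$z))
    attr(panel, "gc_applied") <- TRUE
  }
  attr(panel, "lambda_gc") <- c(attr(panel, "lambda_gc"), setNames(lam, trait))
  panel
}
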