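#' Default column mapping for summary-statistics files
#'
#' Maps internal field names to column headers of a tab-delimited GWAS
#' summary-statistics file.  Override individual entries via the
#' `column_map` argument of [read_sumstats()].
#'
#' @return Named character vector (field name -> column header).
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chr = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    beta = "BETA", se = "SE", p = "P", z = "Z", intergenic = "INTERGENIC")
}

new_trait_panel <- function(df, trait_name, n_cases = NA_integer_,
                            n_controls = NA_integer_, rejected = list()) {
  rownames(df) <- NULL
  structure(df,
            class = c("trait_panel", "data.frame"),
            trait_name = trait_name,
            n_cases = n_cases, n_controls = n_controls,
            rejected = rejected)
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-delimited file of per-SNP summary statistics, validates each
#' record, and returns a trait panel.  At least one of `p`, `z`, or the pair
#' `(beta, se)` must be mapped; missing `z` is reconstructed as
#' `sign(beta) * qnorm(1 - p/2)` (unsigned if no `beta`), and missing `p` as
#' `2 * pnorm(-|z|)`.
#'
#' Records are rejected (counted, and reported when
#' `options(conjfdr.verbose = TRUE)`) when: `p` is outside `(0, 1]`; the
#' alleles are not distinct A/C/G/T bases; `pos < 1`; the `snp_id` duplicates
#' an earlier row; or, when `beta`, `se` and `p` are all present, the z-score
#' implied by `|beta/se|` disagrees with the z-score implied by `p` by more
#' than `p_z_tol * max(z_p, 1)`.  The z-scale check tolerates the rounding of
#' published effect sizes, which at small p would fail any p-scale relative
#' check.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector overriding [default_column_map()]
#'   entries.
#' @param trait_name Label for the trait.
#' @param n_cases,n_controls Optional participant counts (metadata only).
#' @param p_z_tol Relative tolerance of the beta/se vs p consistency check on
#'   the z scale.
#' @return A `trait_panel`: a data frame with columns `snp_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `z`, `p`, `intergenic`,
#'   and attributes `trait_name` and `rejected` (named rejection counts).
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = "trait",
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          p_z_tol = 0.05) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  mandatory <- c("snp_id", "chr", "pos", "effect_allele", "other_allele")
  for (f in mandatory) {
    if (!cmap[[f]] %in% names(raw)) {
      stop("configuration error: mandatory column '", cmap[[f]],
           "' (field ", f, ") not present in ", path)
    }
  }
  have <- vapply(cmap, function(col) col %in% names(raw), logical(1))
  if (!have[["p"]] && !have[["z"]] && !(have[["beta"]] && have[["se"]])) {
    stop("configuration error: need at least one of p, z, or (beta, se) mapped")
  }
  if (nrow(raw) == 0L) stop("empty panel: ", path, " contains no data rows")

  getcol <- function(f, as = as.numeric) {
    if (have[[f]]) as(raw[[cmap[[f]]]]) else rep(as(NA), nrow(raw))
  }
  df <- data.frame(
    snp_id = as.character(raw[[cmap[["snp_id"]]]]),
    chr = as.character(raw[[cmap[["chr"]]]]),
    pos = as.integer(raw[[cmap[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[cmap[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[cmap[["other_allele"]]]])),
    beta = getcol("beta"), se = getcol("se"),
    z = getcol("z"), p = getcol("p"),
    intergenic = getcol("intergenic", as = as.logical),
    stringsAsFactors = FALSE
  )

  rejected <- list()
  keep <- rep(TRUE, nrow(df))
  flag <- function(bad, why) {
    bad <- bad & keep
    if (any(bad)) {
      rejected[[why]] <<- sum(bad)
      keep[bad] <<- FALSE
    }
  }
  bases <- c("A", "C", "G", "T")
  flag(!is.na(df$p) & !(df$p > 0 & df$p <= 1), "p outside (0,1]")
  flag(is.na(df$p) & !have[["z"]] & !(have[["beta"]] && have[["se"]]), "no statistic")
  flag(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases) |
         df$effect_allele == df$other_allele, "invalid alleles")
  flag(is.na(df$pos) | df$pos < 1L, "position < 1")
  flag(duplicated(df$snp_id), "duplicate snp_id")
  chk <- !is.na(df$beta) & !is.na(df$se) & df$se > 0 & !is.na(df$p)
  if (any(chk)) {
    z_bs <- abs(df$beta[chk] / df$se[chk])
    z_p <- qnorm(1 - df$p[chk] / 2)
    bad <- rep(FALSE, nrow(df))
    bad[chk] <- abs(z_bs - z_p) > p_z_tol * pmax(z_p, 1)
    flag(bad, "beta/se inconsistent with p")
  }
  if (length(rejected)) {
    cj_log("read_sumstats(", trait_name, "): rejected ",
           sum(unlist(rejected)), " rows [",
           paste(names(rejected), unlist(rejected), sep = "=", collapse = ", "), "]")
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty panel: all rows of ", path, " were rejected")

  # fill in missing statistics
  miss_p <- is.na(df$p) & !is.na(df$z)
  df$p[miss_p] <- 2 * pnorm(-abs(df$z[miss_p]))
  miss_z <- is.na(df$z) & !is.na(df$p)
  zmag <- qnorm(1 - df$p[miss_z] / 2)
  sgn <- sign(df$beta[miss_z])
  sgn[is.na(sgn) | sgn == 0] <- 1
  df$z[miss_z] <- sgn * zmag
  if (!have[["intergenic"]]) df$intergenic <- NA
  df$intergenic[is.na(df$intergenic)] <- FALSE

  new_trait_panel(df, trait_name, n_cases, n_controls, rejected)
}

#' Write a trait panel to a tab-delimited file
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces `p`, `beta` and `se` exactly.
#'
#' @param panel A `trait_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(panel, path) {
  out <- data.frame(
    SNP = panel$snp_id, CHR = panel$chr, BP = panel$pos,
    A1 = panel$effect_allele, A2 = panel$other_allele,
    BETA = sprintf("%.17g", panel$beta), SE = sprintf("%.17g", panel$se),
    Z = sprintf("%.17g", panel$z), P = sprintf("%.17g", panel$p),
    INTERGENIC = panel$intergenic,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge two trait panels onto a shared, allele-harmonized SNP set
#'
#' Intersects the two panels by `snp_id` and puts both traits' statistics on
#' a single effect allele per SNP (the first panel's).  Where the second
#' panel's effect/other alleles are swapped relative to the first, its `z`
#' and `beta` signs are flipped; where the allele pair is the reverse
#' complement, the strand is flipped first.  Strand-ambiguous SNPs (A/T or
#' C/G pairs in either panel) and SNPs whose allele pairs cannot be
#' reconciled are dropped.  All actions are counted in the
#' `"harmonization"` attribute.
#'
#' @param panel_a,panel_b Trait panels from [read_sumstats()] or
#'   [simulate_two_traits()].
#' @return A `merged_panel`: data frame with shared `snp_id`, `chr`, `pos`,
#'   `intergenic` (TRUE only when flagged in both panels), the common
#'   `effect_allele`/`other_allele`, and per-trait `beta1/se1/z1/p1`,
#'   `beta2/se2/z2/p2`.
#' @export
harmonize_panels <- function(panel_a, panel_b) {
  if (nrow(panel_a) == 0L || nrow(panel_b) == 0L) stop("empty input panel")
  common <- intersect(panel_a$snp_id, panel_b$snp_id)
  if (length(common) == 0L) stop("empty intersection: no shared SNP ids")
  ia <- match(common, panel_a$snp_id)
  ib <- match(common, panel_b$snp_id)
  a1 <- panel_a$effect_allele[ia]; a2 <- panel_a$other_allele[ia]
  b1 <- panel_b$effect_allele[ib]; b2 <- panel_b$other_allele[ib]

  ambiguous <- (a1 == REVCOMP[a2]) | (b1 == REVCOMP[b2])
  same <- b1 == a1 & b2 == a2
  swapped <- b1 == a2 & b2 == a1
  rc_same <- REVCOMP[b1] == a1 & REVCOMP[b2] == a2
  rc_swapped <- REVCOMP[b1] == a2 & REVCOMP[b2] == a1
  flip <- (swapped | rc_swapped) & !ambiguous
  ok <- (same | swapped | rc_same | rc_swapped) & !ambiguous

  counts <- c(shared = length(common),
              kept = sum(ok),
              sign_flipped = sum(flip),
              strand_flipped = sum((rc_same | rc_swapped) & !ambiguous),
              ambiguous_dropped = sum(ambiguous),
              mismatch_dropped = sum(!ok & !ambiguous))
  cj_log("harmonize_panels: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  if (!any(ok)) stop("empty intersection after allele harmonization")

  ia <- ia[ok]; ib <- ib[ok]; flip <- flip[ok]
  sgn <- ifelse(flip, -1, 1)
  merged <- data.frame(
    snp_id = panel_a$snp_id[ia],
    chr = panel_a$chr[ia], pos = panel_a$pos[ia],
    intergenic = panel_a$intergenic[ia] & panel_b$intergenic[ib],
    effect_allele = panel_a$effect_allele[ia],
    other_allele = panel_a$other_allele[ia],
    beta1 = panel_a$beta[ia], se1 = panel_a$se[ia],
    z1 = panel_a$z[ia], p1 = panel_a$p[ia],
    beta2 = sgn * panel_b$beta[ib], se2 = panel_b$se[ib],
    z2 = sgn * panel_b$z[ib], p2 = panel_b$p[ib],
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  structure(merged,
            class = c("merged_panel", "data.frame"),
            trait_names = c(attr(panel_a, "trait_name") %||% "trait1",
                            attr(panel_b, "trait_name") %||% "trait2"),
            harmonization = counts,
            gc_applied = c(FALSE, FALSE))
}

#' Read a pairwise LD table
#'
#' Accepts a whitespace-delimited table with columns `SNP_A`, `SNP_B`, `R2`
#' (PLINK `.ld` style; extra columns such as `CHR_A`/`BP_A` are ignored when
#' a header names the three needed ones) or a headerless three-column file.
#' Symmetric duplicates are collapsed; self pairs are dropped (r² of a SNP
#' with itself is treated as 1 implicitly); pairs with r² outside \[0, 1\]
#' are rejected and counted.  Absent pairs mean r² = 0.
#'
#' @param path Path to the LD file.
#' @param window Maximum pair distance in base pairs that the table is
#'   understood to cover (metadata; default 1 Mb).
#' @return An `ld_matrix`: data frame `snp_a`, `snp_b`, `r2` with attribute
#'   `window`.
#' @export
read_ld <- function(path, window = 1e6) {
  if (!file.exists(path)) stop("LD file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("SNP_A", first, fixed = TRUE)
  if (length(first) == 0L || (!has_header && !nzchar(trimws(first)))) {
    return(new_ld_matrix(character(0), character(0), numeric(0), window))
  }
  raw <- tryCatch(
    read.table(path, header = has_header, stringsAsFactors = FALSE),
    error = function(e) stop("LD parse error in ", path, ": ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) {
    return(new_ld_matrix(character(0), character(0), numeric(0), window))
  }
  if (has_header) {
    need <- c("SNP_A", "SNP_B", "R2")
    if (!all(need %in% names(raw))) stop("LD header must name SNP_A, SNP_B, R2")
    a <- as.character(raw$SNP_A); b <- as.character(raw$SNP_B)
    r2 <- raw$R2
  } else {
    if (ncol(raw) < 3L) stop("LD file needs three columns: SNP_A SNP_B R2")
    a <- as.character(raw[[1]]); b <- as.character(raw[[2]]); r2 <- raw[[3]]
  }
  if (!is.numeric(r2)) {
    bad <- which(is.na(suppressWarnings(as.numeric(r2))))[1]
    stop("LD parse error: non-numeric r2 at data line ", bad)
  }
  bad <- is.na(r2) | r2 < 0 | r2 > 1
  if (any(bad)) {
    cj_log("read_ld: rejected ", sum(bad), " pairs with r2 outside [0,1]")
    a <- a[!bad]; b <- b[!bad]; r2 <- r2[!bad]
  }
  self <- a == b
  a <- a[!self]; b <- b[!self]; r2 <- r2[!self]
  # canonical order, drop symmetric duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  new_ld_matrix(lo[!dup], hi[!dup], r2[!dup], window)
}

new_ld_matrix <- function(snp_a, snp_b, r2, window = 1e6) {
  structure(data.frame(snp_a = snp_a, snp_b = snp_b, r2 = r2,
                       stringsAsFactors = FALSE),
            class = c("ld_matrix", "data.frame"),
            window = window)
}

#' Write an LD table in PLINK-like layout
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  out <- data.frame(SNP_A = ld$snp_a, SNP_B = ld$snp_b,
                    R2 = sprintf("%.17g", ld$r2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up pairwise r2 values from an LD table
#'
#' @param ld An `ld_matrix`.
#' @param snp_a,snp_b Equal-length SNP id vectors.
#' @return Numeric vector of r² values (1 on the diagonal, 0 for absent pairs).
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  lo <- pmin(snp_a, snp_b); hi <- pmax(snp_a, snp_b)
  key <- paste(lo, hi, sep = "\r")
  tab <- paste(ld$snp_a, ld$snp_b, sep = "\r")
  out <- ld$r2[match(key, tab)]
  out[is.na(out)] <- 0
  out[snp_a == snp_b] <- 1
  out
}

# Adjacency lists (by row index into `snp_ids`) for pairs above a threshold.
# Optionally restricted to pairs on the same chromosome within max_dist bp.
ld_adjacency <- function(ld, snp_ids, r2_threshold = 0.1,
                         chr = NULL, pos = NULL, max_dist = NULL) {
  i <- match(ld$snp_a, snp_ids)
  j <- match(ld$snp_b, snp_ids)
  keep <- !is.na(i) & !is.na(j) & ld$r2 > r2_threshold
  i <- i[keep]; j <- j[keep]
  if (!is.null(max_dist) && length(i)) {
    ok <- chr[i] == chr[j] & abs(pos[i] - pos[j]) <= max_dist
    i <- i[ok]; j <- j[ok]
  }
  adj <- vector("list", length(snp_ids))
  if (length(i)) {
    sp <- split(c(j, i), c(i, j))
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

#' Write a Table-style locus report
#'
#' One tab-delimited row per clumped locus, in the layout of a published
#' shared-risk-locus table: locus rank, index SNP, chromosome, position,
#' nearest gene, effect allele, per-trait "beta (SE)" and p-value, the
#' conjunctional FDR, and the member-SNP count.  Unavailable values are
#' written as `"na"`.
#'
#' @param loci A `locus_table` from [clump()].
#' @param path Output path.
#' @param trait_names Length-2 labels used in the header (defaults to the
#'   names stored on `loci`).
#' @return `path`, invisibly.
#' @export
write_locus_report <- function(loci, path,
                               trait_names = attr(loci, "trait_names")) {
  tn <- trait_names %||% c("trait1", "trait2")
  fmt_beta <- function(b, s) {
    ifelse(is.na(b) | is.na(s), "na", sprintf("%.3g (%.3g)", b, s))
  }
  fmt_num <- function(x, fmt = "%.3g") ifelse(is.na(x), "na", sprintf(fmt, x))
  header <- c("Locus", "Index SNP", "Chr", "Position", "Nearest Gene",
              "Effect allele",
              paste(tn[1], "beta (SE)"), paste(tn[1], "P-value"),
              paste(tn[2], "beta (SE)"), paste(tn[2], "P-value"),
              "Conjunctional FDR", "Members")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(loci)) {
    rows <- data.frame(
      paste0("Locus ", loci$locus),
      loci$index_snp, loci$chr, loci$pos,
      ifelse(is.na(loci$nearest_gene), "na", loci$nearest_gene),
      ifelse(is.na(loci$effect_allele), "na", loci$effect_allele),
      fmt_beta(loci$beta1, loci$se1), fmt_num(loci$p1),
      fmt_beta(loci$beta2, loci$se2), fmt_num(loci$p2),
      fmt_num(loci$conjfdr), loci$n_members,
      stringsAsFactors = FALSE
    )
    writeLines(do.call(paste, c(rows, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a 4-column BED file of gene intervals
#'
#' BED coordinates (0-based, half-open) are converted to 1-based closed
#' intervals internally.
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return Data frame `chr`, `start`, `end`, `name` (1-based closed).
#' @export
read_bed <- function(path) {
  raw <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("BED parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (ncol(raw) < 4L) stop("BED parse error: need 4 columns (chrom start end name)")
  if (!is.numeric(raw[[2]]) || !is.numeric(raw[[3]])) {
    stop("BED parse error: start/end must be numeric")
  }
  data.frame(chr = as.character(raw[[1]]),
             start = as.integer(raw[[2]]) + 1L,
             end = as.integer(raw[[3]]),
             name = as.character(raw[[4]]),
             stringsAsFactors = FALSE)
}
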