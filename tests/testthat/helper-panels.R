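# Small hand-built fixtures used across test files.

tiny_panel <- function(snp_id, p = NULL, z = NULL, beta = NA_real_,
                       se = NA_real_, chr = "1",
                       pos = seq_along(snp_id) * 1000L,
                       a1 = "A", a2 = "G", intergenic = FALSE,
                       trait_name = "trait") {
  n <- length(snp_id)
  if (is.null(z) && !is.null(p)) z <- qnorm(1 - p / 2)
  if (is.null(p) && !is.null(z)) p <- 2 * pnorm(-abs(z))
  df <- data.frame(snp_id = snp_id, chr = rep_len(chr, n),
                   pos = as.integer(rep_len(pos, n)),
                   effect_allele = rep_len(a1, n),
                   other_allele = rep_len(a2, n),
                   beta = rep_len(beta, n), se = rep_len(se, n),
                   z = z, p = p, intergenic = rep_len(intergenic, n),
                   stringsAsFactors = FALSE)
  conjfdr:::new_trait_panel(df, trait_name)
}

tiny_ld <- function(snp_a = character(0), snp_b = character(0),
                    r2 = numeric(0)) {
  conjfdr:::new_ld_matrix(snp_a, snp_b, r2)
}

tiny_merged <- function(p1, p2, snp_id = sprintf("s%03d", seq_along(p1)),
                        pos = seq_along(p1) * 1000L, chr = "1") {
  a <- tiny_panel(snp_id, p = p1, pos = pos, chr = chr, trait_name = "t1")
  b <- tiny_panel(snp_id, p = p2, pos = pos, chr = chr, trait_name = "t2")
  harmonize_panels(a, b)
}

write_sumstats_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
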