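test_that("read_sumstats accepts published-style rows and reconstructs z", {
  path <- write_sumstats_text(c(
    "SNP\tCHR\tBP\tA1\tA2\tBETA\tSE\tP",
    "rs9349379\t6\t13011943\tA\tG\t0.073\t0.014\t6.44E-08",
    "rs733701\t6\t39279840\tT\tC\t-0.058\t0.014\t2.24E-05"
  ))
  panel <- read_sumstats(path, trait_name = "mig")
  expect_s3_class(panel, "trait_panel")
  expect_equal(nrow(panel), 2L)
  expect_equal(panel$p[1], 6.44e-8)
  expect_gt(panel$z[1], 0)     # sign taken from beta
  expect_lt(panel$z[2], 0)
  expect_equal(abs(panel$z[1]), qnorm(1 - 6.44e-8 / 2))
})

test_that("read_sumstats rejects invalid records with counts and errors on empty panels", {
  header <- "SNP\tCHR\tBP\tA1\tA2\tBETA\tSE\tP"
  expect_error(read_sumstats(write_sumstats_text(header)), "empty panel")

  path <- write_sumstats_text(c(
    header,
    "rs1\t1\t100\tA\tG\t0.1\t0.05\t0.0455",   # consistent (z = 2)
    "rs2\t1\t200\tA\tG\t0.1\t0.05\t0",        # p outside (0,1]
    "rs3\t1\t300\tA\tA\t0.1\t0.05\t0.5",      # identical alleles
    "rs4\t1\t400\tA\tG\t0.5\t0.05\t0.5",      # beta/se wildly inconsistent with p
    "rs1\t1\t500\tA\tG\t0.1\t0.05\t0.0455"    # duplicate id
  ))
  panel <- read_sumstats(path)
  expect_equal(panel$snp_id, "rs1")
  rej <- attr(panel, "rejected")
  expect_equal(sum(unlist(rej)), 4L)
  expect_true("p outside (0,1]" %in% names(rej))

  allbad <- write_sumstats_text(c(header, "rs1\t1\t100\tA\tG\t0.1\t0.05\t0"))
  expect_error(read_sumstats(allbad), "empty panel")
})

test_that("read_sumstats flags configuration errors", {
  path <- write_sumstats_text(c("ID\tCHR\tBP\tA1\tA2\tP", "rs1\t1\t100\tA\tG\t0.5"))
  expect_error(read_sumstats(path), "configuration error")
  path2 <- write_sumstats_text(c("SNP\tCHR\tBP\tA1\tA2", "rs1\t1\t100\tA\tG"))
  expect_error(read_sumstats(path2), "configuration error")
  # custom column map resolves the first case
  panel <- read_sumstats(path, column_map = c(snp_id = "ID"))
  expect_equal(panel$snp_id, "rs1")
})

test_that("write/read round trip reproduces p, beta, se exactly", {
  set.seed(1)
  z <- rnorm(50)
  panel <- tiny_panel(sprintf("rs%d", 1:50), z = z, beta = z / 100, se = 0.01)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(panel, path)
  back <- read_sumstats(path, trait_name = "trait")
  expect_identical(back$p, panel$p)
  expect_identical(back$beta, panel$beta)
  expect_identical(back$se, panel$se)
  expect_identical(back$z, panel$z)
})

test_that("harmonization aligns alleles: identity, swap, strand flip, drops", {
  a <- tiny_panel(c("s1", "s2", "s3", "s4", "s5"), z = c(1, 2, 3, 4, 5),
                  beta = 0.1, se = NA_real_, trait_name = "t1")
  a$effect_allele <- c("A", "A", "A", "A", "A")
  a$other_allele  <- c("G", "G", "G", "T", "G")
  b <- a
  b$effect_allele <- c("A", "G", "T", "A", "A")
  b$other_allele  <- c("G", "A", "C", "T", "C")   # same, swapped, revcomp, ambiguous, mismatch
  b$z <- c(1, 2, 3, 4, 5)
  attr(b, "trait_name") <- "t2"

  merged <- harmonize_panels(a, b)
  expect_setequal(merged$snp_id, c("s1", "s2", "s3"))
  expect_equal(merged$z2[merged$snp_id == "s1"], 1)    # identity
  expect_equal(merged$z2[merged$snp_id == "s2"], -2)   # swapped -> sign flip
  expect_equal(merged$z2[merged$snp_id == "s3"], 3)    # reverse complement, same orientation
  counts <- attr(merged, "harmonization")
  expect_equal(unname(counts["ambiguous_dropped"]), 1)
  expect_equal(unname(counts["mismatch_dropped"]), 1)
  # harmonization changes only signs, never magnitudes
  expect_equal(abs(merged$z2), abs(b$z[match(merged$snp_id, b$snp_id)]))
})

test_that("harmonization is idempotent", {
  a <- tiny_panel(c("s1", "s2"), z = c(1.5, -2.5), trait_name = "t1")
  b <- tiny_panel(c("s1", "s2"), z = c(0.5, 1.2), trait_name = "t2")
  b$effect_allele <- c("G", "A"); b$other_allele <- c("A", "G")
  m1 <- harmonize_panels(a, b)
  # rebuild trait panels from the harmonized result and merge again
  b2 <- tiny_panel(m1$snp_id, z = m1$z2, trait_name = "t2")
  m2 <- harmonize_panels(a, b2)
  expect_equal(m2$z2, m1$z2)
  expect_equal(m2$z1, m1$z1)
})

test_that("harmonize_panels errors on empty intersection", {
  a <- tiny_panel("s1", z = 1)
  b <- tiny_panel("s2", z = 1)
  expect_error(harmonize_panels(a, b), "empty intersection")
})

test_that("read_ld deduplicates symmetric pairs and rejects bad r2", {
  path <- write_sumstats_text(c("a\tb\t0.5", "b\ta\t0.5", "c\td\t1.3"))
  ld <- read_ld(path)
  expect_equal(nrow(ld), 1L)
  expect_equal(ld_r2(ld, "a", "b"), 0.5)
  expect_equal(ld_r2(ld, "b", "a"), 0.5)   # symmetric lookup
  expect_equal(ld_r2(ld, "a", "a"), 1)     # diagonal
  expect_equal(ld_r2(ld, "a", "zz"), 0)    # absent pair

  empty <- write_sumstats_text(character(0))
  expect_equal(nrow(read_ld(empty)), 0L)

  plink <- write_sumstats_text(c("CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2",
                                 "1 100 a 1 200 b 0.25"))
  expect_equal(read_ld(plink)$r2, 0.25)
})

test_that("locus report mirrors the published table layout", {
  merged <- tiny_merged(p1 = c(1e-8, 0.5), p2 = c(1e-6, 0.5))
  lt <- clump(c(0.001, 0.9), tiny_ld(), merged)

  path <- tempfile()
  write_locus_report(lt[0, ], path)
  expect_equal(length(readLines(path)), 1L)        # header only

  write_locus_report(lt[1, ], path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "Conjunctional FDR")

  lt$beta1[1] <- NA
  write_locus_report(lt, path)
  expect_match(readLines(path)[2], "\tna\t")       # missing values written as na
})

test_that("read_bed converts to 1-based closed coordinates", {
  path <- write_sumstats_text(c("1\t999\t2000\tGENE1", "2\t0\t100\tGENE2"))
  bed <- read_bed(path)
  expect_equal(bed$start, c(1000L, 1L))
  expect_equal(bed$end, c(2000L, 100L))
  expect_error(read_bed(write_sumstats_text("1\t10\t20")), "BED parse error")
})
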