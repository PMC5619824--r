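test_that("random pruning keeps one uniform representative per LD block", {
  merged <- tiny_merged(p1 = rep(0.5, 3), p2 = rep(0.5, 3),
                        snp_id = c("A", "B", "C"))
  ld <- tiny_ld("A", "B", 0.5)
  sets <- random_prune(merged, ld, n_sets = 100, seed = 1)
  expect_length(sets, 100L)
  sizes <- lengths(sets)
  expect_true(all(sizes == 2L))
  c_idx <- which(merged$snp_id == "C")
  expect_true(all(vapply(sets, function(s) c_idx %in% s, logical(1))))
  reps <- vapply(sets, function(s) merged$snp_id[setdiff(s, c_idx)], character(1))
  expect_setequal(unique(reps), c("A", "B"))
  # uniform within binomial tolerance (4 sd around 50/100)
  expect_gt(sum(reps == "A"), 30)
  expect_lt(sum(reps == "A"), 70)
})

test_that("pruning respects independence, the distance window, and the seed", {
  merged <- tiny_merged(p1 = rep(0.5, 4), p2 = rep(0.5, 4),
                        snp_id = c("A", "B", "C", "D"),
                        pos = c(1e6, 1.5e6, 8e6, 9e6))
  # all r2 <= threshold: every subset is the full panel
  sets <- random_prune(merged, tiny_ld("A", "B", 0.05), n_sets = 5, seed = 2)
  expect_true(all(vapply(sets, identical, logical(1), 1:4)))

  # r2 > 0.1 but 7 Mb apart: no edge
  far <- random_prune(merged, tiny_ld("B", "C", 0.9), n_sets = 3, seed = 2)
  expect_true(all(lengths(far) == 4L))

  ld <- tiny_ld("A", "B", 0.5)
  expect_identical(random_prune(merged, ld, n_sets = 10, seed = 7),
                   random_prune(merged, ld, n_sets = 10, seed = 7))
  expect_equal(length(random_prune(merged, ld, seed = 1)), 100L)  # default
})

test_that("greedy clumping assigns members to the best-ranked index SNP", {
  merged <- tiny_merged(p1 = c(1e-4, 1e-3, 1e-3), p2 = c(1e-4, 1e-3, 1e-3),
                        snp_id = c("A", "B", "C"))
  ld <- tiny_ld("A", "B", 0.5)
  lt <- clump(c(0.001, 0.01, 0.02), ld, merged)
  expect_equal(lt$index_snp, c("A", "C"))
  expect_equal(attr(lt, "members")[["A"]], "B")
  expect_equal(lt$n_members, c(1L, 0L))

  # everything mutually below threshold: every SNP its own locus
  solo <- clump(c(0.3, 0.2, 0.1), tiny_ld("A", "B", 0.05), merged)
  expect_equal(nrow(solo), 3L)

  # tie on conjFDR broken by the smaller trait-1 p
  tie <- clump(c(0.5, 0.5, 0.9), tiny_ld("A", "B", 0.5), merged)
  expect_equal(tie$index_snp[1], "A")
})

test_that("clumped index SNPs are pairwise independent and partition the panel", {
  cfg <- scenario_config("shared-concordant", m_snps = 2500, seed = 21,
                         n_shared = 5)
  sim <- simulate_two_traits(cfg)
  ld <- simulate_ld(cfg)
  merged <- harmonize_panels(sim$panel1, sim$panel2)
  conj <- compute_conjfdr(merged, ld, n_sets = 20, seed = 21)$conjfdr
  lt <- clump(conj, ld, merged)

  # every SNP is an index or a member of exactly one locus
  members <- attr(lt, "members")
  all_ids <- c(lt$index_snp, unlist(members, use.names = FALSE))
  expect_setequal(all_ids, merged$snp_id)
  expect_equal(length(all_ids), nrow(merged))

  # pairwise r2 between index SNPs <= 0.1, checked exhaustively
  idx <- lt$index_snp
  pairs <- t(combn(idx[1:min(60, length(idx))], 2))
  expect_true(all(ld_r2(ld, pairs[, 1], pairs[, 2]) <= 0.1))
})

test_that("significance calls use strict thresholds", {
  merged <- tiny_merged(p1 = rep(0.5, 3), p2 = rep(0.5, 3))
  lt <- clump(c(0.021, 0.065, 0.05), tiny_ld(), merged)
  lt <- call_significance(lt)
  expect_equal(lt$significant, c(TRUE, FALSE, FALSE))
  expect_equal(lt$suggestive, c(TRUE, TRUE, TRUE))
  expect_equal(lt$significant[lt$conjfdr == 0.05], FALSE)  # strict <
  expect_error(call_significance(lt, alpha = 0.1, suggestive = 0.1),
               "configuration error")
})

test_that("region exclusion removes the interval plus one step of LD partners", {
  merged <- tiny_merged(p1 = rep(0.5, 3), p2 = rep(0.5, 3),
                        snp_id = c("A", "B", "C"), pos = c(1000L, 2000L, 3000L))
  ld <- tiny_ld("A", "B", 0.5)
  out <- exclude_region(merged, "1", 900, 1100, ld)
  expect_equal(out$snp_id, "C")
  expect_equal(unname(attr(out, "excluded")), c(1L, 1L))

  # empty interval: unchanged
  same <- exclude_region(merged, "1", 5000, 6000, ld)
  expect_equal(same$snp_id, merged$snp_id)

  # idempotent
  twice <- exclude_region(out, "1", 900, 1100, ld)
  expect_equal(twice$snp_id, out$snp_id)

  expect_error(exclude_region(merged, "1", 1, 1e7, ld), "empties the panel")
  expect_error(exclude_region(merged, "1", 100, 50, ld), "malformed")
})

test_that("nearest-gene annotation uses containment, distance, and name ties", {
  merged <- tiny_merged(p1 = rep(0.5, 3), p2 = rep(0.5, 3),
                        snp_id = c("A", "B", "C"),
                        pos = c(1500L, 3000L, 100L), chr = c("1", "1", "2"))
  lt <- clump(c(0.01, 0.02, 0.03), tiny_ld(), merged)
  genes <- data.frame(chr = "1", start = c(1000L, 3500L, 2500L),
                      end = c(2000L, 4000L, 2600L),
                      name = c("GENE1", "AAA", "BBB"),
                      stringsAsFactors = FALSE)
  lt <- annotate_nearest_gene(lt, genes)
  expect_equal(lt$nearest_gene[lt$index_snp == "A"], "GENE1")  # containment
  # B at 3000 is 400 bp from BBB end and 500 bp from AAA: BBB wins on distance
  expect_equal(lt$nearest_gene[lt$index_snp == "B"], "BBB")
  expect_true(is.na(lt$nearest_gene[lt$index_snp == "C"]))     # no genes on chr 2

  # exact tie resolved lexicographically
  tie_genes <- data.frame(chr = "1", start = c(2500L, 3400L),
                          end = c(2600L, 3500L), name = c("ZZZ", "AAA"),
                          stringsAsFactors = FALSE)
  lt2 <- annotate_nearest_gene(lt, tie_genes)
  expect_equal(lt2$nearest_gene[lt2$index_snp == "B"], "AAA")
})
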