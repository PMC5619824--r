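test_that("exact conditional FDR estimator counts joint tails", {
  p1 <- c(0.01, 0.2, 0.5, 0.9)
  p2 <- c(0.02, 0.03, 0.6, 0.8)
  expect_equal(conditional_fdr_exact(0.01, 0.02, p1, p2), 0.01)  # 0.01 * 1/1
  # v = 1 conditions on nothing: reduces to p * M / rank
  expect_equal(conditional_fdr_exact(0.2, 1, p1, p2), 0.4)       # 0.2 * 4/2
  # cap at 1
  expect_equal(conditional_fdr_exact(0.9, 0.7, c(0.9, 0.95), c(0.5, 0.6)), 1)
  # empty joint tail returns 1 (no evidence)
  expect_equal(conditional_fdr_exact(0.001, 0.001, p1, p2), 1)
  expect_error(conditional_fdr_exact(0.5, 0.5, numeric(0), numeric(0)),
               "nonempty")
})

test_that("lookup nodes equal the brute-force estimator before the monotone pass", {
  set.seed(11)
  n <- 2000
  merged <- tiny_merged(p1 = runif(n), p2 = runif(n))
  grid <- cfdr_grid(31, 7.5)
  lk <- build_cfdr_lookup(merged, "1|2", grid = grid, monotone = FALSE)
  worst <- 0
  for (i in seq_along(grid)) {
    u <- 10^(-grid[i])
    for (j in seq_along(grid)) {
      v <- 10^(-grid[j])
      exact <- conditional_fdr_exact(u, v, merged$p1, merged$p2)
      got <- interpolate_cfdr(lk, u, v)
      worst <- max(worst, abs(got - exact))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the v = 1 column is the unconditional empirical FDR curve", {
  set.seed(12)
  merged <- tiny_merged(p1 = runif(500), p2 = runif(500))
  lk <- build_cfdr_lookup(merged, "1|2", monotone = FALSE)
  u <- 10^(-lk$grid)
  M <- nrow(merged)
  direct <- vapply(u, function(uu) {
    r <- sum(merged$p1 <= uu)
    if (r == 0) 1 else min(1, uu * M / r)
  }, numeric(1))
  expect_equal(lk$values[, 1], direct, tolerance = 0)
})

test_that("value-averaging over pruned sets is the mean of per-set tables", {
  set.seed(13)
  merged <- tiny_merged(p1 = runif(300), p2 = runif(300))
  s1 <- 1:150; s2 <- 151:300
  grid <- cfdr_grid(21, 7.5)
  v_both <- build_cfdr_lookup(merged, "1|2", grid, list(s1, s2),
                              monotone = FALSE, average = "values")
  va <- build_cfdr_lookup(merged, "1|2", grid, list(s1), monotone = FALSE)
  vb <- build_cfdr_lookup(merged, "1|2", grid, list(s2), monotone = FALSE)
  expect_equal(v_both$values, (va$values + vb$values) / 2)
})

test_that("bilinear interpolation: node identity, midpoint, edge clamping", {
  set.seed(14)
  merged <- tiny_merged(p1 = runif(400), p2 = runif(400))
  lk <- build_cfdr_lookup(merged, "1|2", cfdr_grid(16, 7.5))
  # exact node queries return node values
  i <- c(3L, 8L); j <- c(5L, 12L)
  got <- interpolate_cfdr(lk, 10^(-lk$grid[i]), 10^(-lk$grid[j]))
  expect_equal(as.numeric(got), lk$values[cbind(i, j)])

  # midpoint of four nodes valued 0.1, 0.1, 0.3, 0.3 -> 0.2
  hand <- structure(list(grid = c(0, 1),
                         values = matrix(c(0.1, 0.1, 0.3, 0.3), 2, 2),
                         direction = "1|2", n_sets = 1L, monotone = FALSE,
                         average = "counts"),
                    class = "cfdr_lookup")
  expect_equal(as.numeric(interpolate_cfdr(hand, 10^-0.5, 10^-0.5)), 0.2)

  # beyond-edge queries clamp and are flagged
  beyond <- interpolate_cfdr(lk, 1e-12, 0.5)
  at_edge <- interpolate_cfdr(lk, 10^(-max(lk$grid)), 0.5)
  expect_equal(as.numeric(beyond), as.numeric(at_edge))
  expect_true(attr(beyond, "clamped"))
  expect_false(attr(at_edge, "clamped"))
})

test_that("the monotone pass never increases a node value", {
  set.seed(15)
  merged <- tiny_merged(p1 = runif(500), p2 = runif(500))
  raw <- build_cfdr_lookup(merged, "1|2", cfdr_grid(31), monotone = FALSE)
  mono <- build_cfdr_lookup(merged, "1|2", cfdr_grid(31), monotone = TRUE)
  expect_true(all(mono$values <= raw$values + 1e-15))
  # nonincreasing along the primary axis within each column
  expect_true(all(apply(mono$values, 2, diff) <= 1e-15))
})

test_that("conjunction is the elementwise maximum and is symmetric", {
  expect_equal(conjunction(c(0.01, 0.5), c(0.04, 0.2)), c(0.04, 0.5))
  expect_equal(conjunction(c(0.04, 0.2), c(0.01, 0.5)), c(0.04, 0.5))
  x <- runif(10)
  expect_equal(conjunction(x, x), x)
  expect_error(conjunction(1, c(1, 2)), "length")
})

test_that("compute_conjfdr is deterministic and dominates both directions", {
  cfg <- scenario_config("shared-concordant", m_snps = 2000, seed = 3,
                         n_shared = 4)
  sim <- simulate_two_traits(cfg)
  ld <- simulate_ld(cfg)
  merged <- harmonize_panels(sim$panel1, sim$panel2)
  r1 <- compute_conjfdr(merged, ld, n_sets = 10, seed = 99)
  r2 <- compute_conjfdr(merged, ld, n_sets = 10, seed = 99)
  expect_identical(r1$conjfdr, r2$conjfdr)
  expect_true(all(r1$conjfdr >= r1$cfdr12 - 1e-15))
  expect_true(all(r1$conjfdr >= r1$cfdr21 - 1e-15))
  expect_true(all(r1$conjfdr > 0 & r1$conjfdr <= 1))
})

test_that("conjunctional FDR is invariant under trait relabeling", {
  cfg <- scenario_config("shared-concordant", m_snps = 2000, seed = 4,
                         n_shared = 4)
  sim <- simulate_two_traits(cfg)
  ld <- simulate_ld(cfg)
  m_ab <- harmonize_panels(sim$panel1, sim$panel2)
  m_ba <- harmonize_panels(sim$panel2, sim$panel1)
  r_ab <- compute_conjfdr(m_ab, ld, n_sets = 10, seed = 5)
  r_ba <- compute_conjfdr(m_ba, ld, n_sets = 10, seed = 5)
  expect_equal(r_ab$conjfdr, r_ba$conjfdr[match(r_ab$snp_id, r_ba$snp_id)])
})
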