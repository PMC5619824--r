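#' Configuration for the synthetic two-trait GWAS generator
#'
#' The generator works at the summary-statistic level: SNPs sit in
#' equal-sized LD blocks with AR(1) within-block correlation
#' (`cor(z_i, z_j) = ar1_rho^|i-j|`, hence `r2 = ar1_rho^(2|i-j|)`), causal
#' effects are planted per trait and shared between traits, and per-block
#' z-scores are drawn as `z = C %*% (sqrt(n) * gamma) + eps` with
#' `eps ~ MVN(0, C)` — so LD smears causal signal onto neighbouring SNPs the
#' same way it does in real GWAS.  Shared causal SNPs reuse the trait-1
#' effect in trait 2 with its sign flipped with probability
#' `1 - concordance`.  Test statistics can be artificially inflated
#' (`z^2` multiplied by `lambda`) for genomic-control testing.  Intergenic
#' flags are drawn only on non-causal SNPs so the intergenic set is an honest
#' null set.
#'
#' @param m_snps Number of SNPs; must be a multiple of `block_size`.
#' @param block_size SNPs per LD block (default 50).
#' @param ar1_rho Within-block AR(1) correlation decay in \[0, 1).
#' @param n1,n2 Effective sample sizes of the two traits.
#' @param pi1,pi2 Trait-specific causal fractions.
#' @param pi12 Shared causal fraction; shared causal SNPs are placed in
#'   distinct blocks (one per block).
#' @param concordance Probability that a shared effect has the same sign in
#'   both traits, in \[0, 1\].
#' @param effect_sd Causal effect scale on the per-allele (gamma) scale;
#'   `sqrt(n) * effect_sd` is the expected z-score magnitude of a causal SNP
#'   under `effect_dist = "fixed"`.
#' @param effect_dist `"normal"` (gamma ~ N(0, effect_sd^2)) or `"fixed"`
#'   (|gamma| = effect_sd, random sign).
#' @param lambda1,lambda2 Artificial inflation factors (>= 1).
#' @param intergenic_frac Probability a non-causal SNP is flagged intergenic.
#' @param shared_cluster Place all shared causal blocks contiguously in the
#'   middle of the chromosome (single-region design for exclusion
#'   re-analysis); default FALSE (scattered).
#' @param spacing_bp Base-pair spacing between adjacent SNPs (default 5 kb,
#'   so a 50-SNP block spans 245 kb, well under 1 Mb).
#' @param seed RNG seed; everything downstream is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_snps = 20000L, block_size = 50L, ar1_rho = 0.8,
                       n1 = 10000, n2 = 10000,
                       pi1 = 0, pi2 = 0, pi12 = 0, concordance = 1,
                       effect_sd = 0.06, effect_dist = c("normal", "fixed"),
                       lambda1 = 1, lambda2 = 1,
                       intergenic_frac = 0.5, shared_cluster = FALSE,
                       spacing_bp = 5000L, seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  if (m_snps %% block_size != 0L) stop("block_size must divide m_snps")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  fr <- c(pi1 = pi1, pi2 = pi2, pi12 = pi12, concordance = concordance,
          intergenic_frac = intergenic_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (pi1 + pi2 + pi12 > 1) stop("pi1 + pi2 + pi12 must not exceed 1")
  if (lambda1 < 1 || lambda2 < 1) stop("inflation factors must be >= 1")
  structure(list(m_snps = as.integer(m_snps),
                 block_size = as.integer(block_size),
                 ar1_rho = ar1_rho, n1 = n1, n2 = n2,
                 pi1 = pi1, pi2 = pi2, pi12 = pi12,
                 concordance = concordance, effect_sd = effect_sd,
                 effect_dist = effect_dist,
                 lambda1 = lambda1, lambda2 = lambda2,
                 intergenic_frac = intergenic_frac,
                 shared_cluster = shared_cluster,
                 spacing_bp = as.integer(spacing_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named simulation scenarios
#'
#' * `"null"` — no causal SNPs in either trait; calibration testing.
#' * `"shared-concordant"` — 20 shared causal loci (distinct blocks) with
#'   fixed-magnitude effects of expected |z| = 6 and the same sign in both
#'   traits.
#' * `"shared-discordant"` — the same loci with always-opposite signs
#'   (concordance 0), mirroring shared risk variants whose allele raises one
#'   trait's risk and lowers the other's.
#' * `"inflated"` — null with trait-1 statistics inflated by lambda = 1.5.
#'
#' @param scenario Scenario name.
#' @param m_snps,seed Passed through to [sim_config()].
#' @param n_shared Number of shared causal loci for the shared scenarios
#'   (default 20).
#' @param shared_z Expected |z| of shared causal SNPs (default 6).
#' @param ... Further overrides for [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario, m_snps = 20000L, seed = 1L,
                            n_shared = 20L, shared_z = 6, ...) {
  base <- list(m_snps = as.integer(m_snps), seed = as.integer(seed),
               block_size = 50L, ar1_rho = 0.8, n1 = 10000, n2 = 10000)
  extra <- switch(
    scenario,
    "null" = list(),
    "shared-concordant" = list(pi12 = n_shared / m_snps, concordance = 1,
                               effect_dist = "fixed",
                               effect_sd = shared_z / sqrt(10000)),
    "shared-discordant" = list(pi12 = n_shared / m_snps, concordance = 0,
                               effect_dist = "fixed",
                               effect_sd = shared_z / sqrt(10000)),
    "inflated" = list(lambda1 = 1.5),
    stop("unknown scenario '", scenario, "'; available: null, ",
         "shared-concordant, shared-discordant, inflated")
  )
  do.call(sim_config, modifyList(modifyList(base, extra), list(...)))
}

snp_ids <- function(m) sprintf("snp%06d", seq_len(m))

#' Pairwise LD table implied by a simulation configuration
#'
#' Within each block, `r2(i, j) = ar1_rho^(2|i-j|)`; across blocks r² is 0.
#' Pairs with r² below `min_r2` are not stored (absent pairs mean r² = 0).
#'
#' @param config A `sim_config`.
#' @param min_r2 Sparse-storage floor (default 0.01).
#' @return An `ld_matrix`.
#' @export
simulate_ld <- function(config, min_r2 = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_snps; bs <- config$block_size; rho <- config$ar1_rho
  ids <- snp_ids(m)
  if (rho == 0) return(new_ld_matrix(character(0), character(0), numeric(0)))
  dmax <- min(bs - 1L, floor(log(min_r2) / (2 * log(rho))))
  if (dmax < 1L) return(new_ld_matrix(character(0), character(0), numeric(0)))
  offset_in_block <- (seq_len(m) - 1L) %% bs
  pieces <- lapply(seq_len(dmax), function(d) {
    i <- which(offset_in_block < bs - d)
    data.frame(snp_a = ids[i], snp_b = ids[i + d],
               r2 = rho^(2 * d), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  new_ld_matrix(all$snp_a, all$snp_b, all$r2)
}

#' Simulate two-trait GWAS summary statistics with ground truth
#'
#' See [sim_config()] for the data model.  Returns two trait panels whose
#' allele pairs agree (no harmonization churn by construction) and a ground
#' truth table for parameter-recovery testing.
#'
#' @param config A `sim_config`.
#' @return List with `panel1`, `panel2` (trait panels) and `truth` (data
#'   frame `snp_id`, `block`, `causal1`, `causal2`, `shared`, `gamma1`,
#'   `gamma2`).
#' @export
simulate_two_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_snps; bs <- config$block_size; nb <- m %/% bs
  k12 <- round(config$pi12 * m)
  k1 <- round(config$pi1 * m)
  k2 <- round(config$pi2 * m)
  if (k12 > nb) stop("more shared causal SNPs than blocks")

  with_seed(config$seed, {
    draw_eff <- function(k) {
      if (k == 0L) return(numeric(0))
      if (config$effect_dist == "fixed") {
        config$effect_sd * sample(c(-1, 1), k, replace = TRUE)
      } else {
        rnorm(k, 0, config$effect_sd)
      }
    }
    shared_idx <- integer(0)
    if (k12 > 0L) {
      sb <- if (config$shared_cluster) {
        seq(max(1L, nb %/% 2L - k12 %/% 2L), length.out = k12)
      } else {
        sort(sample.int(nb, k12))
      }
      shared_idx <- (sb - 1L) * bs + sample.int(bs, k12, replace = TRUE)
    }
    avail <- setdiff(seq_len(m), shared_idx)
    s1 <- sort(sample(avail, k1))
    s2 <- sort(sample(setdiff(avail, s1), k2))

    g1 <- numeric(m); g2 <- numeric(m)
    if (k12 > 0L) {
      base <- draw_eff(k12)
      g1[shared_idx] <- base
      sgn <- ifelse(runif(k12) < config$concordance, 1, -1)
      g2[shared_idx] <- base * sgn
    }
    g1[s1] <- draw_eff(k1)
    g2[s2] <- draw_eff(k2)

    # per-block z = C (sqrt(n) gamma) + eps, eps ~ MVN(0, C); same C everywhere
    C <- config$ar1_rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
    L <- t(chol(C))
    zmat <- function(g, n, lambda) {
      G <- matrix(g, bs, nb)
      signal <- C %*% (sqrt(n) * G)
      eps <- L %*% matrix(rnorm(m), bs, nb)
      as.vector(signal + eps) * sqrt(lambda)
    }
    z1 <- zmat(g1, config$n1, config$lambda1)
    z2 <- zmat(g2, config$n2, config$lambda2)

    causal_any <- g1 != 0 | g2 != 0
    intergenic <- rep(FALSE, m)
    nc <- which(!causal_any)
    intergenic[nc] <- runif(length(nc)) < config$intergenic_frac

    allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    ap <- allele_pairs[sample.int(4L, m, replace = TRUE)]

    ids <- snp_ids(m)
    mk_panel <- function(z, n, trait_name) {
      p <- pmax(2 * pnorm(-abs(z)), 1e-300)
      df <- data.frame(
        snp_id = ids, chr = "1",
        pos = 1L + (seq_len(m) - 1L) * config$spacing_bp,
        effect_allele = vapply(ap, `[`, character(1), 1L),
        other_allele = vapply(ap, `[`, character(1), 2L),
        beta = z / sqrt(n), se = 1 / sqrt(n), z = z, p = p,
        intergenic = intergenic, stringsAsFactors = FALSE
      )
      new_trait_panel(df, trait_name)
    }
    truth <- data.frame(snp_id = ids, block = rep(seq_len(nb), each = bs),
                        causal1 = g1 != 0, causal2 = g2 != 0,
                        shared = seq_len(m) %in% shared_idx,
                        gamma1 = g1, gamma2 = g2, stringsAsFactors = FALSE)
    list(panel1 = mk_panel(z1, config$n1, "trait1"),
         panel2 = mk_panel(z2, config$n2, "trait2"),
         truth = truth)
  })
}

#' Write a named simulation scenario to disk
#'
#' Produces the standard file bundle for a scenario: two summary-statistics
#' files, an LD table, the ground-truth table and the configuration as YAML.
#' Byte-identical across repeated calls with the same name and seed.
#'
#' @param name Scenario name, see [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param m_snps,seed,... Passed to [scenario_config()].
#' @return Named character vector of the file paths, invisibly.
#' @export
make_fixture <- function(name, dir, m_snps = 20000L, seed = 1L, ...) {
  config <- scenario_config(name, m_snps = m_snps, seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_traits(config)
  ld <- simulate_ld(config)
  paths <- c(trait1 = file.path(dir, "trait1.tsv"),
             trait2 = file.path(dir, "trait2.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  write_sumstats(sim$panel1, paths[["trait1"]])
  write_sumstats(sim$panel2, paths[["trait2"]])
  write_ld(ld, paths[["ld"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- unclass(config)
  cfg$scenario <- name
  writeLines(yaml::as.yaml(cfg), paths[["config"]])
  invisible(paths)
}
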