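#' Random LD pruning into near-independent SNP sets
#'
#' LD blocks are the connected components of the graph whose edges join SNPs
#' with pairwise r² above `r2_threshold` within `max_dist` base pairs on the
#' same chromosome.  Each pruned set keeps exactly one uniformly chosen
#' representative per block, so repeated sets explore the LD structure while
#' staying near-independent within each set.  Deterministic given `seed`.
#'
#' @param merged A `merged_panel` (or any data frame with `snp_id`, `chr`,
#'   `pos`).
#' @param ld An `ld_matrix`.
#' @param n_sets Number of sets (default 100).
#' @param seed RNG seed.
#' @param r2_threshold Block edge threshold (default 0.1).
#' @param max_dist Maximum edge distance in bp (default 1 Mb).
#' @return List of `n_sets` sorted integer vectors of row indices into
#'   `merged`; attributes `blocks` (list of block row indices) and `seed`.
#' @export
random_prune <- function(merged, ld, n_sets = 100L, seed = 1L,
                         r2_threshold = 0.1, max_dist = 1e6) {
  stopifnot(n_sets >= 1L)
  m <- nrow(merged)
  i <- match(ld$snp_a, merged$snp_id)
  j <- match(ld$snp_b, merged$snp_id)
  keep <- !is.na(i) & !is.na(j) & ld$r2 > r2_threshold
  i <- i[keep]; j <- j[keep]
  if (length(i)) {
    ok <- merged$chr[i] == merged$chr[j] &
      abs(merged$pos[i] - merged$pos[j]) <= max_dist
    i <- i[ok]; j <- j[ok]
  }
  if (length(i)) {
    g <- igraph::make_empty_graph(n = m, directed = FALSE)
    g <- igraph::add_edges(g, rbind(i, j))
    membership <- igraph::components(g)$membership
  } else {
    membership <- seq_len(m)
  }
  blocks <- split(seq_len(m), membership)
  singleton <- lengths(blocks) == 1L
  fixed <- sort(unname(unlist(blocks[singleton], use.names = FALSE)))
  multi <- unname(blocks[!singleton])
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      reps <- vapply(multi, function(ix) ix[sample.int(length(ix), 1L)],
                     integer(1))
      sort(c(fixed, unname(reps)))
    })
  })
  structure(sets, blocks = blocks, seed = seed)
}

#' Greedy LD clumping of conjunctional FDR results into loci
#'
#' Ranks all SNPs by increasing conjunctional FDR and repeatedly takes the
#' best-ranked unassigned SNP as an index SNP, assigning every unassigned SNP
#' with r² above `r2_threshold` to it as a locus member, until every SNP is
#' an index or a member.  Ties on conjFDR are broken by smaller trait-1
#' p-value, then smaller position, then lexicographic SNP id.  Index SNPs
#' are pairwise at or below the r² threshold by construction.
#'
#' @param conjfdr Per-SNP conjunctional FDR values aligned with `merged`
#'   (e.g. the `conjfdr` column of [compute_conjfdr()]'s result).
#' @param ld An `ld_matrix`.
#' @param merged The `merged_panel` the values are aligned with.
#' @param r2_threshold Clumping threshold (default 0.1; no distance window).
#' @return A `locus_table`: data frame with one row per locus (`locus`,
#'   `index_snp`, `chr`, `pos`, `nearest_gene`, `effect_allele`, per-trait
#'   `beta`/`se`/`p`, `conjfdr`, `n_members`) ordered by conjFDR; attribute
#'   `members` is a named list of member SNP ids per index SNP.
#' @export
clump <- function(conjfdr, ld, merged, r2_threshold = 0.1) {
  m <- nrow(merged)
  if (length(conjfdr) != m) stop("conjfdr must align with the merged panel")
  adj <- ld_adjacency(ld, merged$snp_id, r2_threshold = r2_threshold)
  ord <- order(conjfdr, merged$p1, merged$pos, merged$snp_id)
  assigned <- logical(m)
  index_at <- integer(0)
  members <- list()
  for (k in ord) {
    if (assigned[k]) next
    assigned[k] <- TRUE
    nb <- adj[[k]]
    nb <- nb[!assigned[nb]]
    assigned[nb] <- TRUE
    index_at <- c(index_at, k)
    members[[merged$snp_id[k]]] <- merged$snp_id[nb]
  }
  loci <- data.frame(
    locus = seq_along(index_at),
    index_snp = merged$snp_id[index_at],
    chr = merged$chr[index_at], pos = merged$pos[index_at],
    nearest_gene = NA_character_,
    effect_allele = merged$effect_allele[index_at],
    beta1 = merged$beta1[index_at], se1 = merged$se1[index_at],
    p1 = merged$p1[index_at],
    beta2 = merged$beta2[index_at], se2 = merged$se2[index_at],
    p2 = merged$p2[index_at],
    conjfdr = conjfdr[index_at],
    n_members = lengths(members),
    stringsAsFactors = FALSE
  )
  rownames(loci) <- NULL
  structure(loci, class = c("locus_table", "data.frame"),
            members = members,
            trait_names = attr(merged, "trait_names"))
}

#' Flag significant and suggestive loci
#'
#' Strict inequalities: a locus is significant when `conjfdr < alpha` and
#' suggestive when `conjfdr < suggestive`.
#'
#' @param loci A `locus_table`.
#' @param alpha Significance threshold (default 0.05).
#' @param suggestive Suggestive-evidence threshold (default 0.1); must exceed
#'   `alpha`.
#' @return The table with logical columns `significant` and `suggestive`.
#' @export
call_significance <- function(loci, alpha = 0.05, suggestive = 0.1) {
  if (alpha >= suggestive) {
    stop("configuration error: alpha must be smaller than the suggestive ",
         "threshold")
  }
  loci$significant <- loci$conjfdr < alpha
  loci$suggestive <- loci$conjfdr < suggestive
  loci
}

#' Remove a genomic region and its LD partners from a panel
#'
#' Drops every SNP inside the closed interval `[start, end]` on `chrom` and,
#' in one propagation step, every SNP with r² above `r2_threshold` to any
#' dropped SNP.  Used for post-hoc re-analysis of how much one locus drives
#' a cross-trait enrichment signal.  Idempotent.
#'
#' @param merged A `merged_panel`.
#' @param chrom Chromosome label.
#' @param start,end 1-based closed interval bounds.
#' @param ld An `ld_matrix`.
#' @param r2_threshold LD propagation threshold (default 0.1).
#' @return The reduced `merged_panel` with attribute `excluded` (counts).
#' @export
exclude_region <- function(merged, chrom, start, end, ld, r2_threshold = 0.1) {
  if (start > end) stop("malformed region: start > end")
  inside <- merged$chr == as.character(chrom) &
    merged$pos >= start & merged$pos <= end
  inside_ids <- merged$snp_id[inside]
  partner <- ld$r2 > r2_threshold &
    (ld$snp_a %in% inside_ids | ld$snp_b %in% inside_ids)
  partner_ids <- setdiff(unique(c(ld$snp_a[partner], ld$snp_b[partner])),
                         inside_ids)
  drop <- inside | merged$snp_id %in% partner_ids
  if (all(drop)) stop("excluding this region empties the panel")
  cj_log("exclude_region: removed ", sum(inside), " SNPs in region and ",
         sum(drop) - sum(inside), " LD partners")
  out <- merged[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(merged)
  for (a in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "excluded") <- c(in_region = sum(inside),
                             ld_partners = sum(drop) - sum(inside))
  out
}

#' Annotate loci with the nearest gene from an interval table
#'
#' Each index SNP gets the gene whose interval contains it, otherwise the
#' gene with minimal base-pair distance on the same chromosome (ties broken
#' by lexicographically first gene name); `NA` when the chromosome has no
#' gene.
#'
#' @param loci A `locus_table`.
#' @param gene_intervals Data frame `chr`, `start`, `end`, `name` with
#'   1-based closed coordinates, e.g. from [read_bed()].
#' @return The table with `nearest_gene` filled in.
#' @export
annotate_nearest_gene <- function(loci, gene_intervals) {
  need <- c("chr", "start", "end", "name")
  if (!all(need %in% names(gene_intervals))) {
    stop("gene_intervals must have columns chr, start, end, name")
  }
  loci$nearest_gene <- vapply(seq_len(nrow(loci)), function(k) {
    g <- gene_intervals[gene_intervals$chr == loci$chr[k], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_character_)
    pos <- loci$pos[k]
    d <- ifelse(pos < g$start, g$start - pos,
                ifelse(pos > g$end, pos - g$end, 0L))
    best <- which(d == min(d))
    g$name[best][order(g$name[best])][1]
  }, character(1))
  loci
}
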