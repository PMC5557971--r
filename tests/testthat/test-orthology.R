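mk_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(qseqid = r[[1]], sseqid = r[[2]], pident = 90, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = as.numeric(r[[4]]),
               bitscore = as.numeric(r[[3]]), stringsAsFactors = FALSE)))
  attr(df, "score_mode") <- "bit"
  df
}

test_that("second-best rule uses a strict 90% boundary and the e-value gate is inclusive", {
  genome_of <- c(a1 = "gA", b1 = "gB", b2 = "gB")
  # runner-up below 90% of best: accepted
  h <- mk_hits(list("a1", "b1", 100, 1e-10), list("a1", "b2", 85, 1e-10))
  best <- best_hit_per_target_genome(h, genome_of)
  expect_equal(best$sseqid, "b1")
  # runner-up at exactly 90%: rejected (strict <)
  h <- mk_hits(list("a1", "b1", 100, 1e-10), list("a1", "b2", 90, 1e-10))
  expect_equal(nrow(best_hit_per_target_genome(h, genome_of)), 0L)
  # e-value 1e-4 fails the gate
  h <- mk_hits(list("a1", "b1", 100, 1e-4))
  expect_equal(nrow(best_hit_per_target_genome(h, genome_of)), 0L)
  # e-value exactly 1e-5 passes (inclusive gate)
  h <- mk_hits(list("a1", "b1", 100, 1e-5))
  expect_equal(nrow(best_hit_per_target_genome(h, genome_of)), 1L)
})

test_that("reciprocity is required for a BRBH pair", {
  genome_of <- c(a1 = "gA", a2 = "gA", b1 = "gB")
  h <- mk_hits(list("a1", "b1", 100, 1e-10), list("b1", "a1", 100, 1e-10))
  pairs <- reciprocal_pairs(best_hit_per_target_genome(h, genome_of))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_a, "a1")
  # b1's best goes to a2 instead: reciprocity fails
  h <- mk_hits(list("a1", "b1", 100, 1e-10), list("b1", "a2", 100, 1e-10))
  pairs <- reciprocal_pairs(best_hit_per_target_genome(h, genome_of))
  expect_equal(nrow(pairs), 0L)
})

test_that("BRBH set equals a literal brute-force application of the rule", {
  set.seed(29)
  for (i in 1:100) {
    tab <- random_hit_table()
    best <- best_hit_per_target_genome(tab$hits, tab$genome_of)
    pairs <- reciprocal_pairs(best)
    got <- sort(paste(pairs$gene_a, pairs$gene_b))
    expect_identical(got, oracle_brbh(tab$hits, tab$genome_of))
  }
})

test_that("BRBH set is invariant under hit-row reordering", {
  set.seed(31)
  tab <- random_hit_table()
  p1 <- reciprocal_pairs(best_hit_per_target_genome(tab$hits, tab$genome_of))
  shuf <- tab$hits[sample(nrow(tab$hits)), , drop = FALSE]
  attr(shuf, "score_mode") <- "bit"
  p2 <- reciprocal_pairs(best_hit_per_target_genome(shuf, tab$genome_of))
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("COGs are connected components of the BRBH graph", {
  pairs <- data.frame(gene_a = c("a1", "b1"), gene_b = c("b1", "c1"),
                      stringsAsFactors = FALSE)
  cogs <- build_cogs(pairs)
  expect_equal(length(unique(cogs$cog_id)), 1L)
  expect_setequal(cogs$gene_id, c("a1", "b1", "c1"))

  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  expect_equal(length(unique(build_cogs(pairs)$cog_id)), 2L)
})

test_that("component structure matches an explicit union-find oracle", {
  set.seed(37)
  for (i in 1:100) {
    nodes <- paste0("n", seq_len(sample(3:15, 1)))
    k <- sample.int(20, 1)
    pairs <- unique(data.frame(gene_a = sample(nodes, k, TRUE),
                               gene_b = sample(nodes, k, TRUE),
                               stringsAsFactors = FALSE))
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    if (nrow(pairs) == 0) next
    cogs <- build_cogs(pairs)
    oracle <- oracle_components(pairs)
    expect_equal(length(unique(cogs$cog_id)), length(oracle))
    got <- lapply(split(cogs$gene_id, cogs$cog_id), sort)
    expect_setequal(unname(got), unname(lapply(oracle, sort)))
  }
})

test_that("planted pangenome structure is recovered exactly at moderate divergence", {
  cfg <- pangenome_config(n_genomes = 4, n_core = 20, n_accessory = 3,
                          n_specific_per_genome = 2, divergence = 0.05,
                          seed = 42)
  sim <- simulate_pangenome(cfg)
  hits <- all_vs_all_protein_hits(sim$proteomes)
  genome_of <- setNames(sim$genes$genome, sim$genes$gene_id)
  cogs <- build_cogs(reciprocal_pairs(
    best_hit_per_target_genome(hits, genome_of)))
  part <- partition_pangenome(cogs, sim$genes, hits)
  expect_equal(length(part$core_cogs), 20L)
  sizes <- table(part$cog_members$cog_id)[part$core_cogs]
  expect_true(all(sizes == 4))
  expect_setequal(part$specific_genes, sim$truth$specific_gene_ids)
  expect_equal(length(part$unresolved_genes), 0L)
})

test_that("core size is non-increasing as genomes are added", {
  cfg <- pangenome_config(n_genomes = 5, n_core = 12, n_accessory = 4,
                          divergence = 0.05, seed = 17)
  sim <- simulate_pangenome(cfg)
  hits <- all_vs_all_protein_hits(sim$proteomes)
  genome_of <- setNames(sim$genes$genome, sim$genes$gene_id)
  core_at <- function(gset) {
    genes <- sim$genes[sim$genes$genome %in% gset, , drop = FALSE]
    keep <- hits$qseqid %in% genes$gene_id & hits$sseqid %in% genes$gene_id
    h <- hits[keep, , drop = FALSE]
    attr(h, "score_mode") <- "raw"
    go <- setNames(genes$genome, genes$gene_id)
    cogs <- build_cogs(reciprocal_pairs(best_hit_per_target_genome(h, go)))
    length(partition_pangenome(cogs, genes, h)$core_cogs)
  }
  gids <- names(sim$genomes)
  counts <- vapply(3:5, function(k) core_at(gids[1:k]), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("partitioning fewer than 2 genomes is an error", {
  genes <- data.frame(genome = "g1", contig = "c", gene_id = "x",
                      start = 1L, end = 3L, strand = "+",
                      stringsAsFactors = FALSE)
  h <- mk_hits(list("x", "x", 100, 1e-10))
  expect_error(partition_pangenome(build_cogs(
    data.frame(gene_a = character(0), gene_b = character(0))), genes, h),
    "fewer than 2 genomes")
})

test_that("specific-gene criterion distinguishes no-hit from no-BRBH", {
  genome_of <- c(a1 = "gA", b1 = "gB", b2 = "gB")
  genes <- data.frame(genome = c("gA", "gB", "gB"), contig = "c",
                      gene_id = c("a1", "b1", "b2"),
                      start = 1L, end = 3L, strand = "+",
                      stringsAsFactors = FALSE)
  # a1 hits both b1 and b2 with close scores: gate passes, BRBH fails
  h <- mk_hits(list("a1", "b1", 100, 1e-10), list("a1", "b2", 95, 1e-10),
               list("b1", "a1", 100, 1e-10), list("b2", "a1", 95, 1e-10))
  cogs <- build_cogs(reciprocal_pairs(best_hit_per_target_genome(h, genome_of)))
  p_nohit <- partition_pangenome(cogs, genes, h, specific_mode = "no_hit")
  expect_equal(p_nohit$specific_genes, character(0))
  expect_setequal(p_nohit$unresolved_genes, c("a1", "b1", "b2"))
  p_nobrbh <- partition_pangenome(cogs, genes, h, specific_mode = "no_brbh")
  expect_setequal(p_nobrbh$specific_genes, c("a1", "b1", "b2"))
})
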