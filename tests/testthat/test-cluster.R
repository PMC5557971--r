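# hand-built ortholog table: cluster of 4 reference genes, genomes vary in
# how many members they carry
mk_cluster_fixture <- function() {
  genes <- expand.grid(genome = c("ref", "gA", "gB", "gC"),
                       fam = paste0("f", 1:4), stringsAsFactors = FALSE)
  genes$gene_id <- paste(genes$genome, genes$fam, sep = "_")
  genes$contig <- paste0(genes$genome, "_c1")
  genes <- genes[order(genes$genome, genes$fam), ]
  genes$start <- as.integer(ave(seq_len(nrow(genes)), genes$genome,
                                FUN = seq_along) * 500L)
  genes$end <- genes$start + 299L
  genes$strand <- "+"
  # gA carries all 4 members, gB carries 2, gC none
  keep <- with(genes, genome == "ref" |
                 (genome == "gA") |
                 (genome == "gB" & fam %in% c("f1", "f2")) |
                 (genome == "gC" & FALSE))
  extra <- data.frame(genome = "gC", fam = "other", gene_id = "gC_other",
                      contig = "gC_c1", start = 100L, end = 399L,
                      strand = "+", stringsAsFactors = FALSE)
  genes <- rbind(genes[keep, c("genome", "contig", "gene_id", "start",
                               "end", "strand", "fam")],
                 extra[, c("genome", "contig", "gene_id", "start", "end",
                           "strand", "fam")])
  cogs <- do.call(rbind, lapply(paste0("f", 1:4), function(f) {
    members <- genes$gene_id[genes$fam == f]
    if (length(members) < 2) return(NULL)
    data.frame(cog_id = paste0("COG_", f), gene_id = members,
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, cogs = cogs,
       spec = cluster_spec("ni_cluster", paste0("ref_f", 1:4)))
}

test_that("genomes are classified complete, partial or absent by ortholog presence", {
  fx <- mk_cluster_fixture()
  rep <- classify_cluster(fx$spec, fx$cogs, fx$genes)
  expect_equal(rep$reference_genome, "ref")
  expect_equal(rep$status[["gA"]], "complete")
  expect_equal(rep$status[["gB"]], "partial")
  expect_equal(rep$status[["gC"]], "absent")
  expect_equal(unname(rep$counts), c(1L, 1L, 1L))
  expect_false("ref" %in% names(rep$status))
})

test_that("the completeness threshold changes the complete/partial call", {
  fx <- mk_cluster_fixture()
  spec50 <- cluster_spec("ni_cluster", paste0("ref_f", 1:4),
                         completeness_threshold = 0.5)
  rep <- classify_cluster(spec50, fx$cogs, fx$genes)
  expect_equal(rep$status[["gB"]], "complete")   # 2 of 4 members
  rep_def <- classify_cluster(fx$spec, fx$cogs, fx$genes)
  expect_equal(rep_def$status[["gB"]], "partial")
})

test_that("adding a present member never demotes a genome's status", {
  fx <- mk_cluster_fixture()
  before <- classify_cluster(fx$spec, fx$cogs, fx$genes)$status
  # grant gB a third member
  fx2 <- fx
  newrow <- fx$genes[fx$genes$gene_id == "gB_f1", ]
  newrow$gene_id <- "gB_f3"; newrow$fam <- "f3"
  newrow$start <- 9000L; newrow$end <- 9299L
  fx2$genes <- rbind(fx$genes, newrow)
  fx2$cogs <- rbind(fx$cogs, data.frame(cog_id = "COG_f3",
                                        gene_id = "gB_f3"))
  after <- classify_cluster(fx$spec, fx2$cogs, fx2$genes)$status
  rank <- c(absent = 0, partial = 1, complete = 2)
  expect_true(all(rank[after[names(before)]] >= rank[before]))
})

test_that("a spec member missing from the gene table is a configuration error", {
  fx <- mk_cluster_fixture()
  bad <- cluster_spec("x", c("ref_f1", "ref_missing"))
  expect_error(classify_cluster(bad, fx$cogs, fx$genes),
               "configuration error.*ref_missing")
})

test_that("contiguity requirement demotes scattered or inverted arrangements", {
  fx <- mk_cluster_fixture()
  spec_syn <- cluster_spec("ni_cluster", paste0("ref_f", 1:4),
                           contiguity_required = TRUE)
  # gA members are consecutive and co-oriented: stays complete
  rep <- classify_cluster(spec_syn, fx$cogs, fx$genes)
  expect_equal(rep$status[["gA"]], "complete")
  # flip one gA member's strand: demoted under the contiguity requirement
  fx$genes$strand[fx$genes$gene_id == "gA_f2"] <- "-"
  rep2 <- classify_cluster(spec_syn, fx$cogs, fx$genes)
  expect_equal(rep2$status[["gA"]], "partial")
  # an unrelated gene between two members breaks contiguity
  fx2 <- mk_cluster_fixture()
  wedge <- fx2$genes[fx2$genes$gene_id == "gA_f1", ]
  wedge$gene_id <- "gA_wedge"; wedge$fam <- "w"
  wedge$start <- fx2$genes$start[fx2$genes$gene_id == "gA_f2"] - 50L
  wedge$end <- wedge$start + 20L
  fx2$genes <- rbind(fx2$genes, wedge)
  rep3 <- classify_cluster(spec_syn, fx2$cogs, fx2$genes)
  expect_equal(rep3$status[["gA"]], "partial")
})

test_that("planted synthetic clusters are classified exactly as planted", {
  cfg <- pangenome_config(
    n_genomes = 6, n_core = 15, divergence = 0.04,
    cluster_spec = list(n_members = 5, complete_in = c("G02", "G03"),
                        partial_in = list(G04 = 2)),
    seed = 19)
  sim <- simulate_pangenome(cfg)
  hits <- all_vs_all_protein_hits(sim$proteomes)
  genome_of <- setNames(sim$genes$genome, sim$genes$gene_id)
  cogs <- build_cogs(reciprocal_pairs(
    best_hit_per_target_genome(hits, genome_of)))
  spec <- cluster_spec("planted",
                       paste0("G01_", sim$truth$cluster_family_ids),
                       contiguity_required = TRUE)
  rep <- classify_cluster(spec, cogs, sim$genes)
  expect_equal(rep$status[["G02"]], "complete")
  expect_equal(rep$status[["G03"]], "complete")
  expect_equal(rep$status[["G04"]], "partial")
  expect_equal(unname(rep$counts), c(2L, 1L, 2L))
})

test_that("ortholog identity profiles match planted divergence and flag missing orthologs", {
  cfg <- pangenome_config(
    n_genomes = 3, n_core = 10, divergence = 0.05,
    cluster_spec = list(n_members = 3, complete_in = "G02"),
    seed = 29)
  sim <- simulate_pangenome(cfg)
  hits <- all_vs_all_protein_hits(sim$proteomes)
  genome_of <- setNames(sim$genes$genome, sim$genes$gene_id)
  cogs <- build_cogs(reciprocal_pairs(
    best_hit_per_target_genome(hits, genome_of)))
  spec <- cluster_spec("planted", paste0("G01_", sim$truth$cluster_family_ids))
  rep <- classify_cluster(spec, cogs, sim$genes)
  prof <- ortholog_identity_profile(spec, rep, sim$genes, sim$genomes)
  # G03 lacks the cluster entirely
  expect_true(all(is.na(prof$identity[, "G03"])))
  # G02 orthologs: identity near the two-lineage site-wise expectation
  get_cds <- function(id) {
    row <- sim$genes[sim$genes$gene_id == id, ]
    s <- substring(as.character(sim$genomes[[row$genome]][[row$contig]]),
                   row$start, row$end)
    if (row$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  for (k in seq_along(spec$members)) {
    ref_cds <- get_cds(spec$members[k])
    oth_cds <- get_cds(rep$ortholog[k, "G02"])
    expect_lt(abs(prof$identity[k, "G02"] -
                    hamming_identity(ref_cds, oth_cds)), 1.0)
  }
  expect_true(all(prof$coverage[, "G02"] > 0.95))
})
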