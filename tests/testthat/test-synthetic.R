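test_that("zero divergence yields identical gene copies in every genome", {
  cfg <- pangenome_config(n_genomes = 3, n_core = 5, n_accessory = 0,
                          n_specific_per_genome = 0, divergence = 0, seed = 1)
  sim <- simulate_pangenome(cfg)
  expect_equal(length(sim$truth$core_family_ids), 5L)
  expect_equal(nrow(sim$genes), 15L)
  for (f in sim$truth$core_family_ids) {
    prots <- vapply(names(sim$proteomes), function(g)
      as.character(sim$proteomes[[g]][[paste0(g, "_", f)]]), "")
    expect_equal(length(unique(prots)), 1L)
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- pangenome_config(n_genomes = 3, n_core = 8, n_accessory = 2,
                          n_specific_per_genome = 1, divergence = 0.05,
                          de_spec = list(n_up = 3, n_down = 2), seed = 7)
  s1 <- simulate_pangenome(cfg)
  s2 <- simulate_pangenome(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(lapply(s1$genomes, as.character),
                   lapply(s2$genomes, as.character))
  expect_identical(lapply(s1$proteomes, as.character),
                   lapply(s2$proteomes, as.character))
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_de_table(s1$truth, cfg),
                   simulate_de_table(s2$truth, cfg))
})

test_that("every generated gene is accounted for exactly once", {
  cfg <- pangenome_config(n_genomes = 4, n_core = 10, n_accessory = 3,
                          n_specific_per_genome = 2, divergence = 0.05,
                          n_contigs_per_genome = 2, seed = 3)
  sim <- simulate_pangenome(cfg)
  expect_setequal(names(sim$truth$family_of_gene), sim$genes$gene_id)
  expect_false(anyDuplicated(sim$genes$gene_id) > 0)
  per_genome <- table(sim$genes$genome)
  expect_true(all(per_genome >= 10 + 2))   # core + specific at minimum
  # genes never overlap within a contig
  for (ct in unique(sim$genes$contig)) {
    rows <- sim$genes[sim$genes$contig == ct, ]
    rows <- rows[order(rows$start), ]
    if (nrow(rows) > 1)
      expect_true(all(rows$start[-1] > rows$end[-nrow(rows)]))
  }
  # coordinates point at the planted CDS (strand-aware)
  for (i in sample(nrow(sim$genes), 10)) {
    row <- sim$genes[i, ]
    contig <- as.character(sim$genomes[[row$genome]][[row$contig]])
    cds <- substring(contig, row$start, row$end)
    if (row$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
    expect_identical(prot, as.character(sim$proteomes[[row$genome]][[row$gene_id]]))
  }
})

test_that("mutate_sequence honors rate, alphabet and determinism contracts", {
  expect_identical(mutate_sequence("ACGT", 0, seed = 1), "ACGT")
  expect_identical(mutate_sequence("", 0.1, seed = 1), "")
  expect_error(mutate_sequence("ACGU", 0.1, seed = 1), "A/C/G/T")
  expect_error(mutate_sequence("ACGT", 0.7), "divergence")
  expect_identical(mutate_sequence(strrep("ACGT", 50), 0.2, seed = 9),
                   mutate_sequence(strrep("ACGT", 50), 0.2, seed = 9))

  s <- strrep("A", 10000)
  m <- mutate_sequence(s, 0.1, seed = 4)
  frac <- 1 - hamming_identity(s, m) / 100
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), sd3)
})

test_that("within-family identity decreases with divergence and matches site-wise expectation", {
  rates <- c(0.01, 0.05, 0.10)
  mean_ident <- vapply(rates, function(r) {
    cfg <- pangenome_config(n_genomes = 10, n_core = 30, divergence = r,
                            seed = 101)
    sim <- simulate_pangenome(cfg)
    fam_seqs <- lapply(sim$truth$core_family_ids, function(f) {
      ids <- sim$genes$gene_id[sim$genes$gene_id %in%
                                 paste0(names(sim$genomes), "_", f)]
      vapply(ids, function(id) {
        row <- sim$genes[sim$genes$gene_id == id, ]
        s <- substring(as.character(sim$genomes[[row$genome]][[row$contig]]),
                       row$start, row$end)
        if (row$strand == "-")
          s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        s
      }, "")
    })
    idents <- unlist(lapply(fam_seqs, function(v) {
      pairs <- utils::combn(length(v), 2)
      apply(pairs, 2, function(p) hamming_identity(v[p[1]], v[p[2]]))
    }))
    mean(idents) / 100
  }, 0)
  expect_true(all(diff(mean_ident) < 0))
  # two independent lineages at rate r agree per site with probability
  # (1-r)^2 + r^2/3 (equal substitutions collide in 1 of 3 bases); the
  # stop-codon redraw shifts this by well under the tolerance
  expected <- (1 - rates)^2 + rates^2 / 3
  expect_equal(mean_ident, expected, tolerance = 0.02)
})

test_that("planted DE counts are reproduced exactly in the simulated table", {
  cfg <- pangenome_config(n_genomes = 2, n_core = 150, divergence = 0.02,
                          de_spec = list(n_up = 90, n_down = 28), seed = 13)
  sim <- simulate_pangenome(cfg)
  de <- simulate_de_table(sim$truth, cfg)
  expect_equal(sum(de$q_value < 0.05 & de$`log2(fold_change)` > 0), 90L)
  expect_equal(sum(de$q_value < 0.05 & de$`log2(fold_change)` < 0), 28L)

  cfg0 <- pangenome_config(n_genomes = 2, n_core = 20,
                           de_spec = list(n_up = 0, n_down = 0), seed = 13)
  sim0 <- simulate_pangenome(cfg0)
  de0 <- simulate_de_table(sim0$truth, cfg0)
  expect_equal(sum(de0$q_value < 0.05), 0L)
})

test_that("contradictory configurations fail naming the offending field", {
  expect_error(pangenome_config(divergence = 0.6), "divergence")
  expect_error(pangenome_config(gene_length = 300.5), "gene_length")
  expect_error(pangenome_config(gene_length = 100), "gene_length")
  expect_error(pangenome_config(n_core = -1), "n_core")
  expect_error(
    pangenome_config(n_genomes = 3,
                     cluster_spec = list(n_members = 4, complete_in = "G09")),
    "cluster_spec genome 'G09'")
  expect_error(
    pangenome_config(n_genomes = 3,
                     cluster_spec = list(n_members = 4, complete_in = "G01")),
    "reference genome")
})

test_that("planted cluster is contiguous and co-oriented where complete", {
  cfg <- pangenome_config(
    n_genomes = 4, n_core = 12, divergence = 0.03, n_contigs_per_genome = 2,
    cluster_spec = list(n_members = 5, complete_in = c("G02", "G03"),
                        partial_in = list(G04 = 2)),
    seed = 23)
  sim <- simulate_pangenome(cfg)
  expect_equal(unname(sim$truth$cluster_status_by_genome),
               c("complete", "complete", "complete", "partial"))
  for (g in c("G01", "G02", "G03")) {
    rows <- sim$genes[sim$genes$genome == g &
                        sim$genes$family %in% sim$truth$cluster_family_ids, ]
    expect_equal(nrow(rows), 5L)
    expect_equal(length(unique(rows$contig)), 1L)
    expect_equal(length(unique(rows$strand)), 1L)
    on_ct <- sim$genes[sim$genes$contig == rows$contig[1], ]
    on_ct <- on_ct[order(on_ct$start), ]
    ranks <- sort(match(rows$gene_id, on_ct$gene_id))
    expect_true(all(diff(ranks) == 1))
  }
  expect_equal(sum(sim$genes$genome == "G04" &
                     sim$genes$family %in% sim$truth$cluster_family_ids), 2L)
})
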