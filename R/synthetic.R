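CODONS <- as.vector(outer(as.vector(outer(c("T", "C", "A", "G"),
                                          c("T", "C", "A", "G"), paste0)),
                          c("T", "C", "A", "G"), paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

#' Configure a synthetic pangenome
#'
#' Describes a set of bacterial genomes descending from common ancestral
#' gene families by independent per-site substitution, with planted core,
#' accessory and strain-specific genes, an optional planted gene cluster
#' carried by a subset of genomes, optional Pfam/GO annotations with one
#' enriched term, and an optional differential-expression table for the
#' focal (first) genome.
#'
#' @param n_genomes number of genomes; the first is the focal/reference one.
#' @param n_core universally present single-copy gene families.
#' @param n_accessory families present in a random subset (2..n_genomes-1)
#'   of genomes.
#' @param n_specific_per_genome genes unique to each genome (fresh random
#'   sequence, no shared ancestry).
#' @param gene_length mean coding-gene length in nucleotides; must be a
#'   multiple of 3 and at least 33.
#' @param divergence per-site substitution probability in `[0, 0.5]` applied
#'   independently on each genome's lineage from the family ancestor.
#' @param n_contigs_per_genome contigs per genome.
#' @param cluster_spec optional planted cluster: list with `cluster_id`,
#'   `n_members`, `complete_in` (non-reference genome ids carrying the full,
#'   contiguous, co-oriented cluster; the reference always does), and
#'   `partial_in` (named list: genome id -> number of leading members
#'   carried, scattered).
#' @param enrichment_spec optional planted annotation: list with `term_id`,
#'   `pfam_id`, `frac_de` (fraction of DE genes carrying the Pfam),
#'   `frac_bg` (background fraction), `n_background_terms`.
#' @param de_spec optional DE table spec: list with `n_up`, `n_down`,
#'   `alpha` (significance threshold, default 0.05).
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   config.
#' @return a validated list of class `pangenome_config`.
#' @export
pangenome_config <- function(n_genomes = 3, n_core = 20, n_accessory = 0,
                             n_specific_per_genome = 0, gene_length = 300,
                             divergence = 0.05, n_contigs_per_genome = 1,
                             cluster_spec = NULL, enrichment_spec = NULL,
                             de_spec = NULL, seed = 1) {
  if (is.na(gene_length) || gene_length < 33 || gene_length %% 3 != 0)
    stop_input("configuration error: field 'gene_length' must be >= 33 and divisible by 3")
  cfg <- list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
              n_accessory = as.integer(n_accessory),
              n_specific_per_genome = as.integer(n_specific_per_genome),
              gene_length = as.integer(gene_length),
              divergence = divergence,
              n_contigs_per_genome = as.integer(n_contigs_per_genome),
              cluster_spec = cluster_spec, enrichment_spec = enrichment_spec,
              de_spec = de_spec, seed = as.integer(seed))
  counts <- c("n_genomes", "n_core", "n_accessory", "n_specific_per_genome",
              "n_contigs_per_genome")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop_input("configuration error: field '%s' must be a count >= 0", f)
  if (cfg$n_genomes < 1)
    stop_input("configuration error: field 'n_genomes' must be >= 1")
  if (cfg$n_contigs_per_genome < 1)
    stop_input("configuration error: field 'n_contigs_per_genome' must be >= 1")
  if (is.na(cfg$divergence) || cfg$divergence < 0 || cfg$divergence > 0.5)
    stop_input("configuration error: field 'divergence' must be in [0, 0.5]")
  if (cfg$gene_length < 33 || cfg$gene_length %% 3 != 0)
    stop_input("configuration error: field 'gene_length' must be >= 33 and divisible by 3")
  if (cfg$n_accessory > 0 && cfg$n_genomes < 3)
    stop_input("configuration error: field 'n_accessory' requires >= 3 genomes")
  gids <- genome_ids(cfg$n_genomes)
  if (!is.null(cluster_spec)) {
    need <- c("n_members")
    for (f in need)
      if (is.null(cluster_spec[[f]]))
        stop_input("configuration error: cluster_spec field '%s' missing", f)
    if (cluster_spec$n_members < 2)
      stop_input("configuration error: cluster_spec field 'n_members' must be >= 2")
    others <- c(cluster_spec$complete_in %||% character(0),
                names(cluster_spec$partial_in %||% list()))
    bad <- setdiff(others, gids)
    if (length(bad))
      stop_input("configuration error: cluster_spec genome '%s' not in genome list",
                 bad[1])
    if (gids[1] %in% others)
      stop_input("configuration error: cluster_spec must not list the reference genome '%s'",
                 gids[1])
    for (g in names(cluster_spec$partial_in %||% list())) {
      k <- cluster_spec$partial_in[[g]]
      if (k < 1 || k >= cluster_spec$n_members)
        stop_input("configuration error: cluster_spec partial_in['%s'] must be in 1..n_members-1", g)
    }
  }
  if (!is.null(de_spec)) {
    de_spec$alpha <- de_spec$alpha %||% 0.05
    if (de_spec$n_up < 0 || de_spec$n_down < 0)
      stop_input("configuration error: de_spec counts must be >= 0")
    cfg$de_spec <- de_spec
  }
  structure(cfg, class = "pangenome_config")
}

genome_ids <- function(n) sprintf("G%02d", seq_len(n))

random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 1, replace = TRUE),
                      collapse = ""))
}

# Redraw any stop codon created by mutation so the CDS stays translatable.
fix_stop_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(seq)
  starts <- seq(1, n - 2, by = 3)
  codons <- substring(seq, starts, starts + 2)
  bad <- which(codons %in% STOP_CODONS)
  if (length(bad)) {
    codons[bad] <- sample(SENSE_CODONS, length(bad), replace = TRUE)
    seq <- paste(codons, collapse = "")
  }
  seq
}

#' Mutate a nucleotide sequence by independent per-site substitution
#'
#' Each site is substituted with probability `divergence` to one of the
#' three other bases chosen uniformly (Jukes-Cantor-like; no indels).
#'
#' @param seq nucleotide string over A/C/G/T.
#' @param divergence substitution probability per site, in `[0, 0.5]`.
#' @param seed optional integer; when given the result is deterministic and
#'   the caller's RNG state is untouched.
#' @return mutated string of the same length.
#' @export
mutate_sequence <- function(seq, divergence, seed = NULL) {
  if (is.na(divergence) || divergence < 0 || divergence > 0.5)
    stop_input("divergence must be in [0, 0.5]")
  if (grepl("[^ACGT]", seq))
    stop_input("sequence contains characters outside A/C/G/T")
  run <- function() {
    n <- nchar(seq)
    if (n == 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- runif(n) < divergence
    if (any(hit)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(chars[hit], bases)
      shift <- sample.int(3, sum(hit), replace = TRUE)
      chars[hit] <- bases[((cur - 1 + shift) %% 4) + 1]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Mutate every contig of a genome by independent substitution
#'
#' Positions are preserved (no indels), so the mutated genome is site-wise
#' comparable with the original — the setting behind planted-divergence
#' ANIb calibration, where per-fragment identity has a closed-form
#' mismatch-count oracle.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param divergence per-site substitution probability in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @return named character vector of mutated contigs.
#' @export
mutate_genome <- function(genome, divergence, seed = NULL) {
  seqs <- if (is.character(genome)) genome else as.character(genome)
  run <- function() vapply(seqs, mutate_sequence, "", divergence = divergence)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  setNames(out, names(seqs))
}

random_spacer <- function(min_len = 20, max_len = 100) {
  len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a pangenome with planted truth
#'
#' Generates genome FASTA-ready contigs, a gene table, proteomes (bacterial
#' translation table 11) and a planted-truth record for every configured
#' feature. Core families contribute exactly one gene to every genome; each
#' genome's gene copies derive from the family's ancestral sequence by
#' independent substitution at the configured divergence; planted-cluster
#' members are contiguous and co-oriented in genomes flagged complete.
#'
#' @param config a [pangenome_config()].
#' @return list with `genomes` (named list of `DNAStringSet`), `genes`
#'   (data.frame), `proteomes` (named list of `AAStringSet`), `truth`
#'   (planted truth), and when configured `annotations` (gene->Pfam
#'   data.frame) and `pfam2go` (named list).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "pangenome_config"))
  with_seed(config$seed, simulate_pangenome_impl(config))
}

simulate_pangenome_impl <- function(cfg) {
  gids <- genome_ids(cfg$n_genomes)
  ref <- gids[1]
  n_cod <- cfg$gene_length / 3

  draw_len <- function() max(11L, n_cod + sample(-5:5, 1L))

  fam <- list() # family id -> list(ancestor, carriers)
  for (i in seq_len(cfg$n_core))
    fam[[sprintf("F%03d", i)]] <- list(seq = random_cds(draw_len()),
                                       carriers = gids)
  for (i in seq_len(cfg$n_accessory)) {
    subset_sizes <- seq(2L, cfg$n_genomes - 1L)
    k <- subset_sizes[sample.int(length(subset_sizes), 1L)]
    fam[[sprintf("A%03d", i)]] <- list(seq = random_cds(draw_len()),
                                       carriers = sort(sample(gids, k)))
  }
  cl <- cfg$cluster_spec
  cluster_fams <- character(0)
  cluster_status <- setNames(rep("absent", cfg$n_genomes), gids)
  if (!is.null(cl)) {
    cluster_fams <- sprintf("CL%02d", seq_len(cl$n_members))
    complete_in <- c(ref, cl$complete_in %||% character(0))
    partial_in <- cl$partial_in %||% list()
    cluster_status[complete_in] <- "complete"
    cluster_status[names(partial_in)] <- "partial"
    for (j in seq_along(cluster_fams)) {
      carriers <- complete_in
      for (g in names(partial_in))
        if (j <= partial_in[[g]]) carriers <- c(carriers, g)
      fam[[cluster_fams[j]]] <- list(seq = random_cds(draw_len()),
                                     carriers = sort(carriers))
    }
  }

  # Ancestral gene order and orientation are conserved across genomes
  # (bacterial synteny; no rearrangement simulation): each genome carries
  # its families in the shared ancestral order, keeping ANIb fragments
  # locally collinear between genomes. Strain-specific genes are inserted
  # at random per-genome positions.
  loose_fams <- setdiff(names(fam), cluster_fams)
  anc_order <- loose_fams[sample.int(length(loose_fams))]
  if (length(cluster_fams)) {
    at <- sample.int(length(anc_order) + 1L, 1L)
    anc_order <- append(anc_order, cluster_fams, after = at - 1L)
  }
  fam_strand <- setNames(sample(c("+", "-"), length(anc_order), replace = TRUE),
                         anc_order)
  if (length(cluster_fams))
    fam_strand[cluster_fams] <- sample(c("+", "-"), 1L)

  gene_rows <- list()
  genomes <- list()
  proteomes <- list()
  family_of_gene <- character(0)

  for (g in gids) {
    fam_here <- anc_order[vapply(anc_order, function(f) g %in% fam[[f]]$carriers,
                                 TRUE)]
    items <- lapply(fam_here, function(fid) {
      s <- mutate_sequence(fam[[fid]]$seq, cfg$divergence)
      list(gene_id = paste0(g, "_", fid), family = fid,
           seq = fix_stop_codons(s), strand = fam_strand[[fid]])
    })
    for (i in seq_len(cfg$n_specific_per_genome)) {
      gid <- sprintf("%s_S%02d", g, i)
      at <- sample.int(length(items) + 1L, 1L)
      items <- append(items, list(list(gene_id = gid, family = gid,
                                       seq = random_cds(draw_len()),
                                       strand = sample(c("+", "-"), 1L))),
                      after = at - 1L)
    }
    # split into contigs at breakpoints that never fall inside the cluster run
    n_items <- length(items)
    fams_in_order <- vapply(items, `[[`, "", "family")
    cl_pos <- which(fams_in_order %in% cluster_fams)
    n_ct <- min(cfg$n_contigs_per_genome, max(1L, n_items))
    allowed <- setdiff(seq_len(max(0L, n_items - 1L)),
                       if (length(cl_pos) > 1) head(cl_pos, -1) else integer(0))
    cuts <- if (n_ct > 1 && length(allowed) >= n_ct - 1)
      sort(sample(allowed, n_ct - 1L)) else integer(0)
    contig_idx <- findInterval(seq_len(n_items), c(0L, cuts) + 1L)

    contig_seqs <- character(0)
    for (ci in seq_len(max(1L, length(cuts) + 1L))) {
      contig_id <- sprintf("%s_c%d", g, ci)
      parts <- character(0)
      pos <- 0L
      for (k in which(contig_idx == ci)) {
        it <- items[[k]]
        sp <- random_spacer()
        parts <- c(parts, sp)
        pos <- pos + nchar(sp)
        glen <- nchar(it$seq)
        placed <- if (it$strand == "+") it$seq else revcomp_chr(it$seq)
        parts <- c(parts, placed)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          genome = g, contig = contig_id, gene_id = it$gene_id,
          start = pos + 1L, end = pos + glen, strand = it$strand,
          family = it$family, stringsAsFactors = FALSE)
        pos <- pos + glen
        family_of_gene[it$gene_id] <- it$family
      }
      parts <- c(parts, random_spacer())
      contig_seqs[contig_id] <- paste(parts, collapse = "")
    }
    # genomes configured with more contigs than placeable chunks still get
    # gene-free filler contigs so contig counts match the config
    while (length(contig_seqs) < cfg$n_contigs_per_genome) {
      contig_id <- sprintf("%s_c%d", g, length(contig_seqs) + 1L)
      contig_seqs[contig_id] <- random_spacer(150, 250)
    }
    genomes[[g]] <- Biostrings::DNAStringSet(contig_seqs)
    cds <- vapply(items, `[[`, "", "seq")
    names(cds) <- vapply(items, `[[`, "", "gene_id")
    prot <- Biostrings::translate(Biostrings::DNAStringSet(cds),
                                  genetic.code = Biostrings::getGeneticCode("11"),
                                  no.init.codon = TRUE)
    proteomes[[g]] <- Biostrings::AAStringSet(prot)
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  truth <- list(
    family_of_gene = family_of_gene,
    core_family_ids = sprintf("F%03d", seq_len(cfg$n_core)),
    specific_gene_ids = genes$gene_id[grepl("_S[0-9]+$", genes$gene_id)],
    cluster_status_by_genome = cluster_status,
    cluster_family_ids = cluster_fams,
    enriched_term_id = cfg$enrichment_spec$term_id %||% NA_character_,
    de_labels = NULL)

  out <- list(genomes = genomes, genes = genes, proteomes = proteomes,
              truth = truth, config = cfg)

  focal_genes <- genes$gene_id[genes$genome == ref]
  if (!is.null(cfg$de_spec)) {
    ds <- cfg$de_spec
    if (ds$n_up + ds$n_down > length(focal_genes))
      stop_input("configuration error: de_spec plants more DE genes than the focal genome carries")
    de_pick <- sample(focal_genes, ds$n_up + ds$n_down)
    labels <- setNames(rep("null", length(focal_genes)), focal_genes)
    labels[de_pick[seq_len(ds$n_up)]] <- "up"
    if (ds$n_down > 0)
      labels[de_pick[ds$n_up + seq_len(ds$n_down)]] <- "down"
    out$truth$de_labels <- labels
  }
  if (!is.null(cfg$enrichment_spec)) {
    de_ids <- if (is.null(out$truth$de_labels)) character(0)
              else names(out$truth$de_labels)[out$truth$de_labels != "null"]
    ann <- simulate_annotations(focal_genes, de_ids, cfg$enrichment_spec)
    out$annotations <- ann$domains
    out$pfam2go <- ann$map
  }
  out
}

#' Simulate a gene -> Pfam domain table and pfam2go mapping
#'
#' Background terms are carried independently of DE status at per-term base
#' rates drawn uniformly on `[0.02, 0.10]`. When `spec` is given, its Pfam is
#' planted on DE genes at `frac_de` and on the rest at `frac_bg`, creating a
#' single truly enriched GO term.
#'
#' @param gene_ids background gene ids.
#' @param de_gene_ids DE subset (must be within `gene_ids`).
#' @param spec enrichment spec (see [pangenome_config()]) or NULL for a null
#'   (no enriched term) annotation set.
#' @param n_terms number of background terms (overridden by
#'   `spec$n_background_terms`).
#' @param seed optional integer seed.
#' @return list with `domains` (data.frame gene_id, pfam) and `map`
#'   (named list Pfam -> GO ids).
#' @export
simulate_annotations <- function(gene_ids, de_gene_ids = character(0),
                                 spec = NULL, n_terms = 20, seed = NULL) {
  run <- function() {
    n_terms <- spec$n_background_terms %||% n_terms
    pfams <- sprintf("PF9%04d", seq_len(n_terms))
    gos <- sprintf("GO:%07d", 8000000 + seq_len(n_terms))
    rates <- runif(n_terms, 0.02, 0.10)
    rows <- list()
    for (i in seq_len(n_terms)) {
      carriers <- gene_ids[runif(length(gene_ids)) < rates[i]]
      if (length(carriers))
        rows[[length(rows) + 1L]] <- data.frame(gene_id = carriers,
                                                pfam = pfams[i],
                                                stringsAsFactors = FALSE)
    }
    map <- as.list(setNames(gos, pfams))
    if (!is.null(spec)) {
      is_de <- gene_ids %in% de_gene_ids
      p <- ifelse(is_de, spec$frac_de, spec$frac_bg)
      carriers <- gene_ids[runif(length(gene_ids)) < p]
      if (length(carriers))
        rows[[length(rows) + 1L]] <- data.frame(gene_id = carriers,
                                                pfam = spec$pfam_id,
                                                stringsAsFactors = FALSE)
      map[[spec$pfam_id]] <- spec$term_id
    }
    domains <- if (length(rows)) do.call(rbind, rows)
               else data.frame(gene_id = character(0), pfam = character(0),
                               stringsAsFactors = FALSE)
    list(domains = domains, map = lapply(map, unname))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a differential-expression table (Cuffdiff dialect)
#'
#' One row per focal-genome gene. Planted "up"/"down" genes receive q-values
#' drawn uniformly below the significance threshold and log2 fold changes of
#' the matching sign; all other genes receive q-values uniform on
#' `(alpha, 1]`, so threshold selection is exact by construction.
#'
#' @param truth planted truth from [simulate_pangenome()] (needs `de_labels`).
#' @param config the matching [pangenome_config()] (needs `de_spec`).
#' @return data.frame in the `gene_exp.diff` column dialect.
#' @export
simulate_de_table <- function(truth, config) {
  stopifnot(inherits(config, "pangenome_config"))
  if (is.null(config$de_spec) || is.null(truth$de_labels))
    stop_input("de_spec/de_labels missing: configure de_spec before simulating a DE table")
  with_seed(config$seed + 104729L, {
    labels <- truth$de_labels
    ids <- names(labels)
    n <- length(ids)
    alpha <- config$de_spec$alpha
    q <- alpha + runif(n) * (1 - alpha)
    lfc <- rnorm(n, 0, 0.2)
    up <- labels == "up"; down <- labels == "down"
    q[up | down] <- runif(sum(up | down), alpha * 1e-6, alpha * (1 - 1e-9))
    lfc[up] <- runif(sum(up), 1, 4)
    lfc[down] <- -runif(sum(down), 1, 4)
    v1 <- rlnorm(n, meanlog = 4, sdlog = 1)
    v2 <- v1 * 2^lfc
    df <- data.frame(
      test_id = ids, gene_id = ids, gene = ids,
      locus = paste0("chr:", seq_len(n)),
      sample_1 = "control", sample_2 = "treated", status = "OK",
      value_1 = v1, value_2 = v2,
      `log2(fold_change)` = lfc,
      test_stat = rnorm(n), p_value = q / 2, q_value = q,
      significant = ifelse(q < alpha, "yes", "no"),
      check.names = FALSE, stringsAsFactors = FALSE)
    df
  })
}

#' Write a simulated pangenome to disk
#'
#' One genome FASTA per genome, one proteome FASTA per genome, a TSV gene
#' table, and truth tables as TSV.
#'
#' @param sim result of [simulate_pangenome()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_pangenome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in names(sim$genomes)) {
    p <- file.path(dir, paste0(g, ".fasta"))
    write_fasta(sim$genomes[[g]], p)
    paths[paste0("genome_", g)] <- p
    p <- file.path(dir, paste0(g, ".faa"))
    write_fasta(sim$proteomes[[g]], p)
    paths[paste0("proteome_", g)] <- p
  }
  p <- file.path(dir, "genes.tsv")
  write_gene_table(sim$genes, p)
  paths["gene_table"] <- p
  p <- file.path(dir, "truth_families.tsv")
  write.table(data.frame(gene_id = names(sim$truth$family_of_gene),
                         family = unname(sim$truth$family_of_gene)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_families"] <- p
  p <- file.path(dir, "truth_cluster_status.tsv")
  write.table(data.frame(genome = names(sim$truth$cluster_status_by_genome),
                         status = unname(sim$truth$cluster_status_by_genome)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_cluster_status"] <- p
  invisible(paths)
}
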