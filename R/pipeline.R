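stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 977L) %% 2147483647L
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulation` (a [pangenome_config()]) or `inputs` (a named
#' list of file paths: `genomes`, `proteomes`, `gene_table`, and optionally
#' `hits`, `de_table`, `domain_table`, `pfam2go`) must be given.
#'
#' @param outdir output directory.
#' @param simulation optional [pangenome_config()].
#' @param inputs optional named list of input paths.
#' @param brbh [brbh_params()].
#' @param anib [anib_params()].
#' @param align [align_params()].
#' @param alpha DE significance threshold.
#' @param cluster optional [cluster_spec()]; with simulation input the
#'   planted cluster is used automatically when present.
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   stage-name hash.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, simulation = NULL, inputs = NULL,
                       brbh = brbh_params(), anib = anib_params(),
                       align = align_params(), alpha = 0.05, cluster = NULL,
                       seed = 1) {
  if (is.null(simulation) == is.null(inputs))
    stop_input("exactly one of 'simulation' or 'inputs' must be configured")
  if (!is.null(inputs)) {
    need <- c("genomes", "proteomes", "gene_table")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop_input("inputs missing required path(s): %s",
                 paste(miss, collapse = ", "))
    for (f in unlist(inputs))
      if (!file.exists(f)) stop_input("input path does not exist: %s", f)
  }
  structure(list(outdir = outdir, simulation = simulation, inputs = inputs,
                 brbh = brbh, anib = anib, align = align, alpha = alpha,
                 cluster = cluster, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; parameter blocks
#' (`brbh`, `anib`, `align`, `simulation`, `cluster`) hold the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) if (is.null(args)) NULL else do.call(ctor, args)
  run_config(
    outdir = y$outdir %||% stop_input("config missing 'outdir'"),
    simulation = build(pangenome_config, y$simulation),
    inputs = y$inputs,
    brbh = build(brbh_params, y$brbh) %||% brbh_params(),
    anib = build(anib_params, y$anib) %||% anib_params(),
    align = build(align_params, y$align) %||% align_params(),
    alpha = y$alpha %||% 0.05,
    cluster = if (is.null(y$cluster)) NULL else
      cluster_spec(y$cluster$cluster_id %||% "cluster",
                   y$cluster$members,
                   y$cluster$completeness_threshold %||% 1.0,
                   y$cluster$contiguity_required %||% FALSE),
    seed = y$seed %||% 1)
}

#' Run the full comparative-genomics pipeline
#'
#' Stages, in dependency order: simulate/load inputs, all-vs-all protein
#' hits, BRBH orthology and pangenome partition, ANIb matrix, distance
#' transform and neighbor-joining tree, cluster conservation report,
#' DE selection plus GO enrichment and per-contig chi-squared test. Every
#' output file is recorded in the returned manifest with its md5 checksum;
#' re-running with an identical config reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @return invisibly, a manifest data.frame (`stage`, `file`, `md5`), also
#'   written to `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, files)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = files, stringsAsFactors = FALSE)
  ## stage: data
  de_table <- NULL; annotations <- NULL; pfam2go <- NULL
  cluster <- config$cluster
  if (!is.null(config$simulation)) {
    sim <- simulate_pangenome(config$simulation)
    datadir <- file.path(out, "data")
    paths <- write_pangenome(sim, datadir)
    genomes <- sim$genomes; proteomes <- sim$proteomes; genes <- sim$genes
    if (!is.null(config$simulation$de_spec)) {
      de_table_raw <- simulate_de_table(sim$truth, config$simulation)
      p <- file.path(datadir, "gene_exp.diff")
      write.table(de_table_raw, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths["de_table"] <- p
      de_table <- read_de_table(p)
    }
    if (!is.null(sim$annotations)) {
      annotations <- sim$annotations
      pfam2go <- sim$pfam2go
      p <- file.path(datadir, "domains.tsv")
      write.table(annotations, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths["domains"] <- p
    }
    if (is.null(cluster) && length(sim$truth$cluster_family_ids)) {
      ref <- names(sim$genomes)[1]
      cluster <- cluster_spec(
        "planted_cluster",
        paste0(ref, "_", sim$truth$cluster_family_ids))
    }
    note("data", unname(paths))
  } else {
    ins <- config$inputs
    genomes <- lapply(ins$genomes, read_fasta, type = "DNA")
    names(genomes) <- vapply(ins$genomes, function(p)
      sub("\\.(fa|fasta|fna)$", "", basename(p)), "")
    proteomes <- lapply(ins$proteomes, read_fasta, type = "AA")
    names(proteomes) <- vapply(ins$proteomes, function(p)
      sub("\\.(fa|fasta|faa)$", "", basename(p)), "")
    genes <- read_gene_table(ins$gene_table)
    if (!is.null(ins$de_table)) de_table <- read_de_table(ins$de_table)
    if (!is.null(ins$domain_table))
      annotations <- read.delim(ins$domain_table, stringsAsFactors = FALSE)
    if (!is.null(ins$pfam2go)) pfam2go <- read_pfam2go(ins$pfam2go)
    note("data", unlist(ins))
  }
  genome_of <- setNames(genes$genome, genes$gene_id)

  ## stage: hits
  hits <- if (!is.null(config$inputs$hits)) read_tabular_hits(config$inputs$hits)
          else all_vs_all_protein_hits(proteomes, config$align)
  p_hits <- file.path(out, "hits.tsv")
  write_tabular_hits(hits, p_hits)
  note("hits", p_hits)

  ## stage: orthology
  best <- best_hit_per_target_genome(hits, genome_of, config$brbh)
  pairs <- reciprocal_pairs(best)
  cogs <- build_cogs(pairs)
  part <- partition_pangenome(cogs, genes, hits, config$brbh)
  p_cogs <- file.path(out, "cogs.tsv")
  write.table(cogs, p_cogs, sep = "\t", quote = FALSE, row.names = FALSE)
  p_part <- file.path(out, "partition_summary.tsv")
  write.table(part$summary, p_part, sep = "\t", quote = FALSE, row.names = FALSE)
  p_spec <- file.path(out, "specific_genes.txt")
  writeLines(part$specific_genes, p_spec)
  note("orthology", c(p_cogs, p_part, p_spec))

  ## stage: anib + tree
  ani <- anib_matrix(genomes, config$anib)
  p_ani <- file.path(out, "anib_matrix.tsv")
  write_matrix_tsv(ani, p_ani)
  d <- ani_to_distance(ani)
  p_d <- file.path(out, "distances.tsv")
  write_matrix_tsv(d, p_d)
  tree <- neighbor_joining(d)
  p_tree <- file.path(out, "tree.nwk")
  write_newick(tree, p_tree)
  note("anib", c(p_ani, p_d))
  note("tree", p_tree)

  ## stage: cluster conservation
  if (!is.null(cluster)) {
    consrep <- classify_cluster(cluster, cogs, genes)
    p_cl <- file.path(out, "cluster_report.tsv")
    write.table(data.frame(genome = names(consrep$status),
                           status = unname(consrep$status)),
                p_cl, sep = "\t", quote = FALSE, row.names = FALSE)
    note("cluster", p_cl)
  }

  ## stage: enrichment
  if (!is.null(de_table)) {
    sets <- select_de_genes(de_table, config$alpha)
    p_de <- file.path(out, "de_genes.tsv")
    write.table(data.frame(
      gene_id = c(sets$up, sets$down),
      direction = c(rep("up", length(sets$up)), rep("down", length(sets$down)))),
      p_de, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- p_de
    if (!is.null(annotations) && !is.null(pfam2go)) {
      background <- de_table$gene_id
      gene2go <- annotate_genes_go(annotations, pfam2go, background)
      for (dir in c("up", "down")) {
        tab <- if (length(sets[[dir]]))
          enrich_gene_set(sets[[dir]], background, gene2go)
        else NULL
        p_en <- file.path(out, sprintf("enrichment_%s.tsv", dir))
        if (!is.null(tab))
          write.table(tab, p_en, sep = "\t", quote = FALSE, row.names = FALSE)
        else writeLines(paste(c("term_id", "k", "n", "K", "N",
                                "fold_enrichment", "p_raw", "p_adj"),
                              collapse = "\t"), p_en)
        files <- c(files, p_en)
      }
    }
    # positional test between the two gene-richest contigs of the focal genome
    focal <- genes$genome[1]
    ctab <- sort(table(genes$contig[genes$genome == focal]), decreasing = TRUE)
    if (length(ctab) >= 2) {
      de_ids <- c(sets$up, sets$down)
      ca <- names(ctab)[1]; cb <- names(ctab)[2]
      de_a <- sum(genes$contig[genes$gene_id %in% de_ids] == ca)
      de_b <- sum(genes$contig[genes$gene_id %in% de_ids] == cb)
      res <- try(contig_chi_squared(de_a, ctab[[1]], de_b, ctab[[2]]),
                 silent = TRUE)
      if (!inherits(res, "try-error")) {
        p_ct <- file.path(out, "contig_test.tsv")
        write.table(data.frame(contig_a = ca, contig_b = cb,
                               de_a = de_a, genes_a = ctab[[1]],
                               de_b = de_b, genes_b = ctab[[2]],
                               statistic = res$statistic,
                               p_value = res$p_value),
                    p_ct, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, p_ct)
      }
    }
    note("enrichment", files)
  }

  ## manifest + effective config
  p_cfg <- file.path(out, "effective_config.yaml")
  yaml::write_yaml(config_to_list(config), p_cfg)
  note("config", p_cfg)
  man <- do.call(rbind, manifest)
  man$md5 <- unname(tools::md5sum(man$file))
  p_man <- file.path(out, "manifest.tsv")
  write.table(man, p_man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}

config_to_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs recorded in the manifest and returns consistency-
#' checked summary tables; a missing stage output is an error naming it.
#'
#' @param outdir the pipeline output directory.
#' @return list with `partition`, `anib`, `tree` (newick string), and when
#'   present `cluster_counts`, `enrichment`, `contig_test`; a text rendering
#'   is written to `report.txt`.
#' @export
make_report <- function(outdir) {
  p_man <- file.path(outdir, "manifest.tsv")
  if (!file.exists(p_man)) stop_input("missing stage output: manifest.tsv")
  man <- read.delim(p_man, stringsAsFactors = FALSE)
  gone <- man$file[!file.exists(man$file)]
  if (length(gone)) stop_input("missing stage output: %s", gone[1])

  rep <- list()
  rep$partition <- read.delim(file.path(outdir, "partition_summary.tsv"),
                              stringsAsFactors = FALSE)
  rep$anib <- read_matrix_tsv(file.path(outdir, "anib_matrix.tsv"))
  rep$tree <- readLines(file.path(outdir, "tree.nwk"))
  p <- file.path(outdir, "cluster_report.tsv")
  if (file.exists(p)) {
    cl <- read.delim(p, stringsAsFactors = FALSE)
    rep$cluster_status <- setNames(cl$status, cl$genome)
    rep$cluster_counts <- c(complete = sum(cl$status == "complete"),
                            partial = sum(cl$status == "partial"),
                            absent = sum(cl$status == "absent"))
  }
  for (dir in c("up", "down")) {
    p <- file.path(outdir, sprintf("enrichment_%s.tsv", dir))
    if (file.exists(p))
      rep[[paste0("enrichment_", dir)]] <- read.delim(p, stringsAsFactors = FALSE)
  }
  p <- file.path(outdir, "contig_test.tsv")
  if (file.exists(p)) rep$contig_test <- read.delim(p, stringsAsFactors = FALSE)

  lines <- c("pipeline report", "================", "",
             "pangenome partition:",
             paste(sprintf("  %s = %s", rep$partition$metric,
                           rep$partition$value), collapse = "\n"))
  if (!is.null(rep$cluster_counts))
    lines <- c(lines, "", sprintf(
      "cluster conservation: %d complete / %d partial / %d absent",
      rep$cluster_counts["complete"], rep$cluster_counts["partial"],
      rep$cluster_counts["absent"]))
  if (!is.null(rep$contig_test))
    lines <- c(lines, "", sprintf(
      "contig DE enrichment: chi-squared = %.4f, p = %.3g",
      rep$contig_test$statistic, rep$contig_test$p_value))
  writeLines(lines, file.path(outdir, "report.txt"))
  rep
}
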