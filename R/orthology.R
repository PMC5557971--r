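#' Best-reciprocal-hit filtering parameters
#'
#' External (BLAST tabular) hits are gated on e-value <= `max_evalue`;
#' internal raw-score hits on score >= `min_score`. A best hit is accepted
#' only when the second-best hit from the same target genome scores strictly
#' below `second_best_ratio` times the best score.
#'
#' @param max_evalue e-value gate for external hits (inclusive).
#' @param second_best_ratio fraction in (0, 1]; default 0.90.
#' @param min_score raw-score floor for internal-mode hits.
#' @param score_field "auto" picks by the hits' `score_mode` attribute;
#'   otherwise "bit_score" or "raw_score".
#' @return list of class `brbh_params`.
#' @export
brbh_params <- function(max_evalue = 1e-5, second_best_ratio = 0.90,
                        min_score = 50, score_field = "auto") {
  if (max_evalue <= 0) stop_input("max_evalue must be > 0")
  if (second_best_ratio <= 0 || second_best_ratio > 1)
    stop_input("second_best_ratio must be in (0, 1]")
  structure(list(max_evalue = max_evalue,
                 second_best_ratio = second_best_ratio,
                 min_score = min_score, score_field = score_field),
            class = "brbh_params")
}

hits_score_mode <- function(hits, params) {
  if (params$score_field == "raw_score") return("raw")
  if (params$score_field == "bit_score") return("bit")
  attr(hits, "score_mode") %||% "bit"
}

# Cross-genome hits surviving the e-value gate (external) or score floor
# (internal). Within-genome (paralog) hits are dropped entirely.
filter_hits <- function(hits, genome_of, params = brbh_params()) {
  qg <- genome_of[hits$qseqid]
  sg <- genome_of[hits$sseqid]
  if (anyNA(qg) || anyNA(sg))
    stop_input("hit references gene id absent from the gene table: %s",
               c(hits$qseqid[is.na(qg)], hits$sseqid[is.na(sg)])[1])
  keep <- qg != sg
  mode <- hits_score_mode(hits, params)
  keep <- keep & (if (mode == "raw") hits$bitscore >= params$min_score
                  else hits$evalue <= params$max_evalue)
  out <- hits[keep, , drop = FALSE]
  out$.target_genome <- sg[keep]
  attr(out, "score_mode") <- mode
  out
}

#' Accepted best hit per (query gene, target genome)
#'
#' For each query gene and each other genome, hits failing the gate are
#' discarded; the top-scoring survivor is accepted only if the second-best
#' hit from that same genome scores strictly below `second_best_ratio` times
#' the best score (ties for best therefore reject the pair).
#'
#' @param hits hit data.frame ([read_tabular_hits()] or
#'   [all_vs_all_protein_hits()]).
#' @param genome_of named character vector: gene id -> genome id.
#' @param params [brbh_params()].
#' @return data.frame with columns `qseqid`, `target_genome`, `sseqid`,
#'   `score` (one row per accepted best hit).
#' @export
best_hit_per_target_genome <- function(hits, genome_of, params = brbh_params()) {
  fh <- filter_hits(hits, genome_of, params)
  if (nrow(fh) == 0)
    return(data.frame(qseqid = character(0), target_genome = character(0),
                      sseqid = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  dt <- data.table::data.table(q = fh$qseqid, tg = fh$.target_genome,
                               s = fh$sseqid, score = fh$bitscore)
  # aggregate duplicate (q, s) rows to their best score first
  dt <- dt[, list(score = max(score)), by = c("q", "tg", "s")]
  data.table::setorder(dt, q, tg, -score, s)
  ratio <- params$second_best_ratio
  best <- dt[, {
    b <- score[1]
    ok <- .N == 1 || score[2] < ratio * b
    if (ok) list(s = s[1], score = b)
    else list(s = character(0), score = numeric(0))
  }, by = c("q", "tg")]
  data.frame(qseqid = best$q, target_genome = best$tg, sseqid = best$s,
             score = best$score, stringsAsFactors = FALSE)
}

#' Best-reciprocal-hit gene pairs
#'
#' Pair (a, b) is kept iff a's accepted best hit in b's genome is b and b's
#' accepted best hit in a's genome is a. The returned set is deduplicated
#' with `gene_a < gene_b` lexicographically.
#'
#' @param best data.frame from [best_hit_per_target_genome()].
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_pairs <- function(best) {
  if (nrow(best) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  fwd <- paste(best$qseqid, best$sseqid, sep = "\r")
  rev <- paste(best$sseqid, best$qseqid, sep = "\r")
  mutual <- fwd %in% rev
  a <- pmin(best$qseqid[mutual], best$sseqid[mutual])
  b <- pmax(best$qseqid[mutual], best$sseqid[mutual])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Build clusters of orthologous genes (COGs)
#'
#' COGs are the connected components of the BRBH graph (default), or its
#' maximal-clique-like strict mode where a component is kept only if every
#' member pair is a BRBH pair.
#'
#' @param pairs data.frame from [reciprocal_pairs()].
#' @param mode "components" (default) or "cliques" (strict: components that
#'   are complete graphs; others are split into nothing and their genes left
#'   unclustered).
#' @return data.frame with columns `cog_id`, `gene_id`.
#' @export
build_cogs <- function(pairs, mode = c("components", "cliques")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0)
    return(data.frame(cog_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  if (mode == "cliques") {
    n_edges <- tabulate(comp$membership[pairs$gene_a] , nbins = comp$no)
    full <- vapply(seq_along(members), function(i) {
      k <- length(members[[i]])
      n_edges[i] == k * (k - 1) / 2
    }, TRUE)
    members <- members[full]
  }
  # deterministic ids ordered by smallest member gene id
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, "", 1))]
  data.frame(
    cog_id = rep(sprintf("COG%05d", seq_along(members)), lengths(members)),
    gene_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Partition a pangenome into core, accessory and strain-specific genes
#'
#' Core COGs have exactly one member in every analyzed genome; all other
#' COGs are accessory. Strain-specific genes have no accepted cross-genome
#' hit at all under the gate (`specific_mode = "no_hit"`, mirroring genes
#' "not identified in any other genome"), or merely no BRBH partner
#' (`"no_brbh"`). Genes with accepted hits but no COG are reported as
#' `unresolved`.
#'
#' @param cogs data.frame from [build_cogs()].
#' @param genes gene table (data.frame with `gene_id`, `genome`).
#' @param accepted_hits gate-surviving hits, as returned by
#'   [best_hit_per_target_genome()]'s input filter — pass the full hit table
#'   here; the gate is re-applied internally.
#' @param params [brbh_params()].
#' @param specific_mode "no_hit" (default) or "no_brbh".
#' @return list of class `pangenome_partition` with `core_cogs`,
#'   `accessory_cogs` (character vectors of cog ids), `cog_members`,
#'   `specific_genes`, `unresolved_genes`, `summary` data.frame.
#' @export
partition_pangenome <- function(cogs, genes, accepted_hits,
                                params = brbh_params(),
                                specific_mode = c("no_hit", "no_brbh")) {
  specific_mode <- match.arg(specific_mode)
  genome_list <- sort(unique(genes$genome))
  if (length(genome_list) < 2)
    stop_input("pangenome partition undefined for fewer than 2 genomes")
  genome_of <- setNames(genes$genome, genes$gene_id)
  if (!all(cogs$gene_id %in% genes$gene_id))
    stop_input("COG member '%s' absent from the gene table",
               setdiff(cogs$gene_id, genes$gene_id)[1])

  core <- character(0); accessory <- character(0)
  if (nrow(cogs) > 0) {
    per <- split(genome_of[cogs$gene_id], cogs$cog_id)
    is_core <- vapply(per, function(gs) {
      tb <- table(gs)
      length(tb) == length(genome_list) && all(tb == 1)
    }, TRUE)
    core <- names(per)[is_core]
    accessory <- names(per)[!is_core]
  }

  clustered <- unique(cogs$gene_id)
  if (specific_mode == "no_hit") {
    fh <- filter_hits(accepted_hits, genome_of, params)
    seen <- unique(c(fh$qseqid, fh$sseqid))
  } else {
    seen <- clustered
  }
  specific <- setdiff(genes$gene_id, seen)
  unresolved <- setdiff(setdiff(genes$gene_id, clustered), specific)

  structure(list(
    core_cogs = core, accessory_cogs = accessory, cog_members = cogs,
    specific_genes = sort(specific), unresolved_genes = sort(unresolved),
    genome_list = genome_list,
    summary = data.frame(
      metric = c("genomes", "cogs", "core_cogs", "accessory_cogs",
                 "specific_genes", "unresolved_genes"),
      value = c(length(genome_list),
                length(core) + length(accessory), length(core),
                length(accessory), length(specific), length(unresolved)))),
    class = "pangenome_partition")
}
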