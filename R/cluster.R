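#' Specify a reference gene cluster
#'
#' Names the ordered member genes (reference-genome gene ids) of a cluster
#' of interest, e.g. a metal-resistance efflux operon, for conservation
#' classification across genomes.
#'
#' @param cluster_id label.
#' @param members ordered reference gene ids (at least 2).
#' @param completeness_threshold presence fraction at or above which a
#'   genome counts as carrying the complete cluster (default 1.0).
#' @param contiguity_required if TRUE, "complete" additionally demands the
#'   present orthologs be consecutive and co-oriented on one contig.
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(cluster_id, members, completeness_threshold = 1.0,
                         contiguity_required = FALSE) {
  if (length(members) < 2) stop_input("cluster needs at least 2 members")
  if (completeness_threshold <= 0 || completeness_threshold > 1)
    stop_input("completeness_threshold must be in (0, 1]")
  structure(list(cluster_id = cluster_id, members = as.character(members),
                 completeness_threshold = completeness_threshold,
                 contiguity_required = contiguity_required),
            class = "cluster_spec")
}

cog_lookup <- function(cogs) setNames(cogs$cog_id, cogs$gene_id)

#' Classify cluster conservation per genome
#'
#' A member is "present" in a genome iff its COG contains at least one gene
#' of that genome. Status is `complete` when the presence fraction reaches
#' the completeness threshold, `absent` when no member is present, and
#' `partial` otherwise. The reference genome (the one carrying the spec
#' members) is excluded from the status counts.
#'
#' @param spec a [cluster_spec()].
#' @param cogs COG membership data.frame ([build_cogs()]).
#' @param genes gene table (data.frame with `gene_id`, `genome`, `contig`,
#'   `start`, `strand`).
#' @return list of class `conservation_report`: `status` (named character,
#'   non-reference genomes), `presence` (member x genome logical matrix),
#'   `counts` (complete/partial/absent), `reference_genome`.
#' @export
classify_cluster <- function(spec, cogs, genes) {
  stopifnot(inherits(spec, "cluster_spec"))
  missing_members <- setdiff(spec$members, genes$gene_id)
  if (length(missing_members))
    stop_input("configuration error: cluster member '%s' absent from the reference gene table",
               missing_members[1])
  genome_of <- setNames(genes$genome, genes$gene_id)
  ref <- unique(genome_of[spec$members])
  if (length(ref) != 1)
    stop_input("cluster members must all come from one reference genome")
  genomes <- setdiff(sort(unique(genes$genome)), ref)
  lut <- cog_lookup(cogs)
  member_cog <- lut[spec$members]

  presence <- matrix(FALSE, length(spec$members), length(genomes),
                     dimnames = list(spec$members, genomes))
  ortholog <- matrix(NA_character_, length(spec$members), length(genomes),
                     dimnames = list(spec$members, genomes))
  for (k in seq_along(spec$members)) {
    cid <- member_cog[k]
    if (is.na(cid)) next
    mem <- cogs$gene_id[cogs$cog_id == cid]
    gm <- genome_of[mem]
    for (g in intersect(unique(gm), genomes)) {
      presence[k, g] <- TRUE
      ortholog[k, g] <- mem[gm == g][1]
    }
  }

  frac <- colMeans(presence)
  status <- ifelse(frac == 0, "absent",
                   ifelse(frac >= spec$completeness_threshold,
                          "complete", "partial"))
  if (spec$contiguity_required) {
    for (g in names(status)[status == "complete"]) {
      og <- ortholog[presence[, g], g]
      if (!is_contiguous_cooriented(og, genes)) status[g] <- "partial"
    }
  }
  counts <- c(complete = sum(status == "complete"),
              partial = sum(status == "partial"),
              absent = sum(status == "absent"))
  structure(list(cluster_id = spec$cluster_id, status = status,
                 presence = presence, ortholog = ortholog, counts = counts,
                 reference_genome = ref),
            class = "conservation_report")
}

# genes consecutive (adjacent in start order among the contig's genes) and
# on one strand of one contig
is_contiguous_cooriented <- function(gene_ids, genes) {
  rows <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  if (length(unique(rows$contig)) != 1) return(FALSE)
  if (length(unique(rows$strand)) != 1) return(FALSE)
  on_contig <- genes[genes$contig == rows$contig[1], , drop = FALSE]
  on_contig <- on_contig[order(on_contig$start), , drop = FALSE]
  ranks <- match(gene_ids, on_contig$gene_id)
  all(diff(sort(ranks)) == 1)
}

#' Nucleotide identity of each cluster member versus its orthologs
#'
#' Aligns the reference coding sequence of each member (as the full-length
#' query fragment) against the ortholog's coding sequence with the local
#' nucleotide aligner; reports percent identity and query coverage.
#' Undefined (`NA`) where the ortholog is missing.
#'
#' @param spec a [cluster_spec()].
#' @param report a `conservation_report` from [classify_cluster()].
#' @param genes gene table.
#' @param genomes named list of genome sequences (contigs).
#' @param params [align_params()].
#' @return list with matrices `identity` and `coverage`
#'   (member x genome).
#' @export
ortholog_identity_profile <- function(spec, report, genes, genomes,
                                      params = align_params()) {
  get_cds <- function(gene_id) {
    row <- genes[genes$gene_id == gene_id, , drop = FALSE]
    contig <- as.character(genomes[[row$genome]][row$contig])
    s <- substring(contig, row$start, row$end)
    if (row$strand == "-") revcomp_chr(s) else s
  }
  members <- spec$members
  gnms <- colnames(report$presence)
  ident <- matrix(NA_real_, length(members), length(gnms),
                  dimnames = list(members, gnms))
  cover <- ident
  for (k in seq_along(members)) {
    ref_cds <- get_cds(members[k])
    for (g in gnms) {
      og <- report$ortholog[k, g]
      if (is.na(og)) next
      al <- local_align_nucleotide(ref_cds, get_cds(og), params,
                                   exhaustive = TRUE)
      ident[k, g] <- al$percent_identity
      cover[k, g] <- al$query_coverage
    }
  }
  list(identity = ident, coverage = cover)
}
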