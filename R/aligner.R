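#' Alignment scoring parameters
#'
#' Defaults follow common search-tool practice: BLOSUM80 with gap open 10 /
#' extend 1 for proteins; match +2 / mismatch -3 with gap open 5 / extend 2
#' for nucleotides. A gap of length L costs `open + L * extend`.
#'
#' @param protein_gap_open,protein_gap_extend affine gap costs, protein mode.
#' @param nt_match,nt_mismatch nucleotide match / mismatch scores.
#' @param nt_gap_open,nt_gap_extend affine gap costs, nucleotide mode.
#' @param min_score reporting floor for internal all-vs-all protein hits.
#' @param kmer_k,kmer_min_shared protein k-mer prescreen: only gene pairs
#'   sharing at least `kmer_min_shared` distinct `kmer_k`-mers are aligned.
#' @param anchor_k nucleotide anchor word size for long-target search.
#' @return a list of class `align_params`.
#' @export
align_params <- function(protein_gap_open = 10, protein_gap_extend = 1,
                         nt_match = 2, nt_mismatch = -3,
                         nt_gap_open = 5, nt_gap_extend = 2,
                         min_score = 50, kmer_k = 4, kmer_min_shared = 2,
                         anchor_k = 11) {
  structure(list(protein_gap_open = protein_gap_open,
                 protein_gap_extend = protein_gap_extend,
                 nt_match = nt_match, nt_mismatch = nt_mismatch,
                 nt_gap_open = nt_gap_open, nt_gap_extend = nt_gap_extend,
                 min_score = min_score, kmer_k = kmer_k,
                 kmer_min_shared = kmer_min_shared, anchor_k = anchor_k),
            class = "align_params")
}

blosum80 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM80", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM80
    }
    cache
  }
})

PROTEIN_ALPHABET <- NULL # set at load from BLOSUM80 row names

protein_alphabet <- function() rownames(blosum80())

encode_protein <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, protein_alphabet())
  if (anyNA(idx))
    stop_input("invalid protein residue(s): %s",
               paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

NT_ALPHABET <- c("A", "C", "G", "T", "N")

encode_nt <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, NT_ALPHABET)
  if (anyNA(idx))
    stop_input("invalid nucleotide base(s): %s",
               paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

nt_score_matrix <- function(params) {
  S <- matrix(params$nt_mismatch, 5, 5,
              dimnames = list(NT_ALPHABET, NT_ALPHABET))
  diag(S)[1:4] <- params$nt_match
  S["N", "N"] <- params$nt_mismatch # N never counts as a match
  S
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

alignment_result <- function(st, query_len, strand = NA_character_) {
  span <- if (st$aligned_length > 0) st$q_end - st$q_start + 1L else 0L
  list(score = st$score,
       percent_identity = if (st$aligned_length > 0)
         100 * st$matches / st$aligned_length else 0,
       query_coverage = span / query_len,
       aligned_length = st$aligned_length,
       matches = st$matches, mismatches = st$mismatches,
       gap_opens = st$gap_opens,
       q_start = st$q_start, q_end = st$q_end,
       s_start = st$s_start, s_end = st$s_end,
       strand = strand)
}

#' Local protein alignment (Smith-Waterman, BLOSUM80, affine gaps)
#'
#' Optimal local alignment under BLOSUM80; identity and query coverage are
#' computed on the optimal traceback. When no residue pair scores positively
#' the alignment is empty with score 0.
#'
#' @param a,b amino-acid strings (20-letter alphabet plus X/B/Z/*).
#' @param params an [align_params()] list.
#' @return list with `score`, `percent_identity`, `query_coverage`,
#'   `aligned_length`, match/mismatch/gap counts and 1-based coordinates.
#' @export
local_align_protein <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop_input("protein sequences must be non-empty")
  st <- sw_align_cpp(encode_protein(a), encode_protein(b), blosum80() + 0,
                     params$protein_gap_open, params$protein_gap_extend)
  alignment_result(st, nchar(a))
}

# Candidate diagonal windows from exact k-mer anchors; returns target
# substrings (1-based start offsets) worth full DP.
anchor_windows <- function(frag_code, tgt_code, k, frag_len, tgt_len,
                           max_windows = 5L, pad = 60L) {
  diags <- kmer_diagonals_cpp(frag_code, tgt_code, k)
  if (length(diags) == 0) return(NULL)
  # cluster diagonals into bins of width 2*pad, vote per bin
  bin <- floor(diags / pad)
  votes <- sort(table(bin), decreasing = TRUE)
  bins <- as.integer(names(votes))[seq_len(min(max_windows, length(votes)))]
  out <- lapply(bins, function(b) {
    d0 <- b * pad
    s1 <- max(1L, d0 + 1L - pad)
    s2 <- min(tgt_len, d0 + frag_len + 2L * pad)
    c(s1, s2)
  })
  unique(out)
}

align_nt_core <- function(frag_code, frag_len, tgt_code, params, exhaustive) {
  S <- nt_score_matrix(params)
  tgt_len <- length(tgt_code)
  if (exhaustive || tgt_len <= 5000) {
    st <- sw_align_cpp(frag_code, tgt_code, S,
                       params$nt_gap_open, params$nt_gap_extend)
    return(st)
  }
  wins <- anchor_windows(frag_code, tgt_code, params$anchor_k,
                         frag_len, tgt_len)
  best <- list(score = 0, matches = 0L, mismatches = 0L, gap_opens = 0L,
               aligned_length = 0L, q_start = 0L, q_end = 0L,
               s_start = 0L, s_end = 0L)
  if (is.null(wins)) return(best)
  for (w in wins) {
    sub_code <- tgt_code[w[1]:w[2]]
    st <- sw_align_cpp(frag_code, sub_code, S,
                       params$nt_gap_open, params$nt_gap_extend)
    if (st$score > best$score) {
      st$s_start <- st$s_start + w[1] - 1L
      st$s_end <- st$s_end + w[1] - 1L
      best <- st
    }
  }
  best
}

align_nt_one_strand <- function(frag, frag_code, target, params, exhaustive) {
  align_nt_core(frag_code, nchar(frag), encode_nt(target), params, exhaustive)
}

#' Local nucleotide alignment over both strands
#'
#' Aligns a fragment against a target and its reverse complement, reporting
#' the better hit. Long targets are searched via exact k-mer anchoring
#' (diagonal voting) followed by windowed dynamic programming; targets of at
#' most 5 kb are aligned exhaustively.
#'
#' @param fragment,target nucleotide strings over A/C/G/T/N.
#' @param params an [align_params()] list.
#' @param exhaustive force full dynamic programming regardless of length.
#' @return as [local_align_protein()], plus `strand` ("+" or "-"); subject
#'   coordinates refer to the reported strand's orientation.
#' @export
local_align_nucleotide <- function(fragment, target, params = align_params(),
                                   exhaustive = FALSE) {
  if (!nzchar(fragment) || !nzchar(target))
    stop_input("fragment and target must be non-empty")
  frag_code <- encode_nt(fragment)
  fwd <- align_nt_one_strand(fragment, frag_code, target, params, exhaustive)
  rev <- align_nt_one_strand(fragment, frag_code, revcomp_chr(target),
                             params, exhaustive)
  if (rev$score > fwd$score) alignment_result(rev, nchar(fragment), "-")
  else alignment_result(fwd, nchar(fragment), "+")
}

#' All-vs-all internal protein search
#'
#' Smith-Waterman alignment of every cross-genome protein pair that survives
#' a shared-k-mer prescreen, reported in BLAST "outfmt 6" column layout. In
#' this internal mode `bitscore` carries the raw Smith-Waterman score and
#' `evalue` a length-normalized surrogate `qlen * slen * 2^-score` (not a
#' calibrated expectation value); records are flagged via the `score_mode`
#' attribute, and downstream best-hit filtering applies its score floor
#' instead of an e-value gate.
#'
#' @param proteomes named list (one element per genome) of named character
#'   vectors or `AAStringSet`s of protein sequences; names are gene ids.
#' @param params an [align_params()] list; `min_score` is the reporting floor.
#' @return data.frame of hit records (see [read_tabular_hits()]) with
#'   attribute `score_mode = "raw"`.
#' @export
all_vs_all_protein_hits <- function(proteomes, params = align_params()) {
  if (length(proteomes) < 2) stop_input("need proteomes from at least 2 genomes")
  if (is.null(names(proteomes))) stop_input("proteomes must be a named list")
  seqs <- character(0); genome_of <- character(0)
  for (g in names(proteomes)) {
    v <- if (is.character(proteomes[[g]])) proteomes[[g]]
         else as.character(proteomes[[g]])
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop_input("proteome '%s' has unnamed sequences", g)
    seqs <- c(seqs, v)
    genome_of <- c(genome_of, rep(g, length(v)))
  }
  if (anyDuplicated(names(seqs)))
    stop_input("duplicate gene id across proteomes: %s",
               names(seqs)[anyDuplicated(names(seqs))])
  codes <- lapply(unname(seqs), encode_protein)
  n <- length(codes)
  # candidate ordered cross-genome pairs via shared k-mers
  idx_all <- seq_len(n)
  cand <- kmer_pair_candidates_cpp(codes, idx_all, idx_all, params$kmer_k,
                                   params$kmer_min_shared,
                                   length(protein_alphabet()))
  keep <- genome_of[cand[, 1]] != genome_of[cand[, 2]]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_hits(internal = TRUE))
  res <- sw_batch_cpp(codes, cand[, 1], cand[, 2], blosum80() + 0,
                      params$protein_gap_open, params$protein_gap_extend)
  ok <- res$score >= params$min_score
  cand <- cand[ok, , drop = FALSE]
  res <- res[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_hits(internal = TRUE))
  qlen <- nchar(seqs)[cand[, 1]]
  slen <- nchar(seqs)[cand[, 2]]
  hits <- data.frame(
    qseqid = names(seqs)[cand[, 1]],
    sseqid = names(seqs)[cand[, 2]],
    pident = 100 * res$matches / res$aligned_length,
    length = res$aligned_length,
    mismatch = res$mismatches,
    gapopen = res$gap_opens,
    qstart = res$q_start, qend = res$q_end,
    sstart = res$s_start, send = res$s_end,
    evalue = qlen * slen * 2^(-res$score),
    bitscore = res$score,
    stringsAsFactors = FALSE)
  ord <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "score_mode") <- "raw"
  hits
}

empty_hits <- function(internal = FALSE) {
  h <- data.frame(qseqid = character(0), sseqid = character(0),
                  pident = numeric(0), length = integer(0),
                  mismatch = integer(0), gapopen = integer(0),
                  qstart = integer(0), qend = integer(0),
                  sstart = integer(0), send = integer(0),
                  evalue = numeric(0), bitscore = numeric(0),
                  stringsAsFactors = FALSE)
  attr(h, "score_mode") <- if (internal) "raw" else "bit"
  h
}
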