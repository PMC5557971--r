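#' ANIb parameters (Goris-style)
#'
#' Defaults follow the classic ANIb recipe: genomes are cut into
#' consecutive 1020-nt fragments, each fragment is aligned to the other
#' genome on both strands, and fragments whose best hit reaches at least 30%
#' identity over at least 70% of the fragment contribute their identity to
#' the mean.
#'
#' @param fragment_length fragment size in nt.
#' @param min_identity minimum percent identity for a fragment to qualify.
#' @param min_coverage minimum aligned fraction of the fragment.
#' @param min_terminal_fragment shortest terminal remainder kept.
#' @param align [align_params()] used for fragment alignment.
#' @return list of class `anib_params`.
#' @export
anib_params <- function(fragment_length = 1020, min_identity = 30,
                        min_coverage = 0.70, min_terminal_fragment = 100,
                        align = align_params()) {
  if (fragment_length <= 0) stop_input("fragment_length must be > 0")
  if (min_identity < 0 || min_identity > 100)
    stop_input("min_identity must be in [0, 100]")
  if (min_coverage < 0 || min_coverage > 1)
    stop_input("min_coverage must be in [0, 1]")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity = min_identity, min_coverage = min_coverage,
                 min_terminal_fragment = as.integer(min_terminal_fragment),
                 align = align),
            class = "anib_params")
}

#' Cut a genome into consecutive fragments
#'
#' Per contig, non-overlapping windows of `fragment_length` starting at
#' position 1; the terminal remainder is kept iff it is at least
#' `min_terminal_fragment` nt long. Coordinates are 1-based inclusive.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param params [anib_params()].
#' @return data.frame with columns `contig`, `start`, `end`.
#' @export
fragment_genome <- function(genome, params = anib_params()) {
  seqs <- if (is.character(genome)) genome else as.character(genome)
  if (is.null(names(seqs))) stop_input("genome contigs must be named")
  fl <- params$fragment_length
  rows <- lapply(names(seqs), function(ct) {
    len <- nchar(seqs[[ct]])
    if (len < 1) return(NULL)
    n_full <- len %/% fl
    starts <- if (n_full > 0) seq(1L, by = fl, length.out = n_full) else integer(0)
    ends <- starts + fl - 1L
    rem <- len - n_full * fl
    if (len < fl) { # short contig: single fragment, kept whole
      starts <- 1L; ends <- len
    } else if (rem >= params$min_terminal_fragment) {
      starts <- c(starts, n_full * fl + 1L); ends <- c(ends, len)
    }
    data.frame(contig = ct, start = as.integer(starts), end = as.integer(ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' ANIb between an ordered genome pair
#'
#' Every query fragment is locally aligned against each subject contig on
#' both strands; fragments whose best hit passes the identity and coverage
#' thresholds contribute their percent identity. ANIb is the arithmetic mean
#' of contributing identities. When no fragment qualifies the value is
#' undefined and returned as `NA` (never 0).
#'
#' @param query,subject genomes (named character vectors or `DNAStringSet`).
#' @param params [anib_params()].
#' @return ANIb percentage, or `NA_real_` when undefined.
#' @export
anib_pair <- function(query, subject, params = anib_params()) {
  qseqs <- if (is.character(query)) query else as.character(query)
  sseqs <- if (is.character(subject)) subject else as.character(subject)
  if (length(qseqs) == 0 || length(sseqs) == 0)
    stop_input("both genomes must be non-empty")
  frags <- fragment_genome(qseqs, params)
  if (nrow(frags) == 0) return(NA_real_)
  ap <- params$align
  tgt_fwd <- lapply(sseqs, encode_nt)
  tgt_rev <- lapply(sseqs, function(s) encode_nt(revcomp_chr(s)))
  idents <- rep(NA_real_, nrow(frags))
  for (i in seq_len(nrow(frags))) {
    frag <- substring(qseqs[[frags$contig[i]]], frags$start[i], frags$end[i])
    fc <- encode_nt(frag)
    flen <- nchar(frag)
    best <- NULL
    for (k in seq_along(sseqs)) {
      for (code in list(tgt_fwd[[k]], tgt_rev[[k]])) {
        st <- align_nt_core(fc, flen, code, ap, exhaustive = FALSE)
        if (is.null(best) || st$score > best$score) best <- st
      }
    }
    if (best$aligned_length > 0) {
      pid <- 100 * best$matches / best$aligned_length
      cov <- (best$q_end - best$q_start + 1) / flen
      if (pid >= params$min_identity && cov >= params$min_coverage)
        idents[i] <- pid
    }
  }
  ok <- !is.na(idents)
  if (!any(ok)) return(NA_real_)
  mean(idents[ok])
}

#' Pairwise ANIb matrix
#'
#' All ordered genome pairs; the diagonal is exactly 100. Undefined pairs
#' (no qualifying fragment) are `NA` and listed in the matrix's
#' `undefined_pairs` attribute.
#'
#' @param genomes named list of genomes.
#' @param params [anib_params()].
#' @return numeric matrix (query rows, subject columns), possibly
#'   asymmetric, with attribute `undefined_pairs`.
#' @export
anib_matrix <- function(genomes, params = anib_params()) {
  ids <- names(genomes)
  if (length(ids) < 2) stop_input("need at least 2 genomes")
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  undef <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- anib_pair(genomes[[i]], genomes[[j]], params)
    m[i, j] <- v
    if (is.na(v)) undef <- c(undef, paste(ids[i], ids[j], sep = "->"))
  }
  if (length(undef))
    warning("ANIb undefined for pair(s): ", paste(undef, collapse = ", "))
  attr(m, "undefined_pairs") <- undef
  m
}

#' Convert an ANIb matrix to a symmetric distance matrix
#'
#' `d(i, j) = 1 - mean(ANIb(i, j), ANIb(j, i)) / 100`, zero diagonal.
#' The two directions of a pair are averaged here, preserving the raw
#' asymmetric matrix upstream.
#'
#' @param m matrix from [anib_matrix()].
#' @return symmetric distance matrix.
#' @export
ani_to_distance <- function(m) {
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop_input("ANIb matrix must have matching row/column labels")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop_input("undefined ANIb for pair(s): %s",
               paste(paste(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]],
                           sep = "->"), collapse = ", "))
  }
  d <- 1 - (m + t(m)) / 200
  diag(d) <- 0
  d
}
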