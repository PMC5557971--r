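# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, sharing no code with the package paths it
# verifies.

# Quadratic-space affine-gap local alignment, score only. Gap of length L
# costs open + L * ext.
oracle_sw_score <- function(a, b, S, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  H <- matrix(0, na + 1, nb + 1)
  E <- matrix(-Inf, na + 1, nb + 1)
  F <- matrix(-Inf, na + 1, nb + 1)
  best <- 0
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

oracle_nt_matrix <- function(match = 2, mismatch = -3) {
  S <- matrix(mismatch, 5, 5,
              dimnames = list(c("A","C","G","T","N"), c("A","C","G","T","N")))
  diag(S)[1:4] <- match
  S
}

# Exact upper-tail hypergeometric by summing binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal application of the BRBH rule: e-value gate (inclusive), best hit
# per target genome accepted only when the runner-up from that genome scores
# strictly below ratio * best, then reciprocity.
oracle_brbh <- function(hits, genome_of, max_evalue = 1e-5, ratio = 0.9) {
  accepted <- list()
  hits <- hits[genome_of[hits$qseqid] != genome_of[hits$sseqid], , drop = FALSE]
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  for (q in unique(hits$qseqid)) {
    hq <- hits[hits$qseqid == q, , drop = FALSE]
    for (tg in unique(genome_of[hq$sseqid])) {
      ht <- hq[genome_of[hq$sseqid] == tg, , drop = FALSE]
      per_subject <- tapply(ht$bitscore, ht$sseqid, max)
      ord <- order(-per_subject, names(per_subject))
      scores <- per_subject[ord]
      if (length(scores) >= 2 && !(scores[2] < ratio * scores[1])) next
      accepted[[paste(q, tg)]] <- names(scores)[1]
    }
  }
  pairs <- character(0)
  for (key in names(accepted)) {
    q <- strsplit(key, " ")[[1]][1]
    s <- accepted[[key]]
    back <- accepted[[paste(s, genome_of[[q]])]]
    if (!is.null(back) && back == q)
      pairs <- c(pairs, paste(min(q, s), max(q, s)))
  }
  sort(unique(pairs))
}

# Connected-component count / membership by explicit union-find.
oracle_components <- function(pairs) {
  nodes <- unique(c(pairs$gene_a, pairs$gene_b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[r]); rb <- find(pairs$gene_b[r])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# Textbook Pearson chi-squared statistic on a 2x2 table.
oracle_chisq_stat <- function(m, yates = FALSE) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  adj <- if (yates) pmin(abs(m - E), 0.5) else 0
  sum((abs(m - E) - adj)^2 / E)
}

# Random hit table over 3 genomes with <= `genes_per` genes each; scores
# drawn coarsely so score ties occur.
random_hit_table <- function(genes_per = 5) {
  genomes <- c("ga", "gb", "gc")
  genes <- unlist(lapply(genomes, function(g)
    paste0(g, "_", seq_len(sample.int(genes_per, 1)))))
  genome_of <- stats::setNames(sub("_.*", "", genes), genes)
  q <- character(0); s <- character(0)
  while (length(q) == 0) {
    n <- sample.int(60, 1)
    q <- sample(genes, n, replace = TRUE)
    s <- sample(genes, n, replace = TRUE)
    keep <- q != s
    q <- q[keep]; s <- s[keep]
  }
  hits <- data.frame(
    qseqid = q, sseqid = s,
    pident = runif(length(q), 30, 100), length = 100L, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 10^-sample(0:20, length(q), replace = TRUE),
    bitscore = sample(seq(50, 200, by = 10), length(q), replace = TRUE),
    stringsAsFactors = FALSE)
  attr(hits, "score_mode") <- "bit"
  list(hits = hits, genome_of = genome_of)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, TRUE), collapse = "")
}

# Substitute ~8% of residues of a protein uniformly.
mutate_protein_like <- function(s, rate = 0.08) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- sample(aa, sum(hit), TRUE)
  paste(v, collapse = "")
}

# Per-site mismatch proportion between equal-length strings.
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  100 * mean(av == bv)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

blosum80_matrix <- function() {
  e <- new.env(); utils::data("BLOSUM80", package = "Biostrings", envir = e)
  e$BLOSUM80
}
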