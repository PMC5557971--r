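#' Read a FASTA file
#'
#' Sequences are uppercased on read. Duplicate ids, empty sequences and
#' (for nucleotide files) bases outside A/C/G/T/N are rejected.
#'
#' @param path FASTA file.
#' @param type "DNA" or "AA".
#' @return a `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- names(raw)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_input("FASTA %s: record with empty header", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_input("FASTA %s: duplicate id '%s'", path, dup[1])
  wz <- Biostrings::width(raw) == 0
  if (any(wz))
    stop_input("FASTA %s: empty sequence for id '%s'", path, ids[which(wz)[1]])
  seqs <- toupper(as.character(raw))
  if (type == "DNA") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop_input("FASTA %s: invalid nucleotide characters in '%s'",
                 path, ids[which(bad)[1]])
    Biostrings::DNAStringSet(setNames(seqs, ids))
  } else {
    Biostrings::AAStringSet(setNames(seqs, ids))
  }
}

#' Write sequences as FASTA (80-column wrapping)
#'
#' @param records named character vector or `XStringSet`.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    if (is.null(names(records))) stop_input("records must be named")
    records <- Biostrings::BStringSet(records)
  }
  if (anyDuplicated(names(records)))
    stop_input("duplicate record id '%s'", names(records)[anyDuplicated(records)])
  Biostrings::writeXStringSet(records, path, width = 80L)
  invisible(path)
}

GENE_TABLE_COLS <- c("genome", "contig", "gene_id", "start", "end", "strand")

#' Read a gene table
#'
#' Tab-separated with header columns genome, contig, gene_id, start, end,
#' strand. Coordinates are 1-based inclusive; strand is "+" or "-".
#'
#' @param path TSV file.
#' @param contig_lengths optional named vector of contig lengths for bounds
#'   checking.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop_input("gene table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_gene_table(df, contig_lengths)
}

validate_gene_table <- function(df, contig_lengths = NULL) {
  miss <- setdiff(GENE_TABLE_COLS, names(df))
  if (length(miss))
    stop_input("gene table missing column(s): %s", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start)
  if (length(bad))
    stop_input("gene table row %d: invalid coordinates (1-based, start <= end)",
               bad[1])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop_input("gene table row %d: unknown strand '%s'", bad[1], df$strand[bad[1]])
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop_input("gene table row %d: duplicate gene_id '%s'", dup[1], df$gene_id[dup[1]])
  if (!is.null(contig_lengths)) {
    key <- df$contig
    unknown <- which(!key %in% names(contig_lengths))
    if (length(unknown))
      stop_input("gene table row %d: unknown contig '%s'",
                 unknown[1], key[unknown[1]])
    over <- which(df$end > contig_lengths[key])
    if (length(over))
      stop_input("gene table row %d: end beyond contig length", over[1])
  }
  df[, c(GENE_TABLE_COLS, setdiff(names(df), GENE_TABLE_COLS))]
}

#' Write a gene table as TSV
#' @param genes data.frame with the gene-table columns.
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, GENE_TABLE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read all-vs-all protein hits in BLAST tabular ("outfmt 6") dialect
#'
#' Twelve tab-separated columns, no header; scientific-notation e-values are
#' parsed; row order is preserved.
#'
#' @param path tabular hits file.
#' @return data.frame of hit records with `score_mode = "bit"` attribute.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop_input("hits file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits(internal = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  bad <- which(nc != 12L)
  if (length(bad))
    stop_input("hits file %s row %d: expected 12 columns, found %d",
               path, bad[1], nc[bad[1]])
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(hits$pident) | is.na(hits$evalue) | is.na(hits$bitscore))
  if (length(bad))
    stop_input("hits file %s row %d: non-numeric field", path, bad[1])
  if (any(hits$pident < 0 | hits$pident > 100))
    stop_input("hits file %s: percent identity outside [0, 100]", path)
  if (any(hits$evalue < 0))
    stop_input("hits file %s: negative e-value", path)
  attr(hits, "score_mode") <- "bit"
  hits
}

#' Write hits in BLAST tabular dialect
#' @param hits data.frame of hit records.
#' @param path output file.
#' @export
write_tabular_hits <- function(hits, path) {
  write.table(format(hits[, HIT_COLS], trim = TRUE, scientific = NA,
                     digits = 6),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pfam2go mapping file
#'
#' Lines of the form `Pfam:PF04234 CopC > GO:copper ion binding ; GO:0005507`;
#' lines starting with `!` are comments. One Pfam accession may map to many
#' GO ids (union over lines) and vice versa.
#'
#' @param path pfam2go flat file.
#' @return named list: Pfam accession -> character vector of GO ids.
#' @export
read_pfam2go <- function(path) {
  if (!file.exists(path)) stop_input("pfam2go file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  m <- regmatches(lines,
                  regexec("^Pfam:(PF[0-9]+)[^>]*>.*;\\s*(GO:[0-9]{7})\\s*$",
                          lines))
  bad <- which(lengths(m) != 3)
  if (length(bad))
    stop_input("pfam2go %s line %d: malformed mapping line", path, bad[1])
  pf <- vapply(m, `[`, "", 2)
  go <- vapply(m, `[`, "", 3)
  lapply(split(go, pf), unique)
}

#' Read a differential-expression table (Cuffdiff gene_exp.diff dialect)
#'
#' Requires header columns for a gene id (`gene_id`, `gene` or `test_id`),
#' `log2(fold_change)` and `q_value`; `value_1`/`value_2` are carried through
#' when present; unknown extra columns are ignored. Fold-change markers
#' "inf"/"-inf" become +/-`Inf`.
#'
#' @param path TSV file with header.
#' @return data.frame with columns gene_id, value_1, value_2,
#'   log2_fold_change, q_value.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop_input("DE table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- intersect(c("gene_id", "gene", "test_id"), names(df))
  if (length(idcol) == 0)
    stop_input("DE table %s: missing gene id column (gene_id/gene/test_id)", path)
  lfccol <- intersect(c("log2(fold_change)", "log2_fold_change"), names(df))
  if (length(lfccol) == 0)
    stop_input("DE table %s: missing column 'log2(fold_change)'", path)
  if (!"q_value" %in% names(df))
    stop_input("DE table %s: missing column 'q_value'", path)
  lfc_raw <- tolower(trimws(as.character(df[[lfccol[1]]])))
  lfc <- suppressWarnings(as.numeric(lfc_raw))
  lfc[lfc_raw %in% c("inf", "+inf")] <- Inf
  lfc[lfc_raw == "-inf"] <- -Inf
  q <- as.numeric(df$q_value)
  if (any(is.na(q) | q < 0 | q > 1))
    stop_input("DE table %s: q_value outside [0, 1]", path)
  out <- data.frame(
    gene_id = as.character(df[[idcol[1]]]),
    value_1 = if ("value_1" %in% names(df)) as.numeric(df$value_1)
              else rep(NA_real_, nrow(df)),
    value_2 = if ("value_2" %in% names(df)) as.numeric(df$value_2)
              else rep(NA_real_, nrow(df)),
    log2_fold_change = lfc,
    q_value = q,
    stringsAsFactors = FALSE)
  out
}

needs_newick_quote <- function(x) grepl("[][ \t():;,']", x)

#' Write a tree in newick format
#'
#' Branch lengths keep at least 6 significant digits; labels containing
#' whitespace or newick metacharacters are single-quoted. Unrooted trees are
#' emitted with their trifurcating root node.
#'
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  quote_idx <- which(needs_newick_quote(labs))
  if (length(quote_idx)) {
    placeholders <- sprintf("ORTHANIQ%dQ", quote_idx)
    tree$tip.label[quote_idx] <- placeholders
  }
  s <- ape::write.tree(tree, digits = digits)
  if (length(quote_idx)) {
    for (k in seq_along(quote_idx)) {
      lab <- gsub("'", "''", labs[quote_idx[k]])
      s <- sub(sprintf("ORTHANIQ%dQ", quote_idx[k]),
               paste0("'", lab, "'"), s, fixed = TRUE)
    }
  }
  writeLines(s, path)
  invisible(path)
}

#' Write / read a labeled numeric matrix as TSV
#' @param m matrix with row and column names.
#' @param path TSV file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
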