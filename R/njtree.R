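#' Neighbor-joining tree from a symmetric distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` is joined;
#' branch lengths come from the standard two-point formulas. Negative
#' estimated lengths are clamped to zero with the deficit transferred to the
#' sister branch. Ties on the minimal Q are broken by the lexicographically
#' smallest label pair (each cluster is labelled by its smallest leaf), so
#' the output does not depend on input row order. The result is unrooted
#' with a trifurcating root node.
#'
#' @param d symmetric numeric matrix with zero diagonal, labelled rows and
#'   columns, and finite entries; at least 3 taxa (2 taxa yield the single
#'   edge of length `d[1, 2]`, split evenly across the two pendant
#'   branches).
#' @return an `ape::phylo` tree with non-negative branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_input("distance matrix must be square")
  labels <- rownames(d)
  if (is.null(labels) || !identical(labels, colnames(d)))
    stop_input("distance matrix must have matching row/column labels")
  if (anyNA(d) || any(!is.finite(d)))
    stop_input("distance matrix entries must be finite")
  if (max(abs(d - t(d))) > 1e-8)
    stop_input("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop_input("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (n < 2) stop_input("need at least 2 taxa")

  fmt <- function(x) sprintf("%.15g", max(0, x))
  # trees are assembled over placeholder leaf names (t1, t2, ...) and
  # relabelled after parsing, so labels with spaces or metacharacters
  # survive intact
  relabel <- function(s) {
    tree <- ape::read.tree(text = s)
    tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
    tree
  }

  if (n == 2) {
    s <- sprintf("(t1:%s,t2:%s);", fmt(d[1, 2] / 2), fmt(d[1, 2] / 2))
    return(relabel(s))
  }

  # active clusters: newick fragment + smallest-leaf label for tie-breaks
  nwk <- sprintf("t%d", seq_len(n))
  tag <- labels
  D <- d

  while (length(tag) > 3) {
    m <- length(tag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(tag[cand[, 1]], tag[cand[, 2]])
    hi <- pmax(tag[cand[, 1]], tag[cand[, 2]])
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(0, li); lj <- max(0, lj)

    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_tag <- min(tag[i], tag[j])
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    tag <- c(tag[keep], new_tag)
  }

  if (length(tag) == 3) {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    ord <- order(tag)
    lens <- c(l1, l2, l3)[ord]
    s <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[ord[1]], fmt(lens[1]), nwk[ord[2]], fmt(lens[2]),
                 nwk[ord[3]], fmt(lens[3]))
  } else { # two clusters remain (even starting size)
    s <- sprintf("(%s:%s,%s:%s);", nwk[1], fmt(D[1, 2] / 2),
                 nwk[2], fmt(D[1, 2] / 2))
  }
  relabel(s)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree an `ape::phylo`.
#' @return symmetric matrix of leaf-to-leaf path lengths, rows/columns in
#'   sorted label order.
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(m))
  m[ord, ord]
}
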