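#' Pairwise difference counts between aligned sequences
#'
#' Entry (i, j) is the number of retained columns at which both sequences
#' carry unambiguous bases (A/C/G/T) that differ.  Masked columns, spacer
#' columns, and positions dropped by the codon filter never contribute.
#'
#' @param sm a `mito_supermatrix`.
#' @param filter a [position_filter()].
#' @param scale `"counts"` (default) or `"per_site"` (counts divided by the
#'   number of retained columns).
#' @return symmetric numeric matrix with accession dimnames.
#' @export
pairwise_differences <- function(sm, filter = position_filter("P123"),
                                 scale = c("counts", "per_site")) {
  scale <- match.arg(scale)
  cols <- retained_columns(sm, filter)
  sub <- sm$seq[, cols, drop = FALSE]
  enc <- match(sub, c("A", "C", "G", "T"), nomatch = 0L)
  dim(enc) <- dim(sub)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(rownames(sm$seq), rownames(sm$seq)))
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in (i + 1L):n) {
      xj <- enc[j, ]
      d <- sum(xi != xj & xi > 0L & xj > 0L)
      D[i, j] <- D[j, i] <- d
    }
  }
  if (scale == "per_site") D <- D / length(cols)
  D
}

#' Neighbor joining on a distance matrix
#'
#' Native implementation of the Saitou-Nei agglomeration.  Negative
#' intermediate branch lengths are clamped to zero with the deficit shifted
#' to the sibling branch; the number of clamped branches is attached as
#' attribute `"clamped"`.
#'
#' @param D symmetric distance matrix with zero diagonal (taxa dimnames).
#' @return unrooted `phylo` tree with branch lengths on the scale of `D`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  lab <- rownames(D)
  nodes <- lab   # newick fragment per active cluster
  anchor <- lab  # lexicographically smallest leaf in each cluster
  clamped <- 0L
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    hits <- which(Q - min(Q) > -1e-12 & Q - min(Q) < 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # exact ties (common with integer count distances) break on the sorted
    # anchor-label pair, so the result is independent of input order
    keys <- apply(hits, 1L, function(p)
      paste(sort(c(anchor[p[1]], anchor[p[2]])), collapse = "\r"))
    ij <- hits[order(keys)[1], ]
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0; clamped <- clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; clamped <- clamped + 1L }
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], li, nodes[j], lj)
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nodes <- c(nodes[keep], merged)
    anchor <- c(anchor[keep], min(anchor[c(i, j)]))
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(la, lb, lc), 0)
  clamped <- clamped + sum(c(la, lb, lc) < 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[1], ls[1], nodes[2], ls[2], nodes[3], ls[3])
  phy <- ape::read.tree(text = nwk)
  attr(phy, "clamped") <- clamped
  phy
}

#' Neighbor-joining tree from a supermatrix
#' @inheritParams pairwise_differences
#' @param scale passed to [pairwise_differences()]; `"counts"` reproduces
#'   NJ on counts of differences, `"per_site"` gives subs/site lengths.
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(sm, filter = position_filter("P123"), scale = "counts") {
  neighbor_joining(pairwise_differences(sm, filter, scale))
}
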