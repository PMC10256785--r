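# Internal rooted-binary tree arrays used by the tree searches.
#
# Nodes are numbered: leaves 1..n, internals n+1..2n-1; the root has degree
# 2 and an arbitrary position on the unrooted topology (reversible models
# and Fitch counts are invariant to it).  Fields:
#   kids  (m x 2 integer; 0 rows for leaves)
#   par   (integer m; 0 at the root)
#   blen  (numeric m; length of the edge above each node; NA at the root)
#   root, nleaf, labels (leaf labels, index = leaf id)

itree_new <- function(nleaf, labels) {
  m <- 2L * nleaf - 1L
  list(kids = matrix(0L, m, 2L), par = integer(m),
       blen = rep(NA_real_, m), root = nleaf + 1L,
       nleaf = nleaf, labels = labels)
}

# Internal nodes, children before parents (root last).
itree_postorder <- function(tr) {
  pre <- integer(0)
  stack <- tr$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v)
    if (tr$kids[v, 1L]) stack <- c(stack, tr$kids[v, ], recursive = TRUE)
  }
  rev(pre[pre > tr$nleaf])
}

itree_descendants <- function(tr, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, x)
    if (tr$kids[x, 1L]) stack <- c(stack, tr$kids[x, ])
  }
  out
}

itree_newick <- function(tr, digits = 12L) {
  fmt <- function(x) if (is.na(x)) "" else sprintf(":%.*g", digits, x)
  rec <- function(v) {
    if (v <= tr$nleaf) return(paste0(tr$labels[v], fmt(tr$blen[v])))
    inner <- paste(rec(tr$kids[v, 1L]), rec(tr$kids[v, 2L]), sep = ",")
    paste0("(", inner, ")", if (v == tr$root) "" else fmt(tr$blen[v]))
  }
  paste0(rec(tr$root), ";")
}

itree_to_phylo <- function(tr, unroot = TRUE) {
  phy <- ape::read.tree(text = itree_newick(tr))
  if (unroot) phy <- ape::unroot(phy)
  phy
}

# Accepts binary phylo trees, rooted or unrooted (basal trifurcation); an
# unrooted tree is rooted along its first basal child edge (length kept on
# that child, zero on the other root edge).
phylo_to_itree <- function(phy) {
  n <- length(phy$tip.label)
  if (any(tabulate(phy$edge[, 1]) > 3L) ||
      any(tabulate(phy$edge[, 1])[-(n + 1L)] > 2L))
    stop("multifurcating trees are not supported")
  nn <- phy$Nnode
  el <- if (is.null(phy$edge.length)) rep(1, nrow(phy$edge)) else phy$edge.length
  basal_kids <- phy$edge[phy$edge[, 1] == n + 1L, 2]
  if (length(basal_kids) == 2L) {            # already binary-rooted
    tr <- itree_new(n, phy$tip.label)
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
      slot <- if (tr$kids[p, 1L] == 0L) 1L else 2L
      tr$kids[p, slot] <- c
      tr$par[c] <- p
      tr$blen[c] <- el[e]
    }
    tr$root <- n + 1L
    return(tr)
  }
  if (length(basal_kids) != 3L)
    stop("unexpected root degree ", length(basal_kids))
  tr <- itree_new(n, phy$tip.label)
  newroot <- 2L * n - 1L
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    if (p == n + 1L && c == basal_kids[1]) next  # re-attached below
    slot <- if (tr$kids[p, 1L] == 0L) 1L else 2L
    tr$kids[p, slot] <- c
    tr$par[c] <- p
    tr$blen[c] <- el[e]
  }
  tr$kids[newroot, ] <- c(basal_kids[1], n + 1L)
  tr$par[basal_kids[1]] <- newroot
  tr$par[n + 1L] <- newroot
  tr$blen[basal_kids[1]] <-
    el[phy$edge[, 1] == n + 1L & phy$edge[, 2] == basal_kids[1]]
  tr$blen[n + 1L] <- 0
  tr$root <- newroot
  tr$par[newroot] <- 0L
  tr$blen[newroot] <- NA_real_
  tr
}

# One NNI: swap child `a` of internal node v with w (v's sibling, or a child
# of the opposite root child for the root edge).
itree_swap <- function(tr, a, w) {
  pa <- tr$par[a]; pw <- tr$par[w]
  tr$kids[pa, which(tr$kids[pa, ] == a)] <- w
  tr$kids[pw, which(tr$kids[pw, ] == w)] <- a
  tr$par[a] <- pw
  tr$par[w] <- pa
  tr
}

# All NNI neighbours as a list of (a, w) swap pairs.
itree_nni_moves <- function(tr) {
  moves <- list()
  for (v in seq_len(nrow(tr$kids))) {
    if (tr$kids[v, 1L] == 0L || v == tr$root) next
    u <- tr$par[v]
    if (u == tr$root) next  # handled as the root edge below
    sib <- setdiff(tr$kids[u, ], v)
    moves <- c(moves, list(c(tr$kids[v, 1L], sib), c(tr$kids[v, 2L], sib)))
  }
  rk <- tr$kids[tr$root, ]
  if (all(rk > tr$nleaf)) {
    a <- tr$kids[rk[1], 1L]
    moves <- c(moves, list(c(a, tr$kids[rk[2], 1L]), c(a, tr$kids[rk[2], 2L])))
  }
  moves
}

# SPR: prune the subtree rooted at s and regraft it onto the edge above
# `target`.  Returns NULL for degenerate/no-op combinations.
itree_spr <- function(tr, s, target) {
  root <- tr$root
  p <- tr$par[s]
  if (p == 0L) return(NULL)
  if (p == root) {
    sib <- setdiff(tr$kids[root, ], s)
    if (sib <= tr$nleaf) return(NULL)
    c12 <- tr$kids[sib, ]
    if (target %in% c12) return(NULL)          # recreates the same topology
    intree <- itree_descendants(tr, s)
    if (target %in% c(intree, root, sib)) return(NULL)
    tr$kids[root, ] <- c12
    tr$par[c12] <- root
    w <- sib                                    # freed node, reused
  } else {
    g <- tr$par[p]
    sib <- setdiff(tr$kids[p, ], s)
    if (target %in% c(sib, p)) return(NULL)
    intree <- itree_descendants(tr, s)
    if (target %in% c(intree, root)) return(NULL)
    tr$kids[g, which(tr$kids[g, ] == p)] <- sib
    tr$par[sib] <- g
    if (!is.na(tr$blen[p]) && !is.na(tr$blen[sib]))
      tr$blen[sib] <- tr$blen[sib] + tr$blen[p]
    w <- p
  }
  tp <- tr$par[target]
  tr$kids[w, ] <- c(target, s)
  tr$par[w] <- tp
  tr$kids[tp, which(tr$kids[tp, ] == target)] <- w
  tr$par[target] <- w
  tr$par[s] <- w
  half <- tr$blen[target] / 2
  tr$blen[w] <- half
  tr$blen[target] <- half
  tr
}

# Insert `leaf` on the edge above `v` (used by random stepwise addition).
itree_insert_leaf <- function(tr, v, leaf, new_internal) {
  p <- tr$par[v]
  tr$kids[new_internal, ] <- c(v, leaf)
  tr$par[new_internal] <- p
  tr$kids[p, which(tr$kids[p, ] == v)] <- new_internal
  tr$par[v] <- new_internal
  tr$par[leaf] <- new_internal
  tr$blen[new_internal] <- 1
  tr$blen[leaf] <- 1
  tr
}
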