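# Site-pattern compression shared by the parsimony and likelihood engines.
# `labels` fixes the leaf-id order (column order of the bit matrix).
make_patterns <- function(sm, filter = position_filter("P123"),
                          labels = sm$taxa$accession) {
  cols <- retained_columns(sm, filter)
  sub <- sm$seq[labels, cols, drop = FALSE]
  bits <- iupac_bits(sub)
  dim(bits) <- dim(sub)
  key <- apply(bits, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(bits = t(bits[, first, drop = FALSE]),   # npat x n
       weights = weights, labels = labels, ncols = length(cols))
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes over all retained columns, equally
#' weighted; cells with gaps or unresolved ambiguity codes behave as the
#' full state set (missing data).
#'
#' @param tree a `phylo` whose tip labels match the supermatrix accessions.
#' @param sm a `mito_supermatrix`.
#' @param filter a [position_filter()].
#' @return integer tree length.
#' @export
fitch_length <- function(tree, sm, filter = position_filter("P123")) {
  if (!setequal(tree$tip.label, sm$taxa$accession))
    stop("tree leaves and supermatrix taxa differ")
  tr <- phylo_to_itree(tree)
  pat <- make_patterns(sm, filter, labels = tr$labels)
  fitch_itree(tr, pat)
}

fitch_itree <- function(tr, pat) {
  fitch_count(pat$bits, pat$weights, itree_postorder(tr), tr$kids)
}

# ACCTRAN-style deterministic resolution of the Fitch state sets; returns
# per-node single states (bit values) for every pattern.
acctran_states <- function(tr, pat) {
  post <- itree_postorder(tr)
  m <- nrow(tr$kids)
  npat <- nrow(pat$bits)
  S <- matrix(0L, npat, m)
  S[, seq_len(tr$nleaf)] <- pat$bits
  for (v in post) {
    l <- S[, tr$kids[v, 1L]]; r <- S[, tr$kids[v, 2L]]
    inter <- bitwAnd(l, r)
    S[, v] <- ifelse(inter > 0L, inter, bitwOr(l, r))
  }
  lowbit <- function(x) bitwAnd(x, -x)
  F <- matrix(0L, npat, m)
  F[, tr$root] <- lowbit(S[, tr$root])
  for (v in rev(post)) {
    for (c in tr$kids[v, ]) {
      fp <- F[, v]
      hit <- bitwAnd(fp, S[, c]) > 0L
      F[, c] <- ifelse(hit, fp, lowbit(S[, c]))
    }
  }
  F
}

# Per-edge substitution counts under the ACCTRAN resolution; named by child
# node id (the edge above it).
acctran_edge_counts <- function(tr, pat) {
  F <- acctran_states(tr, pat)
  counts <- rep(NA_real_, nrow(tr$kids))
  for (v in seq_len(nrow(tr$kids))) {
    if (v == tr$root) next
    if (v > tr$nleaf && tr$kids[v, 1L] == 0L) next  # unused slot
    counts[v] <- sum(pat$weights * (F[, v] != F[, tr$par[v]]))
  }
  counts
}

#' Maximum parsimony search (equal weights, SPR)
#'
#' Hill-climbing subtree-prune-regraft search from random stepwise-addition
#' starting trees.  All distinct topologies attaining the best length found
#' are returned, with branch substitution counts assigned by an
#' ACCTRAN-style resolution of the Fitch ambiguity.
#'
#' @param sm a `mito_supermatrix` (at least 4 taxa).
#' @param filter a [position_filter()].
#' @param n_starts number of random-addition starts (default 10).
#' @param seed RNG seed for the addition orders.
#' @return object of class `mito_mp`: `trees` (list of `phylo`, edge lengths
#'   = ACCTRAN substitution counts), `length`, `n_starts`.
#' @export
mp_search <- function(sm, filter = position_filter("P123"), n_starts = 10L,
                      seed = 1L) {
  if (nrow(sm$seq) < 4L) stop("parsimony search needs at least 4 taxa")
  labels <- sm$taxa$accession
  pat <- make_patterns(sm, filter, labels)
  best <- list(); best_len <- Inf
  orders <- with_seed(seed, replicate(n_starts, sample(length(labels)),
                                      simplify = FALSE))
  for (ord in orders) {
    tr <- random_addition_tree(pat, ord, labels)
    res <- spr_hillclimb(tr, pat)
    if (res$len < best_len - 1e-9) {
      best <- list(res$tree); best_len <- res$len
    } else if (abs(res$len - best_len) < 1e-9) {
      best <- c(best, list(res$tree))
    }
  }
  phys <- lapply(best, itree_to_phylo)
  dup <- logical(length(phys))
  if (length(phys) > 1L) for (i in 2:length(phys))
    for (j in 1:(i - 1L)) if (!dup[j] && ape::dist.topo(phys[[i]], phys[[j]]) == 0)
      { dup[i] <- TRUE; break }
  keep <- which(!dup)
  trees <- lapply(keep, function(i) {
    tr <- best[[i]]
    tr$blen <- acctran_edge_counts(tr, pat)
    itree_to_phylo(tr)
  })
  structure(list(trees = trees, length = best_len, n_starts = n_starts),
            class = "mito_mp")
}

#' @export
print.mito_mp <- function(x, ...) {
  cat(sprintf("<mito_mp> %d minimum-length tree(s), length %d (from %d random-addition starts)\n",
              length(x$trees), as.integer(x$length), x$n_starts))
  invisible(x)
}

random_addition_tree <- function(pat, ord, labels) {
  n <- length(labels)
  tr <- itree_new(n, labels)
  t1 <- ord[1]; t2 <- ord[2]; t3 <- ord[3]
  root <- n + 1L; x <- n + 2L
  tr$kids[root, ] <- c(t1, x)
  tr$kids[x, ] <- c(t2, t3)
  tr$par[c(t1, x)] <- root
  tr$par[c(t2, t3)] <- x
  tr$blen[c(t1, t2, t3, x)] <- 1
  next_id <- n + 3L
  used <- c(t1, t2, t3, root, x)
  for (k in 4:n) {
    leaf <- ord[k]
    cand <- setdiff(used, root)
    best_v <- cand[1]; best_len <- Inf
    for (v in cand) {
      tt <- itree_insert_leaf(tr, v, leaf, next_id)
      len <- fitch_itree(tt, pat)
      if (len < best_len) { best_len <- len; best_v <- v }
    }
    tr <- itree_insert_leaf(tr, best_v, leaf, next_id)
    used <- c(used, leaf, next_id)
    next_id <- next_id + 1L
  }
  tr
}

spr_hillclimb <- function(tr, pat) {
  cur_len <- fitch_itree(tr, pat)
  repeat {
    improved <- FALSE
    nodes <- seq_len(nrow(tr$kids))
    real <- nodes[nodes <= tr$nleaf | tr$kids[nodes, 1L] > 0L]
    subtrees <- setdiff(real, tr$root)
    targets <- setdiff(real, tr$root)
    best_tr <- NULL; best_len <- cur_len
    for (s in subtrees) {
      for (v in targets) {
        tt <- itree_spr(tr, s, v)
        if (is.null(tt)) next
        len <- fitch_itree(tt, pat)
        if (len < best_len - 1e-9) { best_len <- len; best_tr <- tt }
      }
    }
    if (!is.null(best_tr)) { tr <- best_tr; cur_len <- best_len; improved <- TRUE }
    if (!improved) break
  }
  list(tree = tr, len = cur_len)
}

# Evaluate a function with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
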