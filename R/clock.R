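#' Convert a clock-tree node height to an age in Kyr
#'
#' Pure arithmetic: `age_Ka = height / (rate / 1000)`, the fixed-rate
#' strict-clock conversion applied per lineage (the divergence rate between
#' two lineages is twice the substitution rate, but node heights are already
#' per-lineage path lengths).  With the default rate, a height of 0.008234
#' subs/site dates a node at 716 Ka.
#'
#' @param height node height in substitutions/site (>= 0).
#' @param rate substitution rate in subs/site/Myr (default 0.0115).
#' @return age in Kyr (Ka).
#' @export
#' @examples
#' node_age(0.008234)          # 716.0 Ka
#' node_age(0.0115)            # 1000 Ka: unit identity
node_age <- function(height, rate = 0.0115) {
  stopifnot(rate > 0)
  if (any(height < 0)) stop("negative node height")
  height / (rate / 1000)
}

#' Linearize a rooted tree under a strict molecular clock
#'
#' Fixes the topology, roots by the designated outgroup, and re-estimates
#' node heights under ultrametric constraints.  Method `"ml"` maximizes the
#' GTR+I likelihood over node heights (root height on log scale, every
#' other internal node as a fraction of its parent's height, so nesting is
#' maintained by construction); `"ls"` is the closed-form least-squares
#' projection in which each node height is the mean of half the patristic
#' distances between the leaf pairs it joins (for a two-leaf tree with
#' branches a and b this gives (a+b)/2), with parent heights lifted where
#' needed so ages stay nested.  `"ml"` is used when an alignment is
#' supplied, otherwise `"ls"`.
#'
#' @param tree `phylo` with branch lengths in subs/site (an ML tree).
#' @param sm optional `mito_supermatrix` (required for `method = "ml"`).
#' @param outgroup tip label(s) designating the outgroup; `NULL` if `tree`
#'   is already rooted.
#' @param rate clock rate in subs/site/Myr.
#' @param method `"auto"`, `"ml"`, or `"ls"`.
#' @param params [gtr_params()] for the likelihood (default empirical).
#' @param filter a [position_filter()].
#' @return object of class `mito_clock`: `tree` (ultrametric rooted
#'   `phylo`), `heights` (per internal node, subs/site), `ages` (Ka),
#'   `rate`, `method`.
#' @export
linearize <- function(tree, sm = NULL, outgroup = NULL, rate = 0.0115,
                      method = c("auto", "ml", "ls"), params = NULL,
                      filter = position_filter("P123")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (is.null(sm)) "ls" else "ml"
  if (!is.null(outgroup)) {
    tree <- root_by_outgroup(tree, outgroup)
  } else if (!ape::is.rooted(tree)) {
    stop("tree is unrooted and no outgroup was designated")
  }
  n <- length(tree$tip.label)
  h <- ls_heights(tree)
  if (method == "ml") {
    if (is.null(sm)) stop("method 'ml' needs the alignment (sm)")
    if (is.null(params)) params <- empirical_gtr(sm, filter)
    h <- ml_heights(tree, sm, params, filter, init = h)
  }
  heights <- h  # named by node id (n+1 .. n+Nnode), tips at 0
  ct_tree <- tree
  all_h <- c(rep(0, n), heights)
  for (e in seq_len(nrow(tree$edge)))
    ct_tree$edge.length[e] <- all_h[tree$edge[e, 1]] - all_h[tree$edge[e, 2]]
  structure(list(tree = ct_tree, heights = heights,
                 ages = node_age(heights, rate), rate = rate, method = method),
            class = "mito_clock")
}

# Closed-form least-squares clock heights: height of node v = mean over leaf
# pairs whose MRCA is v of half their patristic distance; parents are then
# lifted to at least the highest child so heights stay nested.
ls_heights <- function(tree) {
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  M <- ape::mrca(tree)
  h <- vapply((n + 1L):(n + tree$Nnode), function(v) {
    sel <- M == v & upper.tri(M)
    mean(D[sel]) / 2
  }, 0)
  names(h) <- (n + 1L):(n + tree$Nnode)
  # enforce nesting bottom-up
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    if (c > n) h[as.character(p)] <- max(h[as.character(p)], h[as.character(c)])
  }
  h
}

# Constrained-ML heights: root height log-transformed, every other internal
# node a logit fraction of its parent's height.
ml_heights <- function(tree, sm, params, filter, init) {
  tr <- phylo_to_itree(tree)
  pdat <- ml_pattern_data(make_patterns(sm, filter, labels = tr$labels))
  eig <- gtr_eigen(params)
  n <- tr$nleaf
  internals <- itree_postorder(tr)
  nonroot <- setdiff(internals, tr$root)
  # map itree node ids to the phylo ids init is named by
  phy_ids <- itree_node_map(tree, tr)
  h_init <- setNames(pmax(init[as.character(phy_ids[as.character(internals)])], 1e-8),
                     as.character(internals))
  root_h <- max(h_init[as.character(tr$root)], 1e-6)
  frac <- vapply(nonroot, function(v) {
    hp <- h_init[as.character(tr$par[v])]
    min(max(h_init[as.character(v)] / max(hp, 1e-8), 1e-3), 1 - 1e-3)
  }, 0)
  enc <- c(log(root_h), stats::qlogis(frac))
  heights_from <- function(x) {
    h <- setNames(numeric(length(internals)), as.character(internals))
    h[as.character(tr$root)] <- exp(x[1])
    fr <- stats::plogis(x[-1])
    for (v in rev(internals)) {       # parents before children
      if (v == tr$root) next
      h[as.character(v)] <- h[as.character(tr$par[v])] *
        fr[match(v, nonroot)]
    }
    h
  }
  obj <- function(x) {
    h <- heights_from(x)
    tt <- tr
    for (v in seq_len(nrow(tr$kids))) {
      if (v == tr$root) next
      if (v > n && tr$kids[v, 1L] == 0L) next
      hv <- if (v <= n) 0 else h[as.character(v)]
      tt$blen[v] <- max(h[as.character(tr$par[v])] - hv, 1e-9)
    }
    -gtr_loglik_itree(tt, pdat, params, eig)
  }
  opt <- optim(enc, obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-9))
  h <- heights_from(opt$par)
  out <- setNames(h[as.character(internals)],
                  as.character(phy_ids[as.character(internals)]))
  out[order(as.integer(names(out)))]
}

#' Root an unrooted tree on the branch separating the outgroup
#'
#' Locates the split whose one side is exactly the designated outgroup and
#' places the root at the midpoint of that branch.  (Plain `ape::root` picks
#' the smallest clade containing the outgroup relative to the stored
#' arbitrary basal node, which silently misroots when that basal node sits
#' inside the outgroup.)
#'
#' @param phy `phylo` (rooted input is unrooted first).
#' @param outgroup tip label(s); must form one side of a branch.
#' @return rooted binary `phylo`.
#' @export
root_by_outgroup <- function(phy, outgroup) {
  if (!all(outgroup %in% phy$tip.label))
    stop("outgroup ", paste(setdiff(outgroup, phy$tip.label), collapse = ","),
         " absent from tree")
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  all_tips <- phy$tip.label
  if (length(outgroup) == 1L) {
    v <- match(outgroup, phy$tip.label)
  } else {
    v <- NA_integer_
    candidates <- c(seq_len(n), setdiff((n + 1L):(n + phy$Nnode), n + 1L))
    for (node in candidates) {
      tips <- phy$tip.label[tip_descendants(phy, node)]
      if (setequal(tips, outgroup) ||
          setequal(tips, setdiff(all_tips, outgroup))) { v <- node; break }
    }
    if (is.na(v))
      stop("outgroup does not form a split in the tree")
  }
  el <- phy$edge.length[phy$edge[, 2] == v]
  phytools::reroot(phy, v, position = el / 2)
}

# Match itree internal nodes to phylo internal node ids via leaf sets.
itree_node_map <- function(tree, tr) {
  n <- tr$nleaf
  phy_clades <- lapply((n + 1L):(n + tree$Nnode), function(v)
    sort(tree$tip.label[tip_descendants(tree, v)]))
  ids <- setNames(integer(0), character(0))
  for (v in itree_postorder(tr)) {
    leaves <- sort(tr$labels[itree_descendants(tr, v)[itree_descendants(tr, v) <= n]])
    hit <- which(vapply(phy_clades, identical, TRUE, y = leaves))
    ids[as.character(v)] <- if (length(hit)) n + hit[1] else NA_integer_
  }
  ids
}

# Tip indices descending from node v (small trees; simple edge walk).
tip_descendants <- function(tree, v) {
  n <- length(tree$tip.label)
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= n) out <- c(out, x)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
  }
  out
}

#' @export
print.mito_clock <- function(x, ...) {
  cat(sprintf("<mito_clock> %d-leaf ultrametric tree (%s), rate %.4g subs/site/Myr\n",
              length(x$tree$tip.label), x$method, x$rate))
  cat(sprintf("  root height %.6f subs/site = %.0f Ka; %d dated nodes\n",
              max(x$heights), max(x$ages), length(x$heights)))
  invisible(x)
}

#' Node table of a linearized clock tree
#'
#' @param ct a `mito_clock`.
#' @return data.frame: node id, clade leaf list, height (subs/site), age
#'   (Ka, rounded to the nearest integer for reporting).
#' @export
clock_table <- function(ct) {
  tree <- ct$tree
  ids <- as.integer(names(ct$heights))
  data.frame(
    node = ids,
    clade = vapply(ids, function(v)
      paste(sort(tree$tip.label[tip_descendants(tree, v)]),
            collapse = ","), ""),
    height_subs_per_site = unname(ct$heights),
    age_Ka = round(unname(ct$ages)),
    stringsAsFactors = FALSE)
}
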