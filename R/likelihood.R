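#' GTR+I substitution model parameters
#'
#' @param rates six exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (GT conventionally 1).
#' @param freqs stationary base frequencies (A, C, G, T), summing to 1.
#' @param p_inv proportion of invariant sites, in `[0, 1)`.
#' @return object of class `mito_gtr`.
#' @export
gtr_params <- function(rates = rep(1, 6), freqs = rep(0.25, 4), p_inv = 0) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(freqs) == 4L, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8,
            p_inv >= 0, p_inv < 1)
  structure(list(rates = as.numeric(rates), freqs = as.numeric(freqs),
                 p_inv = as.numeric(p_inv)),
            class = "mito_gtr")
}

#' @export
print.mito_gtr <- function(x, ...) {
  cat("<mito_gtr> rates(AC,AG,AT,CG,CT,GT) =",
      paste(signif(x$rates, 4), collapse = " "),
      "\n  freqs(A,C,G,T) =", paste(signif(x$freqs, 4), collapse = " "),
      " p_inv =", signif(x$p_inv, 4), "\n")
  invisible(x)
}

# Normalized GTR rate matrix (expected rate 1 substitution/site/unit time).
gtr_Q <- function(params) {
  r <- params$rates; pi <- params$freqs
  R <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  R[1, 2:4] <- r[1:3]; R[2, 3:4] <- r[4:5]; R[3, 4] <- r[6]
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)      # Q[i, j] = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# Eigen system of the normalized Q for fast P(t) = U exp(L t) Uinv.
gtr_eigen <- function(params) {
  Q <- gtr_Q(params)
  pi <- params$freqs
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = diag(1 / sq) %*% es$vectors, Uinv = t(es$vectors) %*% diag(sq),
       lambda = es$values)
}

gtr_P <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

# Pattern preparation for the likelihood: bitmasks plus the invariant-class
# compatibility matrix (pattern p can be an all-`b` invariant site iff every
# sequence's ambiguity set at p contains b).
ml_pattern_data <- function(pat) {
  allbits <- Reduce(bitwAnd, asplit(pat$bits, 2L))
  invcomp <- vapply(0:3, function(s) bitwAnd(allbits, bitwShiftL(1L, s)) > 0L,
                    logical(nrow(pat$bits)))
  if (nrow(pat$bits) == 1L) invcomp <- matrix(invcomp, nrow = 1L)
  c(pat, list(invcomp = invcomp))
}

# Per-edge transition matrices as one flat vector (16 slots per node).
build_P <- function(tr, params, eig) {
  m <- nrow(tr$kids)
  P <- numeric(16L * m)
  scale <- 1 - params$p_inv
  for (v in seq_len(m)) {
    if (v == tr$root || (v > tr$nleaf && tr$kids[v, 1L] == 0L)) next
    P[16L * (v - 1L) + 1:16] <- gtr_P(eig, max(tr$blen[v], 0) / scale)
  }
  P
}

# Core log-likelihood on the itree representation.  `P` may carry cached
# transition matrices (valid whenever params and branch lengths are
# unchanged; topology moves alone do not invalidate it).
gtr_loglik_itree <- function(tr, pdat, params, eig = gtr_eigen(params),
                             P = NULL) {
  if (is.null(P)) P <- build_P(tr, params, eig)
  logLvar <- pruning_loglik_patterns(pdat$bits, itree_postorder(tr), tr$kids,
                                     P, params$freqs)
  sum_pattern_loglik(pdat, params, logLvar)
}

#' GTR+I log-likelihood of a tree
#'
#' Felsenstein pruning over compressed site patterns with an invariant-site
#' mixture.  Branch lengths are expected substitutions per site averaged
#' over both site classes (so the variable class evolves at length
#' `b / (1 - p_inv)`).
#'
#' @param tree `phylo` with branch lengths in subs/site.
#' @param sm a `mito_supermatrix`.
#' @param params a [gtr_params()].
#' @param filter a [position_filter()].
#' @return log-likelihood (numeric scalar).
#' @export
gtr_log_likelihood <- function(tree, sm, params,
                               filter = position_filter("P123")) {
  if (!inherits(params, "mito_gtr")) stop("params must be a mito_gtr object")
  tr <- phylo_to_itree(tree)
  pdat <- ml_pattern_data(make_patterns(sm, filter, labels = tr$labels))
  ll <- gtr_loglik_itree(tr, pdat, params)
  if (!is.finite(ll))
    stop("non-finite log-likelihood (branch lengths: ",
         paste(signif(range(tr$blen, na.rm = TRUE), 3), collapse = ".."),
         "; p_inv ", params$p_inv, ")")
  ll
}

# Empirical starting parameters from the alignment.
empirical_gtr <- function(sm, filter = position_filter("P123")) {
  cols <- retained_columns(sm, filter)
  sub <- sm$seq[, cols, drop = FALSE]
  tab <- table(factor(sub, levels = c("A", "C", "G", "T")))
  freqs <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  const <- mean(apply(sub, 2L, function(x) {
    x <- x[x %in% c("A", "C", "G", "T")]
    length(unique(x)) <= 1L
  }))
  gtr_params(rates = c(1, 2, 1, 1, 2, 1), freqs = freqs,
             p_inv = min(0.8, const * 0.5))
}

# Coordinate-wise Brent on every free edge.  The two root-child edges form a
# single unrooted edge: its length is carried by child 1, child 2 pinned near
# zero (re-merged here because NNI moves can relocate the root children).
optimize_blens <- function(tr, pdat, params, eig) {
  k <- tr$kids[tr$root, ]
  if (!is.na(tr$blen[k[2]]) && tr$blen[k[2]] > 1e-9) {
    tr$blen[k[1]] <- tr$blen[k[1]] + tr$blen[k[2]]
  }
  tr$blen[k[2]] <- 1e-9
  P <- build_P(tr, params, eig)
  post <- itree_postorder(tr)
  scale <- 1 - params$p_inv
  for (v in seq_len(nrow(tr$kids))) {
    if (v == tr$root || v == k[2]) next
    if (v > tr$nleaf && tr$kids[v, 1L] == 0L) next
    slot <- 16L * (v - 1L) + 1:16
    f <- function(x) {
      P[slot] <- gtr_P(eig, x / scale)
      -sum_pattern_loglik(pdat, params,
                          pruning_loglik_patterns(pdat$bits, post, tr$kids, P,
                                                  params$freqs))
    }
    opt <- optimize(f, interval = c(1e-9, 3), tol = 1e-7)
    tr$blen[v] <- opt$minimum
    P[slot] <- gtr_P(eig, opt$minimum / scale)
  }
  tr
}

# Fold per-pattern variable-class log-likelihoods through the +I mixture.
sum_pattern_loglik <- function(pdat, params, logLvar) {
  if (params$p_inv > 0) {
    inv_pi <- as.numeric(pdat$invcomp %*% params$freqs)
    a <- log(params$p_inv) + log(inv_pi)
    b <- log1p(-params$p_inv) + logLvar
    ll <- ifelse(inv_pi > 0, pmax(a, b) + log1p(exp(-abs(a - b))), b)
  } else ll <- logLvar
  sum(pdat$weights * ll)
}

optimize_gtr <- function(tr, pdat, params) {
  enc <- c(log(params$rates[1:5] / params$rates[6]),
           log(params$freqs[1:3] / params$freqs[4]),
           stats::qlogis(max(params$p_inv, 1e-4)))
  dec <- function(x) {
    fr <- exp(c(x[6:8], 0)); fr <- fr / sum(fr)
    gtr_params(rates = c(exp(x[1:5]), 1), freqs = fr,
               p_inv = stats::plogis(x[9]) * 0.999)
  }
  obj <- function(x) -gtr_loglik_itree(tr, pdat, dec(x))
  opt <- optim(enc, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  dec(opt$par)
}

#' Maximum-likelihood tree search (GTR+I, NNI)
#'
#' Alternates nearest-neighbor-interchange topology moves with numeric
#' optimization of branch lengths (coordinate-wise Brent) and model
#' parameters (Nelder-Mead on transformed coordinates) until no move
#' improves the log-likelihood by more than `tol`.
#'
#' @param sm a `mito_supermatrix`.
#' @param start starting `phylo` (default: NJ tree on per-site distances).
#' @param params starting [gtr_params()] (default: empirical).
#' @param filter a [position_filter()].
#' @param tol convergence tolerance in log-likelihood units.
#' @param max_outer cap on outer iterations.
#' @param optimize_params logical; refit the GTR+I parameters (TRUE for the
#'   main search; bootstrap replicates may hold them fixed).
#' @param optimize_topology logical; set FALSE to keep the start topology
#'   and only fit branch lengths and parameters.
#' @return object of class `mito_ml`: `tree` (unrooted `phylo`, subs/site),
#'   `params`, `loglik`, `trace` (log-likelihood after each accepted step).
#' @export
ml_search <- function(sm, start = NULL, params = NULL,
                      filter = position_filter("P123"),
                      tol = 1e-6, max_outer = 20L, optimize_params = TRUE,
                      optimize_topology = TRUE) {
  if (is.null(start)) start <- nj_tree(sm, filter, scale = "per_site")
  if (is.null(params)) params <- empirical_gtr(sm, filter)
  tr <- phylo_to_itree(start)
  # a start tree without substitution-scale lengths (none at all, or values
  # far beyond plausible subs/site) keeps its topology but re-initializes
  # branch lengths; the first sweep then fits them from scratch
  bl <- tr$blen[!is.na(tr$blen)]
  if (!length(bl) || !all(is.finite(bl)) || stats::median(bl) > 0.1)
    tr$blen[!is.na(tr$blen)] <- 0.01
  tr$blen[!is.na(tr$blen) & tr$blen < 1e-8] <- 1e-8
  pdat <- ml_pattern_data(make_patterns(sm, filter, labels = tr$labels))
  eig <- gtr_eigen(params)
  ll <- gtr_loglik_itree(tr, pdat, params, eig)
  trace <- ll
  for (outer in seq_len(max_outer)) {
    ll_start <- ll
    tr <- optimize_blens(tr, pdat, params, eig)
    if (optimize_params) {
      params <- optimize_gtr(tr, pdat, params)
      eig <- gtr_eigen(params)
      tr <- optimize_blens(tr, pdat, params, eig)
    }
    ll <- gtr_loglik_itree(tr, pdat, params, eig)
    trace <- c(trace, ll)
    # NNI sweep: accept the best improving interchange, repeat to local opt
    repeat {
      if (!optimize_topology) break
      moves <- itree_nni_moves(tr)
      best <- NULL; best_ll <- ll
      Pc <- build_P(tr, params, eig)
      for (mv in moves) {
        tt <- itree_swap(tr, mv[1], mv[2])
        lt <- gtr_loglik_itree(tt, pdat, params, eig, P = Pc)
        if (lt > best_ll + 1e-9) { best_ll <- lt; best <- tt }
      }
      if (is.null(best)) break
      tr <- optimize_blens(best, pdat, params, eig)
      ll <- gtr_loglik_itree(tr, pdat, params, eig)
      trace <- c(trace, ll)
    }
    if (ll - ll_start < tol) break
  }
  phy <- itree_to_phylo(tr)
  structure(list(tree = phy, params = params, loglik = ll, trace = trace),
            class = "mito_ml")
}

#' @export
print.mito_ml <- function(x, ...) {
  cat(sprintf("<mito_ml> %d-taxon GTR+I tree, log-likelihood %.3f (%d accepted steps)\n",
              length(x$tree$tip.label), x$loglik, length(x$trace) - 1L))
  print(x$params)
  invisible(x)
}
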