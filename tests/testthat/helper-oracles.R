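# Independent brute-force oracles, deliberately naive.

# Minimum changes on a tree by exhaustive enumeration of internal states.
brute_fitch <- function(phy, mat) {
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  states <- c("A", "C", "G", "T")
  total <- 0L
  for (j in seq_len(ncol(mat))) {
    leaf <- match(mat[phy$tip.label, j], states)
    best <- Inf
    for (code in 0:(4^nn - 1)) {
      ass <- (code %/% 4^(0:(nn - 1))) %% 4 + 1
      full <- c(leaf, ass)
      changes <- sum(full[phy$edge[, 1]] != full[phy$edge[, 2]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# GTR(+I) likelihood by summation over all ancestral-state assignments,
# matrix exponentials via Matrix::expm (scaling-and-squaring Pade,
# independent of the package's eigen route).
brute_gtr_loglik <- function(phy, mat, params) {
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  states <- c("A", "C", "G", "T")
  pi <- params$freqs
  r <- params$rates
  R <- matrix(0, 4, 4)
  R[1, 2:4] <- r[1:3]; R[2, 3:4] <- r[4:5]; R[3, 4] <- r[6]
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))
  scale <- 1 - params$p_inv
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
    as.matrix(Matrix::expm(Matrix::Matrix(Q * phy$edge.length[e] / scale))))
  root <- n + 1L
  ll <- 0
  for (j in seq_len(ncol(mat))) {
    leaf <- match(mat[phy$tip.label, j], states)
    Lvar <- 0
    for (code in 0:(4^nn - 1)) {
      ass <- (code %/% 4^(0:(nn - 1))) %% 4 + 1
      full <- c(leaf, ass)
      p <- pi[full[root]]
      for (e in seq_len(nrow(phy$edge)))
        p <- p * Ps[[e]][full[phy$edge[e, 1]], full[phy$edge[e, 2]]]
      Lvar <- Lvar + p
    }
    Linv <- if (length(unique(leaf)) == 1L) pi[leaf[1]] else 0
    ll <- ll + log(params$p_inv * Linv + (1 - params$p_inv) * Lvar)
  }
  ll
}

# Least-squares branch-length fit of a fixed 4-taxon topology to a distance
# matrix; returns the residual sum of squares.
ls_fit_rss <- function(split, D) {
  # split: character(2) tips forming one cherry; remaining two form the other
  tips <- rownames(D)
  a <- split[1]; b <- split[2]; cd <- setdiff(tips, split)
  c <- cd[1]; d <- cd[2]
  # path design matrix over branches (a,b,c,d,internal)
  pairs <- t(combn(tips, 2))
  X <- t(apply(pairs, 1, function(p) {
    v <- setNames(numeric(5), c(a, b, c, d, "i"))
    v[p[1]] <- 1; v[p[2]] <- 1
    same_cherry <- all(p %in% c(a, b)) || all(p %in% c(c, d))
    if (!same_cherry) v["i"] <- 1
    v
  }))
  y <- D[cbind(pairs[, 1], pairs[, 2])]
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# Definition-level site classification of one column (>= 2 states each in
# >= 2 taxa => informative), ignoring non-ACGT cells.
classify_column_oracle <- function(col) {
  col <- col[col %in% c("A", "C", "G", "T")]
  tab <- table(col)
  if (length(tab) <= 1L) "constant"
  else if (sum(tab >= 2L) >= 2L) "parsimony_informative"
  else "variable_singleton"
}

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTWSRYKM", "TGCAWSYRMK", s), "")[[1]]),
        collapse = "")
}
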