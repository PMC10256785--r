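#' Nonparametric bootstrap support for a phylogeny
#'
#' Alignment columns retained after masking and codon-position filtering are
#' resampled with replacement; the chosen inference method is re-run on each
#' replicate under the same conditions as the point estimate, and support
#' for each internal branch of the point-estimate tree is the percentage of
#' replicate trees containing that bipartition.
#'
#' @param sm a `mito_supermatrix`.
#' @param method `"NJ"`, `"MP"`, or `"ML"`.
#' @param B number of replicates (the study scale is 3000; tests and small
#'   runs use far fewer).
#' @param seed RNG seed driving the column resampling.
#' @param filter a [position_filter()].
#' @param tree optional precomputed point-estimate `phylo`; computed with
#'   `method` when missing.
#' @param control list of method settings: `mp_starts` (random-addition
#'   starts per replicate), `ml_max_outer`, `ml_optimize_params`.
#' @return object of class `mito_boot`: `tree` (point estimate with
#'   `node.label` percent support), `support`, `B`, `method`.
#' @export
bootstrap <- function(sm, method = c("NJ", "MP", "ML"), B = 100L, seed = 1L,
                      filter = position_filter("P123"), tree = NULL,
                      control = list()) {
  method <- match.arg(method)
  stopifnot(B >= 1L)
  ctl <- modifyList(list(mp_starts = 2L, ml_max_outer = 3L,
                         ml_optimize_params = FALSE), control)
  infer <- function(smx, i) {
    switch(method,
           NJ = nj_tree(smx, filter),
           MP = mp_search(smx, filter, n_starts = ctl$mp_starts,
                          seed = seed + i)$trees[[1]],
           ML = ml_search(smx, filter = filter, max_outer = ctl$ml_max_outer,
                          optimize_params = ctl$ml_optimize_params)$tree)
  }
  if (is.null(tree)) tree <- infer(sm, 0L)
  cols <- retained_columns(sm, filter)
  reps <- with_seed(seed, lapply(seq_len(B), function(i) {
    samp <- sample(cols, length(cols), replace = TRUE)
    infer(resample_supermatrix(sm, samp), i)
  }))
  class(reps) <- "multiPhylo"
  tree2 <- tree
  counts <- ape::prop.clades(tree2, reps, rooted = FALSE)
  support <- 100 * counts / B
  tree2$node.label <- round(support, 1)
  structure(list(tree = tree2, support = support, B = B, method = method),
            class = "mito_boot")
}

# A supermatrix whose columns are an arbitrary resample of another's;
# masks are empty because masking happened before resampling.
resample_supermatrix <- function(sm, columns) {
  structure(list(seq = sm$seq[, columns, drop = FALSE],
                 taxa = sm$taxa,
                 partitions = data.frame(gene = "resampled", start = 1L,
                                         end = length(columns),
                                         strand = "heavy",
                                         stringsAsFactors = FALSE),
                 excluded = integer(), spacer = integer(),
                 codon_pos = sm$codon_pos[columns],
                 reference = sm$reference),
            class = "mito_supermatrix")
}

#' @export
print.mito_boot <- function(x, ...) {
  s <- x$support[!is.na(x$support)]
  cat(sprintf("<mito_boot> %s, %d replicates: support median %.0f%%, min %.0f%%\n",
              x$method, x$B, stats::median(s), min(s)))
  invisible(x)
}
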