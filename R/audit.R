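#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique leaf-to-leaf
#' path; on MP trees with ACCTRAN edge counts the entries are substitution
#' counts, matching how within- and between-subspecies differences are
#' reported.
#'
#' @param tree `phylo` with branch lengths.
#' @return symmetric matrix, tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  as.matrix(stats::cophenetic(tree))
}

#' Within- versus between-label patristic comparisons
#'
#' For every taxon label the maximum patristic distance among its members
#' (undefined, reported NA, for single-member labels), and for every label
#' pair the minimum and maximum between-label distance together with the
#' diagnostic boolean `between_max_lt_within`: is the largest distance
#' between the two labels smaller than the largest within-label distance of
#' either?  TRUE flags nominal taxa less differentiated than the variation
#' inside their relatives, the signature used to argue for synonymy.
#'
#' @param tree `phylo` with branch lengths.
#' @param labels named character vector `accession -> label` (defaults to
#'   everything before the first underscore of each tip label).
#' @return object of class `mito_patristic`: `within`, `between`, `pairs`.
#' @export
within_between_report <- function(tree, labels = NULL) {
  D <- patristic_matrix(tree)
  labels <- resolve_labels(tree, labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 labels")
  labs <- sort(unique(labels))
  within <- data.frame(label = labs,
                       n = as.integer(table(labels)[labs]),
                       max_within = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(labs)) {
    mem <- names(labels)[labels == labs[k]]
    if (length(mem) >= 2L)
      within$max_within[k] <- max(D[mem, mem])
  }
  combs <- utils::combn(labs, 2L)
  between <- data.frame(label1 = combs[1, ], label2 = combs[2, ],
                        min_between = NA_real_, max_between = NA_real_,
                        between_max_lt_within = NA, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    m1 <- names(labels)[labels == combs[1, k]]
    m2 <- names(labels)[labels == combs[2, k]]
    sub <- D[m1, m2, drop = FALSE]
    between$min_between[k] <- min(sub)
    between$max_between[k] <- max(sub)
    wmax <- suppressWarnings(max(within$max_within[within$label %in% combs[, k]],
                                 na.rm = TRUE))
    if (is.finite(wmax))
      between$between_max_lt_within[k] <- between$max_between[k] < wmax
  }
  pairs <- data.frame(acc1 = rep(rownames(D), ncol(D)),
                      acc2 = rep(colnames(D), each = nrow(D)),
                      distance = as.vector(D), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$acc1 < pairs$acc2, ]
  rownames(pairs) <- NULL
  structure(list(within = within, between = between, pairs = pairs),
            class = "mito_patristic")
}

#' @export
print.mito_patristic <- function(x, ...) {
  cat("<mito_patristic> within-label maxima:\n")
  print(x$within, row.names = FALSE)
  cat("between-label extremes:\n")
  print(x$between, row.names = FALSE)
  invisible(x)
}

resolve_labels <- function(tree, labels) {
  if (is.null(labels))
    labels <- setNames(sub("_.*$", "", tree$tip.label), tree$tip.label)
  if (is.data.frame(labels))
    labels <- setNames(labels$taxon_label, labels$accession)
  if (!all(tree$tip.label %in% names(labels)))
    stop("labels missing for some tips")
  labels[tree$tip.label]
}

#' Flag probably misassigned taxon labels
#'
#' A leaf is a misassignment candidate when its local neighbourhood in the
#' tree is majority-labeled with one foreign multi-member label (the leaf's
#' side of every split is scanned, smallest neighbourhood first, until one
#' returns a strict majority verdict -- a rooting-invariant generalization
#' of walking up the clades containing the leaf), and the leaf sits closer
#' (patristic) to that foreign label's members than to any member of its
#' own label.
#' Candidates are confirmed greedily, strongest evidence first (largest
#' d_own/d_foreign ratio); each confirmed flag removes that leaf from the
#' trusted member sets and the scan repeats, so a pair of swapped labels
#' cannot shield each other and a flagged stray cannot drag honest
#' neighbours into the list.  By default only leaves whose own label has at
#' least two members are eligible: a single-sequence label placed inside
#' another label's clade reads as legitimate nested phylogeographic
#' structure, not error; `strict = TRUE` lifts that requirement.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param labels named vector `accession -> label` (see
#'   [within_between_report()]).
#' @param strict also audit single-member labels.
#' @return data.frame of flags: accession, flag, nearest_label,
#'   d_foreign, d_own (one row per flagged leaf; zero rows when clean).
#' @export
flag_misassigned <- function(tree, labels = NULL, strict = FALSE) {
  if (!ape::is.rooted(tree))
    stop("misassignment flagging needs a rooted tree (root by outgroup first)")
  D <- patristic_matrix(tree)
  labels <- resolve_labels(tree, labels)
  flagged <- list()
  repeat {
    cand <- flag_misassigned_pass(tree, labels, D, strict,
                                  exclude = names(flagged))
    cand <- cand[!cand$accession %in% names(flagged), , drop = FALSE]
    if (!nrow(cand)) break
    ratio <- cand$d_own / cand$d_foreign
    ratio[is.na(ratio)] <- Inf
    best <- cand[which.max(ratio), , drop = FALSE]
    flagged[[best$accession]] <- best
  }
  if (length(flagged)) {
    out <- do.call(rbind, unname(flagged))
    rownames(out) <- NULL
    out[order(out$accession), , drop = FALSE]
  } else {
    data.frame(accession = character(), flag = character(),
               nearest_label = character(), d_foreign = numeric(),
               d_own = numeric(), stringsAsFactors = FALSE)
  }
}

flag_misassigned_pass <- function(tree, labels, D, strict, exclude) {
  trusted <- labels[setdiff(names(labels), exclude)]
  n <- length(tree$tip.label)
  clade_sets <- lapply((n + 1L):(n + tree$Nnode), function(v)
    tree$tip.label[tip_descendants(tree, v)])
  clade_sets <- c(clade_sets, as.list(tree$tip.label))
  flags <- list()
  for (acc in setdiff(tree$tip.label, exclude)) {
    own_label <- labels[[acc]]
    eligible <- strict ||
      length(setdiff(names(labels)[labels == own_label], acc)) >= 1L
    if (!eligible) next
    # scan the leaf's side of every tree split, smallest neighbourhood
    # first, until one returns a strict majority label verdict; using both
    # sides of each split makes the verdict rooting-invariant, so a leaf
    # lying in the basal (outgroup-side) grade is judged like any other
    hoods <- lapply(clade_sets, function(C) {
      N <- if (acc %in% C) C else setdiff(tree$tip.label, C)
      setdiff(intersect(N, names(trusted)), acc)
    })
    hoods <- unique(hoods[order(lengths(hoods))])
    verdict <- NULL
    for (others in hoods) {
      if (length(others) < 2L) next
      tab <- sort(table(trusted[others]), decreasing = TRUE)
      if (tab[1] * 2L > length(others)) { verdict <- names(tab)[1]; break }
    }
    if (is.null(verdict) || verdict == own_label) next
    fmem <- names(trusted)[trusted == verdict]
    if (length(fmem) < 2L) next
    own <- setdiff(names(trusted)[trusted == own_label], acc)
    d_own <- if (length(own)) min(D[acc, own]) else Inf
    d_for <- min(D[acc, fmem])
    if (d_for < d_own) {
      flags[[length(flags) + 1L]] <- data.frame(
        accession = acc, flag = "misassigned", nearest_label = verdict,
        d_foreign = d_for, d_own = if (is.finite(d_own)) d_own else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(accession = character(), flag = character(),
               nearest_label = character(), d_foreign = numeric(),
               d_own = numeric(), stringsAsFactors = FALSE)
}

#' Runs of exclusively shared parsimony-informative sites for a pair
#'
#' Scans the parsimony-informative columns of the alignment for maximal
#' runs at which the two sequences share an unambiguous state carried by no
#' other taxon.  Faulty (chimeric) sequence pairs announce themselves as
#' long such runs; honest relatives produce only short ones.  `mode
#' "informative"` (default) counts adjacency in the sequence of informative
#' columns; `"alignment"` additionally requires the columns to be adjacent
#' in alignment coordinates.
#'
#' @param sm a `mito_supermatrix`.
#' @param pair character vector of two accessions.
#' @param mode `"informative"` or `"alignment"`.
#' @param sites optional precomputed [classify_sites()] result for `sm`
#'   (saves recomputation in all-pairs scans).
#' @return data.frame of maximal runs: start, end (alignment columns),
#'   length (number of exclusive informative sites in the run).
#' @export
informative_run_scan <- function(sm, pair, mode = c("informative", "alignment"),
                                 sites = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% rownames(sm$seq)))
    stop("unknown accession: ", paste(setdiff(pair, rownames(sm$seq)), collapse = ","))
  if (is.null(sites)) sites <- classify_sites(sm)
  inf_cols <- sites$retained[sites$category == "parsimony_informative"]
  if (!length(inf_cols))
    return(data.frame(start = integer(), end = integer(), length = integer()))
  a <- sm$seq[pair[1], inf_cols]
  b <- sm$seq[pair[2], inf_cols]
  others <- sm$seq[setdiff(rownames(sm$seq), pair), inf_cols, drop = FALSE]
  shared <- a == b & a %in% c("A", "C", "G", "T")
  exclusive <- shared & colSums(others == rep(a, each = nrow(others))) == 0L
  runs <- rle(exclusive)
  out <- list()
  pos <- cumsum(c(1L, runs$lengths))
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    idx <- pos[k]:(pos[k] + runs$lengths[k] - 1L)
    segs <- if (mode == "alignment") split(idx, cumsum(c(1L, diff(inf_cols[idx]) != 1L)))
            else list(idx)
    for (sg in segs)
      out[[length(out) + 1L]] <- data.frame(start = inf_cols[sg[1]],
                                            end = inf_cols[sg[length(sg)]],
                                            length = length(sg))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), length = integer())
}

#' Full taxonomic audit of a dataset
#'
#' Combines [flag_misassigned()] with an all-pairs [informative_run_scan()]:
#' pairs with an exclusive informative run of at least `run_threshold` sites
#' yield `chimeric_run` flags, and a chimeric pair whose members also sit
#' further from every member of their own label than that label's internal
#' maximum is additionally flagged `attraction_outlier` (branch attraction
#' between two faulty sequences).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sm the supermatrix the tree came from.
#' @param labels named vector `accession -> label`.
#' @param run_threshold minimum exclusive run length for a chimeric flag
#'   (default 5; the diagnostic faulty pair in real data shows runs of 7).
#' @param strict passed to [flag_misassigned()].
#' @return data.frame of class `mito_audit`: accession, flag, evidence.
#' @export
audit_report <- function(tree, sm, labels = NULL, run_threshold = 5L,
                         strict = FALSE) {
  labels <- resolve_labels(tree, labels)
  mis <- flag_misassigned(tree, labels, strict)
  rows <- if (nrow(mis))
    data.frame(accession = mis$accession, flag = mis$flag,
               evidence = sprintf("nearest=%s d_foreign=%.4g d_own=%.4g",
                                  mis$nearest_label, mis$d_foreign, mis$d_own),
               stringsAsFactors = FALSE)
  else data.frame(accession = character(), flag = character(),
                  evidence = character(), stringsAsFactors = FALSE)
  D <- patristic_matrix(tree)
  accs <- rownames(sm$seq)
  wb <- within_between_report(tree, labels)
  sites <- classify_sites(sm)
  for (i in seq_len(length(accs) - 1L)) for (j in (i + 1L):length(accs)) {
    pr <- c(accs[i], accs[j])
    runs <- informative_run_scan(sm, pr, sites = sites)
    long <- runs[runs$length >= run_threshold, , drop = FALSE]
    if (!nrow(long)) next
    for (k in 1:2) {
      acc <- pr[k]
      ev <- paste(sprintf("run %d-%d (%d sites) shared with %s", long$start,
                          long$end, long$length, pr[3 - k]), collapse = "; ")
      rows <- rbind(rows, data.frame(accession = acc, flag = "chimeric_run",
                                     evidence = ev, stringsAsFactors = FALSE))
      own_label <- labels[[acc]]
      own <- setdiff(names(labels)[labels == own_label], acc)
      wmax <- wb$within$max_within[wb$within$label == own_label]
      if (length(own) && length(wmax) && !is.na(wmax) &&
          min(D[acc, own]) > wmax) {
        rows <- rbind(rows, data.frame(
          accession = acc, flag = "attraction_outlier",
          evidence = sprintf("d_own_min=%.4g > within_max=%.4g (partner %s)",
                             min(D[acc, own]), wmax, pr[3 - k]),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(rows, class = c("mito_audit", "data.frame"))
}

#' @export
print.mito_audit <- function(x, ...) {
  if (!nrow(x)) cat("<mito_audit> no flags: dataset looks clean\n")
  else {
    cat(sprintf("<mito_audit> %d flag(s):\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
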