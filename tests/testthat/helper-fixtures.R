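# Shared fixtures, built once per test run.

# A supermatrix object straight from a character matrix (rows = taxa).
make_sm <- function(mat, labels = NULL, reference = rownames(mat)[1]) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (is.null(labels)) labels <- rownames(mat)
  structure(list(
    seq = mat,
    taxa = data.frame(accession = rownames(mat), taxon_label = labels,
                      stringsAsFactors = FALSE),
    partitions = data.frame(gene = "GENE", start = 1L, end = ncol(mat),
                            strand = "heavy", stringsAsFactors = FALSE),
    excluded = integer(), spacer = integer(),
    codon_pos = rep_len(1:3, ncol(mat)), reference = reference),
    class = "mito_supermatrix")
}

seq_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

.fx <- new.env()

# 3 clades x 3 leaves, full gene layout: the small workhorse dataset.
small_config <- function(seed = 11, ...) {
  sim_config(n_clades = 3L, leaves_per_clade = 3L,
             clade_ages = c(780, 540), crown_age = 100,
             clade_labels = c("mellifera", "jemenitica", "scutellata"),
             seed = seed, ...)
}

small_dataset <- function() {
  if (is.null(.fx$small)) .fx$small <- simulate_dataset(small_config())
  .fx$small
}

small_supermatrix <- function() {
  if (is.null(.fx$small_sm))
    .fx$small_sm <- build_supermatrix(unname(small_dataset()$genomes))
  .fx$small_sm
}

preset_dataset <- function() {
  if (is.null(.fx$preset)) .fx$preset <- simulate_dataset(sim_config(seed = 7))
  .fx$preset
}

preset_supermatrix <- function() {
  if (is.null(.fx$preset_sm))
    .fx$preset_sm <- build_supermatrix(unname(preset_dataset()$genomes))
  .fx$preset_sm
}

outgroup_accessions <- function(truth, clade = "mellifera") {
  truth$taxa$accession[truth$taxa$clade == clade]
}

tip_desc_test <- function(tree, v) {
  n <- length(tree$tip.label)
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= n) out <- c(out, x)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
  }
  out
}

# Pair estimated clock-node ages with true simulated ages via clade leaf sets.
align_node_ages <- function(ct, true_phy, true_ages) {
  key_of <- function(tree, ids) vapply(ids, function(v)
    paste(sort(tree$tip.label[tip_desc_test(tree, v)]), collapse = ","), "")
  est_tree <- ct$tree
  ne <- length(est_tree$tip.label)
  est_ids <- as.integer(names(ct$ages))
  est_keys <- key_of(est_tree, est_ids)
  nt <- length(true_phy$tip.label)
  true_ids <- (nt + 1L):(nt + true_phy$Nnode)
  true_keys <- key_of(true_phy, true_ids)
  shared <- intersect(est_keys, true_keys)
  data.frame(
    est = unname(ct$ages[match(shared, est_keys)]),
    true = unname(true_ages[match(shared, true_keys)]))
}
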