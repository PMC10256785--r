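test_that("site classification matches the definition on exhaustive 4-taxon columns", {
  states <- c("A", "C", "G", "T")
  cols <- expand.grid(states, states, states, states, stringsAsFactors = FALSE)
  m <- t(as.matrix(cols))
  rownames(m) <- paste0("t", 1:4)
  sm <- make_sm(m)
  got <- as.character(classify_sites(sm)$category)
  want <- apply(m, 2, classify_column_oracle)
  expect_identical(got, unname(want))
  # gap/ambiguity cells do not create informativeness
  m2 <- seq_matrix(a = "AA", b = "AA", c = "AC", d = "-N")
  got2 <- as.character(classify_sites(make_sm(m2))$category)
  expect_identical(got2, c("constant", "variable_singleton"))
  expect_error(classify_sites(make_sm(m2[1:2, , drop = FALSE])), "3 taxa")
})

test_that("P12 drops third positions and never increases counts", {
  sm <- small_supermatrix()
  p123 <- classify_sites(sm, position_filter("P123"))
  p12 <- classify_sites(sm, position_filter("P12"))
  expect_identical(sum(p12$counts),
                   length(retained_columns(sm, position_filter("P12"))))
  expect_true(all(p12$counts <= p123$counts))
  expect_lt(sum(p12$counts), sum(p123$counts))
})

test_that("informative-site counts are invariant to taxon and column order", {
  sm <- small_supermatrix()
  base <- classify_sites(sm)$counts
  perm <- sample(nrow(sm$seq))
  sm2 <- sm; sm2$seq <- sm$seq[perm, ]; sm2$taxa <- sm$taxa[perm, ]
  expect_identical(classify_sites(sm2)$counts, base)
  cols <- retained_columns(sm)
  shuffle <- sample(cols)
  m3 <- sm$seq[, shuffle]
  expect_identical(classify_sites(make_sm(m3))$counts, base)
})

test_that("informative fraction grows with tree height", {
  fracs <- vapply(c(0.25, 1, 4), function(mult) {
    cfg <- sim_config(n_clades = 2L, leaves_per_clade = 3L,
                      clade_ages = 600 * mult, crown_age = 150 * mult,
                      seed = 5)
    sm <- build_supermatrix(unname(simulate_dataset(cfg)$genomes))
    st <- classify_sites(sm)
    st$counts[["parsimony_informative"]] / sum(st$counts)
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("translation uses the invertebrate mitochondrial code", {
  sm <- small_supermatrix()
  aa <- translate_partition(sm)
  expect_identical(ncol(aa$aa), sum(apis_gene_table()$length_triplets))
  # independent route: Biostrings translation of the concatenated partitions
  nd3 <- sm$partitions[sm$partitions$gene == "ND3", ]
  row1 <- paste(sm$seq[1, nd3$start:nd3$end], collapse = "")
  ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(row1), genetic.code = Biostrings::getGeneticCode("5")))
  p <- aa$partitions[aa$partitions$gene == "ND3", ]
  expect_identical(paste(aa$aa[1, p$start:p$end], collapse = ""), ref)
  # codon grid: ATG -> M wherever it occurs
  expect_identical(unname(Biostrings::getGeneticCode("5")[["ATG"]]), "M")
  # codons touching the exclusion window translate to X
  nd4 <- aa$partitions[aa$partitions$gene == "ND4", ]
  masked_res <- unique(aa$aa[, nd4$end - 0:12])
  expect_true("X" %in% masked_res)
  # an all-identical matrix has zero variable amino-acid sites
  g <- small_dataset()$genomes[[1]]
  g2 <- g; g2$accession <- "C1"
  g3 <- g; g3$accession <- "C2"
  sm0 <- build_supermatrix(list(g, g2, g3))
  expect_identical(n_variable_aa(translate_partition(sm0)), 0L)
  # width not divisible by 3 errors, naming the gene
  bad <- make_sm(seq_matrix(a = "ACGTA", b = "ACGTA", c = "ACGTA"))
  bad$partitions$gene <- "ND6"
  expect_error(translate_partition(bad), "ND6")
})

test_that("a simulated alignment translates to the oracle's variable-site count", {
  sm <- small_supermatrix()
  aa <- translate_partition(sm)
  # independent scan: per residue column, >1 distinct non-X residue
  oracle <- sum(vapply(seq_len(ncol(aa$aa)), function(j) {
    col <- aa$aa[, j]; length(unique(col[col != "X"])) > 1L
  }, TRUE))
  expect_identical(n_variable_aa(aa), oracle)
  expect_gt(oracle, 0L)
})
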