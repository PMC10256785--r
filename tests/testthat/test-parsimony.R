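quartets <- lapply(list(c("t1","t2"), c("t1","t3"), c("t1","t4")), function(p)
  ape::read.tree(text = sprintf("((%s,%s),%s,%s);", p[1], p[2],
                                setdiff(paste0("t", 1:4), p)[1],
                                setdiff(paste0("t", 1:4), p)[2])))

test_that("Fitch length matches textbook cases", {
  m <- seq_matrix(t1 = "A", t2 = "A", t3 = "C", t4 = "C")
  expect_identical(fitch_length(quartets[[1]], make_sm(m)), 1)   # ((A,A),(C,C))
  expect_identical(fitch_length(quartets[[2]], make_sm(m)), 2)   # ((A,C),(A,C))
  const <- seq_matrix(t1 = "ACGT", t2 = "ACGT", t3 = "ACGT", t4 = "ACGT")
  for (q in quartets) expect_identical(fitch_length(q, make_sm(const)), 0)
  expect_error(fitch_length(quartets[[1]],
                            make_sm(seq_matrix(x = "A", y = "A", z = "C", w = "C"))),
               "differ")
})

test_that("Fitch length equals the exhaustive-labeling oracle", {
  for (seed in 1:6) {
    m <- withr::with_seed(seed, matrix(sample(c("A","C","G","T"), 4 * 20,
                                              replace = TRUE), 4, 20))
    rownames(m) <- paste0("t", 1:4)
    sm <- make_sm(m)
    for (q in quartets)
      expect_identical(fitch_length(q, sm), brute_fitch(q, m))
  }
  # and the established implementation agrees on a larger case
  sm <- small_supermatrix()
  tree <- nj_tree(sm)
  dat <- phangorn::phyDat(sm$seq[, retained_columns(sm)])
  expect_identical(fitch_length(tree, sm),
                   as.numeric(phangorn::parsimony(tree, dat, method = "fitch")))
})

test_that("ACCTRAN edge counts sum to the Fitch length", {
  sm <- small_supermatrix()
  mp <- mp_search(sm, n_starts = 2L, seed = 3)
  for (t in mp$trees)
    expect_equal(sum(t$edge.length), mp$length)
})

test_that("SPR search attains the exhaustive optimum on 6 taxa", {
  cfg <- sim_config(n_clades = 3L, leaves_per_clade = 2L,
                    clade_ages = c(780, 400), crown_age = 150, seed = 21,
                    clade_labels = c("a", "b", "c"))
  sm <- build_supermatrix(unname(simulate_dataset(cfg)$genomes))
  mp <- mp_search(sm, n_starts = 3L, seed = 1)
  all_tr <- phangorn::allTrees(6, rooted = FALSE, tip.label = rownames(sm$seq))
  best <- min(vapply(all_tr, fitch_length, 0, sm = sm))
  expect_equal(mp$length, best)
})

test_that("high-signal data recover the generating topology", {
  ds <- small_dataset()
  sm <- small_supermatrix()
  mp <- mp_search(sm, n_starts = 4L, seed = 2)
  true <- ape::unroot(ds$truth$tree)
  rfs <- vapply(mp$trees, function(t) as.numeric(ape::dist.topo(t, true)), 0)
  # every labeled clade is recovered; residual RF only at near-zero branches
  for (t in mp$trees)
    for (cl in split(ds$truth$taxa$accession, ds$truth$taxa$clade))
      expect_true(ape::is.monophyletic(t, cl))
  expect_true(any(rfs <= 2))
})

test_that("a duplicated taxon attaches as zero-length sister to its twin", {
  ds <- small_dataset()
  genomes <- unname(ds$genomes)[1:6]
  dup <- genomes[[2]]; dup$accession <- "TWIN"
  sm <- build_supermatrix(c(genomes, list(dup)))
  mp <- mp_search(sm, n_starts = 2L, seed = 4)
  for (t in mp$trees) {
    expect_true(ape::is.monophyletic(t, c(genomes[[2]]$accession, "TWIN")))
    D <- patristic_matrix(t)
    expect_equal(unname(D[genomes[[2]]$accession, "TWIN"]), 0)
  }
})

test_that("MP length never exceeds that of the NJ topology", {
  sm <- small_supermatrix()
  nj <- nj_tree(sm)
  mp <- mp_search(sm, n_starts = 2L, seed = 5)
  expect_lte(mp$length, fitch_length(nj, sm))
})

test_that("masked columns contribute nothing to tree length", {
  sm <- small_supermatrix()
  tree <- nj_tree(sm)
  base <- fitch_length(tree, sm)
  cols <- retained_columns(sm)
  sub <- sm$seq[, cols]
  const_col <- cols[which(apply(sub, 2, function(x) all(x == x[1])))[1]]
  var_col <- cols[which(apply(sub, 2, function(x) length(unique(x)) > 1L))[1]]
  sm_c <- sm; sm_c$excluded <- sort(c(sm$excluded, const_col))
  sm_v <- sm; sm_v$excluded <- sort(c(sm$excluded, var_col))
  expect_identical(fitch_length(tree, sm_c), base)
  expect_lt(fitch_length(tree, sm_v), base)
})
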