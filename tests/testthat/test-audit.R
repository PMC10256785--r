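test_that("patristic distances equal path sums on the tree", {
  cherry <- ape::read.tree(text = "(A:3,B:4);")
  expect_equal(unname(patristic_matrix(cherry)["A", "B"]), 7)
  expect_equal(unname(patristic_matrix(cherry)["A", "A"]), 0)
  # random 12-leaf tree vs an independent graph shortest-path oracle
  phy <- withr::with_seed(3, ape::rtree(12))
  D <- patristic_matrix(phy)
  g <- igraph::graph_from_edgelist(matrix(as.character(phy$edge), ncol = 2),
                                   directed = FALSE)
  igraph::E(g)$weight <- phy$edge.length
  gd <- igraph::distances(g)
  labs <- as.character(seq_len(12))
  expect_equal(unname(D[phy$tip.label, phy$tip.label]),
               unname(gd[labs, labs]), tolerance = 1e-10)
  # invariance under re-rooting
  re <- ape::root(ape::unroot(phy), outgroup = phy$tip.label[5],
                  resolve.root = TRUE)
  expect_equal(patristic_matrix(re)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
  bad <- ape::read.tree(text = "(A,B,C);")
  expect_error(patristic_matrix(bad), "branch lengths")
})

test_that("within/between report separates tight distant clades", {
  cfg <- sim_config(n_clades = 2L, leaves_per_clade = 4L, clade_ages = 700,
                    crown_age = 80, clade_labels = c("north", "south"),
                    seed = 19)
  ds <- simulate_dataset(cfg)
  sm <- build_supermatrix(unname(ds$genomes))
  tree <- nj_tree(sm)
  rep <- within_between_report(tree, ds$truth$taxa)
  expect_identical(nrow(rep$between), 1L)
  expect_gt(rep$between$min_between, max(rep$within$max_within))
  expect_identical(rep$between$between_max_lt_within, FALSE)
  # every sequence its own label: within section all NA
  solo <- setNames(ds$truth$taxa$accession, ds$truth$taxa$accession)
  rep2 <- within_between_report(tree, solo)
  expect_true(all(is.na(rep2$within$max_within)))
})

test_that("injected mislabels are recovered exactly, clean data yield no flags", {
  cfg <- small_config(seed = 23, mislabels = 2L)
  ds <- simulate_dataset(cfg)
  sm <- build_supermatrix(unname(ds$genomes))
  labels <- setNames(ds$truth$taxa$taxon_label, ds$truth$taxa$accession)
  og <- setdiff(outgroup_accessions(ds$truth), ds$truth$anomalies$accession)[1]
  tree <- ape::root(nj_tree(sm), outgroup = og, resolve.root = TRUE)
  flags <- flag_misassigned(tree, labels)
  injected <- ds$truth$anomalies$accession[ds$truth$anomalies$type == "mislabel"]
  expect_setequal(flags$accession, injected)
  # evidence points to the true clade
  for (i in seq_len(nrow(flags))) {
    truth_clade <- ds$truth$taxa$clade[ds$truth$taxa$accession == flags$accession[i]]
    expect_identical(flags$nearest_label[i], truth_clade)
    expect_lt(flags$d_foreign[i], flags$d_own[i])
  }
  # the clean version of the same dataset has nothing to flag
  ds0 <- simulate_dataset(small_config(seed = 23))
  sm0 <- build_supermatrix(unname(ds0$genomes))
  tree0 <- ape::root(nj_tree(sm0),
                     outgroup = outgroup_accessions(ds0$truth)[1],
                     resolve.root = TRUE)
  expect_identical(nrow(flag_misassigned(tree0, setNames(
    ds0$truth$taxa$taxon_label, ds0$truth$taxa$accession))), 0L)
})

test_that("nested single-member labels are accepted unless strict", {
  # a lone label placed inside a foreign clade, like a nested subspecies
  cfg <- sim_config(n_clades = 2L, leaves_per_clade = c(3L, 4L),
                    clade_ages = 700, crown_age = 100,
                    clade_labels = c("out", "host"), seed = 29)
  ds <- simulate_dataset(cfg)
  sm <- build_supermatrix(unname(ds$genomes))
  labels <- setNames(ds$truth$taxa$taxon_label, ds$truth$taxa$accession)
  host <- ds$truth$taxa$accession[ds$truth$taxa$clade == "host"]
  labels[host[2]] <- "nested_single"
  tree <- ape::root(nj_tree(sm), outgroup = outgroup_accessions(ds$truth, "out")[1],
                    resolve.root = TRUE)
  expect_false(host[2] %in% flag_misassigned(tree, labels)$accession)
  strict <- flag_misassigned(tree, labels, strict = TRUE)
  expect_true(host[2] %in% strict$accession)
  expect_identical(strict$nearest_label[strict$accession == host[2]], "host")
})

test_that("chimeric pairs produce long exclusive runs, honest pairs do not", {
  cfg <- small_config(seed = 37, chimera = list(gene = "CO1", start = 101L,
                                                length = 600L))
  ds <- simulate_dataset(cfg)
  sm <- build_supermatrix(unname(ds$genomes))
  reg <- ds$truth$anomalies[ds$truth$anomalies$type == "chimera", ]
  pair <- reg$accession
  runs <- informative_run_scan(sm, pair)
  expect_gt(nrow(runs), 0L)
  co1 <- sm$partitions[sm$partitions$gene == "CO1", ]
  block_cols <- (co1$start + reg$start[1] - 1L):(co1$start + reg$start[1] + reg$length[1] - 2L)
  long <- runs[runs$length >= 5L, ]
  expect_gt(nrow(long), 0L)
  expect_true(all(long$start >= min(block_cols) & long$end <= max(block_cols)))
  # scan is symmetric in the pair
  expect_identical(runs, informative_run_scan(sm, rev(pair)))
  # an honest pair from different clades has only short runs
  honest <- c(setdiff(outgroup_accessions(ds$truth, "mellifera"), pair)[1],
              setdiff(outgroup_accessions(ds$truth, "scutellata"), pair)[1])
  r2 <- informative_run_scan(sm, honest)
  expect_true(nrow(r2) == 0L || max(r2$length) <= 2L)
  expect_error(informative_run_scan(sm, c("XX", "YY")), "unknown accession")
  # identical triplet: no exclusive runs
  m <- seq_matrix(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "AGGTACGA")
  expect_identical(nrow(informative_run_scan(make_sm(m), c("a", "b"))), 0L)
})

test_that("the full audit combines misassignment and chimera flags", {
  cfg <- small_config(seed = 43, mislabels = 1L,
                      chimera = list(gene = "CO3", start = 31L, length = 500L))
  ds <- simulate_dataset(cfg)
  sm <- build_supermatrix(unname(ds$genomes))
  labels <- setNames(ds$truth$taxa$taxon_label, ds$truth$taxa$accession)
  og <- setdiff(outgroup_accessions(ds$truth),
                ds$truth$anomalies$accession)[1]
  tree <- ape::root(nj_tree(sm), outgroup = og, resolve.root = TRUE)
  rep <- audit_report(tree, sm, labels)
  reg <- ds$truth$anomalies
  mis_true <- reg$accession[reg$type == "mislabel"]
  chi_true <- reg$accession[reg$type == "chimera"]
  expect_setequal(rep$accession[rep$flag == "misassigned"], mis_true)
  expect_true(all(chi_true %in% rep$accession[rep$flag == "chimeric_run"]))
  # precision: no unflagged-in-truth accession is flagged
  expect_true(all(rep$accession %in% reg$accession))
})
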