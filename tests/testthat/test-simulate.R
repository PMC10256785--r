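test_that("the same seed reproduces the dataset exactly; seeds differ", {
  a <- simulate_dataset(small_config(seed = 5))
  b <- simulate_dataset(small_config(seed = 5))
  expect_identical(lapply(a$genomes, `[[`, "sequence"),
                   lapply(b$genomes, `[[`, "sequence"))
  expect_identical(ape::write.tree(a$truth$tree), ape::write.tree(b$truth$tree))
  c <- simulate_dataset(small_config(seed = 6))
  expect_false(identical(a$genomes[[1]]$sequence, c$genomes[[1]]$sequence))
})

test_that("configured clade-split ages appear in the truth exactly", {
  cfg <- small_config(seed = 11)
  sim <- simulate_clock_tree(cfg)
  ages <- sort(unname(sim$ages), decreasing = TRUE)
  expect_equal(ages[1:2], c(780, 540))
  expect_true(all(ages[-(1:2)] <= cfg$crown_age))
  # clades are monophyletic with the right sizes
  for (cl in split(sim$taxa$accession, sim$taxa$clade)) {
    expect_length(cl, 3L)
    expect_true(ape::is.monophyletic(sim$tree, cl))
  }
  # a single two-leaf clade is a cherry with the crown age at the root
  cfg1 <- sim_config(n_clades = 1L, leaves_per_clade = 2L,
                     clade_ages = numeric(0), crown_age = 50,
                     clade_labels = "solo", seed = 2)
  sim1 <- simulate_clock_tree(cfg1)
  expect_identical(length(sim1$tree$tip.label), 2L)
  expect_equal(unname(sim1$ages), 50)
})

test_that("rate zero transmits the root sequence unchanged", {
  cfg <- sim_config(n_clades = 2L, leaves_per_clade = 2L, clade_ages = 700,
                    crown_age = 100, rate = 0, clade_labels = c("a", "b"),
                    seed = 3)
  ds <- simulate_dataset(cfg)
  seqs <- vapply(ds$genomes, `[[`, "", "sequence")
  expect_identical(length(unique(seqs)), 1L)
})

test_that("observed divergence matches the GTR expectation", {
  # one cherry at a known age: total path = 2 x crown x rate
  cfg <- sim_config(n_clades = 1L, leaves_per_clade = 2L,
                    clade_ages = numeric(0), crown_age = 400,
                    clade_labels = "pair", seed = 8)
  ds <- simulate_dataset(cfg)
  s1 <- strsplit(ds$genomes[[1]]$sequence, "")[[1]]
  s2 <- strsplit(ds$genomes[[2]]$sequence, "")[[1]]
  L <- length(s1)
  obs <- mean(s1 != s2)
  t_tot <- 2 * 400 / 1000 * cfg$rate
  expected <- expected_diff_proportion(cfg$gtr, t_tot)
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("emitted records honor the layout and strand encoding", {
  ds <- small_dataset()
  g <- ds$genomes[[1]]
  tab <- apis_gene_table()
  expect_identical(g$features$gene, tab$gene)
  expect_identical(g$features$strand, tab$strand)
  expect_identical(nchar(g$sequence),
                   sum(tab$length_bases) + 20L * (nrow(tab) + 1L))
  # registry coordinates sit inside the emitted sequences
  cfg <- small_config(seed = 37, chimera = list(gene = "CO1", start = 101L,
                                                length = 600L))
  ds2 <- simulate_dataset(cfg)
  reg <- ds2$truth$anomalies
  f <- ds2$truth$features
  for (i in which(reg$type == "chimera")) {
    fe <- f[f$gene == reg$gene[i], ]
    expect_lte(fe$start + reg$start[i] + reg$length[i] - 2L, fe$end)
  }
  # overlapping chimera blocks are rejected
  ds3 <- simulate_dataset(small_config(seed = 37))
  expect_error(
    inject_anomalies(inject_anomalies(ds3, small_config(
      seed = 37, chimera = list(gene = "CO1", start = 101L, length = 600L))),
      small_config(seed = 38, chimera = list(gene = "CO1", start = 301L,
                                             length = 200L))),
    "overlapping")
  # zero injections are the identity
  same <- inject_anomalies(ds3, small_config(seed = 37))
  expect_identical(lapply(same$genomes, `[[`, "sequence"),
                   lapply(ds3$genomes, `[[`, "sequence"))
  expect_identical(nrow(same$truth$anomalies), 0L)
})
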