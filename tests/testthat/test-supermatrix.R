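test_that("identical genomes give a supermatrix with zero variable columns", {
  g <- small_dataset()$genomes[[1]]
  g2 <- g; g2$accession <- "COPY1"
  g3 <- g; g3$accession <- "COPY2"
  sm <- build_supermatrix(list(g, g2, g3))
  st <- classify_sites(sm)
  expect_identical(unname(st$counts[["variable_singleton"]] +
                            st$counts[["parsimony_informative"]]), 0L)
})

test_that("default build has the documented geometry", {
  sm <- small_supermatrix()
  expect_identical(ncol(sm$seq), 11043L)
  expect_identical(analyzed_columns(sm), 11006L)
  # partitions disjoint, in canonical order, jointly tiling with spacers
  p <- sm$partitions
  expect_identical(p$gene, MITO_GENES)
  expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  expect_identical(sum(p$end - p$start + 1L) + length(sm$spacer), ncol(sm$seq))
  # codon positions cycle 1,2,3 within each partition
  for (i in seq_len(nrow(p)))
    expect_identical(sm$codon_pos[p$start[i]:p$end[i]],
                     rep_len(1:3, p$end[i] - p$start[i] + 1L))
  # the ND4 exclusion window sits at the 3' end of the ND4 partition
  nd4 <- p[p$gene == "ND4", ]
  expect_identical(sm$excluded, (nd4$end - 36L):nd4$end)
  # with no indels, analyzed columns = sum of simulated gene lengths - mask
  expect_identical(analyzed_columns(sm),
                   sum(apis_gene_table()$length_bases) - 37L)
})

test_that("a single-taxon triplet insertion is aligned out and masked", {
  ds <- small_dataset()
  genomes <- lapply(ds$genomes[1:4], identity)
  g <- genomes[[3]]
  f <- g$features[g$features$gene == "CO2", ]
  at <- f$start + 90L           # insertion after sense position 90 of CO2
  s <- g$sequence
  g$sequence <- paste0(substr(s, 1, at - 1L), "TGA", substr(s, at, nchar(s)))
  fe <- g$features
  fe$end[fe$gene == "CO2"] <- fe$end[fe$gene == "CO2"] + 3L
  later <- fe$start > f$end
  fe$start[later] <- fe$start[later] + 3L
  fe$end[later] <- fe$end[later] + 3L
  genomes[[3]] <- mito_genome(g$accession, g$taxon_label, g$sequence, fe)
  sm <- build_supermatrix(unname(genomes), reference = genomes[[1]]$accession)
  co2 <- sm$partitions[sm$partitions$gene == "CO2", ]
  expect_identical(co2$end - co2$start + 1L, 678L + 3L)
  ins_cols <- intersect(sm$excluded, co2$start:co2$end)
  expect_length(ins_cols, 3L)
  expect_identical(ins_cols, co2$start + 90L + 0:2)
  # everyone but the insert carrier holds gaps in the masked columns
  expect_true(all(sm$seq[-3L, ins_cols] == "-"))
  expect_true(all(sm$seq[3L, ins_cols] != "-"))
  # a larger unresolvable mismatch drops the record with a warning
  bad <- genomes[[4]]
  fe2 <- bad$features
  bad$sequence <- paste0(bad$sequence, paste(rep("A", 30), collapse = ""))
  fe2$end[fe2$gene == "ND1"] <- fe2$end[fe2$gene == "ND1"] + 30L
  genomes[[4]] <- mito_genome(bad$accession, bad$taxon_label, bad$sequence, fe2)
  expect_warning(sm2 <- build_supermatrix(unname(genomes),
                                          reference = genomes[[1]]$accession),
                 "not resolvable")
  expect_false(bad$accession %in% rownames(sm2$seq))
})

test_that("supermatrix interchange files round-trip exactly", {
  sm <- small_supermatrix()
  prefix <- file.path(withr::local_tempdir(), "aln")
  write_supermatrix(sm, prefix)
  back <- read_supermatrix(prefix)
  expect_identical(back$seq, sm$seq)
  expect_identical(back$taxa, sm$taxa)
  expect_identical(back$partitions$start, sm$partitions$start)
  expect_identical(back$partitions$end, sm$partitions$end)
  expect_identical(back$excluded, sm$excluded)
  expect_identical(back$spacer, sm$spacer)
  expect_identical(back$codon_pos, sm$codon_pos)
  expect_identical(back$reference, sm$reference)
})

test_that("ambiguity resolution follows the column consensus rules", {
  m <- seq_matrix(ref = "AATA", x = "AWTA", y = "AATW")
  sm <- make_sm(m)
  rs <- resolve_ambiguities(sm)
  # (A, W, A) -> unanimous A; column becomes invariant
  expect_identical(unname(rs$seq[, 2]), c("A", "A", "A"))
  expect_identical(unname(rs$seq[, 4]), c("A", "A", "A"))
  expect_identical(nrow(rs$resolution_log), 2L)
  # majority tie resolves to the reference row's state
  m2 <- seq_matrix(ref = "T", x = "A", y = "W")
  rs2 <- resolve_ambiguities(make_sm(m2))
  expect_identical(unname(rs2$seq[, 1]), c("T", "A", "T"))
  # a column without ambiguity codes is untouched
  m3 <- seq_matrix(a = "ACGT", b = "ACGA", c = "ACGT")
  rs3 <- resolve_ambiguities(make_sm(m3))
  expect_identical(rs3$seq, m3)
  expect_identical(nrow(rs3$resolution_log), 0L)
})

test_that("extraction commutes with the simulator's strand encoding", {
  # light-strand genes: the record stores the complement; extraction must
  # recover the evolved sense sequence, i.e. re-complementing the stored
  # slice independently gives the same string
  ds <- small_dataset()
  sm <- small_supermatrix()
  g <- ds$genomes[[2]]
  i <- match(g$accession, rownames(sm$seq))
  p <- sm$partitions[sm$partitions$gene == "ND4L", ]
  expect_identical(paste(sm$seq[i, p$start:p$end], collapse = ""),
                   revcomp_oracle(substr(g$sequence,
                                         g$features$start[g$features$gene == "ND4L"],
                                         g$features$end[g$features$gene == "ND4L"])))
})
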