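#' Simulation configuration for clock-tree mitogenome data
#'
#' The default scenario mirrors the phylogeographic structure the pipeline
#' is meant to resolve: six labeled "subspecies" clades hanging off a
#' caterpillar backbone whose split ages echo the late-Pleistocene timeline
#' (780/720/660/540/250 Ka), within-clade diversification at 100 Ka, an
#' AT-rich base composition, a transition-biased GTR model, and the
#' canonical 13-gene layout whose subspecies-level lengths total 11,043
#' coding bases.  All randomness flows from the single `seed`.
#'
#' @param n_clades number of labeled clades (each gets one backbone split).
#' @param leaves_per_clade leaves per clade (scalar or vector).
#' @param clade_ages backbone split ages in Ka, oldest first
#'   (`n_clades - 1` values).
#' @param crown_age within-clade crown age in Ka.
#' @param rate substitution rate, subs/site/Myr.
#' @param gtr a [gtr_params()] (`p_inv` is ignored by the simulator: sites
#'   evolve homogeneously).
#' @param table gene layout, see [apis_gene_table()].
#' @param intergenic bases of neutral spacer between genes (stand-in for
#'   tRNAs; evolved like everything else but not extracted).
#' @param clade_labels labels assigned to the clades, basal first.
#' @param mislabels number of leaves to reassign to a foreign clade's label.
#' @param chimera `NULL`, or `list(recipients = 2 accessions or NULL for
#'   automatic choice, gene =, start =, length =, divergence =)` describing
#'   a donor block copied over both recipients.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list of class `mito_simconfig`.
#' @export
sim_config <- function(n_clades = 6L, leaves_per_clade = 4L,
                       clade_ages = c(780, 720, 660, 540, 250),
                       crown_age = 100,
                       rate = 0.0115,
                       gtr = gtr_params(rates = c(1, 6, 1, 1, 6, 1),
                                        freqs = c(0.42, 0.10, 0.06, 0.42)),
                       table = apis_gene_table("subspecies"),
                       intergenic = 20L,
                       clade_labels = c("mellifera", "ligustica", "caucasia",
                                        "jemenitica", "scutellata",
                                        "iberiensis"),
                       mislabels = 0L, chimera = NULL, seed = 1L) {
  stopifnot(n_clades >= 1L, length(clade_ages) == n_clades - 1L,
            all(diff(clade_ages) < 0) || n_clades <= 2L,
            crown_age > 0, crown_age < min(clade_ages, Inf),
            rate >= 0, length(clade_labels) >= n_clades)
  leaves_per_clade <- rep_len(leaves_per_clade, n_clades)
  structure(list(n_clades = n_clades, leaves_per_clade = leaves_per_clade,
                 clade_ages = clade_ages, crown_age = crown_age, rate = rate,
                 gtr = gtr, table = table, intergenic = intergenic,
                 clade_labels = clade_labels[seq_len(n_clades)],
                 mislabels = mislabels, chimera = chimera, seed = seed),
            class = "mito_simconfig")
}

#' Simulate a labeled clock tree
#'
#' Clades are random-join ultrametric subtrees (uniform split times below
#' the crown age) grafted onto a caterpillar backbone at the configured
#' split ages, basal clade first.  Leaf labels are the clade labels;
#' accessions are `SYN01..`.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list: `tree` (rooted `phylo`, branch lengths in Kyr), `ages`
#'   (node ages in Ka, tips 0), `taxa` (accession, taxon_label, clade).
#' @export
simulate_clock_tree <- function(config, seed = config$seed) {
  with_seed(seed, {
    n <- sum(config$leaves_per_clade)
    labels <- character(n)
    acc <- sprintf("SYN%02d", seq_len(n))
    tr <- itree_new(n, acc)
    # one spare node row: a single-clade run allocates its top before the
    # re-rooting step frees it
    tr$kids <- rbind(tr$kids, c(0L, 0L))
    tr$par <- c(tr$par, 0L)
    tr$blen <- c(tr$blen, NA_real_)
    age <- numeric(2L * n)
    next_int <- n + 2L  # n+1 is the root
    next_leaf <- 1L
    # build one clade, return its top node id
    build_clade <- function(k) {
      nl <- config$leaves_per_clade[k]
      ids <- next_leaf:(next_leaf + nl - 1L)
      next_leaf <<- next_leaf + nl
      labels[ids] <<- config$clade_labels[k]
      if (nl == 1L) return(ids)
      times <- c(config$crown_age, runif(nl - 2L, 0, config$crown_age))
      active <- as.list(ids)
      for (t in sort(times)) {
        pick <- sample(length(active), 2L)
        v <- next_int; next_int <<- next_int + 1L
        tr$kids[v, ] <<- c(active[[pick[1]]], active[[pick[2]]])
        tr$par[tr$kids[v, ]] <<- v
        age[v] <<- t
        active <- c(active[-pick], list(v))
      }
      active[[1]]
    }
    tops <- vapply(seq_len(config$n_clades), build_clade, 0L)
    # caterpillar backbone, youngest split deepest in the list
    spine <- tops[config$n_clades]
    if (config$n_clades >= 2L) {
      for (k in (config$n_clades - 1L):1L) {
        v <- if (k == 1L) n + 1L else { id <- next_int; next_int <- next_int + 1L; id }
        tr$kids[v, ] <- c(tops[k], spine)
        tr$par[tr$kids[v, ]] <- v
        age[v] <- config$clade_ages[k]
        spine <- v
      }
    } else {
      # single clade: re-root its top as the global root
      top <- tops[1]
      tr$kids[n + 1L, ] <- tr$kids[top, ]
      tr$par[tr$kids[n + 1L, ]] <- n + 1L
      age[n + 1L] <- age[top]
      tr$kids[top, ] <- 0L
      tr$par[top] <- 0L
    }
    tr$par[n + 1L] <- 0L
    tr$root <- n + 1L
    for (v in seq_len(2L * n)) {
      if (tr$par[v] == 0L || (v > n && tr$kids[v, 1L] == 0L)) next
      tr$blen[v] <- age[tr$par[v]] - age[v]
    }
    phy <- itree_to_phylo(tr, unroot = FALSE)
    ages <- node_ages_from_itree(tr, age, phy)
    list(tree = phy, ages = ages,
         taxa = data.frame(accession = acc, taxon_label = labels,
                           clade = labels, stringsAsFactors = FALSE))
  })
}

# Carry simulated node ages over to the phylo node numbering.
node_ages_from_itree <- function(tr, age, phy) {
  n <- tr$nleaf
  out <- setNames(numeric(phy$Nnode), (n + 1L):(n + phy$Nnode))
  imap <- itree_node_map(phy, tr)
  for (v in names(imap)) if (!is.na(imap[[v]]))
    out[as.character(imap[[v]])] <- age[as.integer(v)]
  out
}

#' Evolve mitogenome sequences along a clock tree
#'
#' The root heavy-strand genome (genes in canonical order separated by
#' `intergenic` spacer bases, light-strand genes stored as reverse
#' complements of their sense sequence) is drawn from the GTR stationary
#' frequencies and evolved along each branch under the GTR rate matrix with
#' expected subs/site = rate x branch duration.  Records are annotated with
#' the true gene features, so the genome_io layer can extract and
#' re-orient every gene.
#'
#' @param sim result of [simulate_clock_tree()].
#' @param config the same [sim_config()].
#' @param seed overrides `config$seed + 1` when given.
#' @return list: `genomes` (list of [mito_genome()]), `truth` (tree, ages,
#'   taxa, anomaly registry).
#' @export
evolve_sequences <- function(sim, config, seed = config$seed + 1L) {
  tab <- config$table
  glen <- tab$length_bases
  spacer <- config$intergenic
  starts <- cumsum(c(1L + spacer, glen + spacer))[seq_len(nrow(tab))]
  total <- sum(glen) + spacer * (nrow(tab) + 1L)
  features <- data.frame(gene = tab$gene, start = starts,
                         end = starts + glen - 1L, strand = tab$strand,
                         stringsAsFactors = FALSE)
  eig <- gtr_eigen(config$gtr)
  pi <- config$gtr$freqs
  tr <- phylo_to_itree(sim$tree)
  n <- tr$nleaf
  seqs <- with_seed(seed, {
    root_seq <- sample.int(4L, total, replace = TRUE, prob = pi)
    node_seq <- vector("list", nrow(tr$kids))
    node_seq[[tr$root]] <- root_seq
    stack <- tr$root
    order <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      order <- c(order, v)
      if (tr$kids[v, 1L]) stack <- c(stack, tr$kids[v, ])
    }
    for (v in order) {
      if (v == tr$root) next
      t_sub <- max(tr$blen[v], 0) / 1000 * config$rate  # Kyr -> subs/site
      P <- gtr_P(eig, t_sub)
      parent <- node_seq[[tr$par[v]]]
      child <- parent
      for (b in 1:4) {
        idx <- which(parent == b)
        if (length(idx))
          child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
      }
      node_seq[[v]] <- child
    }
    node_seq[seq_len(n)]
  })
  bases <- c("A", "C", "G", "T")
  genomes <- lapply(seq_len(n), function(i) {
    s <- paste(bases[seqs[[i]]], collapse = "")
    mito_genome(tr$labels[i],
                sim$taxa$taxon_label[match(tr$labels[i], sim$taxa$accession)],
                s, features)
  })
  names(genomes) <- vapply(genomes, `[[`, "", "accession")
  truth <- list(tree = sim$tree, ages = sim$ages, taxa = sim$taxa,
                features = features,
                anomalies = data.frame(accession = character(),
                                       type = character(), detail = character(),
                                       gene = character(), start = integer(),
                                       length = integer(),
                                       stringsAsFactors = FALSE))
  list(genomes = genomes, truth = truth)
}

#' Inject labeled anomalies into a simulated dataset
#'
#' Mislabels reassign randomly chosen leaves the label of a foreign clade;
#' the truth registry keeps the real clade, so recovery can be scored.  A
#' chimera copies one contiguous donor block -- a "ghost" haplotype mutated
#' away from a reference genome at `divergence` subs/site (default 0.2, a
#' grossly corrupted foreign block well outside natural variation) -- over
#' the same gene region of both recipient genomes, emulating a faulty
#' submission pair that attracts in trees and shares long exclusive runs of
#' informative sites.
#'
#' @param dataset result of [evolve_sequences()].
#' @param config the [sim_config()].
#' @param seed overrides `config$seed + 2` when given.
#' @return the dataset with modified genomes/taxa and updated registry.
#' @export
inject_anomalies <- function(dataset, config, seed = config$seed + 2L) {
  genomes <- dataset$genomes; truth <- dataset$truth
  with_seed(seed, {
    if (config$mislabels > 0L) {
      clades <- truth$taxa$clade
      k <- config$mislabels
      if (k > nrow(truth$taxa)) stop("more mislabels than leaves")
      victims <- sample(truth$taxa$accession, k)
      for (acc in victims) {
        own <- clades[truth$taxa$accession == acc]
        target <- sample(setdiff(unique(clades), own), 1L)
        i <- match(acc, truth$taxa$accession)
        truth$taxa$taxon_label[i] <- target
        genomes[[acc]]$taxon_label <- target
        truth$anomalies <- rbind(truth$anomalies, data.frame(
          accession = acc, type = "mislabel",
          detail = sprintf("true=%s assigned=%s", own, target),
          gene = NA_character_, start = NA_integer_, length = NA_integer_,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(config$chimera)) {
      ch <- modifyList(list(recipients = NULL, gene = "CO1", start = 101L,
                            length = 600L, divergence = 0.2), config$chimera)
      if (is.null(ch$recipients)) {
        cl <- split(truth$taxa$accession, truth$taxa$clade)
        cl <- cl[lengths(cl) >= 1L]
        ch$recipients <- c(cl[[1]][1], cl[[length(cl)]][1])
      }
      f <- truth$features[truth$features$gene == ch$gene, ]
      if (!nrow(f)) stop("chimera gene ", ch$gene, " not in layout")
      gstart <- f$start + ch$start - 1L
      gend <- gstart + ch$length - 1L
      if (gend > f$end) stop("chimera block extends past gene ", ch$gene)
      prev <- truth$anomalies[truth$anomalies$type == "chimera", , drop = FALSE]
      if (nrow(prev) && any(prev$gene == ch$gene &
                            prev$start < ch$start + ch$length &
                            ch$start < prev$start + prev$length))
        stop("overlapping chimera blocks")
      # ghost donor: root-adjacent haplotype at the requested divergence
      eig <- gtr_eigen(config$gtr)
      P <- gtr_P(eig, ch$divergence)
      donor_src <- strsplit(genomes[[truth$taxa$accession[1]]]$sequence, "")[[1]]
      enc <- match(donor_src[gstart:gend], c("A", "C", "G", "T"))
      for (b in 1:4) {
        idx <- which(enc == b)
        if (length(idx))
          enc[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
      }
      block <- paste(c("A", "C", "G", "T")[enc], collapse = "")
      for (acc in ch$recipients) {
        s <- genomes[[acc]]$sequence
        genomes[[acc]]$sequence <- paste0(substr(s, 1L, gstart - 1L), block,
                                          substr(s, gend + 1L, nchar(s)))
        truth$anomalies <- rbind(truth$anomalies, data.frame(
          accession = acc, type = "chimera",
          detail = sprintf("partner=%s", setdiff(ch$recipients, acc)[1]),
          gene = ch$gene, start = ch$start, length = ch$length,
          stringsAsFactors = FALSE))
      }
    }
  })
  list(genomes = genomes, truth = truth)
}

#' Simulate a complete annotated mitogenome dataset
#'
#' Convenience wrapper: [simulate_clock_tree()], [evolve_sequences()], and
#' [inject_anomalies()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list: `genomes`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_clock_tree(config)
  dataset <- evolve_sequences(sim, config)
  inject_anomalies(dataset, config)
}

#' Expected proportion of differing sites between two sequences
#'
#' Closed-form GTR expectation `sum_i pi_i (1 - P(t)_ii)` at total path
#' length `t` subs/site; used to check the simulator against theory.
#'
#' @param params a [gtr_params()].
#' @param t total path length between the two sequences, subs/site.
#' @export
expected_diff_proportion <- function(params, t) {
  P <- gtr_P(gtr_eigen(params), t)
  sum(params$freqs * (1 - diag(P)))
}
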