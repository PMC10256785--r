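#' Build a concatenated coding-region supermatrix
#'
#' Genes are extracted in sense orientation ([extract_coding_region()]),
#' aligned positionally against a designated reference genome, and
#' concatenated in canonical 5'->3' gene order.  Length differences of
#' exactly one triplet relative to the reference are resolved by a
#' best-match single-triplet indel: an insertion carried by a taxon expands
#' the alignment by 3 gap-filled columns which are added to the exclusion
#' mask (autapomorphic triplet insertions carry no signal and are removed
#' from every downstream statistic); a deletion becomes a 3-base gap in that
#' taxon.  Larger unresolvable length mismatches exclude the record with a
#' warning.  A configurable window of the ND4 partition (by default its
#' final 37 columns, a region hard to align across subspecies) is also
#' masked.  Gene partitions whose width is not a multiple of 3 are padded
#' with all-gap spacer columns so every partition starts in frame.
#'
#' @param genomes list of [mito_genome()] records.
#' @param table gene layout, see [apis_gene_table()].
#' @param reference accession of the alignment reference (default: first
#'   record).
#' @param exclude_window `list(gene=, width=, offset=)` masked window
#'   anchored at the 3' end of the named partition (`offset` columns in from
#'   the 3' end); `NULL` disables.
#' @param aligned_genes optional named list `gene -> named character vector`
#'   of externally aligned per-gene sequences (accession-named, equal
#'   lengths), overriding positional alignment for those genes.
#' @param tolerance per-gene length tolerance passed to
#'   [extract_coding_region()].
#' @return object of class `mito_supermatrix`: fields `seq` (taxa x columns
#'   character matrix), `taxa` (accession, taxon_label), `partitions`,
#'   `excluded`, `spacer`, `codon_pos`, `reference`.
#' @export
build_supermatrix <- function(genomes, table = apis_gene_table(),
                              reference = NULL,
                              exclude_window = list(gene = "ND4", width = 37L,
                                                    offset = 0L),
                              aligned_genes = NULL, tolerance = 30L) {
  stopifnot(length(genomes) >= 1L)
  accs <- vapply(genomes, `[[`, "", "accession")
  if (anyDuplicated(accs)) stop("duplicate accessions in input")
  names(genomes) <- accs
  if (is.null(reference)) reference <- accs[1]
  if (!reference %in% accs) stop("reference accession ", reference, " not in input")

  genes <- table$gene[vapply(table$gene, function(g) {
    nrow(genomes[[reference]]$features[genomes[[reference]]$features$gene == g, ]) > 0L ||
      g %in% names(aligned_genes)
  }, TRUE)]
  if (!length(genes)) stop("reference ", reference, " supplies no extractable gene")

  keep <- rep(TRUE, length(accs))
  gene_aln <- list()
  gene_masked <- list()
  for (g in genes) {
    if (g %in% names(aligned_genes)) {
      aln <- aligned_genes[[g]]
      if (length(unique(nchar(aln))) != 1L)
        stop("externally aligned gene ", g, " has unequal sequence lengths")
      rows <- lapply(accs, function(a) {
        if (a %in% names(aln)) strsplit(toupper(aln[[a]]), "")[[1]]
        else rep("-", nchar(aln[[1]]))
      })
      gene_aln[[g]] <- do.call(rbind, rows)
      gene_masked[[g]] <- integer()
      next
    }
    refseq <- extract_coding_region(genomes[[reference]], g, table, tolerance)
    L <- nchar(refseq)
    refv <- strsplit(refseq, "")[[1]]
    rows <- vector("list", length(accs))
    ins_events <- list()  # taxon index -> insertion split point
    for (i in seq_along(accs)) {
      gnm <- genomes[[accs[i]]]
      if (!nrow(gnm$features[gnm$features$gene == g, , drop = FALSE])) {
        rows[[i]] <- rep("-", L)
        next
      }
      s <- extract_coding_region(gnm, g, table, tolerance)
      d <- nchar(s) - L
      sv <- strsplit(s, "")[[1]]
      if (d == 0L) {
        rows[[i]] <- sv
      } else if (d == 3L) {
        k <- best_indel_split(refv, sv, insertion = TRUE)
        ins_events[[as.character(i)]] <- k
        rows[[i]] <- sv  # expanded later
      } else if (d == -3L) {
        k <- best_indel_split(refv, sv, insertion = FALSE)
        rows[[i]] <- append(sv, rep("-", 3L), after = k)
      } else {
        warning(sprintf("%s %s: length %d vs reference %d not resolvable by the single-triplet indel rule; record excluded",
                        accs[i], g, nchar(s), L))
        keep[i] <- FALSE
        rows[[i]] <- rep("-", L)
      }
    }
    masked <- integer()
    if (length(ins_events)) {
      # expand the alignment at each distinct split point, left to right with
      # a running offset; inserted columns are gap-filled and masked
      newrows <- vector("list", length(rows))
      ks_inc <- sort(unique(unlist(ins_events)))
      for (i in seq_along(rows)) {
        base <- rows[[i]]
        my_k <- ins_events[[as.character(i)]]
        ref_coords <- if (!is.null(my_k)) base[-(my_k + 1:3)] else base
        out <- ref_coords
        off <- 0L
        for (k in ks_inc) {
          fill <- if (!is.null(my_k) && my_k == k) base[my_k + 1:3] else rep("-", 3L)
          out <- append(out, fill, after = k + off)
          off <- off + 3L
        }
        newrows[[i]] <- out
      }
      rows <- newrows
      off <- 0L
      for (k in ks_inc) {
        masked <- c(masked, (k + off + 1L):(k + off + 3L))
        off <- off + 3L
      }
    }
    gene_aln[[g]] <- do.call(rbind, rows)
    gene_masked[[g]] <- masked
  }

  # concatenate with frame-preserving spacer padding
  parts <- data.frame(gene = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  blocks <- list(); excluded <- integer(); spacer <- integer(); codon_pos <- integer()
  pos <- 0L
  for (g in genes) {
    w <- ncol(gene_aln[[g]])
    parts <- rbind(parts, data.frame(
      gene = g, start = pos + 1L, end = pos + w,
      strand = table$strand[table$gene == g], stringsAsFactors = FALSE))
    blocks[[length(blocks) + 1L]] <- gene_aln[[g]]
    excluded <- c(excluded, pos + gene_masked[[g]])
    codon_pos <- c(codon_pos, rep_len(1:3, w))
    pos <- pos + w
    pad <- (3L - w %% 3L) %% 3L
    if (pad) {
      blocks[[length(blocks) + 1L]] <- matrix("-", length(accs), pad)
      spacer <- c(spacer, pos + seq_len(pad))
      codon_pos <- c(codon_pos, rep(NA_integer_, pad))
      pos <- pos + pad
    }
  }
  seqm <- do.call(cbind, blocks)
  rownames(seqm) <- accs

  if (!is.null(exclude_window) && exclude_window$gene %in% parts$gene) {
    p <- parts[parts$gene == exclude_window$gene, ]
    off <- if (is.null(exclude_window$offset)) 0L else exclude_window$offset
    w <- min(exclude_window$width, p$end - p$start + 1L)
    win_end <- p$end - off
    excluded <- c(excluded, (win_end - w + 1L):win_end)
  }
  excluded <- sort(unique(excluded))

  taxa <- data.frame(accession = accs,
                     taxon_label = vapply(genomes, `[[`, "", "taxon_label"),
                     stringsAsFactors = FALSE)
  rownames(taxa) <- NULL
  sm <- structure(list(seq = seqm, taxa = taxa, partitions = parts,
                       excluded = excluded, spacer = sort(unique(spacer)),
                       codon_pos = codon_pos, reference = reference),
                  class = "mito_supermatrix")
  if (!all(keep)) sm <- subset_supermatrix(sm, accs[keep])
  sm
}

# Best split point for a single-triplet indel: k in 0..L such that matching
# prefix [1..k] and (for an insertion in `sv`) suffix sv[k+4..] against
# ref[k+1..] maximizes identity.  Ties resolve to the leftmost split.
best_indel_split <- function(refv, sv, insertion = TRUE) {
  if (insertion) { long <- sv; short <- refv } else { long <- refv; short <- sv }
  L <- length(short)
  pre <- cumsum(long[seq_len(L)] == short)           # matches if split after k
  suf <- rev(cumsum(rev(long[3L + seq_len(L)] == short)))
  score <- c(suf[1], pre[-L] + suf[-1], pre[L])      # k = 0..L
  which.max(score) - 1L
}

#' Restrict a supermatrix to a subset of taxa (columns unchanged)
#' @param sm a `mito_supermatrix`.
#' @param accessions accessions to keep, in order.
#' @export
subset_supermatrix <- function(sm, accessions) {
  stopifnot(all(accessions %in% sm$taxa$accession))
  sm$seq <- sm$seq[accessions, , drop = FALSE]
  sm$taxa <- sm$taxa[match(accessions, sm$taxa$accession), , drop = FALSE]
  rownames(sm$taxa) <- NULL
  sm
}

#' Number of analyzed columns (total minus excluded minus spacer)
#' @param sm a `mito_supermatrix`.
#' @export
analyzed_columns <- function(sm) {
  ncol(sm$seq) - length(sm$excluded) - length(sm$spacer)
}

#' Column indices retained under a codon-position filter
#' @param sm a `mito_supermatrix`.
#' @param filter a [position_filter()] (default P123 keeps all positions).
#' @return increasing integer vector of column indices.
#' @export
retained_columns <- function(sm, filter = position_filter("P123")) {
  cols <- setdiff(seq_len(ncol(sm$seq)), c(sm$excluded, sm$spacer))
  cols[sm$codon_pos[cols] %in% filter$positions]
}

#' Resolve ambiguous base calls against the column consensus
#'
#' At each column containing IUPAC ambiguity codes, ambiguous cells are
#' replaced by the column's unanimous unambiguous state when one exists
#' (making the column invariant); otherwise by the column's majority
#' unambiguous state, with ties broken by the reference row's state.  Every
#' replacement is recorded in the returned object's `$resolution_log`.
#'
#' @param sm a `mito_supermatrix`.
#' @return the supermatrix with ambiguities resolved.
#' @export
resolve_ambiguities <- function(sm) {
  m <- sm$seq
  amb <- !(m %in% c("A", "C", "G", "T", "-"))
  dim(amb) <- dim(m)
  log <- list()
  ref_row <- match(sm$reference, sm$taxa$accession)
  for (j in which(colSums(amb) > 0L)) {
    cells <- which(amb[, j])
    clear <- m[-cells, j]
    clear <- clear[clear %in% c("A", "C", "G", "T")]
    if (!length(clear)) next
    u <- unique(clear)
    if (length(u) == 1L) to <- u
    else {
      tab <- sort(table(clear), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      to <- if (length(top) == 1L) top
      else if (!is.na(ref_row) && m[ref_row, j] %in% top) m[ref_row, j]
      else sort(top)[1]
    }
    for (i in cells) {
      log[[length(log) + 1L]] <- data.frame(
        accession = sm$taxa$accession[i], column = j, from = m[i, j], to = to,
        stringsAsFactors = FALSE)
    }
    m[cells, j] <- to
  }
  sm$seq <- m
  sm$resolution_log <- if (length(log)) do.call(rbind, log) else
    data.frame(accession = character(), column = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  sm
}

#' @export
print.mito_supermatrix <- function(x, ...) {
  cat(sprintf("<mito_supermatrix> %d taxa x %d columns (%d analyzed; %d excluded, %d spacer)\n",
              nrow(x$seq), ncol(x$seq), analyzed_columns(x),
              length(x$excluded), length(x$spacer)))
  cat(sprintf("  %d partitions (%s...), reference %s\n",
              nrow(x$partitions),
              paste(head(x$partitions$gene, 4), collapse = ", "),
              x$reference))
  invisible(x)
}

#' @export
summary.mito_supermatrix <- function(object, ...) {
  p <- object$partitions
  p$width <- p$end - p$start + 1L
  p$excluded <- vapply(seq_len(nrow(p)), function(i)
    sum(object$excluded >= p$start[i] & object$excluded <= p$end[i]), 0L)
  print(object)
  print(p, row.names = FALSE)
  invisible(p)
}

#' Write / read a supermatrix to plain-text interchange files
#'
#' `<prefix>.fasta` holds the aligned rows (headers `accession|label`),
#' `<prefix>.partitions.tsv` the partition table, and `<prefix>.meta.json`
#' the masks and reference; `<prefix>.phy` is a relaxed PHYLIP copy for
#' external tools.  [read_supermatrix()] reproduces the object exactly.
#'
#' @param sm a `mito_supermatrix`.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_supermatrix <- function(sm, prefix) {
  seqs <- apply(sm$seq, 1L, paste, collapse = "")
  hdr <- paste(sm$taxa$accession, sm$taxa$taxon_label, sep = "|")
  writeLines(c(rbind(paste0(">", hdr), seqs)), paste0(prefix, ".fasta"))
  writeLines(c(sprintf("%d %d", nrow(sm$seq), ncol(sm$seq)),
               sprintf("%s  %s", sm$taxa$accession, seqs)),
             paste0(prefix, ".phy"))
  p <- sm$partitions
  p$excluded_columns <- vapply(seq_len(nrow(p)), function(i)
    paste(sm$excluded[sm$excluded >= p$start[i] & sm$excluded <= p$end[i]],
          collapse = ","), "")
  write.table(p, paste0(prefix, ".partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(reference = sm$reference, excluded = sm$excluded,
                            spacer = sm$spacer),
                       paste0(prefix, ".meta.json"))
  invisible(prefix)
}

#' @rdname write_supermatrix
#' @export
read_supermatrix <- function(prefix) {
  ss <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  accs <- vapply(parts, `[[`, "", 1)
  rownames(m) <- accs
  pt <- read.table(paste0(prefix, ".partitions.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"), simplifyVector = TRUE)
  codon_pos <- rep(NA_integer_, ncol(m))
  for (i in seq_len(nrow(pt)))
    codon_pos[pt$start[i]:pt$end[i]] <- rep_len(1:3, pt$end[i] - pt$start[i] + 1L)
  structure(list(
    seq = m,
    taxa = data.frame(accession = accs,
                      taxon_label = vapply(parts, function(x) if (length(x) > 1) x[[2]] else "", ""),
                      stringsAsFactors = FALSE),
    partitions = pt[, c("gene", "start", "end", "strand")],
    excluded = as.integer(meta$excluded), spacer = as.integer(meta$spacer),
    codon_pos = codon_pos, reference = meta$reference),
    class = "mito_supermatrix")
}
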