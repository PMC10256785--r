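#' Construct an annotated mitogenome record
#'
#' @param accession unique sequence identifier.
#' @param taxon_label species or subspecies name as assigned.
#' @param sequence nucleotide string (A/C/G/T plus IUPAC ambiguity codes).
#' @param features data.frame with columns `gene`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates on the heavy strand; strand `"heavy"` or
#'   `"light"`).
#' @return object of class `mito_genome`.
#' @export
mito_genome <- function(accession, taxon_label, sequence,
                        features = empty_features()) {
  stopifnot(is.character(accession), nzchar(accession),
            is.character(sequence), nchar(sequence) > 0L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    stopifnot(all(c("gene", "start", "end", "strand") %in% names(features)),
              all(features$start >= 1L),
              all(features$start <= features$end),
              all(features$end <= nchar(sequence)),
              all(features$strand %in% c("heavy", "light")))
  }
  structure(list(accession = accession, taxon_label = taxon_label,
                 sequence = toupper(sequence), features = features),
            class = "mito_genome")
}

empty_features <- function() {
  data.frame(gene = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s): %d bp, %d gene feature(s)\n",
              x$accession, x$taxon_label, nchar(x$sequence),
              nrow(x$features)))
  invisible(x)
}

#' Parse GenBank flat-file mitogenome records
#'
#' Reads one or more GenBank-format records (the subset emitted by
#' [write_genbank()] and by typical mitogenome submissions: LOCUS, ACCESSION,
#' ORGANISM, CDS features with `/gene` qualifiers, ORIGIN block).  CDS gene
#' names are normalized to the canonical 13 mitochondrial genes (e.g.
#' COX1 -> CO1, COB -> CYTB); unrecognized gene names are skipped with a
#' warning.  `complement(...)` locations become light-strand features.
#'
#' @param file path to a GenBank flat file (possibly multi-record), or a
#'   character vector of its lines.
#' @return list of [mito_genome()] records.
#' @export
parse_genbank <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  if (!any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file: no LOCUS line found")
  starts <- grep("^LOCUS", lines)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    stop("malformed GenBank stream: record starting at line ", starts[length(ends) + 1L],
         " has no terminating '//'")
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]])
  })
}

parse_genbank_record <- function(rec) {
  acc_line <- grep("^ACCESSION", rec, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1] else NA
  if (is.na(accession) || !nzchar(accession)) {
    locus <- strsplit(trimws(sub("^LOCUS", "", rec[1])), "\\s+")[[1]][1]
    accession <- locus
  }
  if (is.na(accession) || !nzchar(accession))
    stop("malformed GenBank record: no ACCESSION or LOCUS name")
  org_line <- grep("^\\s{2,}ORGANISM", rec, value = TRUE)
  taxon <- if (length(org_line)) trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1])) else ""
  # ORIGIN sequence block
  oi <- grep("^ORIGIN", rec)
  if (!length(oi))
    stop("malformed GenBank record ", accession, ": no ORIGIN block")
  seq_lines <- rec[(oi[1] + 1L):(length(rec) - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence))
    stop("malformed GenBank record ", accession, ": empty sequence")

  features <- empty_features()
  fi <- grep("^FEATURES", rec)
  if (length(fi)) {
    fend <- oi[1] - 1L
    flines <- rec[(fi[1] + 1L):fend]
    keys <- grep("^ {5}\\S", flines)
    for (k in seq_along(keys)) {
      block <- flines[keys[k]:(if (k < length(keys)) keys[k + 1L] - 1L else length(flines))]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (key != "CDS") next
      loc <- trimws(sub("^\\s*CDS\\s+", "", block[1]))
      strand <- if (grepl("complement", loc)) "light" else "heavy"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L) {
        warning("record ", accession, ": cannot parse CDS location '", loc, "', skipped")
        next
      }
      start <- as.integer(nums[1]); end <- as.integer(nums[length(nums)])
      gq <- grep("/gene=", block, value = TRUE)
      if (!length(gq)) gq <- grep("/product=", block, value = TRUE)
      raw <- if (length(gq)) gsub('.*=\\s*"?([^"]*)"?.*', "\\1", gq[1]) else ""
      gene <- normalize_gene_name(raw)
      if (is.na(gene) || !length(gene)) {
        warning("record ", accession, ": unrecognized gene name '", raw, "', feature skipped")
        next
      }
      features <- rbind(features,
                        data.frame(gene = gene, start = start, end = end,
                                   strand = strand, stringsAsFactors = FALSE))
    }
  }
  if (nrow(features)) {
    if (any(features$end > nchar(sequence)))
      stop("malformed GenBank record ", accession,
           ": CDS coordinates exceed sequence length")
    features <- features[order(match(features$gene, MITO_GENES), features$start), ,
                         drop = FALSE]
    rownames(features) <- NULL
  } else {
    warning("record ", accession, ": no CDS features found")
  }
  mito_genome(accession, taxon, sequence, features)
}

#' Write mitogenome records as a GenBank flat file
#'
#' Inverse of [parse_genbank()] for the feature subset this package uses.
#' @param genomes list of [mito_genome()] records.
#' @param file output path (or `NULL` to return the lines invisibly).
#' @return invisibly, the character vector of file lines.
#' @export
write_genbank <- function(genomes, file = NULL) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  out <- unlist(lapply(genomes, function(g) {
    n <- nchar(g$sequence)
    feats <- c("FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", n),
               sprintf('                     /organism="%s"', g$taxon_label))
    if (nrow(g$features)) {
      for (i in seq_len(nrow(g$features))) {
        f <- g$features[i, ]
        loc <- if (f$strand == "light")
          sprintf("complement(%d..%d)", f$start, f$end)
        else sprintf("%d..%d", f$start, f$end)
        feats <- c(feats,
                   sprintf("     CDS             %s", loc),
                   sprintf('                     /gene="%s"', f$gene))
      }
    }
    seq <- tolower(g$sequence)
    starts <- seq(1L, n, by = 60L)
    origin <- vapply(starts, function(s) {
      chunk <- substr(seq, s, min(s + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", s, paste(tens, collapse = " "))
    }, character(1))
    c(sprintf("LOCUS       %s %d bp    DNA     circular INV", g$accession, n),
      sprintf("DEFINITION  %s mitochondrion, coding regions.", g$taxon_label),
      sprintf("ACCESSION   %s", g$accession),
      "SOURCE      mitochondrion",
      sprintf("  ORGANISM  %s", g$taxon_label),
      feats, "ORIGIN", origin, "//")
  }))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read mitogenomes from FASTA
#'
#' Headers are `accession|taxon_label`; records carry no features (use
#' [parse_genbank()] for annotated input).
#' @param file FASTA path.
#' @return list of [mito_genome()] records with empty feature tables.
#' @export
read_genomes_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  lapply(seq_along(ss), function(i) {
    parts <- strsplit(names(ss)[i], "|", fixed = TRUE)[[1]]
    mito_genome(parts[1], if (length(parts) > 1) parts[2] else "",
                as.character(ss[[i]]))
  })
}

#' @rdname read_genomes_fasta
#' @param genomes list of [mito_genome()] records.
#' @export
write_genomes_fasta <- function(genomes, file) {
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, function(g) paste(g$accession, g$taxon_label, sep = "|"), "")
  Biostrings::writeXStringSet(ss, file, width = 70L)
  invisible(file)
}

#' Extract a coding region in sense-strand orientation
#'
#' Heavy-strand genes are returned as the annotated slice; light-strand genes
#' (ND5, ND4, ND4L, ND1) are reverse-complemented so that every gene reads
#' 5'->3' in coding direction.
#'
#' @param genome a [mito_genome()].
#' @param gene canonical gene name.
#' @param table gene layout from [apis_gene_table()] (for length checking).
#' @param tolerance flag (not drop) sequences whose length deviates from the
#'   expected layout length by more than this many bases.  Default 30,
#'   accommodating the between-taxon length variation seen in real
#'   mitogenomes (e.g. ATP8 at 162 vs 138 bases).
#' @return nucleotide string, 5'->3' coding direction.
#' @export
extract_coding_region <- function(genome, gene, table = apis_gene_table(),
                                  tolerance = 30L) {
  f <- genome$features[genome$features$gene == gene, , drop = FALSE]
  if (!nrow(f))
    stop("genome ", genome$accession, " has no feature for gene ", gene)
  f <- f[1, ]
  s <- substr(genome$sequence, f$start, f$end)
  if (f$strand == "light") s <- revcomp(s)
  expected <- table$length_bases[table$gene == gene]
  if (length(expected) && abs(nchar(s) - expected) > tolerance)
    warning(sprintf("%s %s: length %d deviates from expected %d by more than %d",
                    genome$accession, gene, nchar(s), expected, tolerance))
  s
}
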