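#' Canonical mitochondrial protein-coding gene layout
#'
#' The 13 protein-coding genes of the insect (honey-bee type) mitogenome in
#' their heavy-strand 5'->3' genomic order, with expected coding lengths and
#' strand assignments.  ND5, ND4, ND4L and ND1 are encoded on the light
#' strand and must be reverse-complemented to sense orientation before
#' concatenation.  Two length sets are carried: `"subspecies"` (the
#' within-species reference layout, total 11,043 bases) and `"species"`
#' (the across-species layout, total 11,070 bases).
#'
#' @param level `"subspecies"` (default) or `"species"`: which expected
#'   length column to use.
#' @return A data.frame with columns `gene`, `length_bases`,
#'   `length_triplets`, `strand` (13 rows, ordered 5'->3').
#' @export
#' @examples
#' tab <- apis_gene_table()
#' sum(tab$length_bases)  # 11043
apis_gene_table <- function(level = c("subspecies", "species")) {
  level <- match.arg(level)
  tab <- data.frame(
    gene = c("ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
             "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1"),
    species_bases = c(1002L, 1563L, 678L, 162L, 681L, 786L, 354L,
                      1668L, 1314L, 264L, 522L, 1152L, 924L),
    subspecies_bases = c(1002L, 1560L, 678L, 138L, 681L, 780L, 354L,
                         1665L, 1347L, 264L, 504L, 1152L, 918L),
    strand = c("heavy", "heavy", "heavy", "heavy", "heavy", "heavy", "heavy",
               "light", "light", "light", "heavy", "heavy", "light"),
    stringsAsFactors = FALSE
  )
  bases <- if (level == "species") tab$species_bases else tab$subspecies_bases
  out <- data.frame(gene = tab$gene,
                    length_bases = bases,
                    length_triplets = bases %/% 3L,
                    strand = tab$strand,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$length_bases == 3L * out$length_triplets))
  out
}

#' @rdname apis_gene_table
#' @format NULL
#' @export
MITO_GENES <- c("ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
                "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

LIGHT_STRAND_GENES <- c("ND5", "ND4", "ND4L", "ND1")

# GenBank /gene and /product spellings normalized to the canonical names.
GENE_SYNONYMS <- c(
  COX1 = "CO1", COI = "CO1", CO1 = "CO1", COXI = "CO1",
  COX2 = "CO2", COII = "CO2", CO2 = "CO2", COXII = "CO2",
  COX3 = "CO3", COIII = "CO3", CO3 = "CO3", COXIII = "CO3",
  COB = "CYTB", CYTB = "CYTB", CYB = "CYTB",
  ATP6 = "ATP6", ATPASE6 = "ATP6", ATP8 = "ATP8", ATPASE8 = "ATP8",
  ND1 = "ND1", NAD1 = "ND1", NADH1 = "ND1",
  ND2 = "ND2", NAD2 = "ND2", NADH2 = "ND2",
  ND3 = "ND3", NAD3 = "ND3", NADH3 = "ND3",
  ND4 = "ND4", NAD4 = "ND4", NADH4 = "ND4",
  ND4L = "ND4L", NAD4L = "ND4L", NADH4L = "ND4L",
  ND5 = "ND5", NAD5 = "ND5", NADH5 = "ND5",
  ND6 = "ND6", NAD6 = "ND6", NADH6 = "ND6"
)

normalize_gene_name <- function(x) {
  key <- toupper(gsub("[ _-]", "", x))
  unname(GENE_SYNONYMS[key])
}

# IUPAC ambiguity sets as 4-bit masks over (A, C, G, T) = (1, 2, 4, 8).
IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, "-" = 15L,
                "?" = 15L)

#' Encode nucleotide characters as IUPAC bit sets
#'
#' A=1, C=2, G=4, T=8; ambiguity codes are unions; gaps and unknowns are the
#' full set 15.  Used by the parsimony and likelihood engines, where a gap or
#' unresolved ambiguity behaves as missing data.
#' @param x character vector of single bases (upper or lower case).
#' @return integer vector of bit sets in 1..15.
#' @keywords internal
iupac_bits <- function(x) {
  b <- IUPAC_BITS[toupper(x)]
  b[is.na(b)] <- 15L
  unname(b)
}

is_unambiguous_base <- function(x) toupper(x) %in% c("A", "C", "G", "T")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Invertebrate mitochondrial genetic code (NCBI transl_table = 5).
mito_genetic_code <- function() Biostrings::getGeneticCode("5")
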