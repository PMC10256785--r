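#' Codon-position filters
#'
#' `"P123"` retains all codon positions; `"P12"` drops third positions, the
#' standard check for saturation-driven artefacts at silent sites.
#' @param name `"P123"` or `"P12"`.
#' @return object of class `mito_filter` with fields `name`, `positions`.
#' @export
position_filter <- function(name = c("P123", "P12")) {
  name <- match.arg(name)
  structure(list(name = name,
                 positions = if (name == "P12") c(1L, 2L) else 1:3),
            class = "mito_filter")
}

#' Classify alignment columns by phylogenetic information content
#'
#' Each retained column is `constant` (at most one state),
#' `variable_singleton` (variable, but no two states are each carried by two
#' or more taxa), or `parsimony_informative` (at least two states each
#' present in at least two taxa, sensu Nei).  Cells holding gaps or
#' unresolved ambiguity codes are excluded from a column's state counts, so
#' a state present only in such cells never creates informativeness.
#'
#' @param sm a `mito_supermatrix` (or plain character matrix of aligned
#'   sequences, in which case all columns are retained).
#' @param filter a [position_filter()].
#' @return object of class `mito_sites`: `category` (factor per retained
#'   column, names = column indices), `counts`, `retained`, and `detail`
#'   (per variable column: states and the taxa carrying each minor state).
#' @export
classify_sites <- function(sm, filter = position_filter("P123")) {
  m <- if (inherits(sm, "mito_supermatrix")) sm$seq else sm
  if (nrow(m) < 3L)
    stop("site classification needs at least 3 taxa")
  cols <- if (inherits(sm, "mito_supermatrix")) retained_columns(sm, filter)
          else seq_len(ncol(m))
  sub <- m[, cols, drop = FALSE]
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(sub == b), numeric(length(cols)))
  if (length(cols) == 1L) counts <- matrix(counts, nrow = 1L)
  nstates <- rowSums(counts > 0L)
  n_ge2 <- rowSums(counts >= 2L)
  category <- ifelse(nstates <= 1L, "constant",
                     ifelse(nstates >= 2L & n_ge2 >= 2L,
                            "parsimony_informative", "variable_singleton"))
  category <- factor(category, levels = c("constant", "variable_singleton",
                                          "parsimony_informative"))
  names(category) <- cols
  vi <- which(nstates >= 2L)
  detail <- if (length(vi)) do.call(rbind, lapply(vi, function(k) {
    tab <- counts[k, counts[k, ] > 0L]
    major <- names(tab)[which.max(tab)]
    minors <- setdiff(names(tab), major)
    taxa <- unlist(lapply(minors, function(s) rownames(sub)[sub[, k] == s]))
    data.frame(column = cols[k], category = as.character(category[k]),
               states = paste(names(sort(tab, decreasing = TRUE)), collapse = "/"),
               minor_taxa = paste(taxa, collapse = ","),
               stringsAsFactors = FALSE)
  })) else data.frame(column = integer(), category = character(),
                      states = character(), minor_taxa = character())
  structure(list(category = category,
                 counts = c(table(category)),
                 retained = cols,
                 detail = detail),
            class = "mito_sites")
}

#' @export
print.mito_sites <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("<mito_sites> %d analyzed columns: %d constant, %d variable (%d singleton + %d parsimony-informative)\n",
              n, x$counts[["constant"]],
              x$counts[["variable_singleton"]] + x$counts[["parsimony_informative"]],
              x$counts[["variable_singleton"]],
              x$counts[["parsimony_informative"]]))
  invisible(x)
}

#' Write the per-column site report as TSV
#' @param sites a `mito_sites`.
#' @param sm the supermatrix the classification came from.
#' @param file output path.
#' @export
write_site_report <- function(sites, sm, file) {
  cols <- sites$retained
  gene <- character(length(cols))
  for (i in seq_len(nrow(sm$partitions)))
    gene[cols >= sm$partitions$start[i] & cols <= sm$partitions$end[i]] <-
      sm$partitions$gene[i]
  rep <- data.frame(column = cols, gene = gene,
                    codon_position = sm$codon_pos[cols],
                    category = as.character(sites$category),
                    stringsAsFactors = FALSE)
  rep <- merge(rep, sites$detail[, c("column", "states")], all.x = TRUE)
  write.table(rep[order(rep$column), ], file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Translate the coding partitions to amino acids
#'
#' Uses the invertebrate mitochondrial genetic code (NCBI transl_table 5).
#' Translation runs on each partition's codon grid; a codon containing a
#' gap, an unresolved ambiguity code, or a masked (excluded) column
#' translates to `X`, so the frame survives the 37-column ND4 exclusion
#' window, whose width is not a triplet multiple.
#'
#' @param sm a `mito_supermatrix` with in-frame partitions.
#' @return list of class `mito_aa`: `aa` (taxa x residue character matrix)
#'   and `partitions` (gene -> residue-column interval).
#' @export
translate_partition <- function(sm) {
  code <- mito_genetic_code()
  aa_blocks <- list()
  parts <- data.frame(gene = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    w <- p$end - p$start + 1L
    if (w %% 3L != 0L)
      stop("partition ", p$gene, " width ", w, " is not divisible by 3")
    cols <- p$start:p$end
    bad_col <- cols %in% sm$excluded
    block <- sm$seq[, cols, drop = FALSE]
    ncod <- w %/% 3L
    aa <- matrix("X", nrow(block), ncod)
    idx1 <- seq(1L, w, by = 3L)
    for (k in seq_len(ncod)) {
      j <- idx1[k] + 0:2
      if (any(bad_col[j])) next
      cod <- paste0(block[, j[1]], block[, j[2]], block[, j[3]])
      ok <- !grepl("[^ACGT]", cod)
      aa[ok, k] <- code[cod[ok]]
    }
    rownames(aa) <- rownames(sm$seq)
    aa_blocks[[p$gene]] <- aa
    parts <- rbind(parts, data.frame(gene = p$gene, start = pos + 1L,
                                     end = pos + ncod, stringsAsFactors = FALSE))
    pos <- pos + ncod
  }
  structure(list(aa = do.call(cbind, aa_blocks), partitions = parts),
            class = "mito_aa")
}

#' Count variable amino-acid columns (ignoring X)
#' @param x a `mito_aa` from [translate_partition()].
#' @export
n_variable_aa <- function(x) {
  sum(apply(x$aa, 2L, function(col) length(unique(col[col != "X"])) > 1L))
}
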