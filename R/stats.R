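#' Pairwise p-distance matrix
#'
#' Uncorrected p-distance: for each strain pair, the proportion of differing
#' sites among comparable columns. Under `deletion = "complete"` (the default)
#' a column is comparable only if it is free of gaps and N in every strain;
#' under `"pairwise"` only the two rows being compared are consulted.
#'
#' @param aln a [locus_alignment] (or concatenated alignment).
#' @param deletion `"complete"` or `"pairwise"` treatment of gap/N columns.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal, strain ids
#'   as dimnames, and attribute `label` set to the locus name.
#' @export
p_distance_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- n_strains(aln)
  if (n < 2L)
    mlsa_stop("mlsa_size_error", "p-distance needs at least 2 strains")
  M <- aln_int_matrix(aln)
  ids <- aln$strain_ids
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (deletion == "complete") {
    keep <- colSums(is.na(M)) == 0L
    if (!any(keep))
      mlsa_stop("mlsa_undefined_distance_error",
        "locus '%s': no column free of gap/N under complete deletion",
        aln$locus_name)
    M <- M[, keep, drop = FALSE]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- mean(M[i, ] != M[j, ])
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(M[i, ]) & !is.na(M[j, ])
        if (!any(ok))
          mlsa_stop("mlsa_undefined_distance_error",
            "locus '%s': no comparable column for pair %s / %s",
            aln$locus_name, ids[i], ids[j])
        d[i, j] <- d[j, i] <- mean(M[i, ok] != M[j, ok])
      }
    }
  }
  attr(d, "label") <- aln$locus_name
  d
}

#' Percent-identity matrix from a p-distance matrix
#'
#' Similarity is the standard percent-identity convention,
#' `100 * (1 - p-distance)`, entrywise; the diagonal is 100.
#'
#' @param d symmetric p-distance matrix from [p_distance_matrix()].
#' @return symmetric percent matrix in \[0, 100\], same dimnames and `label`.
#' @export
similarity_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  s <- 100 * (1 - d)
  attr(s, "label") <- attr(d, "label")
  s
}

#' Number of alleles (distinct haplotypes) in an alignment
#'
#' Exact string equality after uppercasing; N never collapses with a base, so
#' two rows differing only in N placement count as distinct alleles.
#'
#' @param aln a [locus_alignment].
#' @return integer count of distinct row strings.
#' @export
count_alleles <- function(aln) {
  length(unique(unname(aln$seqs)))
}

#' Polymorphic sites of an alignment
#'
#' A column is polymorphic iff at least two distinct bases among `A C G T`
#' occur in it; gaps and N are ignored as states. The reported percentage uses
#' one decimal, rounded half away from zero (see [round_half_away()]).
#'
#' @param aln a [locus_alignment] with at least 2 strains.
#' @return list with `n` (count), `positions` (1-based column indices) and
#'   `pct` (percent of alignment length, 1 decimal).
#' @export
polymorphic_sites <- function(aln) {
  if (n_strains(aln) < 2L)
    mlsa_stop("mlsa_size_error", "polymorphic sites need at least 2 strains")
  M <- aln_int_matrix(aln)
  poly <- apply(M, 2L, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2L
  })
  pos <- which(poly)
  list(n = length(pos), positions = pos,
       pct = round_half_away(100 * length(pos) / aln$length, 1))
}

#' Average G+C content (mol%)
#'
#' Mean over strains of the per-row percentage `100 * (G + C) / (A + C + G + T)`;
#' gaps and N are excluded from numerator and denominator.
#'
#' @param aln a [locus_alignment].
#' @return percent (not rounded).
#' @export
avg_gc_content <- function(aln) {
  M <- aln_int_matrix(aln)
  per_row <- apply(M, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row))
      mlsa_stop("mlsa_degenerate_row_error",
                "a row of '%s' has no unambiguous base", aln$locus_name)
    100 * mean(row == 2L | row == 3L)  # C or G
  })
  mean(per_row)
}

#' Per-locus summary of diversity statistics
#'
#' Assembles the standard characterisation panel for one locus (or the
#' concatenation): length, number of alleles, average G+C content, polymorphic
#' sites (count and percent) and the p-distance range and mean over the strict
#' upper triangle of the pairwise matrix.
#'
#' @param aln a [locus_alignment].
#' @param locus_name optional label override.
#' @param deletion deletion policy passed to [p_distance_matrix()].
#' @return object of class `locus_summary`: a list with fields `locus_name`,
#'   `length_bp`, `n_alleles`, `avg_gc_molpct`, `n_polymorphic`,
#'   `pct_polymorphic`, `p_range` (length-2), `p_mean`.
#' @export
locus_summary <- function(aln, locus_name = aln$locus_name,
                          deletion = "complete") {
  d <- p_distance_matrix(aln, deletion)
  up <- d[upper.tri(d)]
  ps <- polymorphic_sites(aln)
  structure(
    list(locus_name = locus_name,
         length_bp = aln$length,
         n_alleles = count_alleles(aln),
         avg_gc_molpct = round_half_away(avg_gc_content(aln), 1),
         n_polymorphic = ps$n,
         pct_polymorphic = ps$pct,
         p_range = c(min(up), max(up)),
         p_mean = mean(up)),
    class = "locus_summary"
  )
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf(
    "%s: %d bp, %d alleles, G+C %.1f mol%%, %d polymorphic (%.1f%%), p %0.3f-%0.3f (mean %0.3f)\n",
    x$locus_name, x$length_bp, x$n_alleles, x$avg_gc_molpct,
    x$n_polymorphic, x$pct_polymorphic, x$p_range[1], x$p_range[2], x$p_mean))
  invisible(x)
}

#' @export
as.data.frame.locus_summary <- function(x, ...) {
  data.frame(
    Locus = x$locus_name,
    `Length (bp)` = x$length_bp,
    `No. of alleles` = x$n_alleles,
    `Average G+C content (mol%)` = x$avg_gc_molpct,
    `Polymorphic sites No.` = x$n_polymorphic,
    `Polymorphic sites %` = x$pct_polymorphic,
    `P-distance Range` = sprintf("%s-%s", format(round_half_away(x$p_range[1], 3)),
                                 format(round_half_away(x$p_range[2], 3))),
    `P-distance Mean` = round_half_away(x$p_mean, 3),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Write a labeled square matrix as TSV
#'
#' @param m square matrix with dimnames (distances, similarities or DDH).
#' @param path output path.
#' @param digits significant digits used when formatting.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, digits = 6) {
  df <- data.frame(strain = rownames(m),
                   signif(m, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix from TSV
#'
#' Expects the layout written by [write_matrix_tsv()]: a header row of strain
#' ids and a leading label column.
#'
#' @param path input path.
#' @return numeric matrix with strain ids as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m)))
    mlsa_stop("mlsa_io_error", "matrix in '%s' is not square-labeled", path)
  m
}
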