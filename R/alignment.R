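#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a per-locus alignment
#'
#' A `locus_alignment` holds one pre-aligned, pre-trimmed nucleotide locus:
#' equal-length uppercase rows over the alphabet `A C G T N -`, keyed by unique
#' strain identifiers. All downstream statistics and trees consume this type.
#'
#' @param rows named character vector; one aligned sequence per strain, names
#'   are the strain identifiers. Lowercase input is uppercased.
#' @param locus_name label for the locus (e.g. `"leuA"`).
#' @param descriptions optional named character vector of free-text FASTA
#'   descriptions (the header remainder after the identifier token).
#' @return an object of class `locus_alignment` with elements `locus_name`,
#'   `strain_ids`, `seqs` (named character), `length` and `descriptions`.
#' @export
#' @examples
#' locus_alignment(c(s1 = "ACGT", s2 = "ACGA"), "toy")
locus_alignment <- function(rows, locus_name, descriptions = NULL) {
  if (length(rows) < 1L)
    mlsa_stop("mlsa_empty_error", "alignment '%s' has no sequences", locus_name)
  ids <- names(rows)
  if (is.null(ids) || any(!nzchar(ids)))
    mlsa_stop("mlsa_id_error", "alignment '%s': every row needs a strain id",
              locus_name)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    mlsa_stop("mlsa_duplicate_id_error",
              "alignment '%s': duplicate strain id(s): %s",
              locus_name, paste(unique(dup), collapse = ", "))
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    mlsa_stop("mlsa_shape_error",
      "alignment '%s': row '%s' has %d characters, expected %d (record '%s')",
      locus_name, bad, nchar(rows[[bad]]), lens[1L], bad)
  }
  chars <- strsplit(rows, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!(chars[[i]] %in% ALN_ALPHABET))
    if (length(bad))
      mlsa_stop("mlsa_alphabet_error",
        "alignment '%s': illegal character '%s' in strain '%s' at position %d",
        locus_name, chars[[i]][bad[1L]], ids[i], bad[1L])
  }
  structure(
    list(locus_name = locus_name, strain_ids = ids, seqs = rows,
         length = lens[[1L]],
         descriptions = descriptions %||% stats::setNames(rep("", length(ids)), ids)),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d strains x %d bp\n",
              x$locus_name, length(x$strain_ids), x$length))
  invisible(x)
}

n_strains <- function(aln) length(aln$strain_ids)

# character matrix view (strains x columns)
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n_strains(aln), ncol = aln$length, byrow = TRUE)
  rownames(m) <- aln$strain_ids
  m
}

# integer view: A,C,G,T -> 1..4; N and gap -> NA (per-statistic policies
# decide how missing states are treated)
aln_int_matrix <- function(aln) {
  m <- aln_matrix(aln)
  out <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m),
                dimnames = dimnames(m))
  out
}

#' Read one locus alignment from a FASTA file
#'
#' The strain identifier is the first whitespace-delimited token of the FASTA
#' header; the remainder is kept as a free-text description. Rows must be of
#' equal length (a multiple sequence alignment) over `A C G T N -`; lowercase
#' is accepted and uppercased.
#'
#' @param path FASTA file path.
#' @param locus_name label for the locus; defaults to the file name stem.
#' @return a [locus_alignment].
#' @export
read_locus_fasta <- function(path, locus_name = NULL) {
  if (!file.exists(path))
    mlsa_stop("mlsa_io_error", "FASTA file not found: %s", path)
  locus_name <- locus_name %||% sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L)
    mlsa_stop("mlsa_empty_error", "FASTA file '%s' has no records", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  rows <- stats::setNames(as.character(set), ids)
  locus_alignment(rows, locus_name,
                  descriptions = stats::setNames(desc, ids))
}

#' Write a locus alignment to FASTA
#'
#' Sequences are wrapped at 70 columns; headers are the strain identifier
#' followed by the stored description, if any.
#'
#' @param aln a [locus_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  hdr <- aln$strain_ids
  d <- aln$descriptions[aln$strain_ids]
  has_d <- !is.na(d) & nzchar(d)
  hdr[has_d] <- paste(hdr[has_d], d[has_d])
  set <- Biostrings::BStringSet(stats::setNames(unname(aln$seqs), hdr))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Concatenate per-locus alignments into a multilocus alignment
#'
#' Loci are joined in the order given (for the reference scheme:
#' leuA-clpA-pyrH-gatA-rpoD). Every requested strain must be present in every
#' locus. The result records 1-based inclusive column spans per locus so the
#' constituent loci can be recovered exactly.
#'
#' @param loci list of [locus_alignment] objects, in concatenation order.
#' @param strains optional ordered character vector restricting/ordering the
#'   strain set; default: the strain order of the first locus.
#' @param label name for the concatenated pseudo-locus (default `"MLSA"`).
#' @return a `concatenated_alignment` (also a [locus_alignment]) with extra
#'   elements `locus_order` and `offsets` (data.frame `locus`, `start`, `end`).
#' @export
#' @examples
#' a <- locus_alignment(c(x = "AC", y = "AC"), "l1")
#' b <- locus_alignment(c(x = "GT", y = "GA"), "l2")
#' concatenate_loci(list(a, b))$seqs
concatenate_loci <- function(loci, strains = NULL, label = "MLSA") {
  if (length(loci) < 1L)
    mlsa_stop("mlsa_empty_error", "need at least one locus to concatenate")
  strains <- strains %||% loci[[1L]]$strain_ids
  for (aln in loci) {
    missing <- setdiff(strains, aln$strain_ids)
    if (length(missing))
      mlsa_stop("mlsa_missing_strain_error",
                "locus '%s' is missing strain(s): %s",
                aln$locus_name, paste(missing, collapse = ", "))
  }
  lens <- vapply(loci, function(a) a$length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  rows <- vapply(strains, function(s) {
    paste(vapply(loci, function(a) unname(a$seqs[[s]]), character(1)),
          collapse = "")
  }, character(1))
  out <- locus_alignment(stats::setNames(rows, strains), label)
  out$locus_order <- vapply(loci, function(a) a$locus_name, character(1))
  out$offsets <- data.frame(locus = out$locus_order, start = starts,
                            end = ends, stringsAsFactors = FALSE)
  class(out) <- c("concatenated_alignment", class(out))
  out
}

#' Extract one locus from a concatenated alignment by its recorded span
#'
#' @param concat a `concatenated_alignment` from [concatenate_loci()].
#' @param locus locus name present in `concat$locus_order`.
#' @return the [locus_alignment] for that span.
#' @export
extract_locus <- function(concat, locus) {
  if (!inherits(concat, "concatenated_alignment"))
    mlsa_stop("mlsa_type_error", "not a concatenated alignment")
  i <- match(locus, concat$offsets$locus)
  if (is.na(i))
    mlsa_stop("mlsa_missing_locus_error", "no locus '%s' in concatenation", locus)
  rows <- substr(concat$seqs, concat$offsets$start[i], concat$offsets$end[i])
  locus_alignment(stats::setNames(rows, concat$strain_ids), locus)
}
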