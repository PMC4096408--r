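#' Cluster strains into species hypotheses at a similarity cutoff
#'
#' Single linkage (the default) groups strains into the connected components of
#' the graph with an edge wherever pairwise similarity is at least the cutoff
#' (pairs exactly at the cutoff join the same group); complete linkage is
#' available for sensitivity analysis. Groups are labeled with Roman numerals
#' by decreasing size, ties broken by the smallest member identifier.
#'
#' @param s similarity matrix (percent) from [similarity_matrix()].
#' @param cutoff percent identity cutoff in (0, 100].
#' @param linkage `"single"` (connected components at the cutoff) or
#'   `"complete"`.
#' @return object of class `mlsa_partition`: list with `groups` (named
#'   character vector strain -> label), `n_groups`, `sizes` (named integer by
#'   label) and `members` (list of character vectors by label).
#' @export
cluster_at_threshold <- function(s, cutoff, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 100)
    mlsa_stop("mlsa_parameter_error", "cutoff must be in (0, 100]")
  ids <- rownames(s)
  n <- length(ids)
  if (n == 1L) {
    idx <- stats::setNames(1L, ids)
  } else {
    h <- stats::hclust(stats::as.dist(100 - s), method = linkage)
    # merges at height <= 100 - cutoff <=> similarity >= cutoff
    idx <- stats::cutree(h, h = 100 - cutoff + 1e-9)
  }
  label_partition(idx)
}

# assign Roman-numeral labels: decreasing size, ties by smallest member id
label_partition <- function(idx) {
  ids <- names(idx)
  members <- split(ids, idx)
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1L], character(1)))
  members <- members[ord]
  labels <- as.character(utils::as.roman(seq_along(members)))
  names(members) <- labels
  groups <- stats::setNames(rep(labels, lengths(members)),
                            unlist(members, use.names = FALSE))
  groups <- groups[ids]  # original strain order
  structure(
    list(groups = groups, n_groups = length(members),
         sizes = stats::setNames(lengths(members), labels),
         members = members),
    class = "mlsa_partition"
  )
}

#' Build a partition from an explicit strain -> group assignment
#'
#' Relabels an arbitrary grouping with the package's Roman-numeral convention.
#'
#' @param assignment named vector (names = strain ids, values = any group key).
#' @return an `mlsa_partition`.
#' @export
as_partition <- function(assignment) {
  if (is.null(names(assignment)))
    mlsa_stop("mlsa_id_error", "assignment must be named by strain id")
  label_partition(stats::setNames(as.character(assignment), names(assignment)))
}

#' @export
print.mlsa_partition <- function(x, ...) {
  cat(sprintf("<mlsa_partition> %d strains in %d groups\n",
              length(x$groups), x$n_groups))
  sz <- paste(sprintf("%s(%d)", names(x$sizes), x$sizes), collapse = " ")
  cat(" sizes:", sz, "\n")
  invisible(x)
}

range_report <- function(scope, values) {
  if (!length(values)) {
    return(structure(list(scope = scope, min = NA_real_, max = NA_real_,
                          mean = NA_real_, n_pairs = 0L),
                     class = "range_report"))
  }
  structure(list(scope = scope, min = min(values), max = max(values),
                 mean = mean(values), n_pairs = length(values)),
            class = "range_report")
}

#' @export
print.range_report <- function(x, ...) {
  if (x$n_pairs == 0L)
    cat(sprintf("%s: no pairs\n", x$scope))
  else
    cat(sprintf("%s: %.1f-%.1f%% (mean %.1f, %d pairs)\n",
                x$scope, x$min, x$max, x$mean, x$n_pairs))
  invisible(x)
}

#' Intraspecies and interspecies similarity ranges
#'
#' Splits the unordered strain pairs of a similarity matrix by same-group vs
#' different-group membership under a partition and summarises each side.
#'
#' @param s similarity matrix (percent).
#' @param p an `mlsa_partition` covering all strains of `s`.
#' @return list with elements `intra` and `inter`, each a `range_report`
#'   (`scope`, `min`, `max`, `mean`, `n_pairs`); the intraspecies report has
#'   `n_pairs = 0` and NA range when all groups are singletons.
#' @export
intra_inter_ranges <- function(s, p) {
  ids <- rownames(s)
  missing <- setdiff(ids, names(p$groups))
  if (length(missing))
    mlsa_stop("mlsa_validation_error",
              "partition does not cover strain(s): %s",
              paste(missing, collapse = ", "))
  g <- p$groups[ids]
  ut <- upper.tri(s)
  same <- outer(g, g, "==")
  list(intra = range_report("intraspecies", s[ut & same]),
       inter = range_report("interspecies", s[ut & !same]))
}

#' Similarity gap between intraspecies and interspecies ranges
#'
#' A gap exists when the smallest intraspecies similarity strictly exceeds the
#' largest interspecies similarity; the open interval between the two is then a
#' valid band of species cutoffs. Otherwise the overlap width is reported
#' (zero at exact equality: a crossover, the failure mode of a marker with no
#' resolving power).
#'
#' @param intra,inter `range_report`s from [intra_inter_ranges()]; both scopes
#'   must be non-empty.
#' @return list with `gap_exists` (logical), `gap_interval` (length-2 numeric
#'   or NULL) and `overlap_width` (0 when a gap exists).
#' @export
similarity_gap <- function(intra, inter) {
  if (intra$n_pairs == 0L || inter$n_pairs == 0L)
    mlsa_stop("mlsa_undefined_gap_error",
              "similarity gap undefined: empty %s scope",
              if (intra$n_pairs == 0L) "intraspecies" else "interspecies")
  exists <- intra$min > inter$max
  list(gap_exists = exists,
       gap_interval = if (exists) c(inter$max, intra$min) else NULL,
       overlap_width = if (exists) 0 else inter$max - intra$min)
}

#' Tabulate per-locus intra/inter ranges
#'
#' @param ranges named list (by locus) of `intra_inter_ranges()` results.
#' @return data.frame with one row per locus x scope.
#' @export
ranges_table <- function(ranges) {
  rows <- lapply(names(ranges), function(locus) {
    r <- ranges[[locus]]
    do.call(rbind, lapply(list(r$intra, r$inter), function(x)
      data.frame(locus = locus, scope = x$scope,
                 min = x$min, max = x$max, mean = x$mean,
                 n_pairs = x$n_pairs, stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}

#' Write a partition as a two-column TSV (strain, group)
#'
#' @param p an `mlsa_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  utils::write.table(
    data.frame(strain = names(p$groups), group = unname(p$groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
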