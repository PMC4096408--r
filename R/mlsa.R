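#' Multilocus sequence analysis for species delimitation
#'
#' Fits the full MLSA species-delimitation analysis to a set of per-locus
#' alignments: per-locus diversity summaries, pairwise p-distance and percent
#' identity matrices, a neighbor-joining tree on the concatenated loci
#' (optionally with bootstrap support), single-linkage delimitation of species
#' hypotheses at a similarity cutoff, intraspecies/interspecies similarity
#' ranges and gap diagnostics per locus, and (when a digital DDH matrix over a
#' strain subset is supplied) per-locus species-boundary similarity cutoffs
#' calibrated at the 70% DDH boundary.
#'
#' Loci whose name contains `"16S"` are summarised and calibrated like any
#' other marker but excluded from the concatenation by default, matching the
#' convention of concatenating only the protein-coding genes.
#'
#' @param loci named list of [locus_alignment] objects sharing a strain set.
#' @param ddh optional DDH matrix (see [read_ddh_tsv()]) over a subset of the
#'   strains; enables calibration.
#' @param cutoff percent-identity cutoff for delimitation on the concatenated
#'   similarity matrix. Default `NULL`: use the DDH-calibrated concatenated
#'   threshold when `ddh` is given, otherwise an error.
#' @param boundary DDH species boundary, percent (default 70).
#' @param bootstrap number of bootstrap replicates for the concatenated tree
#'   (0 = point-estimate tree only).
#' @param seed integer seed driving the bootstrap resampling.
#' @param deletion gap/N deletion policy, `"complete"` or `"pairwise"`.
#' @param linkage clustering linkage, `"single"` or `"complete"`.
#' @param outgroup optional strain id used to root the tree for display.
#' @param concat_loci names of loci to concatenate (default: all non-16S).
#' @return object of class `mlsa`; see Details.
#' @details The returned object is a list with components
#'   `summaries` (named list of [locus_summary()] results, concatenation
#'   last under `"MLSA"`), `dist` and `sim` (named lists of matrices),
#'   `tree` (`phylo`, with `node.label` support if `bootstrap > 0`),
#'   `partition` (`mlsa_partition`), `ranges` (per-locus intra/inter
#'   `range_report`s), `gaps` (per-locus [similarity_gap()] records, NULL
#'   where undefined), `calibration` (per-locus `ddh_calibration` or NULL),
#'   `ranking` ([rank_loci_by_resolution()] table), `cutoff_used`, and the
#'   call parameters.
#' @seealso [make_benchmark()] to generate synthetic inputs, [run_pipeline()]
#'   for the file-based front end.
#' @export
#' @examples
#' bench <- make_benchmark(mlsa_sim_config(
#'   n_species = 3, strains_per_species = c(3, 2, 2),
#'   loci = data.frame(name = c("g1", "g2"), length = c(300L, 300L),
#'                     rate = c(1, 1), gc = c(0.5, 0.5)),
#'   seed = 7))
#' fit <- mlsa(bench$loci, ddh = bench$ddh)
#' fit
mlsa <- function(loci, ddh = NULL, cutoff = NULL, boundary = 70,
                 bootstrap = 0, seed = 1,
                 deletion = c("complete", "pairwise"),
                 linkage = c("single", "complete"),
                 outgroup = NULL, concat_loci = NULL) {
  deletion <- match.arg(deletion)
  linkage <- match.arg(linkage)
  if (!length(loci))
    mlsa_stop("mlsa_parameter_error", "need at least one locus")
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, function(a) a$locus_name, character(1))
  concat_loci <- concat_loci %||%
    names(loci)[!grepl("16S", names(loci), ignore.case = TRUE)]
  if (!length(concat_loci)) concat_loci <- names(loci)
  concat <- concatenate_loci(loci[concat_loci])

  all_aln <- c(loci, list(MLSA = concat))
  dist <- lapply(all_aln, p_distance_matrix, deletion = deletion)
  sim <- lapply(dist, similarity_matrix)
  summaries <- lapply(names(all_aln), function(l)
    locus_summary(all_aln[[l]], locus_name = if (l == "MLSA") "MLSA" else l,
                  deletion = deletion))
  names(summaries) <- names(all_aln)

  tree <- if (bootstrap > 0) {
    bootstrap_support(concat, n_reps = bootstrap, seed = seed,
                      deletion = deletion, outgroup = outgroup)
  } else {
    nj_tree(dist$MLSA, outgroup = outgroup)
  }

  calibration <- NULL
  if (!is.null(ddh)) {
    ddh <- validate_ddh(ddh)
    calibration <- lapply(sim, function(s)
      tryCatch(calibrate_threshold(s, ddh, boundary = boundary),
               mlsa_calibration_undefined_error = function(e) NULL))
  }

  cutoff_used <- cutoff %||% {
    if (is.null(calibration) || is.null(calibration$MLSA))
      mlsa_stop("mlsa_parameter_error",
                "supply a delimitation cutoff or a DDH matrix to calibrate one")
    # the calibrated threshold is the interspecies similarity ceiling; place
    # the clustering cutoff at the midpoint of the calibrated gap so that
    # pairs at the ceiling are not merged
    cal <- calibration$MLSA
    same <- cal$pairs$similarity[cal$pairs$same_species]
    intra_floor <- if (length(same)) min(same) else 100
    if (intra_floor > cal$threshold)
      (cal$threshold + intra_floor) / 2
    else
      cal$threshold
  }
  partition <- cluster_at_threshold(sim$MLSA, cutoff_used, linkage = linkage)

  ranges <- lapply(sim, intra_inter_ranges, p = partition)
  gaps <- lapply(ranges, function(r)
    tryCatch(similarity_gap(r$intra, r$inter),
             mlsa_undefined_gap_error = function(e) NULL))
  ranking <- rank_loci_by_resolution(calibration %||%
                                       stats::setNames(vector("list", length(ranges)),
                                                       names(ranges)),
                                     ranges)

  structure(
    list(summaries = summaries, alignments = all_aln, concat = concat,
         dist = dist, sim = sim, tree = tree, partition = partition,
         ranges = ranges, gaps = gaps, calibration = calibration,
         ranking = ranking, cutoff_used = cutoff_used,
         params = list(boundary = boundary, bootstrap = bootstrap,
                       seed = seed, deletion = deletion, linkage = linkage,
                       outgroup = outgroup, concat_loci = concat_loci),
         call = match.call()),
    class = "mlsa"
  )
}

#' @export
print.mlsa <- function(x, ...) {
  cat("Multilocus sequence analysis\n")
  cat(sprintf("  %d strains, %d loci (+ concatenation, %d bp)\n",
              length(x$concat$strain_ids),
              length(x$alignments) - 1L, x$concat$length))
  cat(sprintf("  delimitation: %d groups at %.1f%% similarity (%s linkage)\n",
              x$partition$n_groups, x$cutoff_used, x$params$linkage))
  g <- x$gaps$MLSA
  if (!is.null(g)) {
    if (g$gap_exists)
      cat(sprintf("  concatenated similarity gap: (%.1f, %.1f)%%\n",
                  g$gap_interval[1], g$gap_interval[2]))
    else
      cat(sprintf("  no concatenated similarity gap (overlap %.1f points)\n",
                  g$overlap_width))
  }
  if (!is.null(x$calibration))
    cat(sprintf("  DDH-calibrated thresholds over %d strains: %s\n",
                x$calibration$MLSA$n_strains,
                paste(sprintf("%s %.1f%%", names(x$calibration),
                              vapply(x$calibration, function(c)
                                if (is.null(c)) NA_real_ else c$threshold,
                                numeric(1))), collapse = ", ")))
  invisible(x)
}

#' Calibrated species-boundary thresholds of an MLSA fit
#'
#' @param object an `mlsa` object.
#' @param ... unused.
#' @return named numeric vector of per-locus calibrated similarity thresholds
#'   (percent); when no DDH matrix was supplied, a single element named
#'   `"cutoff"` with the delimitation cutoff used.
#' @export
coef.mlsa <- function(object, ...) {
  if (is.null(object$calibration))
    return(c(cutoff = object$cutoff_used))
  vapply(object$calibration, function(c)
    if (is.null(c)) NA_real_ else c$threshold, numeric(1))
}

#' Summarise an MLSA fit
#'
#' @param object an `mlsa` object.
#' @param ... unused.
#' @return object of class `summary.mlsa` holding the locus characteristics
#'   table, group sizes, per-locus ranges and the resolution ranking.
#' @export
summary.mlsa <- function(object, ...) {
  structure(
    list(table2 = render_table2(object$summaries),
         sizes = object$partition$sizes,
         cutoff = object$cutoff_used,
         ranges = ranges_table(object$ranges),
         ranking = object$ranking,
         boundary = object$params$boundary,
         has_ddh = !is.null(object$calibration)),
    class = "summary.mlsa")
}

#' @export
print.summary.mlsa <- function(x, ...) {
  cat("Locus characteristics:\n")
  print(x$table2, row.names = FALSE)
  cat(sprintf("\nGroups at %.1f%% similarity: %s\n", x$cutoff,
              paste(sprintf("%s(%d)", names(x$sizes), x$sizes), collapse = " ")))
  cat("\nResolution ranking (gap width = intra.min - inter.max):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Plot an MLSA fit
#'
#' `which = "gap"` draws the per-locus intraspecies/interspecies similarity
#' ranges as paired vertical bars (the gap diagnostic); `which = "ddh"` draws
#' the concatenated similarity against DDH with the species boundary and the
#' calibrated threshold (requires a DDH matrix); `which = "tree"` plots the
#' (display-rooted, if an outgroup was set) NJ tree with bootstrap labels.
#'
#' @param x an `mlsa` object.
#' @param which `"gap"`, `"ddh"` or `"tree"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.mlsa <- function(x, which = c("gap", "ddh", "tree"), ...) {
  which <- match.arg(which)
  if (which == "gap") {
    loci <- names(x$ranges)
    n <- length(loci)
    graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(60, 100),
                   xaxt = "n", xlab = "", ylab = "Sequence similarity (%)", ...)
    graphics::axis(1, at = seq_len(n), labels = loci, las = 2)
    for (i in seq_len(n)) {
      r <- x$ranges[[i]]
      if (r$intra$n_pairs > 0)
        graphics::segments(i - 0.15, r$intra$min, i - 0.15, r$intra$max,
                           lwd = 6, col = "forestgreen")
      if (r$inter$n_pairs > 0)
        graphics::segments(i + 0.15, r$inter$min, i + 0.15, r$inter$max,
                           lwd = 6, col = "firebrick")
    }
    graphics::legend("bottomleft", legend = c("intraspecies", "interspecies"),
                     col = c("forestgreen", "firebrick"), lwd = 6, bty = "n")
  } else if (which == "ddh") {
    if (is.null(x$calibration) || is.null(x$calibration$MLSA))
      mlsa_stop("mlsa_parameter_error", "fit has no DDH calibration to plot")
    cal <- x$calibration$MLSA
    graphics::plot(cal$pairs$ddh, cal$pairs$similarity,
                   xlab = "Estimated DDH (%)",
                   ylab = "Concatenated similarity (%)",
                   col = ifelse(cal$pairs$same_species, "forestgreen", "firebrick"),
                   pch = 19, ...)
    graphics::abline(v = cal$boundary, lty = 2)
    graphics::abline(h = cal$threshold, lty = 3)
  } else {
    tr <- attr(x$tree, "rooted") %||% x$tree
    ape::plot.phylo(tr, show.node.label = TRUE, ...)
  }
  invisible(x)
}
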