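#' Read a pairwise digital DDH matrix from a labeled TSV
#'
#' The expected layout is a square labeled matrix of estimated DNA-DNA
#' hybridization percentages (e.g. as produced by tabulating GGDC output over a
#' set of genomes): a header row of strain ids, a leading id column, values in
#' \[0, 100\], symmetric, diagonal 100.
#'
#' @param path TSV path.
#' @return validated numeric DDH matrix.
#' @export
read_ddh_tsv <- function(path) {
  validate_ddh(read_matrix_tsv(path))
}

validate_ddh <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    mlsa_stop("mlsa_validation_error", "DDH input must be a square matrix")
  if (max(abs(m - t(m))) > 1e-6)
    mlsa_stop("mlsa_validation_error", "DDH matrix is not symmetric")
  if (any(m < -1e-9 | m > 100 + 1e-9))
    mlsa_stop("mlsa_validation_error", "DDH values must lie in [0, 100]")
  diag(m) <- 100
  m
}

#' Label strain pairs as same- or different-species from DDH
#'
#' Pairs at or above the boundary (the classical 70% DDH species boundary by
#' default) are same-species; strictly below is different-species.
#'
#' @param ddh DDH matrix.
#' @param boundary percent DDH boundary (default 70).
#' @return data.frame with columns `strain_a`, `strain_b`, `ddh`,
#'   `same_species`.
#' @export
classify_pairs <- function(ddh, boundary = 70) {
  ddh <- validate_ddh(ddh)
  ids <- rownames(ddh)
  ut <- which(upper.tri(ddh), arr.ind = TRUE)
  data.frame(strain_a = ids[ut[, 1L]], strain_b = ids[ut[, 2L]],
             ddh = ddh[ut], same_species = ddh[ut] >= boundary,
             stringsAsFactors = FALSE)
}

#' Calibrate a species-boundary similarity cutoff against DDH
#'
#' Formalises reading the species boundary off a similarity-vs-DDH scatter:
#' the calibrated threshold is the maximum sequence similarity observed among
#' pairs whose DDH falls below the boundary (different-species pairs). It is
#' the tightest cutoff at which no different-species pair is merged. Conflicts
#' are same-species pairs whose similarity falls below that threshold (the
#' marker then cannot separate species at any cutoff; the classical 16S
#' crossover). A rank correlation of similarity against DDH over the common
#' pairs is reported alongside.
#'
#' @param s similarity matrix (percent) for one locus or the concatenation.
#' @param ddh DDH matrix over a subset of the same strains.
#' @param boundary DDH species boundary, percent (default 70).
#' @param cor_method `"spearman"` (default, robust to the nonlinear
#'   similarity-DDH relationship) or `"pearson"`.
#' @return object of class `ddh_calibration`: list with `locus`, `threshold`,
#'   `n_species_pairs`, `n_nonspecies_pairs`, `conflicts` (data.frame),
#'   `rho`, `n_strains`, `pairs` (data.frame of all common pairs with
#'   similarity and DDH).
#' @export
calibrate_threshold <- function(s, ddh, boundary = 70,
                                cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  ddh <- validate_ddh(ddh)
  common <- intersect(rownames(s), rownames(ddh))
  if (length(common) < 2L)
    mlsa_stop("mlsa_size_error",
              "calibration needs >= 2 strains common to similarity and DDH matrices")
  ss <- s[common, common]
  dd <- ddh[common, common]
  ut <- which(upper.tri(ss), arr.ind = TRUE)
  pairs <- data.frame(
    strain_a = common[ut[, 1L]], strain_b = common[ut[, 2L]],
    similarity = ss[ut], ddh = dd[ut],
    same_species = dd[ut] >= boundary, stringsAsFactors = FALSE)
  diff_pairs <- pairs[!pairs$same_species, , drop = FALSE]
  if (nrow(diff_pairs) == 0L)
    mlsa_stop("mlsa_calibration_undefined_error",
      "no pair below the %g%% DDH boundary; threshold undefined", boundary)
  threshold <- max(diff_pairs$similarity)
  same_pairs <- pairs[pairs$same_species, , drop = FALSE]
  conflicts <- same_pairs[same_pairs$similarity < threshold, , drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(pairs$similarity, pairs$ddh, method = cor_method))
  structure(
    list(locus = attr(s, "label") %||% "locus",
         threshold = threshold, boundary = boundary,
         n_species_pairs = nrow(same_pairs),
         n_nonspecies_pairs = nrow(diff_pairs),
         conflicts = conflicts, rho = rho,
         cor_method = cor_method,
         n_strains = length(common), pairs = pairs),
    class = "ddh_calibration"
  )
}

#' @export
print.ddh_calibration <- function(x, ...) {
  cat(sprintf(
    "<ddh_calibration> %s: threshold %.1f%% at DDH %g%% boundary (%d species / %d non-species pairs over %d strains)\n",
    x$locus, x$threshold, x$boundary,
    x$n_species_pairs, x$n_nonspecies_pairs, x$n_strains))
  if (nrow(x$conflicts))
    cat(sprintf(" %d conflicting same-species pair(s) below the threshold\n",
                nrow(x$conflicts)))
  cat(sprintf(" %s rho(similarity, DDH) = %.3f\n", x$cor_method, x$rho))
  invisible(x)
}

#' Rank loci by species-resolving power
#'
#' Loci are ordered by the width of their intraspecies/interspecies similarity
#' gap (intra.min - inter.max), descending; ties are broken by the lower
#' calibrated threshold. A wider gap means cutoffs inside it are less sensitive
#' to sampling noise.
#'
#' @param calibrations named list (by locus) of `ddh_calibration` objects (may
#'   be NULL entries when no DDH is available).
#' @param ranges named list (by locus) of [intra_inter_ranges()] results.
#' @return data.frame ordered by resolution with columns `locus`, `gap_width`,
#'   `intra_min`, `inter_max`, `threshold`, `rho`.
#' @export
rank_loci_by_resolution <- function(calibrations, ranges) {
  loci <- names(ranges)
  if (!length(loci))
    mlsa_stop("mlsa_parameter_error", "need at least one locus to rank")
  df <- do.call(rbind, lapply(loci, function(l) {
    r <- ranges[[l]]
    cal <- calibrations[[l]]
    data.frame(
      locus = l,
      gap_width = r$intra$min - r$inter$max,
      intra_min = r$intra$min, inter_max = r$inter$max,
      threshold = if (is.null(cal)) NA_real_ else cal$threshold %||% NA_real_,
      rho = if (is.null(cal)) NA_real_ else cal$rho %||% NA_real_,
      stringsAsFactors = FALSE)
  }))
  thr <- ifelse(is.na(df$threshold), Inf, df$threshold)
  df[order(-df$gap_width, thr, df$locus), , drop = FALSE]
}

#' Write a calibration report TSV
#'
#' One row per locus: calibrated threshold, correlation, pair counts and the
#' number of conflicting pairs.
#'
#' @param calibrations named list of `ddh_calibration` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_tsv <- function(calibrations, path) {
  df <- do.call(rbind, lapply(names(calibrations), function(l) {
    x <- calibrations[[l]]
    data.frame(locus = l, threshold = x$threshold, rho = x$rho,
               n_species_pairs = x$n_species_pairs,
               n_nonspecies_pairs = x$n_nonspecies_pairs,
               n_conflicts = nrow(x$conflicts), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
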