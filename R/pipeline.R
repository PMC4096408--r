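#' Read a run configuration file
#'
#' A YAML file declaring the locus manifest and analysis flags. Recognised
#' keys: `loci` (ordered mapping locus name -> FASTA path; order is the
#' concatenation order), `ddh` (optional TSV path), `cutoff`, `boundary`,
#' `bootstrap`, `seed`, `deletion`, `linkage`, `outgroup`, `concat_loci`,
#' `outdir`.
#'
#' @param path YAML file path.
#' @return validated named list (class `mlsa_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    mlsa_stop("mlsa_io_error", "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  # paths are relative to the config file
  cfg$loci <- lapply(cfg$loci, function(p)
    if (file.exists(p)) p else file.path(base, p))
  if (!is.null(cfg$ddh) && !file.exists(cfg$ddh))
    cfg$ddh <- file.path(base, cfg$ddh)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$loci) || !length(cfg$loci))
    mlsa_stop("mlsa_parameter_error", "config must declare a non-empty locus manifest")
  for (l in names(cfg$loci))
    if (!file.exists(cfg$loci[[l]]))
      mlsa_stop("mlsa_io_error", "locus '%s': file not found: %s", l, cfg$loci[[l]])
  if (!is.null(cfg$ddh) && !file.exists(cfg$ddh))
    mlsa_stop("mlsa_io_error", "DDH file not found: %s", cfg$ddh)
  cfg$boundary <- cfg$boundary %||% 70
  cfg$bootstrap <- cfg$bootstrap %||% 0
  cfg$seed <- cfg$seed %||% 1
  cfg$deletion <- cfg$deletion %||% "complete"
  cfg$linkage <- cfg$linkage %||% "single"
  cfg$outdir <- cfg$outdir %||% "mlsa_out"
  structure(cfg, class = "mlsa_run_config")
}

#' Run the full MLSA pipeline from a configuration
#'
#' Loads the per-locus FASTA alignments (and the DDH matrix, if declared),
#' fits [mlsa()], and writes the report set to the output directory: the
#' locus-characteristics table, square similarity/distance matrices per locus,
#' the newick tree (with bootstrap labels when requested), the groups table,
#' the intra/inter ranges table, the calibration report, a parameter log and a
#' manifest of every artifact with its MD5 checksum. Outputs are deterministic
#' for a fixed seed. If no DDH file is declared, the calibration stage is
#' skipped with an explicit notice and a `cutoff` must be configured.
#'
#' @param config an `mlsa_run_config`, a path to a YAML config, or a plain
#'   named list with the same fields.
#' @param outdir optional override of the configured output directory.
#' @return the fitted `mlsa` object, invisibly, with the manifest data.frame
#'   attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "mlsa_run_config")) config <- validate_run_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- "read alignments"
  fit <- tryCatch({
    loci <- lapply(names(config$loci), function(l)
      read_locus_fasta(config$loci[[l]], locus_name = l))
    names(loci) <- names(config$loci)
    ddh <- NULL
    if (!is.null(config$ddh)) {
      stage <- "read DDH matrix"
      ddh <- read_ddh_tsv(config$ddh)
    } else {
      message("no DDH matrix declared: calibration stage skipped")
    }
    stage <- "fit"
    mlsa(loci, ddh = ddh, cutoff = config$cutoff,
         boundary = config$boundary, bootstrap = config$bootstrap,
         seed = config$seed, deletion = config$deletion,
         linkage = config$linkage, outgroup = config$outgroup,
         concat_loci = config$concat_loci)
  }, mlsa_error = function(e) {
    mlsa_stop("mlsa_pipeline_error", "pipeline failed at stage '%s': %s",
              stage, conditionMessage(e))
  })

  files <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    files <<- c(files, p)
    p
  }
  emit("table2.tsv", function(p) write_table2_tsv(fit$summaries, p))
  for (l in names(fit$sim)) {
    emit(sprintf("similarity_%s.tsv", l),
         function(p) write_matrix_tsv(fit$sim[[l]], p))
    emit(sprintf("pdistance_%s.tsv", l),
         function(p) write_matrix_tsv(fit$dist[[l]], p, digits = 8))
  }
  emit("tree_mlsa.nwk", function(p) write_newick(fit$tree, p))
  emit("groups.tsv", function(p) write_partition_tsv(fit$partition, p))
  emit("ranges.tsv", function(p)
    utils::write.table(ranges_table(fit$ranges), p, sep = "\t",
                       quote = FALSE, row.names = FALSE))
  if (!is.null(fit$calibration))
    emit("calibration.tsv", function(p)
      write_calibration_tsv(Filter(Negate(is.null), fit$calibration), p))
  emit("ranking.tsv", function(p)
    utils::write.table(fit$ranking, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("run_log.txt", function(p) {
    writeLines(c(
      sprintf("mlsadelim %s", as.character(utils::packageVersion("mlsadelim"))),
      sprintf("R %s", as.character(getRversion())),
      sprintf("seed: %s", config$seed),
      sprintf("deletion: %s", config$deletion),
      sprintf("linkage: %s", config$linkage),
      sprintf("bootstrap: %s", config$bootstrap),
      sprintf("boundary: %s", config$boundary),
      sprintf("cutoff used: %s", fit$cutoff_used),
      sprintf("loci: %s", paste(names(config$loci), collapse = ", ")),
      sprintf("ddh: %s", config$ddh %||% "none")), p)
  })
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

#' Render the locus-characteristics table
#'
#' One row per locus plus the concatenation, in the column order
#' Locus, Length (bp), No. of alleles, Average G+C content (mol%),
#' Polymorphic sites No., Polymorphic sites %, P-distance Range,
#' P-distance Mean.
#'
#' @param summaries named list of [locus_summary()] objects.
#' @return data.frame in report column order.
#' @export
render_table2 <- function(summaries) {
  do.call(rbind, lapply(summaries, as.data.frame))
}

#' Write the locus-characteristics table as TSV
#'
#' @param summaries named list of [locus_summary()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table2_tsv <- function(summaries, path) {
  utils::write.table(render_table2(summaries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
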