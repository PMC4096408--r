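#' Simulation configuration for a multilocus benchmark
#'
#' Defines the structure of a synthetic MLSA study: a set of species with
#' unequal strain counts, several loci with per-locus lengths, substitution
#' rate multipliers and G+C composition, a within-species divergence scale and
#' a between-species divergence band, and an exponential mapping from
#' concatenated genomic distance to digital DDH. The defaults mirror a typical
#' genus-level bacterial survey: 42 strains in 12 species (one dominant
#' 20-strain species, several singletons), a near-invariant 16S-like locus of
#' 1419 bp beside five variable protein-coding loci of 774/648/504/657/855 bp,
#' intraspecies concatenated similarity above ~96% and interspecies similarity
#' below ~93%.
#'
#' @param n_species number of species.
#' @param strains_per_species integer vector of strain counts per species
#'   (length `n_species`).
#' @param loci data.frame with columns `name`, `length` (bp), `rate`
#'   (multiplier on the tree's substitutions/site) and `gc` (equilibrium G+C
#'   fraction of the root sequence).
#' @param t_intra expected tip depth of each within-species clade
#'   (substitutions/site); same-species tips are `2 * t_intra` apart.
#' @param t_inter_range band (lo, hi) of between-species node depths; two
#'   species diverging at depth D are `2 * D` apart.
#' @param ddh_lambda decay scale of the DDH mapping
#'   `DDH = 100 * exp(-d / ddh_lambda)` over concatenated p-distance `d`.
#' @param ddh_noise_sd Gaussian noise (percent DDH) added to the mapping.
#' @param seed integer; fixes every random draw of the bundle.
#' @return object of class `mlsa_sim_config`.
#' @export
mlsa_sim_config <- function(
    n_species = 12,
    strains_per_species = c(20, 5, 5, 3, 2, 1, 1, 1, 1, 1, 1, 1),
    loci = data.frame(
      name = c("16S", "leuA", "clpA", "pyrH", "gatA", "rpoD"),
      length = c(1419L, 774L, 648L, 504L, 657L, 855L),
      rate = c(0.07, 1.02, 0.83, 1.20, 1.07, 0.93),
      gc = c(0.536, 0.606, 0.615, 0.589, 0.623, 0.596),
      stringsAsFactors = FALSE),
    t_intra = 0.002,
    t_inter_range = c(0.05, 0.10),
    ddh_lambda = 0.12,
    ddh_noise_sd = 2,
    seed = 1) {
  if (length(strains_per_species) != n_species)
    mlsa_stop("mlsa_parameter_error",
              "strains_per_species must have length n_species")
  if (any(strains_per_species < 1))
    mlsa_stop("mlsa_parameter_error", "each species needs >= 1 strain")
  if (any(loci$length < 1))
    mlsa_stop("mlsa_parameter_error", "locus lengths must be >= 1")
  if (any(loci$rate <= 0))
    mlsa_stop("mlsa_parameter_error", "rate multipliers must be > 0")
  if (!(t_intra >= 0 && t_intra < min(t_inter_range)))
    mlsa_stop("mlsa_parameter_error",
              "need 0 <= t_intra < min(t_inter_range)")
  if (t_inter_range[1] > t_inter_range[2])
    mlsa_stop("mlsa_parameter_error", "t_inter_range must be (lo, hi)")
  structure(
    list(n_species = n_species, strains_per_species = strains_per_species,
         loci = loci, t_intra = t_intra, t_inter_range = t_inter_range,
         ddh_lambda = ddh_lambda, ddh_noise_sd = ddh_noise_sd,
         seed = as.integer(seed)),
    class = "mlsa_sim_config"
  )
}

#' Simulate an ultrametric species/strain tree
#'
#' Species lineages coalesce at depths drawn uniformly from `t_inter_range`
#' (sorted, joined in random pairs), so any two different-species strains are
#' between `2 * lo` and `2 * hi` apart. Each species is a star clade: its
#' strains hang from the species node by pendant edges of length `t_intra`, so
#' same-species strains are exactly `2 * t_intra` apart.
#'
#' @param cfg an [mlsa_sim_config()].
#' @return list with `tree` (`phylo` over strain tips `S01_1`, ...),
#'   `partition` (ground-truth `mlsa_partition`) and `species_of` (named
#'   character vector strain -> species).
#' @export
simulate_species_tree <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 1))
  ns <- cfg$n_species
  species <- sprintf("S%02d", seq_len(ns))
  strain_ids <- unlist(lapply(seq_len(ns), function(i)
    sprintf("%s_%d", species[i], seq_len(cfg$strains_per_species[i]))))
  species_of <- stats::setNames(rep(species, cfg$strains_per_species), strain_ids)

  # species subtree: star of pendant edges t_intra (or a bare tip)
  make_species <- function(i) {
    tips <- strain_ids[species_of == species[i]]
    if (length(tips) == 1L)
      list(node = tips[[1L]], depth = 0)
    else
      list(node = list(children = as.list(tips),
                       blens = rep(cfg$t_intra, length(tips))),
           depth = cfg$t_intra)
  }
  active <- lapply(seq_len(ns), make_species)
  if (ns > 1L) {
    depths <- sort(stats::runif(ns - 1L, cfg$t_inter_range[1], cfg$t_inter_range[2]))
    for (k in seq_len(ns - 1L)) {
      pick <- sample.int(length(active), 2L)
      a <- active[[pick[1L]]]; b <- active[[pick[2L]]]
      joined <- list(
        node = list(children = list(a$node, b$node),
                    blens = c(depths[k] - a$depth, depths[k] - b$depth)),
        depth = depths[k])
      active <- c(active[-pick], list(joined))
    }
  }
  root <- active[[1L]]$node
  tree <- if (is.character(root)) NULL else node_to_phylo(root)
  if (is.null(tree))
    mlsa_stop("mlsa_parameter_error", "cannot build a tree from a single strain")
  list(tree = tree, partition = as_partition(species_of),
       species_of = species_of)
}

#' Evolve one locus along a tree under Jukes-Cantor substitution
#'
#' The root sequence is drawn i.i.d. with G+C fraction `gc`; each site then
#' evolves independently down the tree. Along a branch of length `t` (times
#' the locus rate multiplier) a site substitutes to a uniformly chosen
#' different base with probability `(3/4) * (1 - exp(-4 * t * rate / 3))`.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param length locus length in bp.
#' @param rate rate multiplier (> 0).
#' @param gc root G+C fraction (default 0.5).
#' @param seed integer seed.
#' @param locus_name label for the returned alignment.
#' @return a [locus_alignment] over the tree's tips.
#' @export
evolve_locus <- function(tree, length, rate = 1, gc = 0.5, seed = 1,
                         locus_name = "locus") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  freqs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ntip <- base::length(tree$tip.label)
  nn <- max(tree$edge)
  rootn <- ntip + 1L
  seqs <- vector("list", nn)
  seqs[[rootn]] <- sample.int(4L, length, replace = TRUE, prob = freqs)
  tr <- stats::reorder(tree, "cladewise")   # parents before children
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    t_eff <- tr$edge.length[k] * rate
    psub <- 0.75 * (1 - exp(-4 * t_eff / 3))
    s <- seqs[[p]]
    hit <- which(stats::runif(length) < psub)
    if (base::length(hit)) {
      shift <- sample.int(3L, base::length(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[[ch]] <- s
  }
  rows <- vapply(seq_len(ntip), function(i)
    paste(bases[seqs[[i]]], collapse = ""), character(1))
  locus_alignment(stats::setNames(rows, tree$tip.label), locus_name)
}

#' Map genomic distances to a synthetic digital DDH matrix
#'
#' `DDH(d) = 100 * exp(-d / lambda)`, optionally plus symmetric Gaussian noise,
#' clipped to \[0, 100\], diagonal 100. The noiseless map is strictly
#' decreasing in `d` and crosses the 70% species boundary at
#' `d = lambda * log(10/7)`.
#'
#' @param d symmetric non-negative distance matrix (e.g. concatenated
#'   p-distances over the genome-sequenced strains).
#' @param lambda decay scale.
#' @param noise_sd Gaussian noise sd in DDH percentage points (0 = noiseless).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `ddh` (noisy, or identical to noiseless when
#'   `noise_sd = 0`) and `noiseless` matrices.
#' @export
simulate_ddh <- function(d, lambda, noise_sd = 0, seed = 1) {
  if (any(d < -1e-12))
    mlsa_stop("mlsa_parameter_error", "distances must be >= 0")
  noiseless <- 100 * exp(-d / lambda)
  diag(noiseless) <- 100
  ddh <- noiseless
  if (noise_sd > 0) {
    set.seed(seed)
    n <- nrow(d)
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::rnorm(sum(upper.tri(eps)), 0, noise_sd)
    eps <- eps + t(eps)
    ddh <- pmin(pmax(noiseless + eps, 0), 100)
    diag(ddh) <- 100
  }
  dimnames(ddh) <- dimnames(noiseless) <- dimnames(d)
  list(ddh = ddh, noiseless = noiseless)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Simulates the species tree, evolves every locus, concatenates the
#' protein-coding (non-16S-like) loci, picks genome-sequenced representatives
#' (the first strain of every species, plus the full membership of any
#' two-strain species, mimicking a paired type-strain case) and maps their
#' concatenated p-distances to a DDH matrix. Optionally writes the bundle to
#' disk (one FASTA per locus, a DDH TSV, a ground-truth partition TSV).
#'
#' @param cfg an [mlsa_sim_config()].
#' @param dir optional output directory; created if needed.
#' @return list of class `mlsa_benchmark` with `config`, `loci` (named list of
#'   [locus_alignment]), `concat`, `tree`, `truth` (partition), `species_of`,
#'   `representatives`, `ddh`, `ddh_noiseless` and (when written) `files`.
#' @export
make_benchmark <- function(cfg = mlsa_sim_config(), dir = NULL) {
  sim <- simulate_species_tree(cfg)
  loci <- vector("list", nrow(cfg$loci))
  names(loci) <- cfg$loci$name
  for (i in seq_len(nrow(cfg$loci))) {
    loci[[i]] <- evolve_locus(
      sim$tree, cfg$loci$length[i], rate = cfg$loci$rate[i],
      gc = cfg$loci$gc[i], seed = sub_seed(cfg$seed, 100 + i),
      locus_name = cfg$loci$name[i])
  }
  coding <- names(loci)[!grepl("16S", names(loci), ignore.case = TRUE)]
  concat <- concatenate_loci(loci[coding])
  reps <- unlist(lapply(sim$partition$members, function(m) {
    m <- sort(m)
    if (length(m) == 2L) m else m[1L]
  }), use.names = FALSE)
  dcat <- p_distance_matrix(concat)[reps, reps]
  ddh <- simulate_ddh(dcat, cfg$ddh_lambda, cfg$ddh_noise_sd,
                      seed = sub_seed(cfg$seed, 999))
  out <- structure(
    list(config = cfg, loci = loci, concat = concat, tree = sim$tree,
         truth = sim$partition, species_of = sim$species_of,
         representatives = reps, ddh = ddh$ddh, ddh_noiseless = ddh$noiseless),
    class = "mlsa_benchmark")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      stats::setNames(
        vapply(names(loci), function(l) {
          p <- file.path(dir, paste0(l, ".fasta"))
          write_locus_fasta(loci[[l]], p); p
        }, character(1)), names(loci)),
      ddh = write_matrix_tsv(ddh$ddh, file.path(dir, "ddh.tsv")),
      truth = write_partition_tsv(sim$partition, file.path(dir, "truth_groups.tsv")))
    out$files <- files
  }
  out
}

#' @export
print.mlsa_benchmark <- function(x, ...) {
  cat(sprintf(
    "<mlsa_benchmark> %d strains, %d species, %d loci (concat %d bp), %d DDH representatives\n",
    length(x$species_of), x$config$n_species, length(x$loci),
    x$concat$length, length(x$representatives)))
  invisible(x)
}
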