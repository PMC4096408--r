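tiny_cfg <- function(seed = 1, t_intra = 0.01, t_inter_range = c(0.1, 0.2)) {
  mlsa_sim_config(
    n_species = 2, strains_per_species = c(2, 2),
    loci = data.frame(name = "g1", length = 100L, rate = 1, gc = 0.5),
    t_intra = t_intra, t_inter_range = t_inter_range, seed = seed)
}

test_that("config invariants are enforced", {
  expect_error(mlsa_sim_config(n_species = 3, strains_per_species = c(1, 1)),
               class = "mlsa_parameter_error")
  expect_error(tiny_cfg(t_intra = 0.5), class = "mlsa_parameter_error")
  expect_error(mlsa_sim_config(loci = data.frame(
    name = "g", length = 0L, rate = 1, gc = 0.5)),
    class = "mlsa_parameter_error")
  expect_error(mlsa_sim_config(loci = data.frame(
    name = "g", length = 10L, rate = -1, gc = 0.5)),
    class = "mlsa_parameter_error")
})

test_that("species tree respects the planted depth bands", {
  cfg <- mlsa_sim_config(seed = 6)
  sim <- simulate_species_tree(cfg)
  d <- ape::cophenetic.phylo(sim$tree)
  sp <- sim$species_of[rownames(d)]
  same <- outer(sp, sp, "==") & upper.tri(d)
  diff <- !outer(sp, sp, "==") & upper.tri(d)
  expect_true(all(d[same] <= 2 * cfg$t_intra + 1e-9))
  expect_true(all(d[diff] >= 2 * cfg$t_inter_range[1] - 2 * cfg$t_intra - 1e-9))
  expect_true(all(d[diff] <= 2 * cfg$t_inter_range[2] + 2 * cfg$t_intra + 1e-9))
  # ground-truth partition mirrors the strain assignment
  expect_equal(sim$partition$n_groups, cfg$n_species)
  expect_equal(unname(sort(sim$partition$sizes, decreasing = TRUE)),
               sort(cfg$strains_per_species, decreasing = TRUE))
})

test_that("a single species yields one shallow clade", {
  cfg <- mlsa_sim_config(n_species = 1, strains_per_species = 4,
                         loci = data.frame(name = "g", length = 50L,
                                           rate = 1, gc = 0.5),
                         t_intra = 0.01, t_inter_range = c(0.1, 0.2), seed = 2)
  sim <- simulate_species_tree(cfg)
  d <- ape::cophenetic.phylo(sim$tree)
  expect_true(all(d[upper.tri(d)] <= 2 * cfg$t_intra + 1e-9))
})

test_that("the generator is deterministic under a fixed seed", {
  b1 <- make_benchmark(tiny_cfg(seed = 33))
  b2 <- make_benchmark(tiny_cfg(seed = 33))
  expect_identical(b1$loci$g1$seqs, b2$loci$g1$seqs)
  expect_identical(b1$ddh, b2$ddh)
  expect_identical(b1$truth$groups, b2$truth$groups)
  b3 <- make_benchmark(tiny_cfg(seed = 34))
  expect_false(identical(b1$loci$g1$seqs, b3$loci$g1$seqs))
})

test_that("zero rate freezes the root sequence", {
  cfg <- tiny_cfg(seed = 5)
  sim <- simulate_species_tree(cfg)
  aln <- evolve_locus(sim$tree, 200, rate = 0, gc = 0.5, seed = 9)
  expect_equal(count_alleles(aln), 1L)
  expect_equal(max(p_distance_matrix(aln)), 0)
})

test_that("JC69 pairwise divergence matches the closed form", {
  # two tips at total path length 2t: expected p = (3/4)(1 - exp(-8t/3))
  t <- 0.15
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t, t))
  L <- 10000L
  aln <- evolve_locus(tr, L, rate = 1, gc = 0.5, seed = 17)
  p_hat <- p_distance_matrix(aln)["a", "b"]
  p_exp <- 0.75 * (1 - exp(-8 * t / 3))
  mc_se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_hat - p_exp), 3 * mc_se)
})

test_that("a higher rate multiplier increases divergence on the same tree", {
  cfg <- mlsa_sim_config(seed = 12)
  sim <- simulate_species_tree(cfg)
  slow <- evolve_locus(sim$tree, 800, rate = 0.3, gc = 0.5, seed = 21)
  fast <- evolve_locus(sim$tree, 800, rate = 1.5, gc = 0.5, seed = 21)
  expect_lt(mean(p_distance_matrix(slow)), mean(p_distance_matrix(fast)))
})

test_that("the DDH mapping is exact at its anchors and strictly decreasing", {
  d <- matrix(c(0, 0.05, 0.05, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  lam <- 0.12
  out <- simulate_ddh(d, lambda = lam, noise_sd = 0)
  expect_equal(out$noiseless["a", "b"], 100 * exp(-0.05 / lam))
  # the boundary anchor: d = lambda * ln(10/7) maps to exactly 70
  d70 <- matrix(c(0, lam * log(10 / 7), lam * log(10 / 7), 0), 2, 2,
                dimnames = dimnames(d))
  expect_equal(simulate_ddh(d70, lam, 0)$noiseless["a", "b"], 70)
  # zero distance maps to 100
  expect_equal(simulate_ddh(matrix(0, 2, 2, dimnames = dimnames(d)),
                            lam, 0)$noiseless[1, 2], 100)
  # strict monotone decrease over a distance grid
  grid <- seq(0, 0.5, by = 0.01)
  vals <- 100 * exp(-grid / lam)
  m <- matrix(0, length(grid) + 1, length(grid) + 1)
  m[1, -1] <- m[-1, 1] <- grid
  out2 <- simulate_ddh(m, lam, 0)
  expect_true(all(diff(out2$noiseless[1, -1]) < 0))
})

test_that("noise perturbs symmetrically within clipping bounds", {
  set.seed(1)
  d <- matrix(stats::runif(49, 0, 0.3), 7, 7)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(sprintf("s%d", 1:7), sprintf("s%d", 1:7))
  out <- simulate_ddh(d, 0.12, noise_sd = 3, seed = 8)
  expect_equal(out$ddh, t(out$ddh))
  expect_true(all(out$ddh >= 0 & out$ddh <= 100))
  expect_equal(unname(diag(out$ddh)), rep(100, 7))
})

test_that("benchmark bundles are self-consistent and re-readable", {
  dir <- withr::local_tempdir()
  bench <- make_benchmark(mlsa_sim_config(seed = 4), dir = dir)
  # default structure: six loci with the reference lengths
  lens <- vapply(bench$loci, function(a) a$length, integer(1))
  expect_equal(unname(lens), c(1419L, 774L, 648L, 504L, 657L, 855L))
  expect_equal(bench$concat$length, 3438L)
  expect_equal(length(bench$species_of), 42L)
  expect_equal(bench$truth$n_groups, 12L)
  expect_equal(length(bench$representatives), 13L)
  # emitted artifacts re-read through the package interfaces
  back <- read_locus_fasta(file.path(dir, "leuA.fasta"), "leuA")
  expect_identical(back$seqs, bench$loci$leuA$seqs)
  ddh <- read_ddh_tsv(file.path(dir, "ddh.tsv"))
  expect_equal(ddh, bench$ddh, tolerance = 1e-5, ignore_attr = TRUE)
  # per-locus summaries report the construction lengths
  expect_equal(locus_summary(bench$loci$`16S`)$length_bp, 1419L)
})

test_that("a tiny bundle supports end-to-end recovery", {
  bench <- make_benchmark(tiny_cfg(seed = 3))
  s <- similarity_matrix(p_distance_matrix(bench$concat))
  r <- intra_inter_ranges(s, bench$truth)
  mid <- (r$intra$min + r$inter$max) / 2
  p <- cluster_at_threshold(s, mid)
  expect_equal(p$n_groups, 2L)
  expect_equal(mclust::adjustedRandIndex(p$groups[names(bench$truth$groups)],
                                         bench$truth$groups), 1)
})

test_that("any cutoff inside the planted gap recovers the true partition", {
  for (seed in c(2, 9, 14)) {
    bench <- make_benchmark(mlsa_sim_config(seed = seed))
    s <- similarity_matrix(p_distance_matrix(bench$concat))
    r <- intra_inter_ranges(s, bench$truth)
    expect_true(r$intra$min > r$inter$max)
    for (ct in seq(r$inter$max + 0.2, r$intra$min - 0.2, length.out = 3)) {
      p <- cluster_at_threshold(s, ct)
      expect_equal(
        mclust::adjustedRandIndex(p$groups[names(bench$truth$groups)],
                                  bench$truth$groups), 1)
    }
  }
})
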