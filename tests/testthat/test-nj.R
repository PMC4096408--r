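test_that("three taxa give the unique topology with three-point lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(length(tr$tip.label), 3L)
  m <- edge_length_map(tr)
  expect_equal(unname(m[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ is exact on additive matrices (topology and branch lengths)", {
  for (seed in 1:25) {
    n <- 4 + (seed %% 5)
    gen <- random_additive(n, seed = seed)
    tr <- nj_tree(gen$d)
    expect_true(same_topology(tr, gen$tree))
    got <- edge_length_map(tr)
    want <- edge_length_map(gen$tree)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("NJ agrees with ape::nj on additive matrices", {
  for (seed in 1:8) {
    gen <- random_additive(6, seed = 100 + seed)
    expect_true(same_topology(nj_tree(gen$d), ape::nj(gen$d)))
  }
})

test_that("NJ output is invariant under strain permutation", {
  gen <- random_additive(7, seed = 9)
  perm <- sample(rownames(gen$d))
  tr1 <- nj_tree(gen$d)
  tr2 <- nj_tree(gen$d[perm, perm])
  expect_true(same_topology(tr1, tr2))
  expect_equal(edge_length_map(tr2)[names(edge_length_map(tr1))],
               edge_length_map(tr1), tolerance = 1e-9)
})

test_that("degenerate and invalid distance inputs are rejected", {
  d <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), class = "mlsa_size_error")
  d3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), class = "mlsa_validation_error")
})

test_that("negative NJ lengths are clamped to zero, never emitted", {
  # near-degenerate matrix known to produce a negative three-point length
  d <- matrix(c(0, 0.1, 0.11, 0.1, 0, 0.005, 0.11, 0.005, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    m <- matrix(stats::runif(n * n, 0, 0.3), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(sprintf("t%d", 1:n), sprintf("t%d", 1:n))
    expect_true(all(nj_tree(m)$edge.length >= 0))
  }
})

test_that("outgroup requests a display-rooted copy without changing splits", {
  gen <- random_additive(6, seed = 31)
  tr <- nj_tree(gen$d, outgroup = "t01")
  rooted <- attr(tr, "rooted")
  expect_false(is.null(rooted))
  expect_true(ape::is.rooted(rooted))
  expect_true(same_topology(tr, ape::unroot(rooted)))
})

test_that("bipartition extraction matches the ape::prop.part oracle", {
  for (seed in 1:10) {
    tr <- ape::rtree(4 + seed %% 6, rooted = FALSE)
    tr$tip.label <- sprintf("x%02d", seq_along(tr$tip.label))
    expect_setequal(names(tree_bipartitions(tr)), oracle_splits(tr))
  }
})

test_that("shared bipartitions behave as set intersection", {
  gen <- random_additive(8, seed = 17)
  tr <- nj_tree(gen$d)
  expect_setequal(names(shared_bipartitions(tr, tr)),
                  names(tree_bipartitions(tr)))
  # two conflicting 4-taxon resolutions share nothing
  a <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_length(shared_bipartitions(a, b), 0L)
  # random tree pairs equal the oracle intersection
  for (seed in 1:6) {
    t1 <- ape::rtree(7, rooted = FALSE); t1$tip.label <- sprintf("x%d", 1:7)
    t2 <- ape::rtree(7, rooted = FALSE); t2$tip.label <- sprintf("x%d", 1:7)
    expect_setequal(names(shared_bipartitions(t1, t2)),
                    intersect(oracle_splits(t1), oracle_splits(t2)))
  }
  bad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(shared_bipartitions(a, bad), class = "mlsa_validation_error")
})

test_that("bootstrap gives full support to a wide two-clade split and is reproducible", {
  cfg <- mlsa_sim_config(
    n_species = 2, strains_per_species = c(4, 4),
    loci = data.frame(name = "g1", length = 600L, rate = 1, gc = 0.5),
    t_intra = 0.005, t_inter_range = c(0.3, 0.4), seed = 5)
  bench <- make_benchmark(cfg)
  aln <- bench$loci$g1
  tr1 <- bootstrap_support(aln, n_reps = 100, seed = 11)
  sup <- attr(tr1, "support")
  central <- names(tree_bipartitions(tr1))[
    vapply(tree_bipartitions(tr1), length, integer(1)) == 4L]
  expect_equal(unname(sup[central]), 100)
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 11)
  expect_identical(attr(tr2, "support"), sup)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr1))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(sup == round(sup)))
})

test_that("an invariant alignment yields a star with zero support and a warning", {
  inv <- make_aln(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  expect_warning(tr <- bootstrap_support(inv, n_reps = 10, seed = 1),
                 "star")
  expect_equal(tr$Nnode, 1L)
  expect_length(tree_bipartitions(tr), 0L)
})

test_that("bootstrap support is stable across seeds within Monte-Carlo error", {
  cfg <- mlsa_sim_config(
    n_species = 3, strains_per_species = c(2, 2, 2),
    loci = data.frame(name = "g1", length = 500L, rate = 1, gc = 0.5),
    t_intra = 0.01, t_inter_range = c(0.08, 0.2), seed = 2)
  aln <- make_benchmark(cfg)$loci$g1
  s1 <- attr(bootstrap_support(aln, n_reps = 300, seed = 1), "support")
  s2 <- attr(bootstrap_support(aln, n_reps = 300, seed = 2), "support")
  # the difference of two independent binomial proportions at n = 300 has
  # sd at most sqrt(2 * 0.25 / 300) ~ 4.1 points; allow 4 sigma
  expect_true(all(abs(s1 - s2[names(s1)]) <= 4 * sqrt(2 * 0.25 / 300) * 100))
})

test_that("newick i/o round-trips topology, lengths and support labels", {
  gen <- random_additive(7, seed = 3)
  tr <- gen$tree
  tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  expect_setequal(back$node.label, tr$node.label)
  # minimal and malformed inputs
  p2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", p2)
  expect_equal(sort(read_newick(p2)$tip.label), c("A", "B"))
  p3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1;", p3)
  expect_error(read_newick(p3), class = "mlsa_parse_error")
})
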