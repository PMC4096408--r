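# shared fixtures and independent oracles used across the suite

make_aln <- function(..., name = "toy") {
  rows <- c(...)
  locus_alignment(rows, name)
}

random_alignment <- function(n, L, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  locus_alignment(stats::setNames(rows, sprintf("t%02d", seq_len(n))), "rand")
}

# random binary tree with positive branch lengths and its additive matrix
random_additive <- function(n, seed, min_len = 0.1, max_len = 1) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  d <- ape::cophenetic.phylo(tr)
  d <- d[tr$tip.label, tr$tip.label]
  list(tree = tr, d = d)
}

# independent split oracle built on ape::prop.part
oracle_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  ref <- sort(tree$tip.label)[1L]
  for (cl in pp) {
    side <- tree$tip.label[cl]
    if (length(side) %in% c(0L, 1L, ntip - 1L, ntip)) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

same_topology <- function(a, b) {
  setequal(oracle_splits(a), oracle_splits(b)) &&
    setequal(a$tip.label, b$tip.label)
}

# split -> length map for comparing branch lengths between trees (internal
# edges via splits, pendant edges via tip labels)
edge_length_map <- function(tree) {
  bp <- mlsadelim::tree_bipartitions(tree)
  internal <- attr(bp, "lengths")
  ntip <- length(tree$tip.label)
  pend <- tree$edge[, 2L] <= ntip
  pendant <- stats::setNames(tree$edge.length[pend],
                             tree$tip.label[tree$edge[pend, 2L]])
  c(internal, pendant)
}

# breadth-first-search connected components at a similarity cutoff
bfs_components <- function(s, cutoff) {
  n <- nrow(s)
  adj <- s >= cutoff
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  stats::setNames(comp, rownames(s))
}

# enumerate every unrooted binary topology on the given tips (as edge lists
# with tips 1..n and internal nodes as negative integers), by inserting each
# taxon into every edge of every smaller topology
enumerate_topologies <- function(n) {
  base <- list(matrix(c(-1L, 1L, -1L, 2L, -1L, 3L), ncol = 2, byrow = TRUE))
  if (n == 3L) return(base)
  trees <- base
  for (k in 4L:n) {
    nxt <- list()
    for (tr in trees) {
      new_int <- min(tr) - 1L
      for (e in seq_len(nrow(tr))) {
        a <- tr[e, 1L]; b <- tr[e, 2L]
        t2 <- rbind(tr[-e, , drop = FALSE],
                    c(a, new_int), c(new_int, b), c(new_int, k))
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

# per-edge tip side sets of an edge-list topology (tips 1..n)
topology_sides <- function(edges, n) {
  nodes <- unique(as.vector(edges))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1L]); b <- as.character(edges[e, 2L])
    adj[[a]] <- c(adj[[a]], edges[e, 2L])
    adj[[b]] <- c(adj[[b]], edges[e, 1L])
  }
  lapply(seq_len(nrow(edges)), function(e) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    # tips reachable from b without crossing the edge (a, b)
    seen <- c(a, b)
    queue <- b
    tips <- integer(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v >= 1L) tips <- c(tips, v)
      nb <- setdiff(adj[[as.character(v)]], seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    sort(tips)
  })
}

# ordinary least-squares fit of edge lengths for one topology; returns RSS
ls_rss <- function(edges, n, d) {
  sides <- topology_sides(edges, n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  A <- vapply(sides, function(side) {
    ina <- pairs[, 1L] %in% side
    inb <- pairs[, 2L] %in% side
    as.numeric(xor(ina, inb))
  }, numeric(nrow(pairs)))
  y <- d[upper.tri(d)]
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# canonical split keys of an edge-list topology, for comparing with a phylo
topology_keys <- function(edges, n, tip_labels) {
  sides <- topology_sides(edges, n)
  ref <- sort(tip_labels)[1L]
  keys <- character(0)
  for (side in sides) {
    if (length(side) %in% c(0L, 1L, n - 1L, n)) next
    lab <- tip_labels[side]
    if (ref %in% lab) lab <- setdiff(tip_labels, lab)
    keys <- c(keys, paste(sort(lab), collapse = "\r"))
  }
  unique(keys)
}
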