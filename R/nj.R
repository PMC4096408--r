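#' @importFrom ape read.tree write.tree root
NULL

# recursive subtree node -> ape phylo (unrooted, basal multifurcation allowed)
node_to_phylo <- function(root) {
  count_tips <- function(nd) {
    if (is.character(nd)) 1L else sum(vapply(nd$children, count_tips, integer(1)))
  }
  ntip <- count_tips(root)
  env <- new.env()
  env$tip <- character(0)
  env$edge <- matrix(integer(0), 0, 2)
  env$len <- numeric(0)
  env$next_int <- ntip + 1L
  assign_ids <- function(nd) {
    if (is.character(nd)) {
      env$tip <- c(env$tip, nd)
      return(length(env$tip))
    }
    my_id <- env$next_int
    env$next_int <- env$next_int + 1L
    for (k in seq_along(nd$children)) {
      cid <- assign_ids(nd$children[[k]])
      env$edge <- rbind(env$edge, c(my_id, cid))
      env$len <- c(env$len, nd$blens[[k]])
    }
    my_id
  }
  assign_ids(root)
  tr <- list(edge = env$edge, edge.length = env$len,
             tip.label = env$tip, Nnode = env$next_int - ntip - 1L + 1L)
  tr$Nnode <- max(env$edge[, 1L]) - ntip
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on an arbitrary symmetric distance matrix. Ties in
#' the Q-criterion are broken deterministically by the lexicographically
#' smallest pair of current node labels (an internal node inherits the smaller
#' label of the two nodes it joined). Negative branch lengths arising from the
#' NJ formulas are clamped to zero with the deficit moved to the sibling edge.
#'
#' @param d symmetric numeric distance matrix with strain ids as dimnames,
#'   at least 3 strains.
#' @param outgroup optional leaf label; when given, a rooted copy of the tree
#'   (rooted on that pendant edge, display only) is attached as attribute
#'   `"rooted"`.
#' @return unrooted `phylo` tree with branch lengths in the units of `d`
#'   (substitutions/site for p-distances).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    mlsa_stop("mlsa_validation_error", "distance input must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8)
    mlsa_stop("mlsa_validation_error", "distance matrix is not symmetric")
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 3L)
    mlsa_stop("mlsa_size_error", "neighbor-joining needs at least 3 strains")
  if (!is.null(outgroup) && !(outgroup %in% ids))
    mlsa_stop("mlsa_validation_error", "outgroup '%s' is not a leaf", outgroup)

  nodes <- as.list(ids)          # subtree for each active node
  labels <- ids                  # tie-break label per active node
  D <- unname(d)

  while (length(labels) > 3L) {
    m <- length(labels)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lexicographic tie-break on sorted label pairs
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(labels[ij[1L]], labels[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]

    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)

    new_node <- list(children = list(nodes[[i]], nodes[[j]]),
                     blens = c(li, lj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    labels <- c(labels[keep], min(labels[c(i, j)]))
  }

  # final three-point join
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root <- list(children = nodes, blens = pmax(c(la, lb, lc), 0))
  tr <- node_to_phylo(root)
  if (!is.null(outgroup))
    attr(tr, "rooted") <- ape::root(tr, outgroup = outgroup,
                                    resolve.root = TRUE)
  tr
}

# star tree (no internal edges) used when the alignment carries no signal
star_tree <- function(ids) {
  root <- list(children = as.list(ids), blens = rep(0, length(ids)))
  node_to_phylo(root)
}

# canonical key of one split: the side NOT containing the alphabetically first
# leaf, sorted, collapsed
split_key <- function(side, all_tips) {
  ref <- sort(all_tips)[1L]
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves into two sets; the
#' trivial splits cut off by pendant edges are excluded. Splits are returned in
#' canonical form: the side not containing the alphabetically first leaf.
#'
#' @param tree a `phylo` object.
#' @return named list of character vectors (leaf sets); names are internal
#'   canonical keys. Attribute `"lengths"` carries the matching edge lengths,
#'   attribute `"node"` the child node number of each edge.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  nn <- max(tree$edge)
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- all_tips[i]
  tr <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; c <- tr$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  splits <- list(); lens <- numeric(0); nodes <- integer(0)
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2L]
    if (ch <= ntip) next                       # pendant edge: trivial split
    side <- below[[ch]]
    if (length(side) %in% c(0L, 1L, ntip - 1L, ntip)) next
    key <- split_key(side, all_tips)
    splits[[key]] <- sort(if (sort(all_tips)[1L] %in% side)
      setdiff(all_tips, side) else side)
    lens[key] <- if (is.null(tr$edge.length)) NA_real_ else tr$edge.length[k]
    nodes[key] <- ch
  }
  attr(splits, "lengths") <- lens
  attr(splits, "node") <- nodes
  splits
}

#' Bipartitions shared by two trees
#'
#' Used to mark nodes of one tree that are also recovered by an independently
#' inferred tree (e.g. maximum-likelihood or maximum-parsimony trees supplied
#' as newick files).
#'
#' @param a,b `phylo` trees over the same leaf set.
#' @return list of shared splits (canonical character vectors of leaf labels).
#' @export
shared_bipartitions <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    diff <- c(setdiff(a$tip.label, b$tip.label),
              setdiff(b$tip.label, a$tip.label))
    mlsa_stop("mlsa_validation_error",
              "trees have different leaf sets; differing leaves: %s",
              paste(diff, collapse = ", "))
  }
  sa <- tree_bipartitions(a)
  sb <- tree_bipartitions(b)
  sa[intersect(names(sa), names(sb))]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the point-estimate tree with
#' the percentage of replicates containing that bipartition (integer percent,
#' stored in `node.label`). Replicate r derives its RNG stream
#' deterministically from `(seed, r)`, so runs are reproducible.
#'
#' @param aln a [locus_alignment].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer root seed.
#' @param deletion deletion policy for [p_distance_matrix()].
#' @param outgroup optional leaf for display rooting (see [nj_tree()]).
#' @return the point-estimate `phylo` tree with `node.label` holding support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              deletion = "complete", outgroup = NULL) {
  if (n_reps < 1)
    mlsa_stop("mlsa_parameter_error", "n_reps must be >= 1")
  if (polymorphic_sites(aln)$n == 0L) {
    warning("alignment has no polymorphic sites; returning a star tree with zero support")
    tr <- star_tree(aln$strain_ids)
    tr$node.label <- "0"
    return(tr)
  }
  point <- nj_tree(p_distance_matrix(aln, deletion), outgroup = outgroup)
  target <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(target)), names(target))
  M <- aln_int_matrix(aln)
  ids <- aln$strain_ids
  L <- ncol(M)
  for (r in seq_len(n_reps)) {
    set.seed(sub_seed(seed, r))
    cols <- sample.int(L, L, replace = TRUE)
    dr <- tryCatch(p_dist_from_int(M[, cols, drop = FALSE], ids, deletion),
                   error = function(e) NULL)
    if (is.null(dr)) next
    rep_tree <- nj_tree(dr)
    hits <- intersect(names(tree_bipartitions(rep_tree)), names(target))
    counts[hits] <- counts[hits] + 1
  }
  pct <- round_half_away(100 * counts / n_reps, 0)
  # map support onto internal node labels of the point tree
  ntip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  node_of <- attr(target, "node")
  labs[node_of - ntip] <- as.character(pct[names(node_of)])
  point$node.label <- labs
  attr(point, "support") <- pct
  point
}

# p-distance straight from an integer matrix (bootstrap inner loop)
p_dist_from_int <- function(M, ids, deletion = "complete") {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (deletion == "complete") {
    keep <- colSums(is.na(M)) == 0L
    if (!any(keep))
      mlsa_stop("mlsa_undefined_distance_error", "no comparable column")
    M <- M[, keep, drop = FALSE]
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- mean(M[i, ] != M[j, ])
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(M[i, ]) & !is.na(M[j, ])
      if (!any(ok))
        mlsa_stop("mlsa_undefined_distance_error", "no comparable column")
      d[i, j] <- d[j, i] <- mean(M[i, ok] != M[j, ok])
    }
  }
  d
}

#' Read a newick tree file
#'
#' @param path newick file path.
#' @return `phylo` tree (internal node labels, e.g. bootstrap percentages, are
#'   preserved).
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    mlsa_stop("mlsa_io_error", "newick file not found: %s", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e)
                   mlsa_stop("mlsa_parse_error", "malformed newick in '%s': %s",
                             path, conditionMessage(e)))
  if (is.null(tr))
    mlsa_stop("mlsa_parse_error", "malformed newick in '%s'", path)
  tr
}

#' Write a tree as newick
#'
#' Branch lengths are preserved to at least 6 decimals; bootstrap supports (if
#' present) travel as internal node labels.
#'
#' @param tree `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
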