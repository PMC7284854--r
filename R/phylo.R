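# Cas-protein distances and neighbor-joining trees. Distances come from
# global pairwise alignments (BLOSUM62, gap open 11 / extend 1): p is the
# mismatch fraction over aligned non-gap columns, corrected to
# d = -ln(1 - p) (the Poisson many-hits correction), capped at p = 0.95.
# Trees are built by Saitou-Nei neighbor joining with negative branch
# lengths clamped to zero (the deficit moves to the sibling branch).

DIST_P_CAP <- 0.95

#' Pairwise evolutionary distances between proteins
#'
#' @param seqs Named character vector (or tibble with `id`, `seq`) of
#'   protein sequences; at least two.
#' @return A symmetric distance matrix (class `matrix`) with a zero
#'   diagonal, labelled by sequence names.
#' @examples
#' pairwise_distance(c(a = "MKVLA", b = "MKVLA"))["a", "b"]
#' @export
pairwise_distance <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  n <- length(seqs)
  if (n < 2) abort("need at least two sequences")
  nm <- names(seqs) %||% paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- p_distance_pair(seqs[[i]], seqs[[j]])
      if (p > DIST_P_CAP) {
        warn(sprintf("p-distance %.2f capped at %.2f for %s vs %s",
                     p, DIST_P_CAP, nm[i], nm[j]))
        p <- DIST_P_CAP
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

# Mismatch fraction over aligned non-gap columns of a global alignment.
p_distance_pair <- function(a, b) {
  if (identical(a, b)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & sa != "-"
  if (!any(keep)) return(DIST_P_CAP + 1)
  mean(pa[keep] != sa[keep])
}

#' Poisson-corrected distance from a mismatch fraction
#'
#' @param p Mismatch fraction in `[0, 1)`.
#' @return `-ln(1 - p)`.
#' @export
poisson_distance <- function(p) {
  stopifnot(all(p >= 0), all(p < 1))
  -log(1 - p)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: the pair minimizing the Q-criterion is joined
#' at each step, branch lengths follow the standard NJ formulas, and
#' negative branch lengths are clamped to zero with the deficit moved to
#' the sibling branch. Two taxa yield the single cherry with the distance
#' split evenly.
#'
#' @param d Symmetric numeric matrix with labelled rows/columns.
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) abort("need at least two taxa")
  if (n == 2) {
    tr <- list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = rep(d[1, 2] / 2, 2),
      tip.label = labels, Nnode = 1L
    )
    class(tr) <- "phylo"
    return(tr)
  }
  # active nodes carry (id, subtree in edge list form)
  next_node <- n + 1L
  max_nodes <- 2L * n
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  active <- seq_len(n) # node ids
  D <- unname(d)
  storage.mode(D) <- "double"
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }
  node_ids <- active
  while (length(active) > 3L) {
    m <- length(active)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- ij[1]; j <- ij[2]
    if (i > j) { t <- i; i <- j; j <- t }
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    # clamp negatives, moving the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_id <- next_node; next_node <- next_node + 1L
    add_edge(new_id, active[i], li)
    add_edge(new_id, active[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    active <- c(active[keep], new_id)
  }
  # join the last three nodes at a central node
  m <- length(active)
  center <- next_node
  if (m == 3L) {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    for (t in 1:3) {
      add_edge(center, active[t], max(0, c(l1, l2, l3)[t]))
    }
  } else {
    abort("unexpected agglomeration state")
  }
  # renumber internal nodes into ape convention: tips 1..n, root first
  all_nodes <- unique(c(center, edges[, 1]))
  internal <- sort(unique(edges[edges[, 1] > n, 1]))
  internal <- c(center, setdiff(internal, center))
  remap <- stats::setNames(seq.int(n + 1L, n + length(internal)), internal)
  e2 <- edges
  e2[, 1] <- as.integer(remap[as.character(edges[, 1])])
  big <- edges[, 2] > n
  e2[big, 2] <- as.integer(remap[as.character(edges[big, 2])])
  tr <- list(edge = e2, edge.length = lens, tip.label = labels,
             Nnode = length(internal))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Bootstrap support for NJ splits
#'
#' Pairwise alignments are computed once; each replicate resamples every
#' pair's aligned (non-gap) columns with replacement, recomputes the
#' Poisson-corrected distance matrix and the NJ tree, and the support of
#' each internal split of the full-data tree is the percentage of
#' replicates containing it.
#'
#' @param seqs Named character vector of proteins (>= 4 for informative
#'   splits).
#' @param n_reps Number of replicates.
#' @param seed Integer RNG seed.
#' @return A list with `tree` (the full-data NJ tree), `splits` (tibble:
#'   `split` label-set string, `support` percent).
#' @export
bootstrap_support <- function(seqs, n_reps = 100L, seed = 1L) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  n <- length(seqs)
  nm <- names(seqs)
  # cache aligned column mismatch vectors per pair
  mism <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1
      )
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      keep <- pa != "-" & sa != "-"
      mism[[paste(i, j)]] <- (pa != sa)[keep]
    }
  }
  dist_from <- function(sampler) {
    d <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- sampler(mism[[paste(i, j)]])
        p <- min(mean(v), DIST_P_CAP)
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
    d
  }
  full_tree <- nj_tree(dist_from(identity))
  full_splits <- tree_splits(full_tree)
  counts <- stats::setNames(numeric(length(full_splits)), full_splits)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      db <- dist_from(function(v) v[sample.int(length(v), replace = TRUE)])
      reps <- tree_splits(nj_tree(db))
      hit <- full_splits %in% reps
      counts[hit] <- counts[hit] + 1
    }
  })
  list(
    tree = full_tree,
    splits = tibble(split = full_splits,
                    support = 100 * unname(counts) / n_reps)
  )
}

# Internal (non-trivial) splits of an unrooted tree as canonical strings:
# the side not containing the first tip label, sorted and joined.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  anchor <- sort(tree$tip.label)[1]
  out <- character(0)
  for (node in (n + 2L):(n + tree$Nnode)) { # skip the root "split"
    tips <- tips_under(tree, node)
    side <- sort(tree$tip.label[tips])
    if (anchor %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  unique(out)
}

tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  tips <- integer(0)
  while (length(kids)) {
    tips <- c(tips, kids[kids <= n])
    kids <- tree$edge[tree$edge[, 1] %in% kids[kids > n], 2]
  }
  tips
}
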