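test_that("protein distances satisfy the Poisson correction and its closed form", {
  d <- pairwise_distance(c(a = "MKVLAHTQRS", b = "MKVLAHTQRS"))
  expect_equal(d["a", "b"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # closed form: p = 0.25 -> -ln(0.75)
  expect_equal(poisson_distance(0.25), 0.2877, tolerance = 1e-4)
  # a constructed pair with exactly 1 mismatch in 4 aligned columns
  d2 <- pairwise_distance(c(x = "MKVL", y = "MKVI"))
  expect_equal(d2["x", "y"], -log(1 - 0.25), tolerance = 1e-12)

  # heavily diverged pairs are capped with a warning
  # L vs I score positively in BLOSUM62, so the alignment keeps the
  # columns while almost every one mismatches
  expect_warning(
    dcap <- pairwise_distance(c(p = paste0("M", strrep("L", 39)),
                                q = paste0("M", strrep("I", 39)))),
    "capped"
  )
  expect_lte(dcap["p", "q"], -log(1 - 0.95) + 1e-9)
})

test_that("neighbor joining recovers cherries, additive trees and NJ formulas", {
  # two taxa: the forced cherry splits the distance evenly
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  tr2 <- nj_tree(d2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(unname(tr2$edge.length), c(0.2, 0.2))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # additive matrices from random trees are recovered exactly (topology
  # and branch lengths, checked through the path metric)
  withr::with_seed(111, {
    for (i in 1:10) {
      n <- sample(5:8, 1)
      src <- ape::rtree(n)
      dd <- stats::cophenetic(src)
      rec <- nj_tree(dd)
      back <- stats::cophenetic(rec)[rownames(dd), colnames(dd)]
      expect_lt(max(abs(back - dd)), 1e-8)
    }
  })

  # all-equal matrix: every leaf branch is 0.5
  d4 <- matrix(1, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  diag(d4) <- 0
  tr4 <- nj_tree(d4)
  leaf_edges <- tr4$edge[, 2] <= 4
  expect_true(all(abs(tr4$edge.length[leaf_edges] - 0.5) < 1e-9))
  expect_true(all(abs(tr4$edge.length[!leaf_edges]) < 1e-9))
})

test_that("the NJ implementation matches the reference implementation in ape", {
  withr::with_seed(112, {
    for (i in 1:5) {
      n <- sample(5:7, 1)
      d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
      rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
      mine <- nj_tree(d)
      ref <- ape::nj(as.dist(d))
      expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))[1],
                   0)
    }
  })
})

test_that("bootstrap supports separate clean clusters and are seed-stable", {
  withr::with_seed(113, {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    base1 <- paste(sample(aa, 60, TRUE), collapse = "")
    base2 <- paste(sample(aa, 60, TRUE), collapse = "")
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      at <- sample(length(ch), k)
      for (p in at) ch[p] <- sample(setdiff(aa, ch[p]), 1)
      paste(ch, collapse = "")
    }
    seqs <- c(c1a = base1, c1b = mut(base1, 1), c1c = mut(base1, 2),
              c2a = base2, c2b = mut(base2, 1), c2c = mut(base2, 2))
  })
  bs <- bootstrap_support(seqs, n_reps = 50, seed = 7)
  sep <- bs$splits[bs$splits$split %in%
                     c("c2a|c2b|c2c", "c1a|c1b|c1c"), ]
  expect_gte(max(sep$support), 95)
  bs2 <- bootstrap_support(seqs, n_reps = 50, seed = 7)
  expect_identical(bs$splits, bs2$splits)
  bs3 <- bootstrap_support(seqs, n_reps = 20, seed = 8)
  expect_true(is.numeric(bs3$splits$support))
})

test_that("Cas1 panels cluster into subtype-pure clades on simulated data", {
  panel <- cas_panel()
  cas1 <- panel[panel$gene_name %in% c("cas1", "cas1_4_fusion"), ]
  withr::with_seed(114, {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    seqs <- character(0)
    for (i in seq_len(nrow(cas1))) {
      for (rep in 1:2) {
        ch <- strsplit(cas1$seq[i], "")[[1]]
        at <- sample(length(ch), round(0.03 * length(ch)))
        for (p in at) ch[p] <- sample(setdiff(aa, ch[p]), 1)
        seqs[paste0(cas1$subtype[i], "_", rep)] <- paste(ch, collapse = "")
      }
    }
  })
  tr <- nj_tree(pairwise_distance(seqs))
  # each subtype pair forms a cherry: its two leaves share a split
  splits <- crisprmine:::tree_splits(tr)
  for (st in unique(cas1$subtype)) {
    pair <- sort(paste0(st, "_", 1:2))
    other <- setdiff(names(seqs), pair)
    expect_true(any(vapply(strsplit(splits, "\\|"), function(s) {
      setequal(s, pair) || setequal(s, other)
    }, logical(1))))
  }
})
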