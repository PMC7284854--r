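test_that("simulated genomes are reproducible and match their truth exactly", {
  s1 <- simulate_genome("I-C", n_spacers = 5, seed = 7)
  s2 <- simulate_genome("I-C", n_spacers = 5, seed = 7)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome("I-C", n_spacers = 5, seed = 8)
  expect_false(identical(s1$genome$contigs, s3$genome$contigs))

  # n repeats / n-1 spacers with the subtype repeat length
  expect_equal(nrow(s1$truth$repeats), 6)
  expect_equal(nrow(s1$truth$spacers), 5)
  expect_true(all(nchar(s1$truth$repeats$seq) == 33))

  # substring oracle over every recorded interval (repeats, spacers,
  # tracr, operon translation)
  for (st in ALL_SUBTYPES) {
    sim <- simulate_genome(st, n_spacers = 4, seed = 11)
    expect_true(check_truth(sim))
    expect_false(anyDuplicated(sim$truth$spacers$seq) > 0)
  }
})

test_that("simulator plants subtype-canonical operons and tracrRNAs", {
  for (st in ALL_SUBTYPES) {
    sim <- simulate_genome(st, n_spacers = 4, seed = 23)
    tpl <- subtype_template(st)
    expect_equal(sim$truth$operons$gene_name, tpl$operon_gene_order)
    # operon within the flanking window of the array
    gap <- min(sim$truth$operons$start) - sim$truth$arrays$end
    expect_true(gap >= 0 && gap < 20000)
    if (startsWith(st, "II")) {
      tr <- sim$truth$tracr
      expect_equal(tr$end - tr$start, tpl$tracr_template$length)
      expect_equal(tr$placement, tpl$tracr_template$placement)
      # anti-repeat: reverse complement of the repeat with <= 2 mismatches
      anti <- substr(tr$seq, 1, nchar(tpl$repeat_seq))
      mm <- sum(strsplit(anti, "")[[1]] !=
                strsplit(revcomp(tpl$repeat_seq), "")[[1]])
      expect_lte(mm, 2)
    } else {
      expect_null(sim$truth$tracr)
    }
  }
  expect_error(simulate_genome("I-C", 5, background_bp = 100),
               "background_bp")
})

test_that("invader records embed spacers with the planted PAM at the recorded offset", {
  sim <- simulate_genome("I-C", n_spacers = 15, seed = 31)
  inv <- simulate_invaders(sim$truth, n_targeted = 12, pam = "TTC",
                           pam_side = "5prime", n_decoys = 5, seed = 31)
  ps <- inv$truth$protospacers
  expect_equal(nrow(ps), 12)
  for (i in seq_len(nrow(ps))) {
    rec <- inv$invaders$seq[inv$invaders$id == ps$invader_id[i]]
    # substring oracle: PAM immediately 5' of the planted spacer
    expect_equal(substr(rec, ps$offset[i] - 2, ps$offset[i]), "TTC")
    expect_equal(substr(rec, ps$offset[i] + 1,
                        ps$offset[i] + nchar(ps$spacer_seq[i])),
                 ps$spacer_seq[i])
  }
  expect_setequal(unique(inv$invaders$category),
                  c("phage", "plasmid", "virus"))

  # 3' side placement
  inv3 <- simulate_invaders(sim$truth, 3, pam = "GG", pam_side = "3prime",
                            n_decoys = 0, seed = 5)
  ps3 <- inv3$truth$protospacers
  rec <- inv3$invaders$seq[1]
  end <- ps3$offset[1] + nchar(ps3$spacer_seq[1])
  expect_equal(substr(rec, end + 1, end + 2), "GG")

  expect_error(simulate_invaders(sim$truth, 2, pam = "TNX"), "A/C/G/T")
  expect_error(simulate_invaders(sim$truth, 99), "exceeds")

  # decoys only -> the search has nothing to find
  dec <- simulate_invaders(sim$truth, n_targeted = 0, n_decoys = 4, seed = 2)
  sp <- stats::setNames(sim$truth$spacers$seq, sim$truth$spacers$spacer_id)
  hits <- search_protospacers(sp[1:5], dec$invaders)
  expect_equal(nrow(hits), 0)
})

test_that("lineages share the ancestral trailer block and honour deletions", {
  lin <- simulate_lineage(10, 3, 5, seed = 41)
  arrs <- lin$arrays
  expect_length(arrs, 3)
  expect_true(all(lengths(arrs) == 15))
  anc <- lin$truth$ancestor
  for (a in arrs) expect_equal(a[6:15], anc)
  # pairwise: exactly the 10 trailer-end spacers shared
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(intersect(arrs[[i]], arrs[[j]]), anc)
  }

  # deletion of 8 leader spacers from a twin of the previous strain
  lin2 <- simulate_lineage(10, 3, 8, deletion_events = list(c(3, 8)),
                           seed = 42)
  expect_equal(length(lin2$arrays[[2]]) - length(lin2$arrays[[3]]), 8)
  expect_equal(lin2$arrays[[3]], lin2$arrays[[2]][-(1:8)])

  # no acquisitions, no deletions -> identical arrays
  lin3 <- simulate_lineage(6, 2, 0, seed = 43)
  expect_identical(lin3$arrays[[1]], lin3$arrays[[2]])

  expect_error(simulate_lineage(5, 3, 2, deletion_events = list(c(2, 9))),
               "deletion longer")
  expect_error(simulate_lineage(5, 3, 2, deletion_events = list(c(1, 1))),
               "strain index")
})
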