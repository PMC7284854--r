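test_that("planted protospacers are found at truth coordinates with full identity", {
  sim <- simulate_genome("I-C", n_spacers = 10, seed = 601)
  inv <- simulate_invaders(sim$truth, n_targeted = 8, pam = "TTC",
                           pam_side = "5prime", n_decoys = 4, seed = 601)
  sp <- stats::setNames(sim$truth$spacers$seq, sim$truth$spacers$spacer_id)
  hits <- search_protospacers(sp, inv$invaders)
  expect_equal(nrow(hits), 8)
  m <- merge(hits, inv$truth$protospacers,
             by = c("spacer_id", "invader_id"))
  expect_equal(nrow(m), 8)
  expect_equal(m$start, m$offset)
  expect_true(all(m$identity == 100))
  expect_true(all(m$strand.x == "+"))
  expect_true(all(hits$evalue < 1e-3 & hits$identity > 85))
  expect_error(search_protospacers(c(s = "ACGT"), inv$invaders), "18-55")
})

test_that("both inclusion thresholds are strict inequalities", {
  cfg <- run_config()
  border <- tibble::tibble(
    spacer_id = c("a", "b", "c"), invader_id = "x",
    start = 0L, end = 30L, strand = "+",
    identity = c(85.0, 90, 90),
    evalue = c(1e-6, 1e-3, 0.999e-3),
    score = 60, category = "phage"
  )
  kept <- filter_protospacer_hits(border, cfg)
  # identity exactly 85.0 excluded; evalue exactly 1e-3 excluded
  expect_equal(kept$spacer_id, "c")
  just_over <- dplyr::mutate(border[1, ], identity = 85.0 + 1e-9)
  expect_equal(nrow(filter_protospacer_hits(just_over, cfg)), 1)
})

test_that("flanks are extracted in protospacer orientation with edge flags", {
  invs <- tibble::tibble(
    id = "v1",
    seq = paste0(strrep("A", 90), "TTCCCCGGGGATATATATAT", strrep("G", 90))
  )
  hit <- tibble::tibble(spacer_id = "s", invader_id = "v1",
                        start = 100L, end = 110L, strand = "+")
  fl <- extract_flanks(hit, invs, 10)
  expect_equal(fl$upstream, substr(invs$seq, 91, 100))
  expect_equal(fl$downstream, substr(invs$seq, 111, 120))
  expect_false(fl$truncated)

  # minus-strand flanks equal reverse complements of the opposite plus
  # strand flanks
  hitm <- dplyr::mutate(hit, strand = "-")
  flm <- extract_flanks(hitm, invs, 10)
  expect_equal(flm$upstream, revcomp(substr(invs$seq, 111, 120)))
  expect_equal(flm$downstream, revcomp(substr(invs$seq, 91, 100)))

  # hit at the record edge is truncated and flagged
  edge <- tibble::tibble(spacer_id = "s", invader_id = "v1",
                         start = 4L, end = 30L, strand = "+")
  fe <- extract_flanks(edge, invs, 10)
  expect_equal(nchar(fe$upstream), 4)
  expect_true(fe$truncated)
})

test_that("PAM models recover planted motifs and stay silent on noise", {
  # planted TTC immediately 5' of the protospacer, random elsewhere
  withr::with_seed(71, {
    flanks <- tibble::tibble(
      upstream = replicate(12, paste0(random_dna_str(7), "TTC")),
      downstream = replicate(12, random_dna_str(10))
    )
  })
  pam <- infer_pam(flanks, "I-C")
  expect_equal(pam$side, "5prime")
  expect_equal(pam$consensus, "TTC")
  expect_equal(pam$positions[pam$called], c(-3, -2, -1))
  # direct frequency-count oracle for the planted columns (frequencies
  # carry the 0.5 pseudocount: 12.5 / 14)
  expect_true(all(abs(pam$freq["T", 8:9] - 12.5 / 14) < 1e-9))
  expect_true(abs(pam$freq["C", 10] - 12.5 / 14) < 1e-9)
  expect_true(all(pam$info[8:10] > 1.9))

  # zero-entropy input: every position at 2 bits, consensus spans the window
  p5 <- infer_pam(rep("GGGGGGGTTC", 5), "I-C")
  expect_true(all(abs(p5$info - 2) < 1e-9))
  expect_equal(p5$consensus, "GGGGGGGTTC")

  # seeded uniform noise: not clear
  withr::with_seed(72, noise <- replicate(20, random_dna_str(10)))
  pn <- infer_pam(noise, "II-A")
  expect_equal(pn$side, "3prime")
  expect_equal(pn$consensus, "")

  # degenerate TAN: third position is a no-call
  withr::with_seed(73, {
    tan <- replicate(10, paste0(random_dna_str(7), "TA",
                                sample(c("A", "C", "G", "T"), 1)))
  })
  pt <- infer_pam(tan, "I-G")
  expect_equal(pt$consensus, "TA")
  expect_false(pt$called[10])

  # too few hits -> no call regardless of conservation
  expect_equal(infer_pam(rep("AAAAAAATTC", 4), "I-C")$consensus, "")
  # empty input -> empty model
  p0 <- infer_pam(character(0), "I-C")
  expect_equal(p0$n_hits, 0)
  expect_equal(p0$consensus, "")
})

test_that("PAM inference is invariant to invader strand", {
  sim <- simulate_genome("I-C", n_spacers = 10, seed = 611)
  inv <- simulate_invaders(sim$truth, 8, "TTC", "5prime", 2, seed = 611)
  sp <- stats::setNames(sim$truth$spacers$seq, sim$truth$spacers$spacer_id)
  run <- function(invaders) {
    hits <- search_protospacers(sp, invaders)
    infer_pam(extract_flanks_all(hits, invaders), "I-C")
  }
  fwd <- run(inv$invaders)
  rcv <- dplyr::mutate(inv$invaders, seq = revcomp(seq))
  rev <- run(rcv)
  expect_equal(fwd$consensus, rev$consensus)
  expect_equal(fwd$freq, rev$freq)
})

test_that("hit categories count phage, plasmid and virus records", {
  expect_equal(sum(categorize_hits(crisprmine:::empty_hits())$n), 0)
  hits <- tibble::tibble(category = c("phage", "phage", "plasmid"))
  ct <- categorize_hits(hits)
  expect_equal(ct$n[ct$category == "phage"], 2)
  expect_equal(ct$n[ct$category == "virus"], 0)
  expect_equal(crisprmine:::categorize_invader("Uncultured human fecal VIRUS x"),
               "virus")
  expect_equal(crisprmine:::categorize_invader("pBIF_plasmid_apr34"), "plasmid")
  expect_equal(crisprmine:::categorize_invader("contig_0042"), "unknown")

  sim <- simulate_genome("I-C", n_spacers = 8, seed = 613)
  inv <- simulate_invaders(sim$truth, 6, "TTC", "5prime", 0, seed = 613)
  sp <- stats::setNames(sim$truth$spacers$seq, sim$truth$spacers$spacer_id)
  hits <- search_protospacers(sp, inv$invaders)
  truth_ct <- table(inv$truth$protospacers$category)
  got <- categorize_hits(hits)
  for (cat in names(truth_ct)) {
    expect_equal(got$n[got$category == cat], unname(truth_ct[cat]))
  }
})
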