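test_that("base-pair maximization agrees with independent oracles", {
  # small full sweep here; the exhaustive length-10 sweep runs with the
  # acceptance checks
  res <- crisprmine:::nussinov_sweep_cpp(7L, 3L)
  expect_equal(res[2], 0L)

  withr::with_seed(81, {
    for (i in 1:50) {
      s <- paste(sample(c("A", "C", "G", "U"), 24, TRUE), collapse = "")
      np <- crisprmine:::nussinov_max_pairs_cpp(s, 3L)
      expect_equal(np, crisprmine:::brute_max_pairs_cpp(s, 3L))
      expect_equal(np, crisprmine:::alt_max_pairs_cpp(s, 3L))
    }
  })
})

test_that("hairpin structures expose stem, loop and 3' handle geometry", {
  # no complementarity at all
  h0 <- fold_crrna(strrep("A", 24))
  expect_equal(h0$n_pairs, 0)
  expect_equal(h0$handle3_len, 24)

  # designed stem-loop, verified against the exhaustive enumerator
  h <- fold_crrna("GGGGAAAACCCC", min_len = 10)
  expect_equal(h$n_pairs, crisprmine:::brute_max_pairs_cpp("GGGGAAAACCCC", 3L))
  expect_equal(h$n_pairs, 4)
  expect_equal(h$stem_len, 4)
  expect_equal(h$loop_len, 4)
  expect_error(fold_crrna("ACGT"), "length")
  expect_error(fold_crrna(paste0(strrep("A", 25), "X")), "A/C/G/T")

  # pairs are nested, Watson-Crick or G:U, with loops of at least 3
  withr::with_seed(82, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
      hs <- fold_crrna(s, min_len = 20)
      if (hs$n_pairs == 0) next
      expect_true(all(hs$pairs[, 2] - hs$pairs[, 1] > 3))
      ch <- strsplit(s, "")[[1]]
      legal <- c("AT", "TA", "CG", "GC", "GT", "TG")
      expect_true(all(paste0(ch[hs$pairs[, 1] + 1],
                             ch[hs$pairs[, 2] + 1]) %in% legal))
      # conservation: 5' unpaired + paired extent + 3' handle = length
      extent <- max(hs$pairs[, 2]) - min(hs$pairs[, 1]) + 1
      expect_equal(hs$five_prime_len + extent + hs$handle3_len, 30)
    }
  })
})

test_that("shipped Type I repeat templates reproduce the published geometry", {
  geom <- list(
    "I-C" = list(stem = 8, handle = 11),
    "I-E" = list(stem = 6:7, handle = 7:8),
    "I-G" = list(stem = 8:9, handle = 12)
  )
  for (st in names(geom)) {
    h <- fold_crrna(subtype_template(st)$repeat_seq)
    expect_true(h$stem_len %in% geom[[st]]$stem)
    expect_true(h$handle3_len %in% geom[[st]]$handle)
    # the fold is itself optimal per the exhaustive enumerator
    expect_equal(h$n_pairs, crisprmine:::brute_max_pairs_cpp(
      subtype_template(st)$repeat_seq, 3L))
  }
})

test_that("mature crRNA cut sites follow the subtype processing rule", {
  h <- fold_crrna(subtype_template("I-C")$repeat_seq)
  expect_equal(mature_crrna_cut(h, "I-C")$cut_from_3prime, 8)
  expect_equal(mature_crrna_cut(h, "I-G")$cut_from_3prime, 8)
  he <- fold_crrna(subtype_template("I-E")$repeat_seq)
  cut <- mature_crrna_cut(he, "I-E")
  expect_equal(cut$cut_from_3prime, 7)
  # arithmetic identity: 5' segment + cut length = repeat length
  expect_equal(cut$cut_index + cut$cut_from_3prime, 29)
  expect_error(mature_crrna_cut(h, "II-A"), "processing rule")
})

test_that("planted tracrRNAs are recovered with placement and length", {
  for (st in c("II-A", "II-C")) {
    sim <- simulate_genome(st, n_spacers = 25,
                           seed = 700 + match(st, ALL_SUBTYPES))
    lc <- locus_from_truth(sim)
    cand <- find_tracrrna(sim$genome, lc)
    expect_gt(nrow(cand), 0)
    top <- cand[1, ]
    expect_equal(top$start, sim$truth$tracr$start)
    expect_equal(top$end, sim$truth$tracr$end)
    expect_equal(top$placement, sim$truth$tracr$placement)
    expect_equal(top$predicted_length,
                 subtype_template(st)$tracr_template$length)
    expect_lte(top$mismatches, 2)

    # strand symmetry: the anti-repeat window is mirrored exactly on the
    # reverse complement (the transcript orientation follows the reported
    # array consensus, which itself flips with the genome)
    rg <- revcomp_genome(sim$genome)
    L <- nchar(sim$genome$contigs[[1]])
    ra <- find_arrays(rg)[[1]]
    rhits <- dplyr::mutate(lc$cas_hits,
                           os = L - orf_end, oe = L - orf_start,
                           orf_start = os, orf_end = oe,
                           orf_strand = "-")
    rlc <- classify_locus(ra, dplyr::select(rhits, -os, -oe),
                          lc$genome_id)
    rcand <- find_tracrrna(rg, rlc)
    expect_equal(rcand$anti_start[1], L - top$anti_end)
    expect_equal(rcand$anti_end[1], L - top$anti_start)
    expect_equal(rcand$mismatches[1], top$mismatches)
  }
  # Type I locus is a usage error; locus without a window match is empty
  simI <- simulate_genome("I-C", n_spacers = 4, seed = 703)
  expect_error(find_tracrrna(simI$genome, locus_from_truth(simI)),
               "Type II")
})

test_that("duplex prediction labels lower stem, bulge, upper stem and tail hairpins", {
  # designed construct: 6 bp lower stem, 2 nt tracr bulge, 4 bp upper stem,
  # then two tail hairpins and a terminator
  rep10 <- "GGATCCGTAC"
  anti <- revcomp(rep10) # GTACGGATCC
  tracr <- paste0(substr(anti, 1, 4), "AA", substr(anti, 5, 10),
                  "AAA", "CCCCC", "AAAAAA", "GGGGG",
                  "AAA", "CCCCCC", "AAAAAA", "GGGGGG", "ATTTTT")
  d <- predict_duplex(rep10, tracr, min_pairs = 10)
  expect_false(d$no_duplex)
  expect_equal(d$lower_stem_len, 6)
  expect_equal(d$bulge_len, 2)
  expect_equal(d$bulge_on, "tracr")
  expect_equal(d$upper_stem_len, 4)
  expect_length(d$hairpins, 1) # nexus + one further hairpin
  expect_equal(d$nexus$stem_len, 5)
  expect_equal(d$hairpins[[1]]$stem_len, 6)
  # canonical element order
  expect_equal(d$elements$element[1:4],
               c("lower_stem", "bulge", "upper_stem", "nexus"))

  # zero complementarity -> no duplex
  nd <- predict_duplex(strrep("A", 20), strrep("A", 60))
  expect_true(nd$no_duplex)

  # shipped templates: nexus + two terminal hairpins (II-C), three (II-A)
  for (st in c("II-A", "II-C")) {
    tpl <- subtype_template(st)
    dd <- predict_duplex(tpl$repeat_seq, tpl$tracr_template$seq)
    expect_false(dd$no_duplex)
    expect_gte(dd$n_pairs, 34) # 36 nt anti-repeat with 2 planted mismatches
    expect_equal(dd$bulge_len, 2)
    n_tail <- if (st == "II-C") 2 else 3
    expect_length(dd$hairpins, n_tail)
    expect_false(is.null(dd$nexus))
  }
})
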