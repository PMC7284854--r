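test_that("find_orfs scans six frames and recovers planted genes exactly", {
  g0 <- genome("c", c(c1 = strrep("C", 600)))
  expect_equal(nrow(find_orfs(g0, list(contig_id = "c1", start = 0, end = 600))),
               0)

  # plant a 300-codon gene behind a stop guard in random background
  withr::with_seed(55, {
    prot <- paste(c("M", sample(setdiff(LETTERS, c("B", "J", "O", "U", "X",
                                                   "Z")), 299, TRUE)), collapse = "")
    cds <- crisprmine:::back_translate(prot)
    left <- random_dna_str(497)
    seq <- paste0(left, "TAA", cds, random_dna_str(300))
  })
  g <- genome("g", c(c1 = seq))
  orfs <- find_orfs(g, list(contig_id = "c1", start = 0, end = nchar(seq)))
  hit <- orfs[orfs$start == 500, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, 500 + nchar(cds))
  expect_equal(hit$protein, prot)
  expect_equal(hit$strand, "+")
  expect_equal(hit$length_aa, 300L)

  # strand symmetry: reverse complementing the genome flips strands and
  # mirrors coordinates
  rg <- revcomp_genome(g)
  L <- nchar(seq)
  rorfs <- find_orfs(rg, list(contig_id = "c1", start = 0, end = L))
  rhit <- rorfs[rorfs$strand == "-" & rorfs$end == L - 500, ]
  expect_equal(nrow(rhit), 1)
  expect_equal(rhit$protein, prot)
})

test_that("score_cas finds true panel matches and rejects random proteins", {
  panel <- cas_panel()
  self <- panel[panel$gene_name == "cas9" & panel$subtype == "II-C", ]
  hit <- score_cas(list(protein = self$seq), panel)
  expect_equal(hit$gene_name, "cas9")
  expect_equal(hit$identity, 100)
  expect_lt(hit$evalue, 1e-10)

  withr::with_seed(66, {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    rand <- paste(sample(aa, 120, TRUE), collapse = "")
  })
  expect_null(score_cas(list(protein = rand), panel))

  # 10% random substitutions still best-hit the source entry
  cas3 <- panel$seq[panel$gene_name == "cas3" & panel$subtype == "I-C"][1]
  withr::with_seed(67, {
    ch <- strsplit(cas3, "")[[1]]
    pos <- sample(length(ch), round(0.1 * length(ch)))
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
    mut <- paste(ch, collapse = "")
  })
  h <- score_cas(list(protein = mut), panel)
  expect_equal(h$gene_name, "cas3")
  expect_equal(h$subtype_label, "I-C")
  expect_gt(h$identity, 85)
})

test_that("Karlin-Altschul E-values fall with score and scale with database size", {
  ev <- vapply(c(50, 100, 200), function(s) {
    crisprmine:::ka_evalue(s, 300, 10000, 0.267, 0.041)
  }, double(1))
  expect_true(all(diff(ev) < 0))
  e1 <- crisprmine:::ka_evalue(80, 35, 30000, 0.6, 0.41)
  e2 <- crisprmine:::ka_evalue(80, 35, 15000, 0.6, 0.41)
  expect_equal(e1 / e2, 2)
})

test_that("classification rules call the five subtypes and their fallbacks", {
  mk <- function(genes) tibble::tibble(gene_name = genes)
  call <- function(genes) classify_locus(NULL, mk(genes))$subtype_call

  expect_equal(call(c("cas3", "cas5", "cas8c", "cas7", "cas4", "cas1", "cas2")),
               "I-C")
  expect_equal(call(c("cas3", "cse1", "cse2", "cas7", "cas5", "cas6e",
                      "cas1", "cas2")), "I-E")
  expect_equal(call(c("cas3", "cas8u2", "cas7", "cas5", "cas6",
                      "cas1_4_fusion", "cas2")), "I-G")
  expect_equal(call(c("cas9", "cas1", "cas2", "csn2")), "II-A")
  expect_equal(call(c("cas9", "cas1", "cas2")), "II-C")
  # dropping the diagnostic gene demotes, never re-types
  expect_equal(call(c("cas3", "cas1", "cas2")), "I*")
  expect_equal(call(c("cas9", "cas2")), "II*")
  expect_equal(classify_locus(NULL, NULL)$subtype_call, "orphan")
  expect_equal(classify_locus(NULL, mk(character(0)))$subtype_call, "orphan")
  # gene order and strand are irrelevant (presence-based rules)
  expect_equal(call(rev(c("cas1_4_fusion", "cas5", "cas6", "cas3",
                          "cas7", "cas2"))), "I-G")
})

test_that("annotation of simulated loci recovers every canonical subtype", {
  for (st in ALL_SUBTYPES) {
    sim <- simulate_genome(st, n_spacers = 4, seed = 400 + match(st, ALL_SUBTYPES))
    res <- annotate_genome(sim$genome, find_arrays(sim$genome))
    expect_length(res, 1)
    expect_equal(res[[1]]$subtype_call, st)
    expect_setequal(res[[1]]$cas_hits$gene_name,
                    subtype_template(st)$operon_gene_order)
  }
})

test_that("occurrence matrix counts loci and reports integer-percent coverage", {
  genomes <- tibble::tibble(genome_id = paste0("g", 1:10),
                            species = rep(c("sp1", "sp2"), each = 5))
  empty <- occurrence_matrix(list(), genomes)
  expect_equal(empty$fraction_pct, 0)
  expect_equal(empty$n_with_locus, 0)

  loci <- tibble::tibble(genome_id = c("g1", "g2", "g6"),
                         subtype_call = c("I-C", "I-C", "II-C"))
  om <- occurrence_matrix(loci, genomes)
  expect_equal(om$matrix$`I-C`[om$matrix$species == "sp1"], 2)
  expect_equal(om$matrix$`II-C`[om$matrix$species == "sp2"], 1)
  expect_equal(om$fraction_pct, 30)

  # published-scale worked arithmetic: 548 of 954 genomes carry a locus
  big <- tibble::tibble(genome_id = sprintf("b%03d", 1:954),
                        species = "Bifidobacterium_sp")
  with_loci <- tibble::tibble(genome_id = sprintf("b%03d", 1:548),
                              subtype_call = "I-C")
  expect_equal(occurrence_matrix(with_loci, big)$fraction_pct, 57)
})
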