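# Shared fixtures for the suite. Everything is generated in code; genomes
# used by structural tests that do not involve the 20 kb flanking window
# keep the default background so coordinates always reflect study
# conditions.

ALL_SUBTYPES <- c("I-C", "I-E", "I-G", "II-A", "II-C")

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal hand-built array: n identical repeats, distinct spacers.
toy_array <- function(n_spacers = 3, repeat_seq = strrep("ACGTT", 5),
                      spacer_len = 30, degenerate = NULL, seed = 99) {
  withr::with_seed(seed, {
    reps <- rep(repeat_seq, n_spacers + 1)
    if (!is.null(degenerate)) {
      ch <- strsplit(reps[degenerate], "")[[1]]
      pos <- c(3, 11)
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      reps[degenerate] <- paste(ch, collapse = "")
    }
    spacers <- replicate(n_spacers, random_dna_str(spacer_len))
    units <- character(2 * n_spacers + 1)
    units[seq(1, by = 2, length.out = n_spacers + 1)] <- reps
    units[seq(2, by = 2, length.out = n_spacers)] <- spacers
    lens <- nchar(units)
    starts <- cumsum(c(0, lens[-length(lens)]))
    is_rep <- seq_along(units) %% 2 == 1
    crispr_array(
      contig_id = "toy", start = 0L, end = sum(lens),
      repeats = tibble::tibble(start = starts[is_rep],
                               end = starts[is_rep] + lens[is_rep],
                               seq = units[is_rep]),
      spacers = tibble::tibble(start = starts[!is_rep],
                               end = starts[!is_rep] + lens[!is_rep],
                               seq = units[!is_rep]),
      consensus_repeat = repeat_seq
    )
  })
}

# Truth-derived cas_locus (orf coordinates from the simulator), for tests
# that exercise downstream stages without re-running annotation.
locus_from_truth <- function(sim) {
  tr <- sim$truth
  a <- find_arrays(sim$genome)[[1]]
  hits <- tibble::tibble(
    reference_id = paste0(tr$operons$gene_name, "_ref"),
    gene_name = tr$operons$gene_name,
    subtype_label = tr$operons$subtype,
    identity = 100, alignment_score = NA_real_, evalue = 0,
    orf_start = tr$operons$start, orf_end = tr$operons$end,
    orf_strand = tr$operons$strand
  )
  classify_locus(a, hits, sim$truth$genome_id)
}
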