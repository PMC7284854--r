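# Truth-tracked synthetic genome generator.
#
# Each simulated genome carries exactly one CRISPR locus embedded in i.i.d.
# uniform A/C/G/T background (so spurious long repeats have vanishing
# probability): an array of n_spacers + 1 repeats (the last repeat carries
# two planted mutations, the degenerate terminal repeat found at the
# trailer/ancestral end of real arrays), a subtype-canonical cas operon
# back-translated from the bundled panel with the bacterial genetic code,
# and for Type II subtypes a planted tracrRNA whose anti-repeat is the
# reverse complement of the repeat with two mismatches. Every planted
# feature is recorded in a truth object whose intervals can be checked
# against the emitted sequence.

BACTERIAL_CODE <- NULL

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE # table 11 is identical for translation
  split(names(gc), gc)
}

# Back-translate a protein with uniform synonymous codon choice; the
# initiator is always ATG and a TAA stop is appended.
back_translate <- function(protein) {
  tab <- codon_table()
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!all(aas %in% names(tab))) abort("cannot back-translate residue")
  codons <- character(length(aas))
  for (a in unique(aas)) {
    at <- which(aas == a)
    opts <- tab[[a]]
    codons[at] <- opts[sample.int(length(opts), length(at), replace = TRUE)]
  }
  codons[1] <- "ATG"
  paste0(paste(codons, collapse = ""), "TAA")
}

random_spacers <- function(n, min_len = 30L, max_len = 40L) {
  lens <- sample(seq.int(min_len, max_len), n, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  while (anyDuplicated(seqs)) {
    i <- which(duplicated(seqs))
    seqs[i] <- vapply(lens[i], random_dna, character(1))
  }
  seqs
}

#' Simulate a genome carrying one CRISPR-Cas locus
#'
#' Emits a single-contig genome with one repeat-spacer array (`n_spacers`
#' spacers of 30-40 nt, mutually distinct; `n_spacers + 1` repeats, the last
#' one degenerate with two mutations), a canonical cas operon for the
#' template's subtype within the flanking window, and for Type II templates
#' a tracrRNA at the subtype's canonical placement. Deterministic for a
#' given seed.
#'
#' @param template A `subtype_template` or a subtype id string.
#' @param n_spacers Number of spacers (>= 1).
#' @param background_bp Total background sequence around the locus; must be
#'   at least twice the flanking window plus the locus length.
#' @param seed Integer RNG seed.
#' @param flank_window Flanking window the background must cover (bp).
#' @param panel Cas reference panel (defaults to the bundled synthetic one).
#' @return A list with elements `genome` (a [genome()]) and `truth` (class
#'   `sim_truth`: tibbles `arrays`, `repeats`, `spacers`, `operons`, `tracr`).
#' @examples
#' sim <- simulate_genome("I-C", n_spacers = 5, seed = 1)
#' sim$truth$arrays
#' @export
simulate_genome <- function(template, n_spacers, background_bp = NULL,
                            seed = 1L, flank_window = 20000L,
                            panel = cas_panel()) {
  if (is.character(template)) template <- subtype_template(template)
  stopifnot(n_spacers >= 1)
  with_seed(derive_seed(seed, 1L), {
    st <- template$subtype
    rep_seq <- template$repeat_seq
    rl <- nchar(rep_seq)

    spacers <- random_spacers(n_spacers)
    n_rep <- n_spacers + 1L
    repeat_seqs <- rep(rep_seq, n_rep)
    repeat_seqs[n_rep] <- mutate_dna(rep_seq, 2L) # degenerate terminal repeat

    array_units <- character(2L * n_rep - 1L)
    array_units[seq(1L, by = 2L, length.out = n_rep)] <- repeat_seqs
    array_units[seq(2L, by = 2L, length.out = n_spacers)] <- spacers
    array_seq <- paste(array_units, collapse = "")

    # Operon (and tracr for Type II), left to right on the plus strand.
    pieces <- character(0)
    feats <- list() # per-piece feature descriptors
    add_piece <- function(seq, feat = NULL) {
      pieces[[length(pieces) + 1L]] <<- seq
      feats[length(feats) + 1L] <<- list(feat) # keep NULL placeholders
    }
    add_gap <- function(lo = 60L, hi = 120L) {
      add_piece(random_dna(sample.int(hi - lo, 1) + lo))
    }
    add_gene <- function(gene_name) {
      prot <- panel$seq[panel$gene_name == gene_name & panel$subtype == st]
      if (length(prot) != 1) abort(paste0("panel lacks ", gene_name, " for ", st))
      cds <- back_translate(prot)
      # TAA guard immediately upstream keeps the ORF start exact.
      add_piece(paste0("TAA", cds),
                feat = list(kind = "gene", gene = gene_name, protein = prot,
                            guard = 3L))
    }
    add_tracr <- function() {
      tt <- template$tracr_template
      add_piece(tt$seq, feat = list(kind = "tracr", placement = tt$placement))
      add_piece("C") # keeps the planted poly-T terminator maximal
    }

    add_gap(120L, 200L)
    genes <- template$operon_gene_order
    if (st == "II-C") { add_tracr(); add_gap() }
    for (g in genes) {
      add_gene(g)
      if (st == "II-A" && g == "cas9") { add_gap(); add_tracr() }
      add_gap()
    }

    locus_seq <- paste0(array_seq, paste(unlist(pieces), collapse = ""))
    min_bg <- 2L * flank_window
    if (is.null(background_bp)) background_bp <- min_bg + 1000L
    if (background_bp < min_bg) {
      abort(sprintf("background_bp must be >= 2 * flank_window (%d)", min_bg))
    }
    left_bg <- background_bp %/% 2L
    right_bg <- background_bp - left_bg
    contig <- paste0(random_dna(left_bg), locus_seq, random_dna(right_bg))

    gid <- sprintf("sim_%s_%d", gsub("-", "", st), seed)
    cid <- paste0(gid, "_c1")

    # --- truth bookkeeping (0-based half-open) ---
    array_start <- left_bg
    unit_lens <- nchar(array_units)
    unit_starts <- array_start + cumsum(c(0L, unit_lens[-length(unit_lens)]))
    is_rep <- seq_along(array_units) %% 2L == 1L
    rep_idx <- which(is_rep)
    spa_idx <- which(!is_rep)
    array_end <- array_start + nchar(array_seq)

    truth_repeats <- tibble(
      contig_id = cid,
      unit = seq_len(n_rep),
      start = unit_starts[rep_idx],
      end = unit_starts[rep_idx] + unit_lens[rep_idx],
      seq = array_units[rep_idx]
    )
    truth_spacers <- tibble(
      contig_id = cid,
      spacer_id = sprintf("%s_a1_s%d", gid, seq_len(n_spacers)),
      unit = seq_len(n_spacers),
      start = unit_starts[spa_idx],
      end = unit_starts[spa_idx] + unit_lens[spa_idx],
      seq = array_units[spa_idx]
    )
    truth_arrays <- tibble(
      contig_id = cid, array_id = paste0(gid, "_a1"),
      start = array_start, end = array_end,
      n_repeats = n_rep, n_spacers = n_spacers,
      repeat_seq = rep_seq, subtype = st, leader_side = "left"
    )

    pos <- array_end
    op_rows <- list(); tr_rows <- list()
    for (i in seq_along(pieces)) {
      len <- nchar(pieces[[i]])
      f <- feats[[i]]
      if (!is.null(f) && f$kind == "gene") {
        gstart <- pos + f$guard
        op_rows[[length(op_rows) + 1L]] <- tibble(
          contig_id = cid, gene_name = f$gene,
          start = gstart, end = pos + len, strand = "+",
          protein = f$protein, subtype = st
        )
      } else if (!is.null(f) && f$kind == "tracr") {
        tr_rows[[length(tr_rows) + 1L]] <- tibble(
          contig_id = cid, start = pos, end = pos + len, strand = "+",
          seq = pieces[[i]], placement = f$placement
        )
      }
      pos <- pos + len
    }

    truth <- structure(
      list(
        genome_id = gid,
        arrays = truth_arrays,
        repeats = truth_repeats,
        spacers = truth_spacers,
        operons = bind_rows(op_rows),
        tracr = if (length(tr_rows)) bind_rows(tr_rows) else NULL,
        protospacers = NULL
      ),
      class = "sim_truth"
    )

    g <- genome(gid, stats::setNames(contig, cid),
                species = paste0("synthetic_", st))
    list(genome = g, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d array(s), %d operon gene(s)%s\n",
              x$genome_id, nrow(x$arrays), nrow(x$operons),
              if (!is.null(x$tracr)) ", 1 tracrRNA" else ""))
  invisible(x)
}

#' Verify that recorded truth intervals match the emitted genome
#'
#' Checks, exhaustively, that the substring of the genome under every truth
#' interval equals the recorded sequence.
#'
#' @param sim Result of [simulate_genome()].
#' @return `TRUE` invisibly; aborts on any disagreement.
#' @export
check_truth <- function(sim) {
  g <- sim$genome; tr <- sim$truth
  check_tbl <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl) || is.null(tbl$seq)) return(invisible(NULL))
    for (i in seq_len(nrow(tbl))) {
      got <- genome_subseq(g, tbl$contig_id[i], tbl$start[i], tbl$end[i])
      if (got != tbl$seq[i]) abort("truth interval does not match genome")
    }
  }
  check_tbl(tr$repeats); check_tbl(tr$spacers); check_tbl(tr$tracr)
  if (!is.null(tr$operons) && nrow(tr$operons)) {
    for (i in seq_len(nrow(tr$operons))) {
      cds <- genome_subseq(g, tr$operons$contig_id[i], tr$operons$start[i],
                           tr$operons$end[i])
      prot <- translate_cds(cds)
      if (prot != tr$operons$protein[i]) abort("operon truth does not translate")
    }
  }
  invisible(TRUE)
}

# Translate a CDS (start codon .. stop codon) to protein, standard/bacterial
# code, initiator forced to M, stop dropped.
translate_cds <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  aa <- unname(gc[codons])
  if (anyNA(aa)) abort("CDS contains an untranslatable codon")
  if (aa[length(aa)] != "*") abort("CDS does not end at a stop codon")
  aa <- aa[-length(aa)]
  aa[1] <- "M"
  paste(aa, collapse = "")
}
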