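# Subtype templates: repeat sequences, canonical operon gene orders and
# tracrRNA templates used by the simulator.
#
# Repeat design. Each Type I repeat is built from a C-block stem arm, an
# A-only loop, a G-block stem arm and A-only single-stranded segments. With
# no T in the repeat, the only possible base pairs are C:G, so the
# maximum-pairing structure is unique and equals the designed stem. The
# designs reproduce the subtype geometry this pipeline reports: I-C has an
# 8 bp stem and an 11 nt 3' handle on a 33 nt repeat, I-E a 6 bp stem and
# 7 nt handle on 29 nt, I-G an 8 bp stem and 12 nt handle on 36 nt.
#
# tracrRNA design. Type II templates carry an anti-repeat (reverse
# complement of the repeat, two adjacent mismatches planted mid-way),
# followed by a tail of C/G-stem hairpins with A-only loops and linkers and
# a poly-T terminator. Stems have distinct sizes so the maximum-pairing
# decomposition is unique: II-C folds into a nexus plus two terminal
# hairpins (109 nt total), II-A into a nexus plus three terminal hairpins
# (132 nt total).

rep_block <- function(...) paste0(...)
a_ <- function(n) strrep("A", n)
c_ <- function(n) strrep("C", n)
g_ <- function(n) strrep("G", n)

REPEAT_TEMPLATES <- list(
  "I-C"  = rep_block(a_(2), c_(8), a_(4), g_(8), a_(11)),               # 33 nt
  "I-E"  = rep_block(a_(6), c_(6), a_(4), g_(6), a_(7)),                # 29 nt
  "I-G"  = rep_block(a_(4), c_(8), a_(4), g_(8), a_(12)),               # 36 nt
  "II-A" = "GCTAGGATCACCTTGAAGGTCTAGAAGCCTAGGTAC",                      # 36 nt
  "II-C" = "ATCGGACCTAAGGCTTCAGATCCGAAGTTCGACTGA"                       # 36 nt
)

OPERON_ORDERS <- list(
  "I-C"  = c("cas3", "cas5", "cas8c", "cas7", "cas4", "cas1", "cas2"),
  "I-E"  = c("cas3", "cse1", "cse2", "cas7", "cas5", "cas6e", "cas1", "cas2"),
  "I-G"  = c("cas3", "cas8u2", "cas7", "cas5", "cas6", "cas1_4_fusion", "cas2"),
  "II-A" = c("cas9", "cas1", "cas2", "csn2"),
  "II-C" = c("cas9", "cas1", "cas2")
)

# Hairpin unit: C-stem, A-loop, G-stem.
hp_ <- function(s, loop = 6) rep_block(c_(s), a_(loop), g_(s))

tracr_tail <- function(stems, pad) {
  paste0(paste0(vapply(stems, function(s) paste0(a_(3), hp_(s)), ""),
                collapse = ""),
         a_(pad), strrep("T", 5))
}

# Tail lengths: II-C 36 + 73 = 109 nt; II-A 36 + 96 = 132 nt.
TRACR_TEMPLATES <- list(
  "II-A" = list(length = 132L, placement = "between_cas9_and_cas1",
                tail = tracr_tail(c(4L, 5L, 6L, 7L), pad = 11L),
                n_tail_hairpins = 4L),
  "II-C" = list(length = 109L, placement = "upstream_of_cas9",
                tail = tracr_tail(c(5L, 6L, 7L), pad = 5L),
                n_tail_hairpins = 3L)
)

#' Subtype template
#'
#' Returns the locus template for one CRISPR-Cas subtype: the repeat
#' sequence (length 33 for I-C, 29 for I-E and 36 for I-G/II-A/II-C), the
#' canonical operon gene order, and for Type II the tracrRNA template (109 nt
#' for II-C, placed upstream of *cas9*; 132 nt for II-A, placed between
#' *cas9* and *cas1*).
#'
#' @param subtype One of `"I-C"`, `"I-E"`, `"I-G"`, `"II-A"`, `"II-C"`.
#' @return A list of class `subtype_template` with elements `subtype`,
#'   `repeat_seq`, `repeat_length`, `operon_gene_order` and (Type II only)
#'   `tracr_template`.
#' @examples
#' subtype_template("I-C")$repeat_length
#' @export
subtype_template <- function(subtype) {
  subtype <- match.arg(subtype, names(REPEAT_TEMPLATES))
  rep_seq <- REPEAT_TEMPLATES[[subtype]]
  tracr <- NULL
  if (subtype %in% names(TRACR_TEMPLATES)) {
    tt <- TRACR_TEMPLATES[[subtype]]
    anti <- plant_anti_repeat(rep_seq)
    tracr <- list(
      seq = paste0(anti, tt$tail),
      length = tt$length,
      placement = tt$placement,
      n_tail_hairpins = tt$n_tail_hairpins
    )
    stopifnot(nchar(tracr$seq) == tt$length)
  }
  structure(
    list(subtype = subtype,
         repeat_seq = rep_seq,
         repeat_length = nchar(rep_seq),
         operon_gene_order = OPERON_ORDERS[[subtype]],
         tracr_template = tracr),
    class = "subtype_template"
  )
}

#' All subtype identifiers known to the simulator
#' @return Character vector of subtype ids.
#' @export
subtypes <- function() names(REPEAT_TEMPLATES)

# Reverse complement of the repeat with two adjacent mismatches planted at
# positions 17-18, each chosen so that neither Watson-Crick nor G:U pairing
# with the repeat survives.
plant_anti_repeat <- function(repeat_seq, at = 17L) {
  anti <- strsplit(revcomp(repeat_seq), "", fixed = TRUE)[[1]]
  rep_ch <- strsplit(repeat_seq, "", fixed = TRUE)[[1]]
  n <- length(anti)
  for (p in c(at, at + 1L)) {
    partner <- rep_ch[n - p + 1L]
    bad <- switch(partner,
      A = c("C", "G"), C = c("A", "T"), G = c("A", "G"), T = c("C", "T"))
    anti[p] <- setdiff(bad, anti[p])[1]
  }
  paste(anti, collapse = "")
}

#' Load the bundled synthetic Cas reference panel
#'
#' The panel carries one representative protein per gene per subtype with
#' realistic lengths (for example the II-A Cas9 is 1383 aa, i.e. a 4152 bp
#' gene, and the II-C Cas9 1142 aa / 3429 bp). Sequences are synthetic
#' stand-ins generated with a fixed seed; headers follow
#' `id|gene_name|type|subtype`.
#'
#' @param path Optional path to an alternative panel FASTA with the same
#'   header layout.
#' @return A tibble with columns `id`, `gene_name`, `type`, `subtype`, `seq`.
#' @export
cas_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cas_panel_synthetic.fasta",
                        package = "crisprmine")
  }
  x <- read_sequences(path, alphabet = "protein")
  parts <- str_split(x$id, stringr::fixed("|"), simplify = TRUE)
  if (ncol(parts) != 4) abort("panel headers must be id|gene_name|type|subtype")
  tibble(
    id = parts[, 1], gene_name = parts[, 2],
    type = parts[, 3], subtype = parts[, 4],
    seq = x$seq
  )
}
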