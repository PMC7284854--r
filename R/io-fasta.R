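#' Construct a genome object
#'
#' A genome is a named set of contigs. Contig ids must be unique, sequences
#' non-empty; any character outside A/C/G/T/N is normalised to `N`.
#'
#' @param id Genome identifier.
#' @param contigs Named character vector of contig sequences.
#' @param species Optional species label.
#' @return A list of class `genome` with elements `id`, `contigs`, `species`.
#' @export
genome <- function(id, contigs, species = NULL) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    abort("contig ids must be present and unique within a genome")
  }
  if (any(nchar(contigs) == 0L)) abort("contig sequences must be non-empty")
  contigs <- vapply(contigs, normalize_dna, character(1))
  structure(list(id = id, contigs = contigs, species = species),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %s bp total\n", x$id,
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Reverse complement a whole genome
#'
#' Every contig is reverse complemented in place (contig ids are kept).
#' Used mainly by strand-symmetry checks.
#'
#' @param g A `genome`.
#' @return A `genome` with reverse-complemented contigs.
#' @export
revcomp_genome <- function(g) {
  g$contigs <- vapply(g$contigs, revcomp, character(1))
  g
}

#' Read a FASTA file into a tibble
#'
#' Ids are taken from the header up to the first whitespace and sequences are
#' upper-cased. DNA sequences additionally have non-A/C/G/T characters
#' normalised to `N`. Records with empty sequences or duplicated ids are
#' format errors that name the offending record.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_sequences <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- str_to_upper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) abort(paste0("empty sequence: ", ids[empty[1]]))
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(paste0("duplicate id: ", dup[1]))
  if (alphabet == "dna") seqs <- vapply(seqs, normalize_dna, character(1))
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `id` and `seq`, or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, width = 70L) {
  if (is.data.frame(x)) {
    seqs <- x$seq
    names(seqs) <- x$id
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a subsequence from a genome (0-based, half-open)
#'
#' @param g A `genome`.
#' @param contig_id Contig identifier.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return A character scalar.
#' @export
genome_subseq <- function(g, contig_id, start, end, strand = "+") {
  s <- g$contigs[[contig_id]]
  if (is.null(s)) abort(paste0("unknown contig: ", contig_id))
  if (start < 0 || end > nchar(s) || end <= start) {
    abort(sprintf("interval [%d,%d) out of range for contig %s (length %d)",
                  start, end, contig_id, nchar(s)))
  }
  out <- substr(s, start + 1L, end)
  if (strand == "-") out <- revcomp(out)
  out
}
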