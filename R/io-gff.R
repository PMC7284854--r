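# GFF3 output for annotated loci. Internal coordinates are 0-based
# half-open everywhere in the package; conversion to GFF3's 1-based
# inclusive convention happens only here.

#' Write annotated loci as GFF3
#'
#' Arrays are emitted as `repeat_region` features (attributes carry the
#' subtype call and consensus repeat) and cas ORFs as `CDS` features.
#'
#' @param loci List of `cas_locus` objects (possibly empty).
#' @param path Output file.
#' @param genome Optional [genome()] used to validate intervals against
#'   contig lengths.
#' @return `path`, invisibly.
#' @export
write_locus_gff <- function(loci, path, genome = NULL) {
  rows <- list()
  for (lc in loci) {
    a <- lc$array
    if (!is.null(genome)) {
      clen <- nchar(genome$contigs[[a$contig_id]])
      if (is.null(clen) || a$end > clen) {
        abort(sprintf("array interval [%d,%d) exceeds contig %s",
                      a$start, a$end, a$contig_id))
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      seqid = a$contig_id, source = "crisprmine", type = "repeat_region",
      start = a$start + 1L, end = a$end, score = ".",
      strand = if (a$strand == "+") "+" else "-", phase = ".",
      attributes = sprintf(
        "ID=%s_array;subtype=%s;consensus_repeat=%s;n_spacers=%d",
        lc$genome_id %||% "locus", lc$subtype_call, a$consensus_repeat,
        nrow(a$spacers))
    )
    hits <- lc$cas_hits
    if (!is.null(hits) && nrow(hits) && "orf_start" %in% names(hits)) {
      for (i in seq_len(nrow(hits))) {
        rows[[length(rows) + 1L]] <- tibble(
          seqid = a$contig_id, source = "crisprmine", type = "CDS",
          start = hits$orf_start[i] + 1L, end = hits$orf_end[i],
          score = ".", strand = hits$orf_strand[i] %||% "+", phase = "0",
          attributes = sprintf("ID=%s;gene=%s;subtype=%s",
                               hits$reference_id[i], hits$gene_name[i],
                               lc$subtype_call)
        )
      }
    }
  }
  lines <- "##gff-version 3"
  if (length(rows)) {
    tab <- bind_rows(rows) |> arrange(.data$seqid, .data$start)
    lines <- c(lines, do.call(paste, c(as.list(tab), sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read intervals back from a locus GFF3
#'
#' Parses with `rtracklayer` and converts back to the package's 0-based
#' half-open convention; the round trip through [write_locus_gff()] is the
#' identity on intervals.
#'
#' @param path A GFF3 file.
#' @return Tibble with `contig_id`, `type`, `start`, `end`, `strand` and
#'   parsed `subtype`/`consensus_repeat` attributes where present.
#' @export
read_locus_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) {
    return(tibble(contig_id = character(), type = character(),
                  start = integer(), end = integer(), strand = character(),
                  subtype = character(), consensus_repeat = character()))
  }
  md <- S4Vectors::mcols(gr)
  grab <- function(col) {
    if (col %in% names(md)) as.character(md[[col]]) else NA_character_
  }
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    subtype = grab("subtype"),
    consensus_repeat = grab("consensus_repeat")
  )
}
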