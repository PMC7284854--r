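# ORF finding in flanking windows, Cas identification against the reference
# panel, and rule-based type/subtype classification.

START_CODONS <- c("ATG", "GTG", "TTG")

#' Find ORFs in a genome window
#'
#' Scans all six frames (both strands) with the bacterial genetic code.
#' An ORF runs from the first start codon (ATG/GTG/TTG) after the previous
#' stop to the next stop codon; the longest ORF per stop is retained and
#' ORFs shorter than `min_orf_aa` are dropped. Intervals are 0-based
#' half-open and include the stop codon; proteins start with M.
#'
#' @param genome A [genome()].
#' @param window List or one-row data frame with `contig_id`, `start`,
#'   `end` (clipped to the contig).
#' @param min_orf_aa Minimum protein length in amino acids.
#' @return Tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   `protein`, `length_aa`.
#' @export
find_orfs <- function(genome, window, min_orf_aa = 100L) {
  cid <- window$contig_id
  clen <- nchar(genome$contigs[[cid]])
  wstart <- max(0L, as.integer(window$start))
  wend <- min(clen, as.integer(window$end))
  if (wend - wstart < 3L * (min_orf_aa + 2L)) return(empty_orfs())
  seq <- genome_subseq(genome, cid, wstart, wend)
  fwd <- orfs_in_strand(seq, min_orf_aa)
  rev <- orfs_in_strand(revcomp(seq), min_orf_aa)
  wlen <- wend - wstart
  if (nrow(rev)) {
    gs <- wstart + wlen - rev$end
    ge <- wstart + wlen - rev$start
    rev$start <- gs
    rev$end <- ge
    rev$strand <- "-"
  }
  if (nrow(fwd)) {
    fwd$start <- wstart + fwd$start
    fwd$end <- wstart + fwd$end
    fwd$strand <- "+"
  }
  out <- bind_rows(fwd, rev)
  if (is.null(out) || !nrow(out)) return(empty_orfs())
  out$contig_id <- cid
  out |>
    select("contig_id", "start", "end", "strand", "protein", "length_aa") |>
    arrange(.data$start, .data$strand)
}

empty_orfs <- function() {
  tibble(contig_id = character(), start = integer(), end = integer(),
         strand = character(), protein = character(), length_aa = integer())
}

# ORFs on the plus strand of `seq`, 0-based half-open local coordinates.
orfs_in_strand <- function(seq, min_orf_aa) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  rows <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < min_orf_aa + 1L) next
    cod_starts <- frame + seq(1L, by = 3L, length.out = ncod)
    codons <- substring(seq, cod_starts, cod_starts + 2L)
    aa <- unname(gc[codons]) # NA for codons containing N
    is_stop <- !is.na(aa) & aa == "*"
    is_start <- codons %in% START_CODONS
    seg_start <- 1L
    for (s in c(which(is_stop), ncod + 1L)) {
      if (s > seg_start) {
        starts_here <- which(is_start[seg_start:(s - 1L)])
        if (length(starts_here) && s <= ncod) { # require a real stop codon
          i0 <- seg_start + starts_here[1] - 1L
          len_aa <- s - i0
          if (len_aa >= min_orf_aa && !anyNA(aa[i0:s])) {
            prot <- paste(c("M", aa[(i0 + 1L):(s - 1L)]), collapse = "")
            rows[[length(rows) + 1L]] <- tibble(
              start = cod_starts[i0] - 1L,
              end = cod_starts[s] + 2L,
              protein = prot, length_aa = len_aa
            )
          }
        }
      }
      seg_start <- s + 1L
    }
  }
  if (!length(rows)) {
    return(tibble(start = integer(), end = integer(),
                  protein = character(), length_aa = integer()))
  }
  bind_rows(rows)
}

# Karlin-Altschul E-value for a local alignment score. Gapped BLOSUM62
# parameters (lambda 0.267, K 0.041) for proteins; for nucleotide searches
# lambda is solved from the +2/-3 scoring system under uniform base
# composition with K 0.41.
ka_evalue <- function(score, m, n, lambda, K) {
  K * m * n * exp(-lambda * score)
}

PROTEIN_KA <- list(lambda = 0.267, K = 0.041)

nucleotide_lambda <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      f <- function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1
      val <<- stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
    }
    val
  }
})

NUCLEOTIDE_K <- 0.41

# Local protein alignment of two sequences; returns score, identity over
# alignment columns (gaps included) and the aligned width.
align_protein_local <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]])
  list(score = Biostrings::score(aln),
       identity = 100 * matches / cols, ncols = cols)
}

#' Score an ORF against the Cas reference panel
#'
#' Local protein alignment (BLOSUM62, gap open 11 / extend 1) of the ORF
#' against every panel entry, with Karlin-Altschul E-values scaled to the
#' total panel size. The best hit is returned when its E-value is below
#' `evalue_max`; otherwise `NULL`. Panel entries whose length differs from
#' the ORF by more than a factor of two are skipped (they cannot produce a
#' qualifying full-gene hit), but the search size always counts the full
#' panel.
#'
#' @param orf One row of a [find_orfs()] tibble (or a list with `protein`).
#' @param panel A [cas_panel()] tibble.
#' @param evalue_max E-value threshold for reporting a hit.
#' @return A one-row tibble (`reference_id`, `gene_name`, `subtype_label`,
#'   `identity`, `alignment_score`, `evalue`) or `NULL`.
#' @export
score_cas <- function(orf, panel, evalue_max = 1e-3) {
  qlen <- nchar(orf$protein)
  n_db <- sum(nchar(panel$seq))
  lens <- nchar(panel$seq)
  cand <- which(lens >= qlen / 2 & lens <= qlen * 2)
  if (!length(cand)) return(NULL)
  best <- NULL
  for (i in cand) {
    al <- align_protein_local(orf$protein, panel$seq[i])
    if (is.null(best) || al$score > best$score) {
      best <- c(al, list(i = i))
    }
  }
  ev <- ka_evalue(best$score, qlen, n_db, PROTEIN_KA$lambda, PROTEIN_KA$K)
  if (ev >= evalue_max) return(NULL)
  tibble(
    reference_id = panel$id[best$i],
    gene_name = panel$gene_name[best$i],
    subtype_label = panel$subtype[best$i],
    identity = best$identity,
    alignment_score = best$score,
    evalue = ev
  )
}

#' Classify a locus from its Cas hits
#'
#' Presence-based rules, applied in order: no hits is an orphan array;
#' *cas9* marks Type II (with *csn2* subtype II-A, else with *cas1* and
#' *cas2* subtype II-C, else II*); *cas3* marks Type I (*cas8c* I-C,
#' *cse1*/*cas8e* together with *cse2* or *cas6e* I-E, *cas8u2* or the
#' Cas1-Cas4 fusion I-G, otherwise I*). The rules ignore gene order and
#' strand, so rearranged operons classify identically.
#'
#' @param array A `crispr_array` (may be `NULL` for bookkeeping uses).
#' @param hits Tibble of Cas hits (needs a `gene_name` column), or `NULL`.
#' @param genome_id Optional genome identifier stored on the locus.
#' @return A `cas_locus` list with `type_call` and `subtype_call`.
#' @export
classify_locus <- function(array, hits, genome_id = NA_character_) {
  genes <- if (is.null(hits) || !nrow(hits)) character(0) else hits$gene_name
  has <- function(...) any(c(...) %in% genes)
  if (!length(genes)) {
    type <- "untyped"; sub <- "orphan"
  } else if (has("cas9")) {
    type <- "II"
    sub <- if (has("csn2")) "II-A"
    else if (has("cas1") && has("cas2")) "II-C"
    else "II*"
  } else if (has("cas3")) {
    type <- "I"
    sub <- if (has("cas8c")) "I-C"
    else if (has("cse1", "cas8e") && has("cse2", "cas6e")) "I-E"
    else if (has("cas8u2", "cas1_4_fusion")) "I-G"
    else "I*"
  } else {
    # hits but no signature nuclease: untyped, distinct from orphan arrays
    type <- "untyped"; sub <- "untyped"
  }
  structure(
    list(genome_id = genome_id, array = array,
         cas_hits = hits %||% tibble(), type_call = type, subtype_call = sub),
    class = "cas_locus"
  )
}

#' @export
print.cas_locus <- function(x, ...) {
  genes <- if (nrow(x$cas_hits)) paste(x$cas_hits$gene_name, collapse = ",")
           else "none"
  cat(sprintf("<cas_locus> %s  type %s / subtype %s  cas: %s\n",
              x$genome_id, x$type_call, x$subtype_call, genes))
  invisible(x)
}

#' Annotate a CRISPR array: ORFs in the flanking window, Cas hits, subtype
#'
#' Extracts the flanking window on each side of the array, finds ORFs,
#' scores them against the panel and classifies the locus. When several
#' arrays lie on one contig, each ORF is credited to the nearest array
#' (midpoint distance), so co-resident Type I and Type II systems classify
#' independently.
#'
#' @param genome A [genome()].
#' @param arrays List of `crispr_array` objects for this genome.
#' @param panel A [cas_panel()] tibble.
#' @param config A [run_config()].
#' @param min_orf_aa Minimum ORF length in aa.
#' @param genome_wide If `TRUE`, fall back to scanning the whole contig for
#'   cas ORFs when the flanking windows yield no hits.
#' @return A list of `cas_locus` objects, one per array.
#' @export
annotate_genome <- function(genome, arrays, panel = cas_panel(),
                            config = run_config(), min_orf_aa = 100L,
                            genome_wide = FALSE) {
  if (!length(arrays)) return(list())
  fw <- config$flank_window
  orfs <- list()
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    win <- list(contig_id = a$contig_id,
                start = a$start - fw, end = a$end + fw)
    o <- find_orfs(genome, win, min_orf_aa)
    # exclude ORFs overlapping the array itself
    if (nrow(o)) o <- filter(o, .data$end <= a$start | .data$start >= a$end)
    orfs[[i]] <- o
  }
  orfs_all <- distinct(bind_rows(orfs))
  if (genome_wide && !nrow(orfs_all)) {
    for (cid in names(genome$contigs)) {
      win <- list(contig_id = cid, start = 0L,
                  end = nchar(genome$contigs[[cid]]))
      orfs_all <- bind_rows(orfs_all, find_orfs(genome, win, min_orf_aa))
    }
    orfs_all <- distinct(orfs_all)
  }
  if (!nrow(orfs_all)) {
    return(lapply(arrays, function(a) classify_locus(a, NULL, genome$id)))
  }
  # nearest array per ORF, by interval midpoints
  mids <- vapply(arrays, function(a) (a$start + a$end) / 2, numeric(1))
  cids <- vapply(arrays, function(a) a$contig_id, character(1))
  orf_mid <- (orfs_all$start + orfs_all$end) / 2
  assign_to <- vapply(seq_len(nrow(orfs_all)), function(j) {
    same <- which(cids == orfs_all$contig_id[j])
    if (!length(same)) return(NA_integer_)
    same[which.min(abs(mids[same] - orf_mid[j]))]
  }, integer(1))
  lapply(seq_along(arrays), function(i) {
    mine <- orfs_all[which(assign_to == i), , drop = FALSE]
    hits <- list()
    for (j in seq_len(nrow(mine))) {
      h <- score_cas(mine[j, ], panel)
      if (!is.null(h)) {
        h$orf_start <- mine$start[j]; h$orf_end <- mine$end[j]
        h$orf_strand <- mine$strand[j]
        hits[[length(hits) + 1L]] <- h
      }
    }
    hits <- if (length(hits)) bind_rows(hits) else NULL
    # one best hit per gene name keeps duplicated genes from double counting
    if (!is.null(hits)) {
      hits <- hits |> group_by(.data$gene_name) |>
        slice_min(.data$evalue, n = 1, with_ties = FALSE) |> ungroup()
    }
    classify_locus(arrays[[i]], hits, genome$id)
  })
}

#' Species-by-subtype occurrence matrix
#'
#' Counts loci per species and subtype and reports the overall fraction of
#' genomes carrying at least one locus, rounded to integer percent.
#'
#' @param loci List of `cas_locus` objects, or a tibble with `genome_id` and
#'   `subtype_call` columns.
#' @param genomes Tibble with columns `genome_id` and `species` covering the
#'   whole cohort (including genomes without loci).
#' @return A list with `matrix` (tibble species x subtype counts, wide),
#'   `n_genomes`, `n_with_locus` and `fraction_pct`.
#' @export
occurrence_matrix <- function(loci, genomes) {
  if (is.data.frame(loci)) {
    tab <- loci
  } else if (length(loci)) {
    tab <- tibble(
      genome_id = map_chr(loci, "genome_id"),
      subtype_call = map_chr(loci, "subtype_call")
    )
  } else {
    tab <- tibble(genome_id = character(), subtype_call = character())
  }
  tab <- left_join(tab, genomes, by = "genome_id")
  n_genomes <- nrow(genomes)
  n_with <- length(intersect(unique(tab$genome_id), genomes$genome_id))
  wide <- tab |>
    count(.data$species, .data$subtype_call) |>
    tidyr::pivot_wider(names_from = "subtype_call", values_from = "n",
                       values_fill = 0L) |>
    arrange(.data$species)
  if (!nrow(wide)) {
    wide <- tibble(species = sort(unique(genomes$species)))
  }
  list(
    matrix = wide,
    n_genomes = n_genomes,
    n_with_locus = n_with,
    fraction_pct = as.integer(round(100 * n_with / max(1L, n_genomes)))
  )
}
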