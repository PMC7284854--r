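# Spacer -> protospacer homology search, flank extraction and hit
# categorisation. The search is a seeded local nucleotide alignment
# (match +2 / mismatch -3, gap open 5 / extend 2) over both strands of the
# invader database, with Karlin-Altschul E-values scaled to the total
# database length. Both filters are strict inequalities: E-value < 1e-3 and
# identity > 85.0%.

#' Search spacers against an invader database
#'
#' @param spacers Tibble with columns `id`, `seq` (18-55 nt each), or a
#'   named character vector.
#' @param invaders Tibble with columns `id`, `seq` (optionally `category`).
#' @param config A [run_config()] providing the two strict thresholds.
#' @return Tibble of hits passing both thresholds, one best hit per
#'   (spacer, invader) pair: `spacer_id`, `invader_id`, `start`, `end`
#'   (0-based half-open on the invader plus strand), `strand`, `identity`,
#'   `evalue`, `score`, `category`.
#' @export
search_protospacers <- function(spacers, invaders, config = run_config()) {
  if (!is.data.frame(spacers)) {
    spacers <- tibble(id = names(spacers), seq = unname(spacers))
  }
  if (any(nchar(spacers$seq) < 18 | nchar(spacers$seq) > 55)) {
    abort("spacers must be 18-55 nt")
  }
  n_db <- sum(nchar(invaders$seq))
  lambda <- nucleotide_lambda()
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = TRUE)
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    for (j in seq_len(nrow(invaders))) {
      inv <- invaders$seq[j]
      best <- NULL
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") inv else revcomp(inv)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(sp), Biostrings::DNAString(subj),
          type = "local", substitutionMatrix = submat,
          gapOpening = 5, gapExtension = 2
        )
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          pa <- as.character(Biostrings::alignedPattern(aln))
          sa <- as.character(Biostrings::alignedSubject(aln))
          cols <- nchar(pa)
          matches <- sum(strsplit(pa, "")[[1]] == strsplit(sa, "")[[1]])
          s0 <- IRanges::start(Biostrings::subject(aln)) - 1L
          e0 <- IRanges::end(Biostrings::subject(aln))
          if (strand == "-") {
            L <- nchar(inv)
            tmp <- s0
            s0 <- L - e0
            e0 <- L - tmp
          }
          best <- list(score = sc, identity = 100 * matches / cols,
                       start = s0, end = e0, strand = strand)
        }
      }
      ev <- ka_evalue(best$score, nchar(sp), n_db, lambda, NUCLEOTIDE_K)
      rows[[length(rows) + 1L]] <- tibble(
        spacer_id = spacers$id[i], invader_id = invaders$id[j],
        start = as.integer(best$start), end = as.integer(best$end),
        strand = best$strand, identity = best$identity,
        evalue = ev, score = best$score,
        category = categorize_invader(invaders$id[j])
      )
    }
  }
  hits <- if (length(rows)) bind_rows(rows) else empty_hits()
  filter_protospacer_hits(hits, config)
}

empty_hits <- function() {
  tibble(spacer_id = character(), invader_id = character(),
         start = integer(), end = integer(), strand = character(),
         identity = double(), evalue = double(), score = double(),
         category = character())
}

#' Apply the strict protospacer inclusion thresholds
#'
#' A hit is kept only when its E-value is strictly smaller than
#' `config$protospacer_evalue_max` and its identity strictly greater than
#' `config$protospacer_identity_min`: hits at exactly 85.0% identity or
#' exactly the E-value bound are excluded.
#'
#' @param hits Tibble with `identity` and `evalue` columns.
#' @param config A [run_config()].
#' @return The filtered tibble.
#' @export
filter_protospacer_hits <- function(hits, config = run_config()) {
  filter(hits,
         .data$evalue < config$protospacer_evalue_max,
         .data$identity > config$protospacer_identity_min)
}

#' Extract protospacer flanks in protospacer orientation
#'
#' For minus-strand hits the invader is reverse complemented before
#' extraction, so `upstream` always means 5' of the protospacer. Flanks at
#' record edges are truncated and flagged.
#'
#' @param hit One hit row from [search_protospacers()].
#' @param invaders Invader tibble (`id`, `seq`).
#' @param pam_flank Flank width in bp.
#' @return One-row tibble: `spacer_id`, `invader_id`, `upstream`,
#'   `downstream`, `truncated`.
#' @export
extract_flanks <- function(hit, invaders, pam_flank = 10L) {
  inv <- invaders$seq[invaders$id == hit$invader_id]
  if (length(inv) != 1) abort(paste0("unknown invader: ", hit$invader_id))
  L <- nchar(inv)
  if (hit$strand == "-") {
    inv <- revcomp(inv)
    s <- L - hit$end
    e <- L - hit$start
  } else {
    s <- hit$start
    e <- hit$end
  }
  up_start <- max(0L, s - pam_flank)
  dn_end <- min(L, e + pam_flank)
  up <- substr(inv, up_start + 1L, s)
  dn <- substr(inv, e + 1L, dn_end)
  tibble(
    spacer_id = hit$spacer_id, invader_id = hit$invader_id,
    upstream = up, downstream = dn,
    truncated = nchar(up) < pam_flank | nchar(dn) < pam_flank
  )
}

#' Extract flanks for a whole hit table
#'
#' @param hits Hit tibble from [search_protospacers()].
#' @param invaders Invader tibble.
#' @param pam_flank Flank width in bp.
#' @return Tibble of flank pairs, one row per hit.
#' @export
extract_flanks_all <- function(hits, invaders, pam_flank = 10L) {
  if (!nrow(hits)) {
    return(tibble(spacer_id = character(), invader_id = character(),
                  upstream = character(), downstream = character(),
                  truncated = logical()))
  }
  bind_rows(lapply(seq_len(nrow(hits)), function(i) {
    extract_flanks(hits[i, ], invaders, pam_flank)
  }))
}

# Category from the record id/header: lowercased keyword search; an
# "uncultured ... virus" header is a virus.
categorize_invader <- function(id) {
  x <- tolower(id)
  if (str_detect(x, "phage")) "phage"
  else if (str_detect(x, "plasmid")) "plasmid"
  else if (str_detect(x, "virus")) "virus"
  else "unknown"
}

#' Count protospacer hits per category
#'
#' @param hits Hit tibble (with a `category` column, as produced by
#'   [search_protospacers()]); an optional `subtype` column groups counts.
#' @return Tibble of counts per (subtype x) category, with all of phage,
#'   plasmid, virus and unknown present.
#' @export
categorize_hits <- function(hits) {
  cats <- c("phage", "plasmid", "virus", "unknown")
  if (!nrow(hits)) {
    return(tibble(category = cats, n = 0L))
  }
  groups <- if ("subtype" %in% names(hits)) c("subtype", "category")
            else "category"
  counted <- hits |> count(across(all_of(groups)))
  base <- if ("subtype" %in% names(hits)) {
    tidyr::expand_grid(subtype = unique(hits$subtype), category = cats)
  } else {
    tibble(category = cats)
  }
  left_join(base, counted, by = groups) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}
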