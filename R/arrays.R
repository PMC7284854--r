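# De novo CRISPR repeat-spacer array detection.
#
# Algorithm: (i) index exact k-mers (k = kmer_seed_len) per contig; (ii)
# k-mers recurring with a period compatible with one repeat + one spacer
# seed candidate unit chains; (iii) chains are extended column-wise outward,
# growing a consensus repeat, allowing mismatches only in terminal units and
# at most max_repeat_mismatches per unit; (iv) additional units (for example
# the degenerate terminal repeat, whose mutations can break the seed k-mer)
# are recovered by scanning the expected period window for the best Hamming
# match to the consensus; (v) boundaries are trimmed to repeat ends, and
# overlapping candidates are resolved by repeat count then leftmost start.

#' Find CRISPR arrays in a genome
#'
#' @param genome A [genome()].
#' @param params A [detector_params()].
#' @return A list of `crispr_array` objects in genome coordinate order
#'   (sorted by contig id, then start). Empty list when nothing is found.
#' @export
find_arrays <- function(genome, params = detector_params()) {
  out <- list()
  for (cid in sort(names(genome$contigs))) {
    out <- c(out, find_arrays_contig(cid, genome$contigs[[cid]], params))
  }
  out
}

find_arrays_contig <- function(contig_id, seq, params) {
  p <- params
  L <- nchar(seq)
  min_span <- p$min_repeats * p$min_repeat_len +
    (p$min_repeats - 1L) * p$min_spacer_len
  if (L < min_span) return(list())
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- p$kmer_seed_len
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !str_detect(kmers, "N")
  idx <- split(starts[ok], kmers[ok])
  idx <- idx[lengths(idx) >= p$min_repeats]
  if (!length(idx)) return(list())

  pmin_per <- p$min_repeat_len + p$min_spacer_len
  pmax_per <- p$max_repeat_len + p$max_spacer_len
  chains <- list()
  for (pos in idx) {
    d <- diff(pos)
    valid <- d >= pmin_per & d <= pmax_per
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= p$min_repeats - 1L)) {
      chains[[length(chains) + 1L]] <- pos[begins[j]:(ends[j] + 1L)]
    }
  }
  if (!length(chains)) return(list())
  chains <- chains[order(-lengths(chains),
                         vapply(chains, `[`, numeric(1), 1L))]

  arrays <- list()
  covered <- matrix(numeric(0), ncol = 2) # accepted array intervals (1-based)
  for (ch in chains) {
    if (nrow(covered) &&
        any(ch[1] <= covered[, 2] & ch[length(ch)] + k - 1L >= covered[, 1])) {
      next
    }
    arr <- extend_chain(chars, L, ch, k, p)
    if (is.null(arr)) next
    arrays[[length(arrays) + 1L]] <- arr
    covered <- rbind(covered, c(arr$first, arr$last))
  }
  if (!length(arrays)) return(list())
  # Resolve overlaps: higher repeat count wins, ties to the leftmost start.
  ord <- order(-vapply(arrays, function(a) length(a$unit_starts), integer(1)),
               vapply(arrays, function(a) a$first, numeric(1)))
  kept <- list()
  for (a in arrays[ord]) {
    clash <- any(vapply(kept, function(b) a$first <= b$last && a$last >= b$first,
                        logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept <- kept[order(vapply(kept, function(a) a$first, numeric(1)))]
  lapply(kept, function(a) build_array(contig_id, chars, a))
}

# Column acceptance rule during extension: the column consensus is the
# majority base (ties A<C<G<T); at most one unit may mismatch, it must be a
# terminal unit, and its cumulative mismatch count must stay within budget.
# Interior repeat copies are length- and sequence-conserved, so requiring
# them to agree keeps boundary calls exact even for short arrays.
majority_base <- function(cols) {
  counts <- tabulate(match(cols, DNA_BASES), nbins = 4L)
  DNA_BASES[which.max(counts)]
}

extend_chain <- function(chars, L, seeds, k, p) {
  mm <- integer(length(seeds)) # cumulative mismatches per unit vs consensus
  loff <- 0L
  roff <- k # unit i covers seeds[i] + loff .. seeds[i] + roff - 1 (1-based)

  # Accept a column, or name the terminal unit that blocks it. A terminal
  # unit that exhausts its budget (for example a degenerate terminal repeat
  # whose mutation shifted its seed k-mer) is dropped from the chain and
  # recovered later by the augmentation scan at its true offset.
  col_state <- function(off) {
    m <- length(seeds)
    posn <- seeds + off
    if (any(posn < 1L | posn > L)) return(list(ok = FALSE, drop = NA))
    cols <- chars[posn]
    if (any(!cols %in% DNA_BASES)) return(list(ok = FALSE, drop = NA))
    cons <- majority_base(cols)
    bad <- which(cols != cons)
    if (length(bad) == 0L) return(list(ok = TRUE, bad = integer(0)))
    if (length(bad) > 1L || !(bad %in% c(1L, m))) {
      return(list(ok = FALSE, drop = NA))
    }
    if (mm[bad] + 1L > p$max_repeat_mismatches) {
      return(list(ok = FALSE, drop = bad))
    }
    list(ok = TRUE, bad = bad)
  }
  advance <- function(off) {
    repeat {
      st <- col_state(off)
      if (st$ok) {
        if (length(st$bad)) mm[st$bad] <<- mm[st$bad] + 1L
        return(TRUE)
      }
      if (is.na(st$drop) || length(seeds) <= 2L) {
        return(FALSE)
      }
      seeds <<- seeds[-st$drop]
      mm <<- mm[-st$drop]
    }
  }

  repeat { # rightward
    if (roff - loff >= p$max_repeat_len) break
    # keep at least min_spacer_len between this unit's end and the next start
    gaps <- diff(seeds) - (roff + 1L)
    if (any(gaps < p$min_spacer_len)) break
    if (!advance(roff)) break
    roff <- roff + 1L
  }
  repeat { # leftward
    if (roff - loff >= p$max_repeat_len) break
    gaps <- diff(seeds) - (roff - loff)
    if (any(gaps - 1L < p$min_spacer_len)) break
    if (!advance(loff - 1L)) break
    loff <- loff - 1L
  }
  rep_len <- roff - loff
  if (rep_len < p$min_repeat_len || rep_len > p$max_repeat_len) return(NULL)

  unit_starts <- seeds + loff
  consensus <- consensus_of_units(chars, unit_starts, rep_len)

  # Recover flanking units the seed chain missed (degenerate terminal
  # repeats in particular) by scanning the expected period window.
  repeat {
    s1 <- unit_starts[1]
    lo <- s1 - p$max_spacer_len - rep_len
    hi <- s1 - p$min_spacer_len - rep_len
    cand <- best_unit_match(chars, L, lo, hi, consensus, rep_len,
                            p$max_repeat_mismatches)
    if (is.null(cand)) break
    unit_starts <- c(cand, unit_starts)
  }
  repeat {
    sl <- unit_starts[length(unit_starts)]
    lo <- sl + rep_len + p$min_spacer_len
    hi <- sl + rep_len + p$max_spacer_len
    cand <- best_unit_match(chars, L, lo, hi, consensus, rep_len,
                            p$max_repeat_mismatches)
    if (is.null(cand)) break
    unit_starts <- c(unit_starts, cand)
  }

  # Re-place terminal units at the best-matching offset in their expected
  # window: a degenerate terminal repeat can enter the chain at a shifted
  # seed position while still passing the mismatch budget.
  if (length(unit_starts) >= 3L) {
    s2 <- unit_starts[2]
    cand <- best_unit_match(chars, L, s2 - p$max_spacer_len - rep_len,
                            s2 - p$min_spacer_len - rep_len, consensus,
                            rep_len, p$max_repeat_mismatches)
    if (!is.null(cand)) unit_starts[1] <- cand
    sp <- unit_starts[length(unit_starts) - 1L]
    cand <- best_unit_match(chars, L, sp + rep_len + p$min_spacer_len,
                            sp + rep_len + p$max_spacer_len, consensus,
                            rep_len, p$max_repeat_mismatches)
    if (!is.null(cand)) unit_starts[length(unit_starts)] <- cand
  }

  consensus <- consensus_of_units(chars, unit_starts, rep_len)
  cons_ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mmv <- vapply(unit_starts, function(s) {
    sum(chars[s:(s + rep_len - 1L)] != cons_ch)
  }, integer(1))
  keep <- mmv <= p$max_repeat_mismatches
  # trim non-conforming terminal units only
  while (length(keep) && !keep[1]) { keep <- keep[-1]; unit_starts <- unit_starts[-1] }
  while (length(keep) && !keep[length(keep)]) {
    keep <- keep[-length(keep)]; unit_starts <- unit_starts[-length(unit_starts)]
  }
  if (length(unit_starts) < p$min_repeats || any(!keep)) return(NULL)

  list(unit_starts = unit_starts, rep_len = rep_len, consensus = consensus,
       first = unit_starts[1], last = unit_starts[length(unit_starts)] + rep_len - 1L)
}

consensus_of_units <- function(chars, unit_starts, rep_len) {
  mat <- vapply(unit_starts, function(s) chars[s:(s + rep_len - 1L)],
                character(rep_len))
  if (rep_len == 1L) mat <- matrix(mat, nrow = 1L)
  paste(apply(mat, 1L, majority_base), collapse = "")
}

best_unit_match <- function(chars, L, lo, hi, consensus, rep_len, max_mm) {
  lo <- max(1L, lo); hi <- min(hi, L - rep_len + 1L)
  if (hi < lo) return(NULL)
  cons_ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  cand <- lo:hi
  mm <- vapply(cand, function(s) {
    w <- chars[s:(s + rep_len - 1L)]
    if (any(!w %in% DNA_BASES)) return(rep_len) # N aborts the unit
    sum(w != cons_ch)
  }, integer(1))
  best <- which(mm <= max_mm)
  if (!length(best)) return(NULL)
  best <- best[order(mm[best], -cand[best])][1] # fewest mismatches, nearest
  cand[best]
}

build_array <- function(contig_id, chars, a) {
  n <- length(a$unit_starts)
  rep_starts0 <- a$unit_starts - 1L
  reps <- tibble(
    start = rep_starts0,
    end = rep_starts0 + a$rep_len,
    seq = vapply(a$unit_starts, function(s) {
      paste(chars[s:(s + a$rep_len - 1L)], collapse = "")
    }, character(1))
  )
  spacers <- tibble(
    start = reps$end[-n],
    end = reps$start[-1],
    seq = vapply(seq_len(n - 1L), function(i) {
      paste(chars[(reps$end[i] + 1L):reps$start[i + 1L]], collapse = "")
    }, character(1))
  )
  crispr_array(
    contig_id = contig_id,
    start = reps$start[1], end = reps$end[n],
    repeats = reps, spacers = spacers,
    consensus_repeat = a$consensus,
    strand = "+", orientation_confident = FALSE
  )
}

#' Construct a CRISPR array object
#'
#' Checks the structural invariants: `n` repeats alternate with `n - 1`
#' spacers, units tile the array interval without gaps or overlaps, and
#' every repeat is within `max_mm` mismatches of the consensus.
#'
#' @param contig_id Contig the array lies on.
#' @param start,end 0-based half-open array interval.
#' @param repeats,spacers Tibbles with columns `start`, `end`, `seq`
#'   (genomic, 0-based half-open; `seq` is given in array orientation).
#' @param consensus_repeat Consensus repeat sequence.
#' @param strand `"+"` if the array is reported in genome orientation,
#'   `"-"` if it was flipped by [orient_array()].
#' @param orientation_confident Whether the orientation call is confident.
#' @param max_mm Mismatch budget used for the consensus invariant.
#' @return An object of class `crispr_array`.
#' @export
crispr_array <- function(contig_id, start, end, repeats, spacers,
                         consensus_repeat, strand = "+",
                         orientation_confident = FALSE, max_mm = 3L) {
  n <- nrow(repeats)
  if (n != nrow(spacers) + 1L) abort("an array needs n repeats and n-1 spacers")
  tile <- bind_rows(repeats[, c("start", "end")],
                    spacers[, c("start", "end")]) |> arrange(.data$start)
  if (any(tile$start[-1] != tile$end[-nrow(tile)])) {
    abort("repeats and spacers must alternate and tile the interval")
  }
  if (tile$start[1] != start || tile$end[nrow(tile)] != end) {
    abort("array interval must equal the span of its units")
  }
  mm <- vapply(repeats$seq, function(s) {
    if (nchar(s) != nchar(consensus_repeat)) return(Inf)
    hamming(if (strand == "+") s else revcomp(s),
            if (strand == "+") consensus_repeat else revcomp(consensus_repeat))
  }, numeric(1))
  if (any(mm > max_mm)) abort("repeat too far from consensus")
  structure(
    list(contig_id = contig_id, start = as.integer(start),
         end = as.integer(end), repeats = repeats, spacers = spacers,
         consensus_repeat = consensus_repeat, strand = strand,
         orientation_confident = orientation_confident),
    class = "crispr_array"
  )
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf(
    "<crispr_array> %s:[%d,%d)%s  %d repeats / %d spacers, repeat %d nt%s\n",
    x$contig_id, x$start, x$end, x$strand, nrow(x$repeats), nrow(x$spacers),
    nchar(x$consensus_repeat),
    if (x$orientation_confident) ", oriented" else ""))
  invisible(x)
}

#' Consensus of equal-length repeat sequences
#'
#' Per-position majority base; ties resolve to the alphabetically first base
#' (A < C < G < T).
#'
#' @param repeat_seqs Non-empty character vector of equal-length sequences.
#' @return The consensus sequence.
#' @examples
#' consensus_repeat(c("ACGT", "ACGT", "ACGA"))
#' @export
consensus_repeat <- function(repeat_seqs) {
  if (!length(repeat_seqs)) abort("no repeat sequences given")
  if (length(unique(nchar(repeat_seqs))) != 1L) {
    abort("repeat sequences must have equal length")
  }
  mat <- vapply(repeat_seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(nchar(repeat_seqs[1])))
  if (nchar(repeat_seqs[1]) == 1L) mat <- matrix(mat, nrow = 1L)
  paste(apply(mat, 1L, majority_base), collapse = "")
}

#' Orient an array by its degenerate terminal repeat
#'
#' Real arrays acquire spacers at the leader end while the trailer-end
#' repeat decays; if exactly one terminal repeat diverges from the consensus
#' by two or more mismatches the array is flipped, if needed, so that the
#' degenerate repeat is rightmost (trailer end) and the call is confident.
#' Otherwise the array is returned unchanged with
#' `orientation_confident = FALSE`.
#'
#' @param array A `crispr_array`.
#' @return The oriented `crispr_array`.
#' @export
orient_array <- function(array) {
  reps <- array$repeats$seq
  cons <- array$consensus_repeat
  mmf <- hamming(reps[1], cons)
  mml <- hamming(reps[length(reps)], cons)
  deg_first <- mmf >= 2L
  deg_last <- mml >= 2L
  if (deg_first == deg_last) {
    array$orientation_confident <- FALSE
    return(array)
  }
  array$orientation_confident <- TRUE
  if (deg_last) return(array)
  flip_array(array)
}

# Reverse-complement an array in place: genomic interval is unchanged, unit
# order is reversed and sequences complemented; strand records the flip.
flip_array <- function(array) {
  flip_tbl <- function(tbl) {
    tbl <- tbl[rev(seq_len(nrow(tbl))), , drop = FALSE]
    tbl$seq <- revcomp(tbl$seq)
    tbl
  }
  array$repeats <- flip_tbl(array$repeats)
  array$spacers <- flip_tbl(array$spacers)
  array$consensus_repeat <- revcomp(array$consensus_repeat)
  array$strand <- if (array$strand == "+") "-" else "+"
  array
}

#' Per-locus and per-subtype array statistics
#'
#' @param arrays List of `crispr_array` objects.
#' @param subtype_calls Optional character vector (recycled or named by
#'   array index) of subtype calls; defaults to `"unknown"`.
#' @param genome_ids Optional character vector of genome ids per array.
#' @return A list with `loci` (per-locus tibble: spacer count, repeat length
#'   mode) and `subtypes` (per-subtype mean spacer count and repeat-length
#'   histogram as a nested tibble).
#' @export
array_stats <- function(arrays, subtype_calls = NULL, genome_ids = NULL) {
  if (!length(arrays)) {
    return(list(
      loci = tibble(genome_id = character(), contig_id = character(),
                    start = integer(), n_spacers = integer(),
                    repeat_length = integer(), subtype = character()),
      subtypes = tibble(subtype = character(), n_loci = integer(),
                        mean_spacers = double(),
                        repeat_length_hist = list())
    ))
  }
  subtype_calls <- subtype_calls %||% rep("unknown", length(arrays))
  genome_ids <- genome_ids %||% rep(NA_character_, length(arrays))
  loci <- tibble(
    genome_id = genome_ids,
    contig_id = map_chr(arrays, "contig_id"),
    start = map_int(arrays, "start"),
    n_spacers = map_int(arrays, ~ nrow(.x$spacers)),
    repeat_length = map_int(arrays, ~ {
      lens <- nchar(.x$repeats$seq)
      as.integer(names(which.max(table(lens))))
    }),
    subtype = subtype_calls
  ) |> arrange(.data$genome_id, .data$contig_id, .data$start)
  subtypes <- loci |>
    group_by(.data$subtype) |>
    summarise(
      n_loci = n(),
      mean_spacers = mean(.data$n_spacers),
      repeat_length_hist = list(table(.data$repeat_length)),
      .groups = "drop"
    )
  list(loci = loci, subtypes = subtypes)
}
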