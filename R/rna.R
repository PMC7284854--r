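# crRNA repeat hairpin prediction, anti-repeat tracrRNA discovery and
# crRNA:tracrRNA duplex element labelling.
#
# Secondary structure comes from deterministic base-pair maximization
# (Nussinov recursion, min loop 3, G:U allowed, T read as U) rather than
# thermodynamic folding: it is dependency-free, exactly reproducible, and
# sufficient to recover stem/loop/handle geometry. Among equally large
# structures the traceback prefers the most-3' paired region, then maximal
# stem contiguity falls out of the index-sum tie-break.

#' Fold a crRNA repeat into its hairpin structure
#'
#' @param repeat_seq Repeat sequence (DNA; T is read as U), between
#'   `min_len` and `max_len` nt.
#' @param min_len,max_len Accepted length range (relax for short test
#'   constructs).
#' @return A `hairpin_structure`: `seq`, `pairs` (two-column matrix of
#'   0-based indices), `n_pairs`, `stem_len` (longest stack of nested
#'   adjacent pairs), `loop_len` (unpaired span closed by the innermost pair
#'   of that stem), `handle3_len` (unpaired nt 3' of the last paired base;
#'   whole length when nothing pairs), `five_prime_len`, `dot_bracket`.
#' @examples
#' fold_crrna(subtype_template("I-C")$repeat_seq)
#' @export
fold_crrna <- function(repeat_seq, min_len = 20L, max_len = 60L) {
  n <- nchar(repeat_seq)
  if (n < min_len || n > max_len) {
    abort(sprintf("repeat length %d outside [%d, %d]", n, min_len, max_len))
  }
  if (grepl("[^ACGTU]", repeat_seq)) abort("sequence must be A/C/G/T/U")
  pairs <- nussinov_pairs_cpp(repeat_seq, 3L)
  hairpin_structure(repeat_seq, pairs)
}

hairpin_structure <- function(seq, pairs) {
  n <- nchar(seq)
  np <- nrow(pairs)
  if (np) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  db <- rep(".", n)
  if (np) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
  }
  stem <- longest_stack(pairs)
  structure(
    list(
      seq = seq,
      pairs = pairs,
      n_pairs = np,
      stem_len = stem$len,
      loop_len = stem$loop,
      handle3_len = if (np) n - 1L - max(pairs[, 2]) else n,
      five_prime_len = if (np) min(pairs[, 1]) else 0L,
      dot_bracket = paste(db, collapse = "")
    ),
    class = "hairpin_structure"
  )
}

# Longest run of stacked pairs ((i, j), (i+1, j-1), ...) and the loop length
# closed by its innermost pair.
longest_stack <- function(pairs) {
  if (!nrow(pairs)) return(list(len = 0L, loop = NA_integer_))
  key <- paste(pairs[, 1], pairs[, 2])
  best_len <- 0L; best_loop <- NA_integer_
  seen <- new.env(hash = TRUE)
  for (k in key) assign(k, TRUE, envir = seen)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # only start counting at the outer end of a stack
    if (exists(paste(i - 1L, j + 1L), envir = seen)) next
    len <- 0L
    while (exists(paste(i, j), envir = seen)) {
      len <- len + 1L
      i <- i + 1L; j <- j - 1L
    }
    if (len > best_len) {
      best_len <- len
      best_loop <- j - i + 1L # unpaired span inside the innermost pair
    }
  }
  list(len = best_len, loop = best_loop)
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("<hairpin_structure> %d nt, %d pair(s), stem %s, loop %s, 3' handle %d nt\n",
              nchar(x$seq), x$n_pairs,
              x$stem_len, x$loop_len %||% NA, x$handle3_len))
  cat("  ", x$seq, "\n  ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Mature crRNA processing cut site
#'
#' Cas5/Cas6 processing cuts within the repeat 8 nt from the 3' end in
#' subtypes I-C and I-G, 7 nt in subtype I-E.
#'
#' @param structure A `hairpin_structure` for the repeat.
#' @param subtype One of `"I-C"`, `"I-E"`, `"I-G"`.
#' @return List with `cut_from_3prime` (7 or 8) and `cut_index` (0-based
#'   position in the repeat after which cleavage occurs).
#' @export
mature_crrna_cut <- function(structure, subtype) {
  k <- switch(subtype, "I-C" = 8L, "I-G" = 8L, "I-E" = 7L,
              abort(paste0("no processing rule for subtype: ", subtype)))
  n <- nchar(structure$seq)
  list(cut_from_3prime = k, cut_index = n - k)
}

# anti-repeat Hamming scan: positions (1-based) in `region` where a window
# matches `pattern` with <= max_mm mismatches. Vectorised by shifting.
antirepeat_scan <- function(region, pattern, max_mm) {
  L <- nchar(region)
  w <- nchar(pattern)
  if (L < w) return(integer(0))
  rch <- strsplit(region, "", fixed = TRUE)[[1]]
  pch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  nw <- L - w + 1L
  mm <- integer(nw)
  for (t in seq_len(w)) {
    mm <- mm + (rch[t:(t + nw - 1L)] != pch[t])
  }
  which(mm <= max_mm)
}

#' Find tracrRNA candidates near a Type II locus
#'
#' Scans the locus neighbourhood for anti-repeat windows: stretches whose
#' sequence is the reverse complement of the repeat consensus within
#' `max_mismatches`, outside the array and outside cas coding regions. Each
#' candidate is extended 3' to the end of the first poly-T (>= 4 T)
#' terminator, capped at +120 nt, and ranked by (fewest mismatches,
#' placement prior for the subtype: upstream of *cas9* for II-C, between
#' *cas9* and *cas1* for II-A).
#'
#' @param genome A [genome()].
#' @param locus A `cas_locus` whose `cas_hits` carry `orf_start`/`orf_end`
#'   columns (as produced by [annotate_genome()]).
#' @param max_mismatches Maximum anti-repeat mismatches.
#' @param min_antirepeat Minimum anti-repeat length (full repeat length is
#'   used for scanning; shorter repeats are rejected).
#' @param flank_window Scan window on each side of the array.
#' @return Tibble of candidates: `contig_id`, `start`, `end`, `strand`,
#'   `anti_start`, `anti_end`, `mismatches`, `placement`,
#'   `predicted_length`, `seq`; best candidate first.
#' @export
find_tracrrna <- function(genome, locus, max_mismatches = 3L,
                          min_antirepeat = 20L, flank_window = 20000L) {
  if (locus$type_call != "II") abort("tracrRNA search requires a Type II locus")
  a <- locus$array
  rep_cons <- if (a$strand == "+") a$consensus_repeat else revcomp(a$consensus_repeat)
  w <- nchar(rep_cons)
  if (w < min_antirepeat) abort("repeat shorter than min_antirepeat")
  contig <- genome$contigs[[a$contig_id]]
  L <- nchar(contig)
  g0 <- max(0L, a$start - flank_window)
  g1 <- min(L, a$end + flank_window)
  region <- substr(contig, g0 + 1L, g1)

  hits <- locus$cas_hits
  orf_iv <- if (!is.null(hits) && nrow(hits) && "orf_start" %in% names(hits)) {
    hits[, c("gene_name", "orf_start", "orf_end")]
  } else {
    tibble(gene_name = character(), orf_start = integer(), orf_end = integer())
  }

  cands <- list()
  for (strand in c("+", "-")) {
    reg <- if (strand == "+") region else revcomp(region)
    pos <- antirepeat_scan(reg, revcomp(rep_cons), max_mismatches)
    for (t in pos) {
      # genomic anti-repeat interval (0-based half-open)
      if (strand == "+") {
        s <- g0 + t - 1L
      } else {
        s <- g0 + (nchar(reg) - (t - 1L) - w)
      }
      e <- s + w
      if (s < a$end && e > a$start) next # inside the array
      if (nrow(orf_iv) && any(s < orf_iv$orf_end & e > orf_iv$orf_start)) next
      mm <- hamming(if (strand == "+") substr(contig, s + 1L, e)
                    else revcomp(substr(contig, s + 1L, e)),
                    revcomp(rep_cons))
      # 3' extension to the poly-T terminator (cap +120 nt)
      tail_max <- 120L
      tail_seq <- if (strand == "+") {
        substr(contig, e + 1L, min(L, e + tail_max))
      } else {
        revcomp(substr(contig, max(0L, s - tail_max) + 1L, s))
      }
      m <- regexpr("TTTT+", tail_seq)
      ext <- if (m[1] > 0) m[1] + attr(m, "match.length") - 1L else nchar(tail_seq)
      if (strand == "+") {
        cs <- s; ce <- e + ext
      } else {
        cs <- s - ext; ce <- e
      }
      seq <- if (strand == "+") substr(contig, cs + 1L, ce)
             else revcomp(substr(contig, cs + 1L, ce))
      cands[[length(cands) + 1L]] <- tibble(
        contig_id = a$contig_id, start = cs, end = ce, strand = strand,
        anti_start = s, anti_end = e, mismatches = mm,
        placement = tracr_placement(s, e, orf_iv),
        predicted_length = ce - cs, seq = seq
      )
    }
  }
  if (!length(cands)) return(empty_tracr())
  out <- bind_rows(cands) |> distinct()
  # collapse near-duplicate windows (overlapping anti-repeats, same strand)
  out <- out |>
    arrange(.data$mismatches) |>
    group_by(.data$strand) |>
    filter(!duplicated(floor(.data$anti_start / 10))) |>
    ungroup()
  prior <- tracr_prior(locus$subtype_call)
  out |>
    mutate(prior_match = .data$placement == prior) |>
    arrange(.data$mismatches, desc(.data$prior_match), .data$start) |>
    select(-"prior_match")
}

empty_tracr <- function() {
  tibble(contig_id = character(), start = integer(), end = integer(),
         strand = character(), anti_start = integer(), anti_end = integer(),
         mismatches = integer(), placement = character(),
         predicted_length = integer(), seq = character())
}

tracr_prior <- function(subtype) {
  switch(subtype, "II-C" = "upstream_of_cas9", "II-A" = "between_cas9_and_cas1",
         "other")
}

tracr_placement <- function(s, e, orf_iv) {
  cas9 <- orf_iv[orf_iv$gene_name == "cas9", ]
  cas1 <- orf_iv[orf_iv$gene_name == "cas1", ]
  if (nrow(cas9)) {
    if (e <= cas9$orf_start[1]) {
      if (nrow(cas1) && cas1$orf_start[1] < cas9$orf_start[1] &&
          s >= cas1$orf_end[1]) {
        return("between_cas9_and_cas1")
      }
      return("upstream_of_cas9")
    }
    if (nrow(cas1) && s >= cas9$orf_end[1] && e <= cas1$orf_start[1]) {
      return("between_cas9_and_cas1")
    }
  }
  "other"
}

#' Predict the crRNA:tracrRNA duplex and label its elements
#'
#' Anchors an antiparallel alignment of the repeat against the 5' end of
#' the tracrRNA, allowing one internal bulge of up to `max_bulge` nt on
#' either strand, then folds the remaining tracr 3' tail (the poly-T
#' terminator is excluded from folding) and labels nested components in 5'
#' to 3' order: lower stem, bulge, upper stem, nexus (first tail hairpin)
#' and further terminal hairpins.
#'
#' @param repeat_seq Repeat consensus (crRNA side).
#' @param tracr_seq tracrRNA sequence, anti-repeat first.
#' @param min_pairs Minimum duplex pairs; below this the result is
#'   "no duplex".
#' @param max_bulge Maximum bulge length tried on either strand.
#' @return A `duplex_structure` (or a no-duplex marker): `lower_stem_len`,
#'   `bulge_len`, `bulge_on`, `upper_stem_len`, `n_pairs`, `nexus`,
#'   `hairpins` (list of `hairpin_structure`-like summaries), `elements`
#'   (tibble in canonical order).
#' @export
predict_duplex <- function(repeat_seq, tracr_seq, min_pairs = 10L,
                           max_bulge = 3L) {
  r <- nchar(repeat_seq)
  rep_ch <- strsplit(repeat_seq, "", fixed = TRUE)[[1]]
  best <- NULL
  for (bulge_on in c("none", "tracr", "repeat")) {
    blens <- if (bulge_on == "none") 0L else seq_len(max_bulge)
    for (b in blens) {
      m <- if (bulge_on == "none") r else if (bulge_on == "tracr") r + b
           else r - b
      if (m > nchar(tracr_seq) || m < min_pairs) next
      rc_pref <- strsplit(revcomp(substr(tracr_seq, 1L, m)), "",
                          fixed = TRUE)[[1]]
      alen <- min(r, m) # aligned positions outside the bulge
      gaps <- if (bulge_on == "none") 0L else seq_len(alen - 1L)
      for (q in gaps) {
        if (bulge_on == "tracr") {
          aligned_r <- rep_ch
          aligned_t <- rc_pref[-(q + seq_len(b))]
        } else if (bulge_on == "repeat") {
          aligned_r <- rep_ch[-(q + seq_len(b))]
          aligned_t <- rc_pref
        } else {
          aligned_r <- rep_ch
          aligned_t <- rc_pref
        }
        paired <- duplex_match(aligned_r, aligned_t)
        np <- sum(paired)
        if (is.null(best) || np > best$np) {
          best <- list(np = np, paired = paired, q = q, b = b,
                       bulge_on = bulge_on, m = m)
        }
      }
    }
  }
  if (is.null(best) || best$np < min_pairs) {
    return(structure(list(no_duplex = TRUE, n_pairs = best$np %||% 0L),
                     class = "duplex_structure"))
  }
  el <- duplex_elements(best$paired, best$bulge_on, best$q, best$b)
  lower <- el$lower; upper <- el$upper
  bulge_len <- el$bulge_len; bulge_on <- el$bulge_on

  tail_seq <- substr(tracr_seq, best$m + 1L, nchar(tracr_seq))
  tail_seq <- sub("T{4,}$", "", tail_seq) # terminator is not a structural element
  comps <- list()
  if (nchar(tail_seq) >= 5L) {
    pairs <- nussinov_pairs_cpp(tail_seq, 3L)
    comps <- pair_components(pairs, tail_seq)
  }
  nexus <- if (length(comps)) comps[[1]] else NULL
  hairpins <- if (length(comps) > 1) comps[-1] else list()
  elements <- bind_rows(
    tibble(element = "lower_stem", length = lower),
    tibble(element = "bulge", length = bulge_len),
    tibble(element = "upper_stem", length = upper),
    if (!is.null(nexus)) tibble(element = "nexus", length = nexus$stem_len),
    if (length(hairpins)) tibble(
      element = paste0("hairpin_", seq_along(hairpins)),
      length = vapply(hairpins, function(h) h$stem_len, integer(1))
    )
  )
  structure(
    list(no_duplex = FALSE, n_pairs = best$np,
         lower_stem_len = lower, bulge_len = bulge_len, bulge_on = bulge_on,
         upper_stem_len = upper, nexus = nexus, hairpins = hairpins,
         elements = elements),
    class = "duplex_structure"
  )
}

# Lower stem / bulge / upper stem from the pairing profile. For an
# explicit bulge the boundary is the alignment position it follows; without
# one, the first internal unpaired run separates the stems.
duplex_elements <- function(paired, bulge_on, q, b) {
  n <- length(paired)
  if (bulge_on != "none") {
    lower <- 0L
    t <- q
    while (t >= 1L && paired[t]) { lower <- lower + 1L; t <- t - 1L }
    upper <- if (q < n) sum(paired[(q + 1L):n]) else 0L
    return(list(lower = lower, upper = upper, bulge_len = b,
                bulge_on = bulge_on))
  }
  runs <- rle(paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pr <- which(runs$values)
  lower <- runs$lengths[pr[1]]
  if (length(pr) > 1L) {
    gap <- pr[1] + 1L # first internal unpaired run
    list(lower = lower, upper = sum(runs$lengths[pr[-1]]),
         bulge_len = runs$lengths[gap], bulge_on = "both")
  } else {
    list(lower = lower, upper = 0L, bulge_len = 0L, bulge_on = "none")
  }
}

# RNA duplex match in (repeat, revcomp(tracr)) space: Watson-Crick pairs
# appear as equal characters; G:U wobble as repeat G vs A, or repeat T vs C.
duplex_match <- function(r_ch, t_ch) {
  (r_ch == t_ch) |
    (r_ch == "G" & t_ch == "A") |
    (r_ch == "T" & t_ch == "C")
}

# Group nested pairs into top-level components (hairpin elements), 5'->3'.
pair_components <- function(pairs, seq) {
  if (!nrow(pairs)) return(list())
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  top <- rep(NA_integer_, nrow(pairs))
  roots <- integer(0)
  for (rw in seq_len(nrow(pairs))) {
    i <- pairs[rw, 1]; j <- pairs[rw, 2]
    enclosing <- which(pairs[, 1] < i & pairs[, 2] > j)
    if (!length(enclosing)) {
      roots <- c(roots, rw)
      top[rw] <- rw
    } else {
      outer <- enclosing[which.min(pairs[enclosing, 1])]
      top[rw] <- top[outer]
    }
  }
  # stacked root pairs belong to the same component as their enclosing root
  lapply(roots, function(rt) {
    members <- pairs[top == rt, , drop = FALSE]
    st <- longest_stack(members)
    list(start = min(members[, 1]), end = max(members[, 2]) + 1L,
         n_pairs = nrow(members), stem_len = st$len, loop_len = st$loop)
  })
}

#' @export
print.duplex_structure <- function(x, ...) {
  if (isTRUE(x$no_duplex)) {
    cat("<duplex_structure> no duplex\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<duplex_structure> %d pairs: lower stem %d, bulge %d (%s), upper stem %d, %s\n",
    x$n_pairs, x$lower_stem_len, x$bulge_len, x$bulge_on, x$upper_stem_len,
    if (is.null(x$nexus)) "no tail structure"
    else sprintf("nexus + %d hairpin(s)", length(x$hairpins))))
  invisible(x)
}
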