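# Spacer-content strain genotyping: shared ancestral blocks, divergence
# points, deletions and subgrouping. Arrays are compared in spacer-id space
# after unifying identical spacers (and reverse complements) under one id;
# matching is exact, since spacers are either acquired identically or are
# different.

#' Build a spacer dictionary across arrays
#'
#' Assigns integer ids to spacer sequences in first-seen order; a sequence
#' and its reverse complement share one id.
#'
#' @param arrays List of `crispr_array` objects, or a list of character
#'   vectors of spacer sequences.
#' @return A `spacer_dictionary`: tibble `seq` (canonical form), `id`.
#' @export
build_dictionary <- function(arrays) {
  seqs <- unlist(lapply(arrays, function(a) {
    if (inherits(a, "crispr_array")) a$spacers$seq else a
  }), use.names = FALSE)
  if (is.null(seqs)) seqs <- character(0)
  canon <- canonical_spacer(seqs)
  uniq <- unique(canon)
  structure(
    tibble(seq = uniq, id = seq_along(uniq)),
    class = c("spacer_dictionary", "tbl_df", "tbl", "data.frame")
  )
}

# Canonical form: lexicographic min of the sequence and its reverse
# complement, so both orientations map to one id.
canonical_spacer <- function(seqs) {
  if (!length(seqs)) return(character(0))
  rc <- revcomp(seqs)
  ifelse(seqs <= rc, seqs, rc)
}

#' Translate spacer sequences to dictionary ids
#'
#' @param seqs Character vector of spacer sequences.
#' @param dictionary A `spacer_dictionary`.
#' @return Integer vector of ids (`NA` for unknown spacers).
#' @export
spacer_ids <- function(seqs, dictionary) {
  dictionary$id[match(canonical_spacer(seqs), dictionary$seq)]
}

#' Align strain arrays at the trailer (ancestral) end
#'
#' Arrays are anchored at the trailer end (rightmost spacer). Strains are
#' clustered into subgroups by single linkage on the length of their longest
#' common trailer-end suffix (in id space), requiring at least `min_shared`
#' shared spacers to declare common ancestry. Within a subgroup, columns are
#' right-justified with gaps (`NA`) for missing leader-end blocks.
#'
#' @param strain_arrays Named list: per strain, either a `crispr_array`, or
#'   a character vector of spacer sequences ordered leader first / trailer
#'   last.
#' @param dictionary Optional [build_dictionary()] result (built on the fly
#'   otherwise).
#' @param min_shared Minimum shared trailer suffix to join a subgroup.
#' @param try_both_orientations When `TRUE`, arrays flagged
#'   `orientation_confident = FALSE` are also tried reversed; the
#'   orientation maximizing total shared suffix with the other strains wins.
#' @return A `spacer_alignment`: `strains`, `ids` (list of id vectors),
#'   `subgroup` (integer per strain), `matrix` (tibble, strains x columns,
#'   right-justified, `NA` as gap).
#' @export
align_arrays <- function(strain_arrays, dictionary = NULL, min_shared = 3L,
                         try_both_orientations = TRUE) {
  if (length(strain_arrays) < 2L) abort("need at least two strains")
  nm <- names(strain_arrays) %||% sprintf("strain_%02d", seq_along(strain_arrays))
  seqs <- lapply(strain_arrays, function(a) {
    if (inherits(a, "crispr_array")) a$spacers$seq else a
  })
  # plain spacer vectors carry no orientation evidence, so they are also
  # eligible for the both-orientations retry
  unconfident <- vapply(strain_arrays, function(a) {
    if (inherits(a, "crispr_array")) !isTRUE(a$orientation_confident)
    else TRUE
  }, logical(1))
  dictionary <- dictionary %||% build_dictionary(seqs)
  ids <- lapply(seqs, spacer_ids, dictionary = dictionary)
  names(ids) <- nm

  if (try_both_orientations && any(unconfident)) {
    for (i in which(unconfident)) {
      fwd <- ids[[i]]
      rev <- rev(spacer_ids(revcomp(seqs[[i]]), dictionary))
      score <- function(v) {
        sum(vapply(ids[-i], function(o) shared_suffix(v, o), integer(1)))
      }
      if (score(rev) > score(fwd)) ids[[i]] <- rev
    }
  }

  n <- length(ids)
  shared <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) shared[i, j] <- shared[j, i] <- shared_suffix(ids[[i]], ids[[j]])
    }
  }
  subgroup <- single_linkage(shared >= min_shared)

  width <- max(lengths(ids))
  mat <- t(vapply(ids, function(v) {
    c(rep(NA_integer_, width - length(v)), v)
  }, integer(width)))
  if (width == 0L) mat <- matrix(NA_integer_, n, 0L)
  colnames(mat) <- if (width) paste0("c", seq_len(width)) else character(0)
  structure(
    list(strains = nm, ids = ids, subgroup = subgroup,
         shared = shared, matrix = as_tibble(mat) |>
           mutate(strain = nm, subgroup = subgroup, .before = 1)),
    class = "spacer_alignment"
  )
}

# Length of the longest common suffix of two id vectors.
shared_suffix <- function(a, b) {
  k <- 0L
  la <- length(a); lb <- length(b)
  while (k < la && k < lb && !is.na(a[la - k]) && !is.na(b[lb - k]) &&
         a[la - k] == b[lb - k]) {
    k <- k + 1L
  }
  k
}

single_linkage <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && adj[i, j] && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' @export
print.spacer_alignment <- function(x, ...) {
  cat(sprintf("<spacer_alignment> %d strain(s), %d subgroup(s), %d column(s)\n",
              length(x$strains), length(unique(x$subgroup)),
              max(lengths(x$ids))))
  invisible(x)
}

#' Detect acquisition, deletion and divergence events
#'
#' Within each subgroup, strains are compared at the trailer-anchored
#' alignment: leader-end columns carried by one strain only are acquisition
#' events; a strain whose array is a strict trailer-suffix of another
#' strain's (sharing acquired spacers beyond the subgroup-wide ancestral
#' block) lost its leader-most block, a deletion event with the missing
#' length; the first column (counted from the trailer) where a strain's ids
#' leave the subgroup consensus is its divergence point.
#'
#' @param alignment A [align_arrays()] result.
#' @return Tibble of events: `strain`, `type`
#'   (`acquisition`/`deletion`/`divergence`), `length`, `column`
#'   (trailer-anchored index where the event applies), `ids` (list column
#'   with the spacer ids involved).
#' @export
detect_events <- function(alignment) {
  out <- list()
  for (g in unique(alignment$subgroup)) {
    members <- which(alignment$subgroup == g)
    if (length(members) < 2L) next
    ids <- alignment$ids[members]
    strains <- alignment$strains[members]
    # subgroup-wide shared trailer block
    common <- Reduce(function(a, b) {
      k <- shared_suffix(a, b)
      if (k) a[(length(a) - k + 1L):length(a)] else integer(0)
    }, ids)
    nc <- length(common)
    for (m in seq_along(members)) {
      v <- ids[[m]]
      extra <- length(v) - nc
      others <- ids[-m]
      if (extra > 0L) {
        # leader-end block beyond the shared trailer: acquired and retained
        out[[length(out) + 1L]] <- tibble(
          strain = strains[m], type = "acquisition", length = extra,
          column = 0L, ids = list(v[seq_len(extra)])
        )
      }
      # a strain whose whole array is a strict trailer-suffix of another's
      # (so they share acquired spacers) lost its leader-most block
      best_suf <- vapply(others, function(o) shared_suffix(v, o), integer(1))
      twin <- which.max(best_suf)
      if (length(others) && best_suf[twin] >= length(v) &&
          length(others[[twin]]) > length(v)) {
        lost <- length(others[[twin]]) - length(v)
        out[[length(out) + 1L]] <- tibble(
          strain = strains[m], type = "deletion", length = lost,
          column = extra, ids = list(others[[twin]][seq_len(lost)])
        )
      }
      if (length(v) > nc) {
        out[[length(out) + 1L]] <- tibble(
          strain = strains[m], type = "divergence", length = 0L,
          column = nc, ids = list(integer(0))
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(strain = character(), type = character(),
                  length = integer(), column = integer(), ids = list()))
  }
  bind_rows(out) |> arrange(.data$strain, .data$type)
}

#' Replay events against the subgroup ancestral block
#'
#' Reconstructs each strain's id sequence by prepending its retained
#' acquisition block (the `ids` of its acquisition event) to the
#' subgroup-wide shared trailer block. Deletion events describe spacers
#' acquired and subsequently lost, so they contribute nothing to the
#' reconstruction; the round-trip check is that the result equals the
#' observed array exactly.
#'
#' @param alignment A [align_arrays()] result.
#' @param events A [detect_events()] tibble.
#' @return Named list of reconstructed id vectors (only strains in
#'   subgroups of two or more).
#' @export
replay_events <- function(alignment, events) {
  recon <- list()
  for (g in unique(alignment$subgroup)) {
    members <- which(alignment$subgroup == g)
    if (length(members) < 2L) next
    ids <- alignment$ids[members]
    common <- Reduce(function(a, b) {
      k <- shared_suffix(a, b)
      if (k) a[(length(a) - k + 1L):length(a)] else integer(0)
    }, ids)
    for (m in seq_along(members)) {
      strain <- alignment$strains[members[m]]
      acq <- events[events$strain == strain & events$type == "acquisition", ]
      v <- common
      if (nrow(acq)) v <- c(unlist(acq$ids), v)
      recon[[strain]] <- as.integer(v)
    }
  }
  recon
}
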