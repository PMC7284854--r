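#' Simulate a strain lineage by spacer acquisition and deletion
#'
#' All strains descend from a common ancestor whose `ancestor_spacers`
#' spacers form the shared trailer-end (right) block. Each strain then
#' acquires `acquisitions_per_strain` new, strain-specific spacers at the
#' leader end (left). A deletion event `(i, L)` first makes strain `i` an
#' identical twin of strain `i - 1` (copying its acquired block, the way
#' near-identical isolates share recent acquisitions) and then removes the
#' `L` leader-most spacers, emulating loss of recently acquired spacers.
#'
#' @param ancestor_spacers Number of shared ancestral spacers.
#' @param strains Number of strains (>= 2).
#' @param acquisitions_per_strain New leader-end spacers per strain.
#' @param deletion_events List of `c(strain_index, block_length)` pairs;
#'   strain_index must be >= 2 and block_length <= acquisitions_per_strain.
#' @param seed Integer RNG seed.
#' @return A list with `arrays` (named list of spacer-sequence vectors,
#'   leader first / trailer last) and `truth` (tibble of per-strain events
#'   plus the ancestral block).
#' @examples
#' lin <- simulate_lineage(10, 3, 5, seed = 1)
#' lengths(lin$arrays)
#' @export
simulate_lineage <- function(ancestor_spacers, strains,
                             acquisitions_per_strain,
                             deletion_events = list(), seed = 1L) {
  stopifnot(strains >= 2, ancestor_spacers >= 1)
  for (ev in deletion_events) {
    if (ev[1] < 2 || ev[1] > strains) {
      abort("deletion strain index must be in 2..strains")
    }
    if (ev[2] > acquisitions_per_strain) {
      abort("deletion longer than the strain's acquired block")
    }
  }
  with_seed(derive_seed(seed, 3L), {
    ancestor <- random_spacers(ancestor_spacers)
    acq <- lapply(seq_len(strains), function(i) {
      if (acquisitions_per_strain == 0) character(0)
      else random_spacers(acquisitions_per_strain)
    })
    deleted <- integer(strains)
    twins <- integer(0)
    # apply in strain order so a chain of twins always roots at a strain
    # that keeps its full acquired block
    if (length(deletion_events) > 1) {
      deletion_events <- deletion_events[
        order(vapply(deletion_events, `[`, numeric(1), 1))]
    }
    for (ev in deletion_events) {
      i <- ev[1]
      acq[[i]] <- acq[[i - 1L]] # identical twin of the previous strain
      deleted[i] <- as.integer(ev[2])
      twins <- c(twins, i)
    }
    arrays <- lapply(seq_len(strains), function(i) {
      a <- acq[[i]]
      if (deleted[i] > 0) a <- a[-seq_len(deleted[i])]
      c(a, ancestor) # leader first, trailer (ancestral) last
    })
    names(arrays) <- sprintf("strain_%02d", seq_len(strains))
    truth <- tibble(
      strain = names(arrays),
      n_acquired = vapply(seq_len(strains),
                          function(i) length(acq[[i]]) - deleted[i],
                          integer(1)),
      n_deleted = deleted,
      twin_of = ifelse(seq_len(strains) %in% twins,
                       sprintf("strain_%02d", seq_len(strains) - 1L), NA)
    )
    list(arrays = arrays,
         truth = list(events = truth, ancestor = ancestor,
                      acquired = stats::setNames(acq, names(arrays))))
  })
}
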