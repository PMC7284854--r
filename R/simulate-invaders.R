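#' Simulate an invader sequence database with planted protospacers
#'
#' Builds `n_targeted` invader records, each embedding one truth spacer
#' verbatim with the given PAM immediately adjacent on the requested side,
#' plus `n_decoys` records of pure random background verified to contain no
#' run of 20 nt or more matching any spacer. Record ids carry a category
#' label cycling through phage, plasmid and virus.
#'
#' @param truth A `sim_truth` from [simulate_genome()] (or a tibble of
#'   spacers with columns `spacer_id`, `seq`).
#' @param n_targeted Number of spacers to plant (<= number of truth spacers).
#' @param pam PAM sequence to plant (A/C/G/T only).
#' @param pam_side `"5prime"` (PAM immediately 5' of the protospacer) or
#'   `"3prime"`.
#' @param n_decoys Number of decoy records.
#' @param seed Integer RNG seed.
#' @param record_bp Length of each invader record.
#' @return A list with `invaders` (tibble `id`, `seq`, `category`) and
#'   `truth` (the input truth with a `protospacers` tibble recording record
#'   id, 0-based protospacer offset, spacer id, planted PAM and side).
#' @export
simulate_invaders <- function(truth, n_targeted, pam = "TTC",
                              pam_side = c("5prime", "3prime"),
                              n_decoys = 5L, seed = 1L, record_bp = 1500L) {
  pam_side <- match.arg(pam_side)
  if (grepl("[^ACGT]", pam)) abort("pam must contain only A/C/G/T")
  spacers <- if (inherits(truth, "sim_truth")) truth$spacers else truth
  if (n_targeted > nrow(spacers)) {
    abort("n_targeted exceeds the number of truth spacers")
  }
  categories <- c("phage", "plasmid", "virus")
  with_seed(derive_seed(seed, 2L), {
    rows <- list(); ps_rows <- list()
    if (n_targeted > 0) {
      pick <- seq_len(n_targeted)
      for (k in pick) {
        sp <- spacers$seq[k]
        cat_k <- categories[(k - 1L) %% 3L + 1L]
        id <- sprintf("%s_inv%03d", cat_k, k)
        insert <- if (pam_side == "5prime") paste0(pam, sp) else paste0(sp, pam)
        slack <- record_bp - nchar(insert)
        at <- sample.int(slack - 1L, 1) # 1-based position before insert
        seq <- paste0(random_dna(at), insert, random_dna(slack - at))
        offset <- at + if (pam_side == "5prime") nchar(pam) else 0L # 0-based
        rows[[length(rows) + 1L]] <-
          tibble(id = id, seq = seq, category = cat_k)
        ps_rows[[length(ps_rows) + 1L]] <- tibble(
          invader_id = id, offset = as.integer(offset),
          spacer_id = spacers$spacer_id[k], spacer_seq = sp,
          pam = pam, pam_side = pam_side, strand = "+", category = cat_k
        )
      }
    }
    if (n_decoys > 0) {
      kmers <- unlist(lapply(spacers$seq, function(s) {
        if (nchar(s) < 20L) return(character(0))
        substring(s, 1:(nchar(s) - 19L), 20:nchar(s))
      }))
      kmers <- unique(c(kmers, revcomp(kmers)))
      for (k in seq_len(n_decoys)) {
        repeat {
          seq <- random_dna(record_bp)
          hit <- length(kmers) > 0 &&
            any(vapply(kmers, function(km) grepl(km, seq, fixed = TRUE),
                       logical(1)))
          if (!hit) break
        }
        cat_k <- categories[(k - 1L) %% 3L + 1L]
        rows[[length(rows) + 1L]] <-
          tibble(id = sprintf("%s_decoy%03d", cat_k, k), seq = seq,
                 category = cat_k)
      }
    }
    invaders <- bind_rows(rows)
    if (inherits(truth, "sim_truth")) {
      truth$protospacers <- if (length(ps_rows)) bind_rows(ps_rows) else NULL
      list(invaders = invaders, truth = truth)
    } else {
      list(invaders = invaders,
           protospacers = if (length(ps_rows)) bind_rows(ps_rows) else NULL)
    }
  })
}
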