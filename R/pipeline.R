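#' Run detection and annotation on one genome
#'
#' Convenience wrapper: find arrays, orient them, annotate flanking ORFs
#' against the panel, classify each locus, and (for Type II loci) search
#' for tracrRNA candidates.
#'
#' @param genome A [genome()].
#' @param panel A [cas_panel()] tibble.
#' @param config A [run_config()].
#' @param params A [detector_params()].
#' @param tracr Whether to run the tracrRNA search on Type II loci.
#' @return A list with `arrays` (oriented `crispr_array`s), `loci`
#'   (`cas_locus` list), `tracr` (tibble of candidates, possibly empty) and
#'   `summary` (one row per locus).
#' @export
mine_genome <- function(genome, panel = cas_panel(), config = run_config(),
                        params = detector_params(), tracr = TRUE) {
  arrays <- lapply(find_arrays(genome, params), orient_array)
  loci <- annotate_genome(genome, arrays, panel, config)
  tr <- empty_tracr()
  if (tracr) {
    for (lc in loci) {
      if (lc$type_call == "II") {
        cand <- find_tracrrna(genome, lc, flank_window = config$flank_window)
        if (nrow(cand)) {
          cand$genome_id <- genome$id
          cand$subtype <- lc$subtype_call
          tr <- bind_rows(tr, cand[1, ])
        }
      }
    }
  }
  summary <- if (length(loci)) bind_rows(lapply(loci, glance.cas_locus))
             else tibble()
  list(arrays = arrays, loci = loci, tracr = tr, summary = summary)
}
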