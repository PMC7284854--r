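#' Pipeline run configuration
#'
#' Holds the handful of thresholds the pipeline applies globally. Defaults
#' follow the mining protocol this package implements: a 20 kb window is
#' extracted on each side of a CRISPR array when searching for *cas* genes,
#' protospacer hits are kept only when the E-value is strictly below 1e-3
#' *and* the identity is strictly above 85.0%, and 10 bp of flanking sequence
#' on each side of a protospacer feed the PAM model.
#'
#' @param flank_window Width in bp of the flanking window scanned on each side
#'   of an array for *cas* ORFs (and for tracrRNA anti-repeats).
#' @param protospacer_evalue_max Exclusive upper bound on protospacer E-values.
#' @param protospacer_identity_min Exclusive lower bound on protospacer percent
#'   identity.
#' @param pam_flank Number of bases extracted on each side of a protospacer.
#' @param rng_seed Integer seed used by any stage that draws random numbers.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$flank_window
#' @export
run_config <- function(flank_window = 20000L,
                       protospacer_evalue_max = 1e-3,
                       protospacer_identity_min = 85.0,
                       pam_flank = 10L,
                       rng_seed = 1L) {
  stopifnot(
    flank_window > 0, protospacer_evalue_max > 0,
    protospacer_identity_min > 0, pam_flank > 0
  )
  structure(
    list(
      flank_window = as.integer(flank_window),
      protospacer_evalue_max = protospacer_evalue_max,
      protospacer_identity_min = protospacer_identity_min,
      pam_flank = as.integer(pam_flank),
      rng_seed = as.integer(rng_seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' CRISPR array detector parameters
#'
#' Length brackets are chosen to cover observed repeat biology (repeat lengths
#' around 29-36 nt across subtypes) with margin; a locus must show at least
#' `min_repeats` periodic repeat copies before it is reported, because
#' two-copy "arrays" cannot be told apart from generic dispersed repeats.
#'
#' @param min_repeat_len,max_repeat_len Allowed repeat length range (nt).
#' @param min_spacer_len,max_spacer_len Allowed spacer length range (nt).
#' @param min_repeats Minimum number of repeat copies per array.
#' @param max_repeat_mismatches Maximum Hamming distance of any repeat copy
#'   from the array consensus.
#' @param kmer_seed_len Exact k-mer length used to seed detection.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(min_repeat_len = 23L, max_repeat_len = 50L,
                            min_spacer_len = 18L, max_spacer_len = 55L,
                            min_repeats = 3L, max_repeat_mismatches = 3L,
                            kmer_seed_len = 12L) {
  stopifnot(
    min_repeat_len < max_repeat_len,
    min_spacer_len < max_spacer_len,
    kmer_seed_len <= min_repeat_len,
    min_repeats >= 2
  )
  structure(
    list(
      min_repeat_len = as.integer(min_repeat_len),
      max_repeat_len = as.integer(max_repeat_len),
      min_spacer_len = as.integer(min_spacer_len),
      max_spacer_len = as.integer(max_spacer_len),
      min_repeats = as.integer(min_repeats),
      max_repeat_mismatches = as.integer(max_repeat_mismatches),
      kmer_seed_len = as.integer(kmer_seed_len)
    ),
    class = "detector_params"
  )
}
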