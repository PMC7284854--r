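#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @import tibble
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap keep
#' @importFrom rlang abort warn .data %||%
#' @importFrom stringr str_sub str_to_upper str_detect str_split
#' @importFrom Rcpp sourceCpp
#' @useDynLib crisprmine, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Vectorised over its input; `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, upper case).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Uniform random DNA of length n (assumes RNG state is set by the caller).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Replace anything outside A/C/G/T/N with N, after upper-casing.
normalize_dna <- function(x) {
  x <- str_to_upper(x)
  gsub("[^ACGTN]", "N", x)
}

# Hamming distance between two equal-length strings (as char vectors).
hamming <- function(a, b) sum(strsplit(a, "", fixed = TRUE)[[1]] !=
                              strsplit(b, "", fixed = TRUE)[[1]])

# Run code with a fixed RNG seed, restoring the previous state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive an independent 31-bit stream seed from (seed, salt): different
# generator stages fed the same user seed must not replay each other's
# draws (a genome's spacers would otherwise reappear in an invader
# background built from the same stream).
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) %% 44488 * 48271 + salt * 65537) %% 2147483647)
}

# Mutate `n_mut` distinct positions of a DNA string to a different base.
mutate_dna <- function(seq, n_mut) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# Minimal IUPAC code for a set of bases.
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(
    A = "A", C = "C", G = "G", T = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
    CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
  )
  unname(codes[key])
}

# 0-based half-open interval constructor used throughout the package.
interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(start >= 0, end > start)
  list(contig_id = contig_id, start = as.integer(start),
       end = as.integer(end), strand = strand)
}
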