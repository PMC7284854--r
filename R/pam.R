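# PAM inference from protospacer flanks: a per-position nucleotide
# frequency matrix with information content in bits, and an IUPAC consensus
# over positions that carry enough information.

#' Infer a PAM model from protospacer flanks
#'
#' The flank side follows the system type: Type I PAMs sit 5' of the
#' protospacer (upstream flank), Type II PAMs 3' (downstream). Frequencies
#' use a pseudocount of 0.5 per base; the information content of a column is
#' `2 - H` bits with `H` the Shannon entropy (log base 2). The consensus
#' reports IUPAC codes for positions reaching `call_threshold` bits; when no
#' position qualifies, or fewer than `min_hits` flanks are available, the
#' consensus is empty ("not clear").
#'
#' @param flanks Tibble from [extract_flanks_all()] (columns `upstream`,
#'   `downstream`), or a character vector of flank sequences for the chosen
#'   side.
#' @param subtype Subtype label; determines the side (`I*` upstream,
#'   `II*` downstream). Ignored when `side` is given.
#' @param min_hits Minimum number of flanks for a consensus call.
#' @param call_threshold Information content (bits) a position must reach.
#' @param pam_flank Flank width W; matrices are 4 x W.
#' @param side Optional override: `"5prime"` or `"3prime"`.
#' @return A `pam_model`: `side`, `freq` (4 x W), `info` (W bits),
#'   `consensus` (possibly ""), `called` (logical W), `n_hits`.
#' @export
infer_pam <- function(flanks, subtype = "I-C", min_hits = 5L,
                      call_threshold = 1.0, pam_flank = 10L, side = NULL) {
  if (is.null(side)) {
    side <- if (startsWith(subtype, "II")) "3prime" else "5prime"
  }
  if (is.character(flanks)) {
    seqs <- flanks
  } else if (nrow(flanks)) {
    seqs <- if (side == "5prime") flanks$upstream else flanks$downstream
  } else {
    seqs <- character(0)
  }
  W <- pam_flank
  n <- length(seqs)
  counts <- matrix(0, nrow = 4, ncol = W, dimnames = list(DNA_BASES, NULL))
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    # upstream flanks anchor at the protospacer (right edge), downstream at
    # the left edge, so truncated flanks still align position-wise
    k <- length(ch)
    if (k == 0L) next
    cols <- if (side == "5prime") (W - k + 1L):W else 1L:min(k, W)
    ch <- if (side == "5prime") ch else ch[seq_along(cols)]
    for (t in seq_along(cols)) {
      b <- ch[t]
      if (b %in% DNA_BASES) counts[b, cols[t]] <- counts[b, cols[t]] + 1
    }
  }
  freq <- sweep(counts + 0.5, 2, colSums(counts + 0.5), "/")
  # information content from observed proportions (0 log 0 = 0), so a
  # perfectly conserved column scores the full 2 bits; the pseudocount
  # smooths only the reported frequency matrix
  praw <- sweep(counts, 2, pmax(1, colSums(counts)), "/")
  plog <- praw * log2(praw)
  plog[!is.finite(plog)] <- 0
  info <- 2 + colSums(plog)
  info[colSums(counts) == 0] <- 0
  called <- info >= call_threshold & n >= min_hits
  consensus <- ""
  if (any(called)) {
    # a PAM is an adjacency motif: report the contiguous run of called
    # positions nearest the protospacer boundary
    r <- rle(called)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    pick <- if (side == "5prime") runs[length(runs)] else runs[1]
    span <- c(starts[pick], ends[pick])
    codes <- vapply(span[1]:span[2], function(j) {
      if (!called[j]) return("N")
      # IUPAC call on raw count proportions (the pseudocount is only a
      # smoother for the information content)
      f <- sort(counts[, j] / max(1, sum(counts[, j])), decreasing = TRUE)
      top <- names(f)[seq_len(which(cumsum(f) >= 0.9)[1])]
      iupac_code(top)
    }, character(1))
    consensus <- paste(codes, collapse = "")
  }
  positions <- if (side == "5prime") seq.int(-W, -1L) else seq_len(W)
  structure(
    list(side = side, freq = freq, info = unname(info),
         consensus = consensus, called = unname(called),
         positions = positions, n_hits = n),
    class = "pam_model"
  )
}

#' @export
print.pam_model <- function(x, ...) {
  lab <- if (x$side == "5prime") "5' of protospacer" else "3' of protospacer"
  cat(sprintf("<pam_model> %s, %d hit(s): %s\n", lab, x$n_hits,
              if (nzchar(x$consensus)) paste0("5'-", x$consensus, "-3'")
              else "not clear"))
  # text logo: column height proportional to information content
  bars <- vapply(x$info, function(b) {
    strrep("#", max(0L, round(4 * max(0, b))))
  }, character(1))
  top <- apply(x$freq, 2, function(f) DNA_BASES[which.max(f)])
  for (lev in 8:1) {
    row <- ifelse(nchar(bars) >= lev, top, " ")
    cat(" ", paste(row, collapse = ""), "\n", sep = "")
  }
  cat(" ", paste(ifelse(x$positions < 0, "-", "+"), collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PAM model into a per-position tibble
#'
#' @param x A `pam_model`.
#' @param ... Unused.
#' @return Tibble with `position`, per-base frequencies, `info_bits`,
#'   `called`.
#' @export
tidy.pam_model <- function(x, ...) {
  tibble(
    position = x$positions,
    A = x$freq["A", ], C = x$freq["C", ],
    G = x$freq["G", ], T = x$freq["T", ],
    info_bits = x$info, called = x$called
  )
}

#' One-row summary of a PAM model
#' @param x A `pam_model`.
#' @param ... Unused.
#' @return Tibble with `side`, `n_hits`, `consensus`, `max_info_bits`,
#'   `n_called`.
#' @export
glance.pam_model <- function(x, ...) {
  tibble(side = x$side, n_hits = x$n_hits, consensus = x$consensus,
         max_info_bits = max(x$info), n_called = sum(x$called))
}

#' Information-content logo plot for a PAM model
#'
#' @param object A `pam_model`.
#' @param ... Unused.
#' @return A ggplot object: stacked per-base information content by
#'   position.
#' @export
autoplot.pam_model <- function(object, ...) {
  df <- tidy.pam_model(object) |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"),
                        names_to = "base", values_to = "freq") |>
    mutate(bits = .data$freq * .data$info_bits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "position relative to protospacer", y = "bits",
                  fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a PAM matrix as TSV (rows A, C, G, T plus an information row)
#'
#' @param pam A `pam_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pam_tsv <- function(pam, path) {
  m <- rbind(pam$freq, info = pam$info)
  df <- data.frame(row = rownames(m), m, check.names = FALSE)
  names(df) <- c("row", as.character(pam$positions))
  readr::write_tsv(df, path)
  invisible(path)
}
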