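# broom-style accessors and plots for the result objects.

#' Tidy a CRISPR array into one row per unit
#'
#' @param x A `crispr_array`.
#' @param ... Unused.
#' @return Tibble with `unit` (repeat/spacer), `index`, `start`, `end`,
#'   `seq` in array orientation.
#' @export
tidy.crispr_array <- function(x, ...) {
  bind_rows(
    mutate(x$repeats, unit = "repeat", index = dplyr::row_number()),
    mutate(x$spacers, unit = "spacer", index = dplyr::row_number())
  ) |>
    arrange(.data$start) |>
    select("unit", "index", "start", "end", "seq")
}

#' One-row summary of a CRISPR array
#' @param x A `crispr_array`.
#' @param ... Unused.
#' @return Tibble with contig, interval, counts, repeat length and
#'   orientation.
#' @export
glance.crispr_array <- function(x, ...) {
  tibble(
    contig_id = x$contig_id, start = x$start, end = x$end,
    strand = x$strand, n_repeats = nrow(x$repeats),
    n_spacers = nrow(x$spacers),
    repeat_length = nchar(x$consensus_repeat),
    consensus_repeat = x$consensus_repeat,
    orientation_confident = x$orientation_confident
  )
}

#' Tidy a locus into one row per cas hit
#' @param x A `cas_locus`.
#' @param ... Unused.
#' @return Tibble of cas hits annotated with the locus calls.
#' @export
tidy.cas_locus <- function(x, ...) {
  hits <- if (nrow(x$cas_hits)) x$cas_hits else
    tibble(gene_name = character(), identity = double(), evalue = double())
  mutate(hits, genome_id = x$genome_id, type_call = x$type_call,
         subtype_call = x$subtype_call, .before = 1)
}

#' One-row summary of a locus
#' @param x A `cas_locus`.
#' @param ... Unused.
#' @return Tibble with the calls, gene content and array geometry.
#' @export
glance.cas_locus <- function(x, ...) {
  tibble(
    genome_id = x$genome_id,
    type_call = x$type_call,
    subtype_call = x$subtype_call,
    n_cas_genes = nrow(x$cas_hits),
    cas_genes = paste(sort(x$cas_hits$gene_name), collapse = ","),
    n_spacers = if (!is.null(x$array)) nrow(x$array$spacers) else NA_integer_,
    repeat_length = if (!is.null(x$array)) nchar(x$array$consensus_repeat)
                    else NA_integer_
  )
}

#' Tidy a spacer alignment into long format
#' @param x A `spacer_alignment`.
#' @param ... Unused.
#' @return Tibble with `strain`, `subgroup`, `column` (trailer-anchored,
#'   1 = leader-most), `id`.
#' @export
tidy.spacer_alignment <- function(x, ...) {
  x$matrix |>
    tidyr::pivot_longer(cols = dplyr::starts_with("c"),
                        names_to = "column", values_to = "id") |>
    mutate(column = as.integer(sub("^c", "", .data$column)))
}

#' Block diagram of a spacer alignment
#'
#' Strains as rows, trailer-anchored columns as tiles coloured by spacer
#' id; gaps are blank.
#'
#' @param object A `spacer_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacer_alignment <- function(object, ...) {
  df <- tidy.spacer_alignment(object) |> filter(!is.na(.data$id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$strain,
                                   fill = factor(.data$id))) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2,
                       show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), size = 2.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$subgroup),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "array column (leader left, trailer right)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-subtype array-size distributions
#'
#' @param stats Result of [array_stats()].
#' @return A ggplot object (spacer count by subtype).
#' @export
plot_array_sizes <- function(stats) {
  ggplot2::ggplot(stats$loci,
                  ggplot2::aes(x = .data$subtype, y = .data$n_spacers)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "spacers per array") +
    ggplot2::theme_minimal()
}
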