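#' Write tabular pipeline results to a report directory
#'
#' One TSV per named table plus a `summary.json` with row counts. Row order
#' is made deterministic (sorted by genome id then coordinate-like columns
#' when present), so identical inputs produce byte-identical output.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(tables, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) abort(paste0("cannot create directory: ", path))
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named list")
  }
  written <- character(0)
  for (nm in names(tables)) {
    tab <- as_tibble(tables[[nm]])
    sort_cols <- intersect(c("genome_id", "contig_id", "start", "id",
                             "spacer_id", "strain", "species"),
                           names(tab))
    if (length(sort_cols)) {
      tab <- arrange(tab, across(all_of(sort_cols)))
    }
    # list columns cannot go to TSV; serialise them compactly
    for (col in names(tab)) {
      if (is.list(tab[[col]])) {
        tab[[col]] <- vapply(tab[[col]], function(v) {
          paste(v, collapse = ",")
        }, character(1))
      }
    }
    f <- file.path(path, paste0(nm, ".tsv"))
    readr::write_tsv(tab, f)
    written <- c(written, f)
  }
  summary <- lapply(tables, function(t) list(rows = nrow(t), cols = ncol(t)))
  jf <- file.path(path, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, jf))
}
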