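#' Read a count matrix and its sample sheet
#'
#' The counts TSV has `gene_id` as its first column and one column per
#' sample; the sample sheet TSV has `sample_id`, `timepoint_h`, `replicate`.
#' Duplicate gene or sample ids, negative or non-numeric counts, and samples
#' missing from the sheet are rejected. Non-integer counts (e.g. expected
#' counts from posterior-probability quantifiers) are rounded with a
#' warning.
#'
#' @param path Counts TSV.
#' @param sample_sheet_path Sample sheet TSV.
#' @return List: `counts` tibble (`gene_id` + integer sample columns),
#'   `samples` tibble.
#' @export
read_counts <- function(path, sample_sheet_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(counts)[1] != "gene_id") names(counts)[1] <- "gene_id"
  if (anyDuplicated(counts$gene_id)) {
    abort(sprintf("duplicate gene_id '%s' in %s",
                  counts$gene_id[duplicated(counts$gene_id)][1], path))
  }
  samples <- read_sample_sheet(sample_sheet_path)
  sample_cols <- setdiff(names(counts), "gene_id")
  if (anyDuplicated(sample_cols)) abort("duplicate sample columns in counts")
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing)) {
    abort(sprintf("sample '%s' in counts is missing from the sample sheet",
                  missing[1]))
  }
  for (col in sample_cols) {
    v <- counts[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("non-numeric counts in column '%s'", col))
    }
    if (any(is.na(v))) abort(sprintf("missing counts in column '%s'", col))
    if (any(v < 0)) {
      abort(sprintf("negative count at row %d, column '%s'",
                    which(v < 0)[1], col))
    }
    if (any(v != round(v))) {
      warn(sprintf("non-integer counts in column '%s' rounded to integers", col))
      v <- round(v)
    }
    counts[[col]] <- as.integer(v)
  }
  list(counts = counts, samples = samples)
}

#' @rdname read_counts
#' @export
read_sample_sheet <- function(sample_sheet_path) {
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE)
  need <- c("sample_id", "timepoint_h", "replicate")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    abort(sprintf("sample sheet is missing column '%s'", missing[1]))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in sheet")
  samples
}

#' Read a precomputed per-contrast statistics table
#'
#' Accepts externally computed differential-expression statistics (e.g. an
#' edgeR results export) with columns `gene_id`, `timepoint_h`, `log2FC`,
#' `p` and optionally `FDR`; when `FDR` is absent, Benjamini-Hochberg
#' adjustment is applied within each time point. This is the route for
#' reproducing a published DEG selection exactly from its supplementary
#' statistics tables via [filter_degs()].
#'
#' @param path TSV file.
#' @return Contrast tibble: `gene_id`, `timepoint_h`, `log2FC`, `p`, `FDR`.
#' @export
read_stats_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "timepoint_h", "log2FC", "p")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort(sprintf("statistics table is missing column '%s'", missing[1]))
  }
  assert_probability(tab$p, "p")
  if (!"FDR" %in% names(tab)) {
    tab <- tab |> group_by(.data$timepoint_h) |>
      mutate(FDR = adjust_bh(.data$p)) |> ungroup()
  } else {
    assert_probability(tab$FDR, "FDR")
  }
  dup <- duplicated(tab[, c("gene_id", "timepoint_h")])
  if (any(dup)) {
    abort(sprintf("duplicate (gene_id, timepoint_h) row for gene '%s'",
                  tab$gene_id[dup][1]))
  }
  select(tab, "gene_id", "timepoint_h", "log2FC", "p", "FDR")
}

#' Read a two-column gene-to-term annotation map
#'
#' @param path TSV with columns `gene_id`, `term_id` (header optional in GMT
#'   mode; `format = "gmt"` reads one category per line: name, description,
#'   then member genes).
#' @param format `"tsv"` (default) or `"gmt"`.
#' @param class Category class label attached to the map.
#' @return Tibble: `gene_id`, `term_id`, `class`.
#' @export
read_annotation_map <- function(path, format = c("tsv", "gmt"), class = "GO") {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("gene_id", "term_id") %in% names(tab))) {
      if (ncol(tab) >= 2) names(tab)[1:2] <- c("gene_id", "term_id")
      else abort("annotation TSV needs columns gene_id and term_id")
    }
    tab <- select(tab, "gene_id", "term_id")
  } else {
    lines <- readLines(path)
    tab <- purrr::map_dfr(lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) return(NULL)
      tibble(gene_id = parts[-(1:2)], term_id = parts[1])
    })
  }
  tab$class <- class
  distinct(tab)
}

#' Read a motif dictionary file
#'
#' @param path TSV with columns `name`, `tf_family`, `consensus`, or a JSON
#'   array of objects with those fields.
#' @return Motif tibble compatible with [motif_hits()].
#' @export
read_motif_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- as_tibble(jsonlite::fromJSON(path))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
  }
  if (!all(c("name", "consensus") %in% names(tab))) {
    abort("motif file needs columns name and consensus")
  }
  if (!"tf_family" %in% names(tab)) tab$tf_family <- NA_character_
  select(tab, "name", "tf_family", "consensus")
}

#' Write a tibble as TSV (missing values as NA)
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Write a counts tibble and sample sheet
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param samples Sample sheet tibble.
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  write_tsv_na(counts, counts_path)
  write_tsv_na(select(samples, "sample_id", "timepoint_h", "replicate"),
               samples_path)
  invisible(counts_path)
}
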