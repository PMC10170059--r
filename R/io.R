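#' Read a sample sheet
#'
#' A sample sheet maps each sample to its biological condition (developmental
#' stage, tissue, treatment timepoint, ...) and replicate index, and
#' optionally to a group used by grouped stability analyses.
#'
#' @param path Delimited text file with columns `sample_id`, `condition`,
#'   `replicate` and optionally `group`. Tab or comma delimited; the
#'   delimiter is detected from the header line unless `delim` is given.
#' @param delim Optional delimiter override (`"\t"` or `","`).
#' @return A tibble with columns `sample_id`, `condition`, `replicate`
#'   (integer) and, when present in the file, `group`.
#' @export
read_sample_sheet <- function(path, delim = NULL) {
  tbl <- read_delim_auto(path, delim)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("sample sheet %s lacks column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  tbl <- dplyr::mutate(tbl,
    sample_id = as.character(.data$sample_id),
    condition = as.character(.data$condition),
    replicate = as.integer(.data$replicate)
  )
  assert_unique(tbl$sample_id, "sample ids in sample sheet")
  key <- paste(tbl$condition, tbl$replicate, sep = "\r")
  assert_unique(key, "(condition, replicate) pairs")
  tbl
}

#' Read a gene-by-sample TPM expression table
#'
#' Expression tables are wide delimited text: first column `gene_id`, one
#' column per sample, cells holding TPM (transcripts per million). Gene and
#' sample identifiers are opaque case-sensitive strings (ids containing dots
#' are common in draft-genome annotations and pass through untouched).
#' Row and column order are preserved exactly as on disk.
#'
#' @param path Expression table file (TSV or CSV, auto-detected).
#' @param sample_sheet Sample sheet tibble from [read_sample_sheet()], or a
#'   path to one. Every sample column in the matrix must appear in the sheet.
#' @param delim Optional delimiter override.
#' @return A tibble (`gene_id` + sample columns) with the matching sample
#'   sheet attached as attribute `"sample_sheet"`.
#' @export
read_expression <- function(path, sample_sheet, delim = NULL) {
  tbl <- read_delim_auto(path, delim, first_col = "gene_id")
  assert_wide_table(tbl, sprintf("expression table %s", path), min_value = 0)
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  attach_sample_sheet(tbl, sample_sheet)
}

#' Attach and validate a sample sheet on a wide expression/Ct table
#'
#' @param tbl Wide tibble (`gene_id` + sample columns).
#' @param sample_sheet Tibble with at least `sample_id` and `condition`.
#' @return `tbl` with attribute `"sample_sheet"` set (rows ordered to match
#'   the table's sample columns).
#' @export
attach_sample_sheet <- function(tbl, sample_sheet) {
  samples <- setdiff(names(tbl), "gene_id")
  missing <- setdiff(samples, sample_sheet$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples absent from sample sheet: %s",
                  paste(missing, collapse = ", ")))
  }
  sheet <- sample_sheet[match(samples, sample_sheet$sample_id), , drop = FALSE]
  attr(tbl, "sample_sheet") <- sheet
  tbl
}

#' Read a wide Ct (quantification-cycle) table
#'
#' Empty cells and the literal `NA` are read as missing (reactions that
#' failed or were not run). Ct values outside the plausible qPCR range
#' (0, 45) trigger a warning but are kept.
#'
#' @param path Wide delimited text file, first column `gene_id`.
#' @param sample_sheet Optional sample sheet (tibble or path); when given,
#'   attached as for [read_expression()] so grouped analyses can find
#'   sample groups.
#' @param delim Optional delimiter override.
#' @return A tibble (`gene_id` + sample columns); missing Ct are `NA`.
#' @export
read_ct <- function(path, sample_sheet = NULL, delim = NULL) {
  tbl <- read_delim_auto(path, delim, first_col = "gene_id")
  assert_wide_table(tbl, sprintf("Ct table %s", path), allow_na = TRUE)
  vals <- as.matrix(tbl[-1])
  out_of_range <- sum(vals <= 0 | vals >= 45, na.rm = TRUE)
  if (out_of_range > 0) {
    warn(sprintf("%d Ct value(s) outside (0, 45) in %s", out_of_range, path))
  }
  if (!is.null(sample_sheet)) {
    if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
    tbl <- attach_sample_sheet(tbl, sample_sheet)
  }
  tbl
}

#' Write a result table as TSV
#'
#' Deterministic output: column order as in the tibble, numeric columns
#' formatted to 6 significant digits, missing values written as `NA`.
#'
#' @param tbl Non-empty data frame.
#' @param path Output file path.
#' @return `tbl`, invisibly (so calls can sit inside a pipe).
#' @export
write_result_table <- function(tbl, path) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0) {
    abort("refusing to write an empty table")
  }
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, digits = 6)))
  readr::write_tsv(out, path, na = "NA")
  invisible(tbl)
}

# -- internals ---------------------------------------------------------------

# delimiter sniffed from the header line: tab wins if present, else comma
read_delim_auto <- function(path, delim = NULL, first_col = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  tbl <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE,
                           name_repair = "minimal")
  if (!is.null(first_col)) {
    names(tbl)[1] <- first_col
    tbl[[1]] <- as.character(tbl[[1]])
    for (j in seq(2, ncol(tbl))) {
      col <- tbl[[j]]
      if (!is.numeric(col)) {
        parsed <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(parsed) & !is.na(col))
        if (length(bad) > 0) {
          abort(sprintf("%s: unparseable cell at row %d (gene '%s'), column '%s'",
                        path, bad[1], tbl[[1]][bad[1]], names(tbl)[j]))
        }
        tbl[[j]] <- parsed
      }
    }
  }
  tbl
}
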